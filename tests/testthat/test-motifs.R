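test_that("base frequencies exclude N and sum to one", {
  u <- base_frequencies("ACGT")
  expect_equal(unname(u$F), rep(0.25, 4))
  expect_equal(u$T, 4)
  d <- base_frequencies("AAAA")
  expect_equal(unname(d$F["A"]), 1)
  expect_equal(sum(d$F), 1)
  n <- base_frequencies("AANCT")
  expect_equal(n$T, 4)
  expect_equal(unname(n$F["A"]), 0.5)
  expect_error(base_frequencies(character(0)), "empty")
})

test_that("expected occurrence implements the as-printed formula", {
  u <- list(F = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  # (0.25^5 / 5) * 10000
  expect_equal(expected_occurrence(u$F, 10000, "TTGAC"), 1.953125)
  f <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  # (0.3*0.2*0.3*0.2*0.2 / 5) * 1000 for TGACG
  expect_equal(expected_occurrence(f, 1000, "TGACG"), 0.144)
  # linear in T at fixed composition
  expect_equal(expected_occurrence(f, 2000, "TGACG"),
               2 * expected_occurrence(f, 1000, "TGACG"))
  # dropping the /N gives the textbook sliding-window expectation
  expect_equal(expected_occurrence(u$F, 10000, "TTGAC",
                                   standard_expectation = TRUE),
               0.25^5 * 10000)
  expect_error(expected_occurrence(u$F, 100, "TTGAX"), "A/C/G/T")
})

test_that("occurrences count overlaps and degenerate final positions", {
  expect_equal(count_occurrences("TTGACTTGAC", "TTGAC"), 2)
  expect_equal(count_occurrences("TGACGTGACC", "TGACG/C"), 2)
  expect_equal(count_occurrences("AAAAA", "TTGAC"), 0)
  expect_equal(count_occurrences("AAAA", "AA"), 3)  # sliding step 1
  expect_equal(expand_motif("TGACG/C"), c("TGACG", "TGACC"))
})

test_that("region-class statistics self-normalize and flag tiny classes", {
  withr::local_seed(31)
  proms <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
          collapse = ""), character(1))
  names(proms) <- paste0("G", 1:6)
  # one class covering each whole promoter behaves like the total
  whole <- data.frame(gene_id = names(proms), class = "NOR", start = 1,
                      end = 1000, stringsAsFactors = FALSE)
  st <- region_class_motif_stats(proms, whole, "TTGAC")
  expect_equal(st$relative[st$region_class == "NOR"], 1)
  expect_equal(st$corrected[st$region_class == "NOR"],
               st$corrected[st$region_class == "total_promoter"])

  # a class too short for the motif is flagged not-computable
  small <- data.frame(gene_id = "G1", class = "NFR", start = 1, end = 3,
                      stringsAsFactors = FALSE)
  st2 <- region_class_motif_stats(proms["G1"], small, "TTGAC")
  expect_false(st2$computable[st2$region_class == "NFR"])

  # zero observed: corrected 0 with a zero CI lower bound
  pure <- c(G1 = paste(rep("ACGT", 125), collapse = ""))  # no AAAC anywhere
  cl <- data.frame(gene_id = "G1", class = "NFR", start = 1, end = 500,
                   stringsAsFactors = FALSE)
  st3 <- region_class_motif_stats(pure, cl, "AAAC")
  nfr <- st3[st3$region_class == "NFR", ]
  expect_equal(nfr$observed, 0)
  expect_equal(nfr$corrected, 0)
  expect_equal(nfr$ci_low, 0)
})

test_that("motifs planted in NFR segments enrich NFR over NOR", {
  withr::local_seed(77)
  n <- 20
  proms <- character(n)
  classes <- list()
  for (i in 1:n) {
    s <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    # NOR = 1..500, NFR = 501..1000; plant 4 W-boxes only in the NFR half
    for (pos in seq(520, 980, length.out = 4))
      s[pos:(pos + 4)] <- c("T", "T", "G", "A", "C")
    proms[i] <- paste(s, collapse = "")
    classes[[i]] <- data.frame(gene_id = paste0("G", i),
                               class = c("NOR", "NFR"),
                               start = c(1, 501), end = c(500, 1000),
                               stringsAsFactors = FALSE)
  }
  names(proms) <- paste0("G", 1:n)
  st <- region_class_motif_stats(proms, do.call(rbind, classes), "TTGAC")
  rel <- setNames(st$relative, st$region_class)
  expect_gt(rel["NFR"], rel["NOR"])
})

test_that("corrected frequency converges to N on composition-matched DNA", {
  # the as-printed E under-counts the sliding-window expectation by the
  # factor N, so observed/E on i.i.d. sequence converges to N
  withr::local_seed(123)
  seqs <- vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""),
    character(1))
  bf <- base_frequencies(seqs)
  e <- expected_occurrence(bf$F, bf$T, "TGA")
  obs <- count_occurrences(seqs, "TGA")
  expect_equal(obs / e, 3, tolerance = 0.05)  # N = 3, Monte-Carlo slack
})

test_that("hexamer screen is symmetric, exhaustive, and finds plantings", {
  withr::local_seed(55)
  set_a <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
          collapse = ""), character(1))
  same <- hexamer_enrichment(set_a, set_a, set_a)
  expect_equal(nrow(same), 4096)
  expect_equal(anyDuplicated(same$hexamer), 0)
  expect_true(all(abs(same$oe_ratio - 1) < 1e-12))
  expect_true(all(abs(same$lift_ratio - 1) < 1e-12))
  expect_false(any(same$passes))

  # plant one hexamer ~10x more densely in the target set
  plant <- function(seqs, hex, every) {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      for (pos in seq(10, length(ch) - 6, by = every))
        ch[pos:(pos + 5)] <- strsplit(hex, "")[[1]]
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  target <- plant(set_a, "GTTCAA", 100)   # ~20 copies per 2-kb sequence
  contrast <- plant(set_a, "GTTCAA", 1000) # ~2 copies
  hx <- hexamer_enrichment(target, contrast, set_a)
  row <- hx[hx$hexamer == "GTTCAA", ]
  expect_true(row$passes)
  expect_gt(row$oe_ratio, 2)
  expect_gt(row$lift_ratio, 2)
  expect_error(hexamer_enrichment(character(0), set_a, set_a), "empty")
})
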