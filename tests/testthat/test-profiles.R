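test_that("the forty TSS windows follow the stated label convention", {
  w <- tss_windows()
  expect_equal(nrow(w), 40)
  expect_equal(w$label, c(seq(-975, -25, by = 50), seq(25, 975, by = 50)))
  # "-75 means -51 to -100": the -75 window covers offsets -100..-51
  w75 <- w[w$label == -75, ]
  expect_equal(c(w75$rel_start, w75$rel_end), c(-100, -51))
  # TSS base (offset 0) belongs to the first downstream window
  w25 <- w[w$label == 25, ]
  expect_equal(c(w25$rel_start, w25$rel_end), c(0, 49))
  expect_true(all(w$rel_end - w$rel_start + 1 == 50))
})

test_that("window occupancy needs >= 25 continuous bp from one region", {
  g <- tiny_gene(5000, "forward")
  # +25 window covers genomic 5000..5049
  expect_equal(unname(window_occupancy(g, regions_df(5010, 5039))[21]), 1L)
  expect_equal(unname(window_occupancy(g, regions_df(5010, 5033))[21]), 0L)
  expect_equal(unname(window_occupancy(g, regions_df(5010, 5034))[21]), 1L)
  # two 15-bp fragments summing to 30 bp do not count
  split2 <- regions_df(c(5000, 5020), c(5014, 5034))
  expect_equal(unname(window_occupancy(g, split2)[21]), 0L)
  # a regions index missing the gene's chromosome is a lookup error
  expect_error(window_occupancy(g, list(chr9 = regions_df(1, 100))),
               "absent")
})

test_that("occupancy is strand-mirrored and local to the +/-1000 span", {
  withr::local_seed(5)
  tssf <- 50000
  reg <- random_region_set(15, max_pos = 60000)
  fwd <- window_occupancy(tiny_gene(tssf, "forward"), reg)
  # reflect the regions about the TSS: position p -> 2*tss - p
  refl <- data.frame(chrom = "chr1", start = 2 * tssf - reg$end,
                     end = 2 * tssf - reg$start, stringsAsFactors = FALSE)
  rev <- window_occupancy(tiny_gene(tssf, "reverse"), refl)
  expect_identical(fwd, rev)

  # regions outside the +/-1000 bp span never matter
  far <- rbind(reg, regions_df(c(10, 80000), c(200, 80500)))
  expect_identical(window_occupancy(tiny_gene(tssf, "forward"), far), fwd)
})

test_that("group profiles average genes after overlap filtering", {
  g1 <- tiny_gene(5000, "forward", gene_id = "G1")
  g2 <- tiny_gene(50000, "forward", gene_id = "G2")
  genes <- rbind(g1, g2)
  full <- regions_df(3900, 6100)  # covers g1's whole span, g2 empty
  prof <- group_coverage_profile(genes, full)
  expect_equal(unname(prof$mean), rep(0.5, 40))
  expect_equal(prof$n_genes, 2)
  none <- group_coverage_profile(genes, regions_df(integer(0), integer(0)))
  expect_equal(unname(none$mean), rep(0, 40))

  # overlapping +/-1000 spans drop both members of the pair
  g3 <- tiny_gene(5600, "forward", gene_id = "G3")
  kept <- filter_overlapping_genes(rbind(g1, g2, g3))
  expect_equal(kept$gene_id, "G2")
  expect_error(group_coverage_profile(rbind(g1, g3), full), "empty group")
})

test_that("remodeling percentages follow the either-condition denominator", {
  genes <- do.call(rbind, lapply(1:4, function(i)
    tiny_gene(10000 * i + 5000, "forward", gene_id = paste0("G", i))))
  win <- regions_df(integer(0), integer(0))
  occupied <- function(tss) regions_df(tss, tss + 49)  # fills window +25
  # genes 1,2: occupied control only; gene 3: both; gene 4: neither
  ctrl <- do.call(rbind, lapply(genes$tss[1:3], occupied))
  trt <- occupied(genes$tss[3])
  rp <- remodeling_percent_profile(genes, ctrl, trt)
  w <- rp[rp$label == 25, ]
  expect_equal(w$denominator, 3)
  expect_equal(w$depletion_pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(w$enrichment_pct, 0)
  # untouched windows have no denominator
  expect_true(is.na(rp$depletion_pct[rp$label == 975]))

  # identical occupancy on both sides: both percentages zero
  same <- remodeling_percent_profile(genes, ctrl, ctrl)
  expect_true(all(same$depletion_pct[!is.na(same$depletion_pct)] == 0))
  # total depletion: every occupied gene flips 1 -> 0
  allgone <- remodeling_percent_profile(genes, ctrl, win)
  expect_equal(allgone$depletion_pct[allgone$label == 25], 100)
})

test_that("150-bp block t-tests behave at the boundaries", {
  flat <- matrix(0.5, nrow = 3, ncol = 40)
  res <- window_significance(flat, flat)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_equal(nrow(res), 38)  # 40 windows, block of 3, step 1

  # strong separation with tiny within-group spread
  withr::local_seed(8)
  a <- matrix(0.9 + rnorm(120, sd = 0.01), nrow = 3)
  b <- matrix(0.1 + rnorm(120, sd = 0.01), nrow = 3)
  res2 <- window_significance(a, b)
  expect_true(all(res2$q <= 0.05))
  expect_error(window_significance(flat[1, , drop = FALSE], flat),
               "two replicates")
  # sliding by a full block is available
  expect_equal(nrow(window_significance(flat, flat, step = 3)), 13)
})
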