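test_that("runs of qualifying probes become regions with tile extents", {
  pos <- c(1000, 1035, 1070, 1105)
  # per-probe replicate minima 0.1, 0.0, 0.5, 0.2: all qualify at >= 0.0
  vals <- cbind(c(0.1, 0.0, 0.5, 0.2), c(0.4, 0.3, 0.8, 0.9),
                c(0.2, 0.1, 0.6, 0.3))
  reg <- call_regions(make_track(pos, vals), 0.0)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(1000, 1139))  # 4 x 35 = 140 bp
  expect_equal(reg$type, "distinct")
  expect_equal(reg$n_probes, 4L)

  # a 5th qualifying probe tips the span into the fuzzy band
  reg5 <- call_regions(make_track(c(pos, 1140), rbind(vals, 0.2)), 0.0)
  expect_equal(c(reg5$start, reg5$end), c(1000, 1174))  # 5 x 35 = 175 bp
  expect_equal(reg5$type, "fuzzy")

  # three qualifying probes emit nothing
  expect_equal(nrow(call_regions(make_track(pos[1:3], vals[1:3, ]), 0.0)), 0)

  # a probe below threshold in one replicate breaks the run
  vals2 <- vals
  vals2[2, 2] <- -0.5
  expect_equal(nrow(call_regions(make_track(pos, vals2), 0.0)), 0)
})

test_that("runs break across tiling gaps and sub-131-bp spans are logged", {
  # gap of 120 bp between probes 2 and 3 splits an otherwise 6-probe run
  pos <- c(1000, 1035, 1155, 1190, 1225, 1260)
  vals <- matrix(1, nrow = 6, ncol = 3)
  reg <- call_regions(make_track(pos, vals), 0.0)
  expect_equal(nrow(reg), 1)  # only the 4-probe right-hand run survives
  expect_equal(c(reg$start, reg$end), c(1155, 1294))

  # 4 probes at 20-bp pitch span 80 bp < 131: discarded but counted
  tight <- call_regions(make_track(c(100, 120, 140, 160),
                                   matrix(1, 4, 3)), 0.0, probe_pitch = 20)
  expect_equal(nrow(tight), 0)
  expect_equal(attr(tight, "discarded"), 1L)

  expect_equal(nrow(call_regions(make_track(integer(0),
                                            matrix(0, 0, 3)), 0.0)), 0)
  unsorted <- make_track(c(100, 200), matrix(0, 2, 3))
  unsorted$position <- c(200L, 100L)
  expect_error(call_regions(unsorted, 0.0), "increasing")
})

test_that("called base sets match a brute-force per-position oracle", {
  withr::local_seed(42)
  for (case in 1:200) {
    tr <- random_track(sample(5:200, 1))
    thr <- sample(stringency_levels(), 1)
    reg <- call_regions(tr, thr)
    expect_identical(sort(region_bases_set(reg)),
                     sort(oracle_called_bases(tr, thr)))
  }
})

test_that("coverage is monotone across the stringency sweep", {
  withr::local_seed(7)
  levels <- stringency_levels()  # strictly decreasing
  for (case in 1:20) {
    tr <- random_track(150)
    sets <- lapply(levels, function(l) region_bases_set(call_regions(tr, l)))
    for (i in seq_len(length(levels) - 1)) {
      # stricter threshold's bases are a subset of the looser one's
      expect_length(setdiff(sets[[i]], sets[[i + 1]]), 0)
    }
  }
})

test_that("calling is deterministic under row shuffling and type-disjoint", {
  withr::local_seed(13)
  tr <- random_track(120)
  reg <- call_regions(tr, -1.0)
  shuffled <- tr[sample.int(nrow(tr)), ]
  resorted <- probe_track(tr$chrom[1], shuffled$position,
                          probe_values(shuffled))
  expect_equal(call_regions(resorted, -1.0), reg, ignore_attr = TRUE)

  distinct <- region_bases_set(reg[reg$type == "distinct", ])
  fuzzy <- region_bases_set(reg[reg$type == "fuzzy", ])
  expect_length(intersect(distinct, fuzzy), 0)
})

test_that("the stringency sweep tabulates one dataset per grid cell", {
  withr::local_seed(3)
  five <- paste0("chr", 1:5)
  ctrl <- lapply(five, function(ch) random_track(40, chrom = ch))
  names(ctrl) <- five
  trt <- lapply(five, function(ch) random_track(40, chrom = ch))
  names(trt) <- five
  sw <- stringency_sweep(ctrl, trt)
  expect_equal(nrow(sw$summary), 140)  # 7 x 2 x 2 x 5
  # bases consistency between the region list and the summary
  key <- paste(sw$regions$stringency, sw$regions$condition,
               sw$regions$type, sw$regions$chrom)
  expect_equal(sum(sw$summary$n_regions), nrow(sw$regions))
  expect_equal(sum(sw$summary$bases),
               sum(sw$regions$end - sw$regions$start + 1))

  one <- stringency_sweep(ctrl["chr1"], trt["chr1"], levels = -1.0)
  expect_equal(nrow(one$summary), 4)  # 1 level x 2 conditions x 2 types
  expect_equal(nrow(one$summary[one$summary$condition == "control", ]), 2)
  expect_error(stringency_sweep(ctrl["chr1"], trt["chr2"]),
               "different chromosome sets")
})

test_that("bp-per-nucleosome divides chromosome size by region count", {
  reg10 <- regions_df(seq(1, 10 * 200, by = 200), seq(140, 10 * 200, by = 200))
  expect_equal(coverage_per_nucleosome(10000, reg10), 1000)
  reg1000 <- regions_df(seq(1, 1000 * 300, by = 300),
                        seq(140, 1000 * 300, by = 300))
  expect_equal(coverage_per_nucleosome(346000, reg1000), 346)
  expect_warning(v <- coverage_per_nucleosome(1000, regions_df(integer(0),
                                                               integer(0))),
                 "undefined")
  expect_identical(v, Inf)
  expect_error(coverage_per_nucleosome(0, reg10), "positive")
  # literal per-base variant
  expect_equal(coverage_per_nucleosome(10000, regions_df(1, 1000),
                                       per_base = TRUE), 10)
})
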