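test_that("config validation catches impossible worlds", {
  expect_error(simulation_config(probe_pitch = 0), "probe_pitch")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(group_fractions = c(SI = 0.8, SR = 0.4)),
               "sum to <= 1")
  # too many genes for the chromosome: planted regions exceed capacity
  expect_error(simulation_config(n_genes = 100, n_chromosomes = 1,
                                 chrom_length = 100000), "capacity")
})

test_that("the same seed gives checksum-identical outputs", {
  cfg <- simulation_config(seed = 9, n_genes = 8, n_chromosomes = 1,
                           chrom_length = 60000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_dataset(simulate_dataset(cfg), d1)
  p2 <- write_dataset(simulate_dataset(cfg), d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed changes the tracks
  cfg2 <- simulation_config(seed = 10, n_genes = 8, n_chromosomes = 1,
                            chrom_length = 60000)
  d3 <- withr::local_tempdir()
  p3 <- write_dataset(simulate_dataset(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(p1["control"])),
                         unname(tools::md5sum(p3["control"]))))
})

test_that("noise-free plantings are recovered exactly at any level", {
  cfg <- simulation_config(seed = 2, n_genes = 8, n_chromosomes = 1,
                           chrom_length = 60000, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  for (cd in c("control", "treated")) {
    truth <- merge_regions(
      sim$truth$regions[sim$truth$regions$condition == cd, ])
    called <- merge_regions(call_regions_all(sim$tracks[[cd]], -1.0,
                                             condition = cd))
    expect_equal(called[, c("chrom", "start", "end")],
                 truth[, c("chrom", "start", "end")])
    # background never qualifies even at the loosest level
    loose <- merge_regions(call_regions_all(sim$tracks[[cd]], -2.0,
                                            condition = cd))
    expect_equal(loose[, c("chrom", "start", "end")],
                 truth[, c("chrom", "start", "end")])
  }
})

test_that("class bookkeeping is exact and subclasses only on SI/SR", {
  cfg <- simulation_config(seed = 3, n_genes = 100, n_chromosomes = 2,
                           chrom_length = 300000)
  sim <- simulate_dataset(cfg)
  tab <- table(sim$truth$gene_classes$class)
  expect_equal(unname(tab[c("SI", "SR", "CON", "SIL")]),
               rep(25L, 4), ignore_attr = TRUE)
  gc <- sim$truth$gene_classes
  expect_true(all(is.na(gc$subclass[!gc$class %in% c("SI", "SR")])))
  expect_true(all(gc$subclass[gc$class %in% c("SI", "SR")] %in%
                    c("ND", "NI")))
})

test_that("planted expression has the stated interaction structure", {
  cfg <- simulation_config(seed = 4, n_genes = 16, n_chromosomes = 1,
                           chrom_length = 120000, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  gc <- sim$truth$gene_classes
  for (i in seq_len(nrow(gc))) {
    ge <- sim$expression[sim$expression$gene_id == gc$gene_id[i], ]
    an <- anova_two_way(ge$value, ge$genotype, ge$treatment)
    if (identical(gc$subclass[i], "ND")) {
      expect_gt(an$interaction$ss, 0)
    } else if (identical(gc$subclass[i], "NI")) {
      expect_equal(an$interaction$ss, 0)  # additive by construction
    }
  }
})

test_that("SI promoters flip occupied-to-free and SR the reverse", {
  cfg <- simulation_config(seed = 6, n_genes = 16, n_chromosomes = 1,
                           chrom_length = 120000, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  gc <- sim$truth$gene_classes
  reg_c <- call_regions_all(sim$tracks$control, -1.0)
  reg_t <- call_regions_all(sim$tracks$treated, -1.0)
  for (i in seq_len(nrow(gc))) {
    g <- sim$genes[sim$genes$gene_id == gc$gene_id[i], ]
    occ_c <- window_occupancy(g, reg_c)["-75"]
    occ_t <- window_occupancy(g, reg_t)["-75"]
    want <- switch(gc$class[i], SI = c(1L, 0L), SR = c(0L, 1L),
                   CON = c(1L, 1L), SIL = c(0L, 0L), NULL)
    if (!is.null(want))
      expect_equal(unname(c(occ_c, occ_t)), want,
                   label = paste(gc$gene_id[i], gc$class[i]))
  }
})

test_that("planted motifs land in truth-NFR promoter segments", {
  cfg <- simulation_config(seed = 12, n_genes = 16, n_chromosomes = 1,
                           chrom_length = 120000)
  sim <- simulate_dataset(cfg)
  tm <- sim$truth$motifs
  expect_gt(nrow(tm), 0)
  for (i in seq_len(nrow(tm))) {
    seg <- sim$promoter_classes[
      sim$promoter_classes$gene_id == tm$gene_id[i] &
        sim$promoter_classes$class == "NFR", ]
    inside <- any(seg$start <= tm$start[i] &
                    tm$start[i] + nchar(tm$motif[i]) - 1 <= seg$end)
    expect_true(inside, label = paste("motif", i, "in NFR"))
    # the motif text is really in the sequence
    expect_equal(substr(sim$promoters[[tm$gene_id[i]]], tm$start[i],
                        tm$start[i] + nchar(tm$motif[i]) - 1), tm$motif[i])
  }
})
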