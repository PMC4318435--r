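# Synthetic-data generator with planted ground truth.
#
# Emulates the study design: tiling-array probe tracks at 35-bp pitch with
# three replicates under two conditions (control, SA-treated), a gene
# coordinate table, a 2x2 (genotype x treatment) log2 expression matrix,
# and promoter FASTA. Nucleosomes are planted as runs of consecutive probe
# tiles at nucleosome_signal_mean with i.i.d. Gaussian noise per probe per
# replicate over a background_mean floor; SA-induced (SI) genes carry an
# occupied-to-free promoter transition between conditions, SA-repressed
# (SR) genes the reverse, constitutive (CON) genes a stable promoter
# nucleosome, silent (SIL) genes a promoter free under both conditions.
# W-box/TGA motifs are planted preferentially in truth nucleosome-free
# promoter segments of the SA-responsive classes.

#' Build and validate a simulation configuration
#'
#' Defaults state the emulated world: 35-bp probe pitch (the array's
#' resolution), 3 replicates, background at -3.0 log2 and nucleosome signal
#' at +0.5 so the seven stringency thresholds (0.0 .. -2.0) span the
#' planted signal range, and a +/-3 log2 treatment effect comfortably past
#' the +/-2 classification cutoff.
#'
#' @param seed RNG seed (integer).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param probe_pitch probe start-to-start distance (bp).
#' @param probe_length probe length (bp), metadata only.
#' @param replicate_count replicates per condition (and per expression cell).
#' @param noise_sd Gaussian noise sd, log2 units (probe values and
#'   expression).
#' @param nucleosome_signal_mean,background_mean planted means, log2 units.
#' @param n_genes total genes across chromosomes.
#' @param group_fractions named fractions for SI/SR/CON/SIL (sum <= 1;
#'   leftovers become class `"none"`).
#' @param nd_fraction fraction of SI and of SR genes made NPR1-dependent.
#' @param effect_size_log2fc treatment effect for SI/SR expression.
#' @param motif_plant_rate planted W-box/TGA occurrences per kb of truth
#'   nucleosome-free promoter sequence in SI/SR genes.
#' @return validated config list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chromosomes = 2,
                              chrom_length = 200000, probe_pitch = 35,
                              probe_length = 25, replicate_count = 3,
                              noise_sd = 0.3,
                              nucleosome_signal_mean = 0.5,
                              background_mean = -3.0, n_genes = 40,
                              group_fractions = c(SI = 0.25, SR = 0.25,
                                                  CON = 0.25, SIL = 0.25),
                              nd_fraction = 0.5, effect_size_log2fc = 3,
                              motif_plant_rate = 2) {
  if (probe_pitch < 1) stop("probe_pitch must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (replicate_count < 1) stop("replicate_count must be >= 1")
  if (sum(group_fractions) > 1 + 1e-9)
    stop("group fractions must sum to <= 1")
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, probe_pitch = probe_pitch,
              probe_length = probe_length,
              replicate_count = replicate_count, noise_sd = noise_sd,
              nucleosome_signal_mean = nucleosome_signal_mean,
              background_mean = background_mean, n_genes = n_genes,
              group_fractions = group_fractions,
              nd_fraction = nd_fraction,
              effect_size_log2fc = effect_size_log2fc,
              motif_plant_rate = motif_plant_rate)
  genes_per_chrom <- ceiling(n_genes / n_chromosomes)
  slot <- floor(chrom_length / max(1, genes_per_chrom))
  if (slot < 5000)
    stop("planted regions exceed chromosome capacity: ",
         genes_per_chrom, " genes on a ", chrom_length,
         " bp chromosome leaves only ", slot,
         " bp per gene (>= 5000 required)")
  class(cfg) <- "simulation_config"
  cfg
}

# class counts by largest-remainder apportionment (exact bookkeeping)
class_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)  # includes the "none" share
  planned <- round(sum(fractions) * n) - sum(counts)
  if (planned > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(planned)]] <- counts[o[seq_len(planned)]] + 1
  }
  counts
}

# run of n_tiles consecutive probe tiles starting at the first probe at or
# after pos; interval [first start, last start + pitch - 1]
run_at <- function(probe_pos, pos, n_tiles, pitch) {
  i <- which(probe_pos >= pos)[1]
  if (is.na(i) || i + n_tiles - 1 > length(probe_pos))
    stop("planted run exceeds the probe grid")
  c(probe_pos[i], probe_pos[i + n_tiles - 1] + pitch - 1)
}

# all probe tiles fully inside [lo, hi]; interval covering them
run_in <- function(probe_pos, lo, hi, pitch, min_tiles = 4) {
  i <- which(probe_pos >= lo & probe_pos + pitch - 1 <= hi)
  if (length(i) < min_tiles)
    stop("window [", lo, ",", hi, "] holds fewer than ", min_tiles,
         " probe tiles")
  c(probe_pos[i[1]], probe_pos[i[length(i)]] + pitch - 1)
}

#' Simulate a complete dataset with planted ground truth
#'
#' Identical seeds give bit-identical outputs; all draws are ordered
#' deterministically (chromosome, then position, then replicate).
#'
#' @param config a [simulation_config()].
#' @return list with `tracks` (`$control`/`$treated`, named per-chromosome
#'   `probe_track` lists), `genes` (gene table), `expression` (long-format
#'   matrix), `promoters` (named sequences), `promoter_classes` (truth
#'   NOR/NFR/remodeled partition of each promoter, promoter-relative
#'   1..1000 coordinates), `truth` (list: `regions` with per-condition
#'   planted intervals, `gene_classes`, `motifs`) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pitch <- config$probe_pitch
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  probe_pos <- lapply(chroms, function(ch)
    seq(1L, config$chrom_length - pitch + 1L, by = pitch))
  names(probe_pos) <- chroms

  ## --- genes -------------------------------------------------------------
  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  genes <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    slot <- floor(config$chrom_length / k)
    for (i in seq_len(k)) {
      gid <- gid + 1L
      tss <- (i - 1L) * slot + floor(slot / 2)
      strand <- if (gid %% 2 == 1) "forward" else "reverse"
      sgn <- if (strand == "forward") 1L else -1L
      genes[[gid]] <- data.frame(
        gene_id = sprintf("G%04d", gid), chrom = chroms[ci],
        strand = strand, tss = tss,
        start_codon = tss + sgn * 250L, stop_codon = tss + sgn * 1250L,
        mrna_end = tss + sgn * 1450L, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)

  ## --- classes -----------------------------------------------------------
  counts <- class_counts(config$group_fractions, nrow(genes))
  labels <- c(rep(names(counts), counts),
              rep("none", nrow(genes) - sum(counts)))
  cls <- labels[sample.int(nrow(genes))]
  subclass <- rep(NA_character_, nrow(genes))
  for (cl in c("SI", "SR")) {
    idx <- which(cls == cl)
    n_nd <- round(config$nd_fraction * length(idx))
    nd <- idx[sample.int(length(idx))][seq_len(n_nd)]
    subclass[idx] <- "NI"
    subclass[nd] <- "ND"
  }
  gene_classes <- data.frame(gene_id = genes$gene_id, class = cls,
                             subclass = subclass, stringsAsFactors = FALSE)

  ## --- planted nucleosome truth ------------------------------------------
  truth_regions <- list()
  plant <- function(chrom, interval, conditions, source, gene_id = NA) {
    for (cd in conditions)
      truth_regions[[length(truth_regions) + 1L]] <<- data.frame(
        chrom = chrom, start = interval[1], end = interval[2],
        condition = cd, source = source, gene_id = gene_id,
        stringsAsFactors = FALSE)
  }
  both <- c("control", "treated")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pp <- probe_pos[[g$chrom]]
    sgn <- if (g$strand == "forward") 1L else -1L
    # gene-body nucleosome (fuzzy-scale), stable under treatment
    body <- sort(c(g$tss + sgn * 300L, g$tss + sgn * 540L))
    plant(g$chrom, run_in(pp, body[1], body[2], pitch), both,
          "gene_body", g$gene_id)
    # promoter nucleosome over the -215..0 TSS window, class-dependent
    prom <- sort(c(g$tss + sgn * -215L, g$tss))
    prom_iv <- run_in(pp, prom[1], prom[2], pitch)
    conds <- switch(cls[i], SI = "control", SR = "treated",
                    CON = both, SIL = character(0), character(0))
    if (length(conds) > 0)
      plant(g$chrom, prom_iv, conds, "promoter", g$gene_id)
  }
  # intergenic plantings at slot boundaries: a mix of distinct (4-tile) and
  # fuzzy (6-tile) runs, stable or condition-specific
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k < 2) next
    slot <- floor(config$chrom_length / k)
    for (b in seq_len(k - 1)) {
      pos <- b * slot + 300L
      if (b %% 2 == 1) {
        plant(chroms[ci], run_at(probe_pos[[ci]], pos, 4, pitch), both,
              "intergenic_distinct")
      } else if (b %% 4 == 2) {
        plant(chroms[ci], run_at(probe_pos[[ci]], pos, 6, pitch),
              "control", "intergenic_fuzzy")
      } else {
        plant(chroms[ci], run_at(probe_pos[[ci]], pos, 6, pitch),
              "treated", "intergenic_fuzzy")
      }
    }
  }
  truth_regions <- do.call(rbind, c(truth_regions,
                                    list(make.row.names = FALSE)))

  ## --- probe tracks -------------------------------------------------------
  tracks <- list()
  for (cd in both) {
    tr <- truth_regions[truth_regions$condition == cd, ]
    cond_tracks <- list()
    for (ch in chroms) {
      pp <- probe_pos[[ch]]
      occ <- tr[tr$chrom == ch, ]
      signal <- rep(FALSE, length(pp))
      if (nrow(occ) > 0) {
        tiles <- IRanges::IRanges(pp, pp + pitch - 1L)
        planted <- IRanges::reduce(IRanges::IRanges(occ$start, occ$end))
        hits <- IRanges::findOverlaps(tiles, planted, type = "within")
        signal[unique(S4Vectors::queryHits(hits))] <- TRUE
      }
      mu <- ifelse(signal, config$nucleosome_signal_mean,
                   config$background_mean)
      vals <- matrix(stats::rnorm(length(pp) * config$replicate_count,
                                  mean = mu, sd = config$noise_sd),
                     nrow = length(pp), ncol = config$replicate_count)
      cond_tracks[[ch]] <- probe_track(ch, pp, vals)
    }
    tracks[[cd]] <- cond_tracks
  }
  names(tracks) <- c("control", "treated")

  ## --- expression ---------------------------------------------------------
  eff <- config$effect_size_log2fc
  cell_means <- function(class, sub) {
    # rows: Col0-control, Col0-SA, npr1-control, npr1-SA
    switch(class,
      SI = if (identical(sub, "ND")) c(1, 1 + eff, 1, 1)
           else c(1, 1 + eff, 1, 1 + eff),
      SR = if (identical(sub, "ND")) c(1 + eff, 1, 1 + eff, 1 + eff)
           else c(1 + eff, 1, 1 + eff, 1),
      CON = rep(5, 4), SIL = rep(-1, 4), rep(1.5, 4))
  }
  design <- data.frame(genotype = c("Col0", "Col0", "npr1", "npr1"),
                       treatment = c("control", "SA", "control", "SA"),
                       stringsAsFactors = FALSE)
  expr <- list()
  for (i in seq_len(nrow(genes))) {
    mu <- cell_means(cls[i], subclass[i])
    for (j in seq_len(4)) {
      v <- mu[j] + stats::rnorm(config$replicate_count,
                                sd = config$noise_sd)
      expr[[length(expr) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], genotype = design$genotype[j],
        treatment = design$treatment[j],
        replicate = seq_len(config$replicate_count), value = v,
        stringsAsFactors = FALSE)
    }
  }
  expr <- do.call(rbind, c(expr, list(make.row.names = FALSE)))

  ## --- promoters and planted motifs ---------------------------------------
  promoters <- character(nrow(genes))
  names(promoters) <- genes$gene_id
  prom_classes <- list()
  truth_motifs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq_chars <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    pr <- promoter_interval(g, 1000, chrom_length = config$chrom_length)
    # promoter-relative coordinates: position 1000 abuts the TSS
    to_prom <- function(gs, ge) {
      if (g$strand == "forward") {
        c(max(1, gs - pr$start + 1), min(1000, ge - pr$start + 1))
      } else {
        c(max(1, pr$end - ge + 1), min(1000, pr$end - gs + 1))
      }
    }
    occ <- matrix(FALSE, nrow = 1000, ncol = 2,
                  dimnames = list(NULL, both))
    tr <- truth_regions[truth_regions$chrom == g$chrom &
                          truth_regions$end >= pr$start &
                          truth_regions$start <= pr$end, ]
    for (k in seq_len(nrow(tr))) {
      span <- to_prom(max(tr$start[k], pr$start), min(tr$end[k], pr$end))
      occ[span[1]:span[2], tr$condition[k]] <- TRUE
    }
    lab <- ifelse(occ[, 1] & occ[, 2], "NOR",
           ifelse(occ[, 1] | occ[, 2], "remodeled", "NFR"))
    runs <- rle(lab)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    prom_classes[[i]] <- data.frame(gene_id = g$gene_id,
                                    class = runs$values, start = starts,
                                    end = ends, stringsAsFactors = FALSE)
    # plant motifs in NFR segments of the SA-responsive classes
    if (cls[i] %in% c("SI", "SR") && config$motif_plant_rate > 0) {
      nfr <- prom_classes[[i]][prom_classes[[i]]$class == "NFR" &
        prom_classes[[i]]$end - prom_classes[[i]]$start + 1 >= 10, ]
      nfr_len <- sum(nfr$end - nfr$start + 1)
      n_plant <- max(1, round(config$motif_plant_rate * nfr_len / 1000))
      motif <- if (cls[i] == "SI") "TTGAC" else "TGACG"
      placed <- integer(0)
      for (p in seq_len(n_plant)) {
        seg <- nfr[sample.int(nrow(nfr), 1), ]
        pos <- seg$start +
          sample.int(seg$end - seg$start + 1 - nchar(motif) + 1, 1) - 1
        if (any(abs(placed - pos) < nchar(motif) + 1)) next
        seq_chars[pos:(pos + nchar(motif) - 1)] <-
          strsplit(motif, "")[[1]]
        placed <- c(placed, pos)
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          gene_id = g$gene_id, start = pos, motif = motif,
          region_class = "NFR", stringsAsFactors = FALSE)
      }
    }
    promoters[i] <- paste(seq_chars, collapse = "")
  }
  prom_classes <- do.call(rbind, c(prom_classes,
                                   list(make.row.names = FALSE)))
  truth_motifs <- if (length(truth_motifs) > 0)
    do.call(rbind, c(truth_motifs, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(), start = integer(),
                  motif = character(), region_class = character(),
                  stringsAsFactors = FALSE)

  list(tracks = tracks, genes = genes, expression = expr,
       promoters = promoters, promoter_classes = prom_classes,
       truth = list(regions = truth_regions, gene_classes = gene_classes,
                    motifs = truth_motifs),
       config = config)
}

#' Write a simulated dataset to a directory in the interchange formats
#'
#' Emits `control.tsv`/`treated.tsv` probe tracks, `genes.tsv`,
#' `expression.tsv`, `promoters.fa`, and the truth tables
#' (`truth_regions.tsv`, `truth_classes.tsv`, `truth_motifs.tsv`,
#' `promoter_classes.tsv`).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    control = file.path(dir, "control.tsv"),
    treated = file.path(dir, "treated.tsv"),
    genes = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    truth_regions = file.path(dir, "truth_regions.tsv"),
    truth_classes = file.path(dir, "truth_classes.tsv"),
    truth_motifs = file.path(dir, "truth_motifs.tsv"),
    promoter_classes = file.path(dir, "promoter_classes.tsv"))
  write_probe_track(sim$tracks$control, paths["control"])
  write_probe_track(sim$tracks$treated, paths["treated"])
  write_gene_table(sim$genes, paths["genes"])
  write_expression(sim$expression, paths["expression"])
  write_promoter_fasta(sim$promoters, paths["promoters"])
  utils::write.table(sim$truth$regions, paths["truth_regions"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_classes, paths["truth_classes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$motifs, paths["truth_motifs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$promoter_classes, paths["promoter_classes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
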