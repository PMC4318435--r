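# Independent brute-force oracles and small fixture builders. These stay
# deliberately dumb: explicit loops and per-base scans, never sharing code
# with the implementation they check.

make_track <- function(positions, values, chrom = "chr1") {
  probe_track(chrom, positions, as.matrix(values))
}

# random probe track: mostly regular pitch with occasional larger gaps
random_track <- function(n_probes, n_rep = 3, pitch = 35,
                         chrom = "chr1") {
  gaps <- sample(c(pitch, pitch, pitch, pitch, 70, 120), n_probes,
                 replace = TRUE)
  pos <- cumsum(gaps) + 100
  vals <- matrix(stats::rnorm(n_probes * n_rep, mean = -1, sd = 1.2),
                 nrow = n_probes)
  make_track(pos, vals, chrom)
}

# brute-force caller: per-probe, per-replicate qualification checked one
# value at a time; runs accumulated by explicit forward scan with the gap
# rule; returns the set of covered bases
oracle_called_bases <- function(track, threshold, pitch = 35,
                                max_gap = 50, min_run = 4) {
  vals <- probe_values(track)
  n <- nrow(track)
  qual <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (r in seq_len(ncol(vals))) if (!(vals[i, r] >= threshold)) ok <- FALSE
    qual[i] <- ok
  }
  bases <- integer(0)
  i <- 1
  while (i <= n) {
    if (!qual[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= n && qual[j + 1] &&
           track$position[j + 1] - track$position[j] <= max_gap) j <- j + 1
    if (j - i + 1 >= min_run) {
      span_start <- track$position[i]
      span_end <- track$position[j] + pitch - 1
      if (span_end - span_start + 1 >= 131)
        bases <- c(bases, span_start:span_end)
    }
    i <- j + 1
  }
  bases
}

region_bases_set_by_chrom <- function(regions) {
  lapply(split(regions, regions$chrom), region_bases_set)
}

region_bases_set <- function(regions) {
  if (nrow(regions) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(regions)),
                function(i) regions$start[i]:regions$end[i]),
         use.names = FALSE)
}

# per-base membership partition of two single-chromosome region sets
oracle_partition <- function(ctrl, trt, max_pos = 1e4) {
  in_c <- rep(FALSE, max_pos); in_t <- rep(FALSE, max_pos)
  for (i in seq_len(nrow(ctrl))) in_c[ctrl$start[i]:ctrl$end[i]] <- TRUE
  for (i in seq_len(nrow(trt))) in_t[trt$start[i]:trt$end[i]] <- TRUE
  list(depleted = sum(in_c & !in_t), enriched = sum(!in_c & in_t),
       common = sum(in_c & in_t), total = sum(in_c | in_t))
}

random_region_set <- function(n, max_pos = 1e4, chrom = "chr1") {
  start <- sort(sample.int(max_pos - 200, n))
  end <- pmin(start + sample.int(150, n), max_pos)
  merge_regions(data.frame(chrom = chrom, start = start, end = end,
                           stringsAsFactors = FALSE))
}

# double-loop Benjamini-Hochberg: q_i = min over ranks k with
# p_(k) >= p_i of m * p_(k) / k
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, m * ps[k] / k)
    q[o[i]] <- min(1, best)
  }
  q
}

# ANOVA oracle through R's own linear-model machinery
oracle_anova <- function(value, genotype, treatment) {
  fit <- summary(stats::aov(value ~ g * t,
                            data = data.frame(value = value,
                                              g = factor(genotype),
                                              t = factor(treatment))))[[1]]
  list(F = fit[["F value"]][1:3], p = fit[["Pr(>F)"]][1:3],
       ss = fit[["Sum Sq"]])
}

tiny_gene <- function(tss = 50000, strand = "forward", chrom = "chr1",
                      gene_id = "G1") {
  sgn <- if (strand == "forward") 1 else -1
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
             start_codon = tss + sgn * 200, stop_codon = tss + sgn * 1200,
             mrna_end = tss + sgn * 1400, stringsAsFactors = FALSE)
}

regions_df <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length.out = length(start)),
             start = start, end = end, stringsAsFactors = FALSE)
}
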