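# TSS-anchored occupancy profiles: per-gene binary occupancy over forty
# 50-bp windows spanning -1000..+1000 bp from the TSS, group-averaged
# coverage, per-window remodeling percentages, and 150-bp-block t-tests.
#
# Window convention: upstream window k covers TSS-relative offsets
# [-50k, -50k+49] and is labeled -(50k-25) (so -75 means -100..-51);
# downstream window k covers [50(k-1), 50k-1] and is labeled 50k-25, with
# the TSS base (offset 0) in window +25.

#' The forty 50-bp TSS-relative windows
#' @return data.frame with `label` (window center), `rel_start`, `rel_end`
#'   (TSS-relative offsets, inclusive), ordered -975 .. +975.
#' @export
tss_windows <- function() {
  k <- 20:1
  up <- data.frame(label = -(50 * k - 25), rel_start = -50L * k,
                   rel_end = -50L * k + 49L)
  k <- 1:20
  down <- data.frame(label = 50 * k - 25, rel_start = 50L * (k - 1L),
                     rel_end = 50L * k - 1L)
  rbind(up, down)
}

#' Binary nucleosome occupancy of one gene's forty TSS windows
#'
#' A window counts as occupied (1) iff a single called region covers at
#' least `min_stretch` consecutive bp within it; two disjoint fragments
#' summing past the cutoff do not count.
#'
#' @param gene one-row data frame (or list) with `chrom`, `tss`, `strand`.
#' @param regions region data.frame, or a list of region data.frames keyed
#'   by chromosome (an index); with an index, a gene whose chromosome is
#'   missing from it raises a lookup error.
#' @param min_stretch minimum continuous covered bp (default 25).
#' @return named integer vector of 40 zeros/ones (names = window labels).
#' @export
window_occupancy <- function(gene, regions, min_stretch = 25) {
  if (!is.data.frame(regions) && is.list(regions)) {
    if (is.null(regions[[as.character(gene$chrom)]]))
      stop("chromosome ", gene$chrom, " absent from the regions index")
    regions <- regions[[as.character(gene$chrom)]]
  }
  strand <- normalize_strand(gene$strand)
  w <- tss_windows()
  # genomic coordinates of each window on this gene's strand
  if (strand == "forward") {
    gstart <- gene$tss + w$rel_start
    gend <- gene$tss + w$rel_end
  } else {
    gstart <- gene$tss - w$rel_end
    gend <- gene$tss - w$rel_start
  }
  occ <- integer(40)
  r <- regions[regions$chrom == as.character(gene$chrom), , drop = FALSE]
  if (nrow(r) > 0) {
    for (i in seq_len(40)) {
      ov_start <- pmax(r$start, gstart[i])
      ov_end <- pmin(r$end, gend[i])
      if (any(ov_end - ov_start + 1 >= min_stretch)) occ[i] <- 1L
    }
  }
  names(occ) <- w$label
  occ
}

#' Occupancy matrix for a set of genes
#' @param genes gene table data.frame.
#' @param regions region data.frame (or per-chromosome index list).
#' @param min_stretch see [window_occupancy()].
#' @return integer matrix, genes x 40 windows; rownames are gene ids.
#' @export
occupancy_matrix <- function(genes, regions, min_stretch = 25) {
  m <- t(vapply(seq_len(nrow(genes)),
                function(i) window_occupancy(genes[i, ], regions,
                                             min_stretch = min_stretch),
                integer(40)))
  rownames(m) <- genes$gene_id
  m
}

#' Drop genes whose +/- flank spans overlap another gene's span
#'
#' Both members of an overlapping pair are removed, so the surviving genes
#' have mutually disjoint TSS-anchored spans.
#'
#' @param genes gene table data.frame.
#' @param flank half-span in bp (default 1000).
#' @return filtered gene table.
#' @export
filter_overlapping_genes <- function(genes, flank = 1000) {
  keep <- rep(TRUE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    s <- genes$tss[i] - flank
    e <- genes$tss[i] + flank
    ir <- IRanges::IRanges(s, e)
    hits <- IRanges::findOverlaps(ir, ir)
    ov <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
    bad <- unique(S4Vectors::queryHits(hits)[ov])
    keep[i[bad]] <- FALSE
  }
  genes[keep, , drop = FALSE]
}

#' Group-averaged TSS coverage profile
#'
#' Filters overlapping-span genes out of the group, then averages the
#' binary window occupancy across the remaining genes: on the consensus
#' (all-replicates) region set for reporting and, when per-replicate region
#' sets are supplied, on each replicate's own calls for testing.
#'
#' @param genes gene table for one group.
#' @param regions consensus region data.frame.
#' @param replicate_region_sets optional list of per-replicate region
#'   data.frames.
#' @param flank,min_stretch see [filter_overlapping_genes()],
#'   [window_occupancy()].
#' @return list with `mean` (named numeric, 40 windows), `n_genes`, and
#'   `replicate_means` (replicates x 40 matrix or NULL).
#' @export
group_coverage_profile <- function(genes, regions,
                                   replicate_region_sets = NULL,
                                   flank = 1000, min_stretch = 25) {
  genes <- filter_overlapping_genes(genes, flank = flank)
  if (nrow(genes) == 0)
    stop("empty group after overlap filtering")
  cons <- colMeans(occupancy_matrix(genes, regions, min_stretch))
  rep_means <- NULL
  if (!is.null(replicate_region_sets)) {
    rep_means <- t(vapply(replicate_region_sets, function(r)
      colMeans(occupancy_matrix(genes, r, min_stretch)), numeric(40)))
  }
  list(mean = cons, n_genes = nrow(genes), replicate_means = rep_means)
}

#' Per-window depletion and enrichment percentages between conditions
#'
#' For each window, the denominator is the number of genes occupied in
#' either condition; depletion% counts 1-to-0 transitions
#' (control-occupied, treated-free) and enrichment% 0-to-1 transitions.
#' Windows with zero denominator are reported as `NA`.
#'
#' @param genes gene table for one group.
#' @param regions_control,regions_sa region data.frames per condition.
#' @param min_stretch see [window_occupancy()].
#' @return data.frame with `label`, `denominator`, `depletion_pct`,
#'   `enrichment_pct`.
#' @export
remodeling_percent_profile <- function(genes, regions_control, regions_sa,
                                       min_stretch = 25) {
  occ_c <- occupancy_matrix(genes, regions_control, min_stretch)
  occ_s <- occupancy_matrix(genes, regions_sa, min_stretch)
  denom <- colSums(occ_c == 1 | occ_s == 1)
  dep <- colSums(occ_c == 1 & occ_s == 0)
  enr <- colSums(occ_c == 0 & occ_s == 1)
  data.frame(label = tss_windows()$label,
             denominator = denom,
             depletion_pct = ifelse(denom > 0, 100 * dep / denom, NA_real_),
             enrichment_pct = ifelse(denom > 0, 100 * enr / denom, NA_real_))
}

#' Sliding 150-bp-block significance between two groups' profiles
#'
#' Slides a block of `block` consecutive 50-bp windows (150 bp covers one
#' nucleosome) across the forty windows in steps of `step` windows. Per
#' block, each replicate contributes its mean coverage over the block's
#' windows, and a two-sample Student's t-test (N = replicates per group)
#' compares groups; p-values are adjusted across blocks.
#'
#' Zero-variance blocks: equal means give p = 1 by convention; unequal
#' means with zero variance are flagged with p set to the smallest positive
#' double and a warning.
#'
#' @param prof_a,prof_b replicate x 40 matrices of per-window per-replicate
#'   mean coverage (see [group_coverage_profile()]).
#' @param block number of 50-bp windows per test block (default 3 = 150 bp).
#' @param step slide in windows (default 1 = 50 bp).
#' @param method multiple-testing adjustment, `"BH"` or `"storey"`.
#' @return data.frame with the block's first window `label`, `t`, `p`, `q`.
#' @export
window_significance <- function(prof_a, prof_b, block = 3, step = 1,
                                method = "BH") {
  if (nrow(prof_a) < 2 || nrow(prof_b) < 2)
    stop("at least two replicates per group are required for a t-test")
  labels <- tss_windows()$label
  starts <- seq(1, ncol(prof_a) - block + 1, by = step)
  res <- lapply(starts, function(i) {
    a <- rowMeans(prof_a[, i:(i + block - 1), drop = FALSE])
    b <- rowMeans(prof_b[, i:(i + block - 1), drop = FALSE])
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    if (pooled_var == 0) {
      if (mean(a) == mean(b)) {
        tt <- 0; p <- 1
      } else {
        warning("zero-variance block with unequal means at window ",
                labels[i])
        tt <- Inf; p <- .Machine$double.xmin
      }
    } else {
      se <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
      tt <- (mean(a) - mean(b)) / se
      p <- 2 * stats::pt(-abs(tt), df = length(a) + length(b) - 2)
    }
    data.frame(label = labels[i], t = tt, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- adjust_pvalues(out$p, method = method)
  out
}
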