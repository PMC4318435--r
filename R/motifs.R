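# Motif enrichment statistics over promoter region classes.
#
# The expected occurrence of a motif in a region uses the region's local
# base composition:
#
#   T = bases counted in the region (N bases excluded)
#   F(b) = count of base b / T
#   E = (prod of F over the motif's bases) / N_motif * T
#
# The division by the motif length N is kept exactly as the source analysis
# used it (its observed/expected tables were produced with it); the
# `standard_expectation` switch drops it for users wanting the textbook
# sliding-window expectation. Under the as-printed formula the corrected
# frequency (observed/E) of a motif in i.i.d. composition-matched sequence
# converges to N_motif rather than 1.

#' Expand a motif spec with degenerate final-position alternatives
#'
#' `"TGACG/C"` expands to `c("TGACG", "TGACC")`; a plain motif maps to
#' itself. Only single-base alternatives after `/` are supported.
#'
#' @param motif motif spec string.
#' @return character vector of concrete motif variants.
#' @export
expand_motif <- function(motif) {
  parts <- strsplit(toupper(motif), "/", fixed = TRUE)[[1]]
  if (any(!grepl("^[ACGT]+$", parts)))
    stop("motif must be over A/C/G/T (with optional /X alternatives): ",
         motif)
  base <- parts[1]
  if (length(parts) == 1) return(base)
  stem <- substr(base, 1, nchar(base) - 1)
  c(base, paste0(stem, parts[-1]))
}

#' Local base frequencies of a sequence set
#'
#' Counts A/C/G/T over all sequences; N bases are excluded from both the
#' counts and the total.
#'
#' @param sequences character vector (or `DNAStringSet`) of sequences.
#' @return list with `F` (named frequencies summing to 1) and `T` (counted
#'   bases).
#' @export
base_frequencies <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0 || sum(nchar(sequences)) == 0)
    stop("empty sequence input")
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(sequences)))[, c("A", "C", "G", "T"),
                                                  drop = FALSE])
  total <- sum(counts)
  if (total == 0) stop("no A/C/G/T bases in input")
  list(F = counts / total, T = total)
}

#' Expected occurrence of a motif under local base composition
#'
#' `E = (prod of F over the motif's bases, in order) / N * T` with N the
#' motif length, exactly as printed in the source formula;
#' `standard_expectation = TRUE` drops the `/N`. For a degenerate motif
#' spec the variant expectations are summed.
#'
#' @param freq named base frequencies (A, C, G, T).
#' @param total total bases T.
#' @param motif motif spec (plain or `"XXXXG/C"` style).
#' @param standard_expectation drop the division by motif length.
#' @return expected occurrence (numeric scalar).
#' @export
expected_occurrence <- function(freq, total, motif,
                                standard_expectation = FALSE) {
  variants <- expand_motif(motif)
  n <- nchar(variants[1])
  e <- sum(vapply(variants, function(v) {
    prod(freq[strsplit(v, "")[[1]]])
  }, numeric(1)))
  if (!standard_expectation) e <- e / n
  e * total
}

# start positions of (overlapping) motif occurrences in one sequence
motif_starts <- function(sequence, variants) {
  s <- Biostrings::DNAString(toupper(sequence))
  sort(unique(unlist(lapply(variants, function(v)
    BiocGenerics::start(Biostrings::matchPattern(v, s))))))
}

#' Count motif occurrences in a sequence set
#'
#' Overlapping occurrences are counted (sliding step 1), on the given
#' strand only; degenerate specs (`"TGACG/C"`) count all variants.
#'
#' @param sequences character vector (or `DNAStringSet`).
#' @param motif motif spec.
#' @return integer total count.
#' @export
count_occurrences <- function(sequences, motif) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  variants <- expand_motif(motif)
  sum(vapply(sequences, function(s)
    length(motif_starts(s, variants)), integer(1)))
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(low = 0, high = 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Motif statistics per promoter region class
#'
#' Region classes (`NOR`, `NFR`, `remodeled`) partition each promoter's
#' bases; `total_promoter` is always added. Per (motif, class): T and F are
#' computed from the class's own bases (local composition), E from the
#' printed formula, `observed` counts occurrences whose 5'-most base falls
#' in the class, `corrected = observed / E`, and `relative` rescales by the
#' total-promoter corrected frequency. The 95% CI is a Wilson score
#' interval on observed/T, rescaled to the corrected-frequency axis.
#'
#' @param promoters named character vector of promoter sequences (names =
#'   gene ids), each written 5' to 3' on the gene's strand.
#' @param classes data.frame `gene_id, class, start, end` with 1-based
#'   inclusive coordinates within each promoter; classes must not overlap
#'   within a promoter.
#' @param motifs character vector of motif specs (e.g. `c("TTGAC",
#'   "TGACG/C")`).
#' @param standard_expectation see [expected_occurrence()].
#' @return data.frame, one row per (motif, class): `motif, region_class, T,
#'   E, observed, corrected, relative, ci_low, ci_high, computable`.
#' @export
region_class_motif_stats <- function(promoters, classes, motifs,
                                     standard_expectation = FALSE) {
  stopifnot(!is.null(names(promoters)))
  class_names <- c("total_promoter", sort(unique(classes$class)))
  # class bases (for F and T) and per-promoter membership lookup
  class_seqs <- list(total_promoter = unname(promoters))
  for (cl in setdiff(class_names, "total_promoter")) {
    rows <- classes[classes$class == cl, ]
    segs <- substring(promoters[rows$gene_id], rows$start, rows$end)
    class_seqs[[cl]] <- segs[nchar(segs) > 0]
  }
  # observed occurrences assigned by 5'-most base
  occ <- list()
  for (m in motifs) {
    variants <- expand_motif(m)
    per_class <- stats::setNames(integer(length(class_names)), class_names)
    for (g in names(promoters)) {
      starts <- motif_starts(promoters[[g]], variants)
      if (length(starts) == 0) next
      per_class[["total_promoter"]] <-
        per_class[["total_promoter"]] + length(starts)
      gcl <- classes[classes$gene_id == g, ]
      if (nrow(gcl) == 0) next
      hit <- vapply(starts, function(s) {
        i <- which(gcl$start <= s & s <= gcl$end)
        if (length(i) == 0) NA_character_ else gcl$class[i[1]]
      }, character(1))
      tab <- table(hit[!is.na(hit)])
      per_class[names(tab)] <- per_class[names(tab)] + as.integer(tab)
    }
    occ[[m]] <- per_class
  }
  rows <- list()
  corrected_total <- stats::setNames(numeric(length(motifs)), motifs)
  for (m in motifs) {
    n_motif <- nchar(expand_motif(m)[1])
    for (cl in class_names) {
      seqs <- class_seqs[[cl]]
      t_cl <- if (length(seqs) > 0) sum(nchar(seqs)) else 0
      computable <- t_cl >= n_motif
      if (computable) {
        bf <- base_frequencies(seqs)
        e <- expected_occurrence(bf$F, bf$T, m,
                                 standard_expectation = standard_expectation)
        obs <- occ[[m]][[cl]]
        corrected <- if (e > 0) obs / e else NA_real_
        ci <- wilson_ci(obs, bf$T)
        scale <- if (e > 0) bf$T / e else NA_real_
        row <- data.frame(motif = m, region_class = cl, T = bf$T, E = e,
                          observed = obs, corrected = corrected,
                          ci_low = ci["low"] * scale,
                          ci_high = ci["high"] * scale,
                          computable = TRUE, stringsAsFactors = FALSE)
      } else {
        row <- data.frame(motif = m, region_class = cl, T = t_cl,
                          E = NA_real_, observed = NA_integer_,
                          corrected = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, computable = FALSE,
                          stringsAsFactors = FALSE)
      }
      if (cl == "total_promoter") corrected_total[m] <- row$corrected
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$relative <- out$corrected / corrected_total[out$motif]
  out
}

#' Hexamer lift and observed/expected enrichment screen
#'
#' Scores every hexamer (4^6 = 4096) in a target set against a contrast set
#' with a shared background: `oe(set) = (observed + pseudocount) / E` with E
#' from the set's own local composition and the printed formula;
#' `lift(set) = hexamer frequency in set / frequency in background`,
#' frequencies over sliding hexamer windows with the same pseudocount. A
#' hexamer passes when both `oe_ratio = oe(target)/oe(contrast)` and
#' `lift_ratio = lift(target)/lift(contrast)` reach `fold_min`.
#'
#' @param target_seqs,contrast_seqs,background_seqs character vectors (or
#'   `DNAStringSet`s) of sequences.
#' @param fold_min enrichment fold-change cutoff (default 2).
#' @param pseudocount added to every observed count in ratios (default 1).
#' @param standard_expectation see [expected_occurrence()].
#' @return data.frame of 4096 rows: `hexamer, obs_target, obs_contrast,
#'   obs_background, oe_target, oe_contrast, oe_background, oe_ratio,
#'   lift_target, lift_contrast, lift_ratio, passes`.
#' @export
hexamer_enrichment <- function(target_seqs, contrast_seqs, background_seqs,
                               fold_min = 2, pseudocount = 1,
                               standard_expectation = FALSE) {
  count_set <- function(seqs) {
    if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    if (length(seqs) == 0 || sum(nchar(seqs)) == 0)
      stop("empty sequence set")
    ss <- Biostrings::DNAStringSet(toupper(seqs))
    counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = 6))
    windows <- sum(pmax(0, nchar(seqs) - 5))
    bf <- base_frequencies(seqs)
    list(counts = counts, windows = windows, F = bf$F, T = bf$T)
  }
  tg <- count_set(target_seqs)
  ct <- count_set(contrast_seqs)
  bg <- count_set(background_seqs)
  hex <- names(tg$counts)
  e_for <- function(set) vapply(hex, function(h)
    expected_occurrence(set$F, set$T, h,
                        standard_expectation = standard_expectation),
    numeric(1))
  oe <- function(set, e) (set$counts + pseudocount) / e
  e_tg <- e_for(tg); e_ct <- e_for(ct); e_bg <- e_for(bg)
  oe_tg <- oe(tg, e_tg); oe_ct <- oe(ct, e_ct); oe_bg <- oe(bg, e_bg)
  freq <- function(set) (set$counts + pseudocount) / set$windows
  lift_tg <- freq(tg) / freq(bg)
  lift_ct <- freq(ct) / freq(bg)
  out <- data.frame(hexamer = hex,
                    obs_target = as.integer(tg$counts),
                    obs_contrast = as.integer(ct$counts),
                    obs_background = as.integer(bg$counts),
                    oe_target = oe_tg, oe_contrast = oe_ct,
                    oe_background = oe_bg,
                    oe_ratio = oe_tg / oe_ct,
                    lift_target = lift_tg, lift_contrast = lift_ct,
                    lift_ratio = lift_tg / lift_ct,
                    stringsAsFactors = FALSE)
  out$passes <- out$oe_ratio >= fold_min & out$lift_ratio >= fold_min
  rownames(out) <- NULL
  out
}
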