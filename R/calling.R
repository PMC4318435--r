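# Nucleosome calling from replicate tiling-array enrichment tracks.
#
# A probe qualifies at a stringency level when its enrichment value is >=
# the level in every replicate. Maximal runs of >= 4 consecutive qualifying
# probes become regions; each qualifying probe claims a pitch-wide tile, so
# at the array's 35-bp pitch a 4-probe run spans 140 bp (a distinct
# nucleosome, 131-161 bp) and a 5-probe run 175 bp (fuzzy, >= 161 bp).

#' The seven stringency levels of the enrichment-value sweep
#' @return numeric vector of log2 thresholds, strictly decreasing.
#' @export
stringency_levels <- function() c(0.0, -0.01, -0.1, -0.5, -1.0, -1.5, -2.0)

DISTINCT_MIN <- 131L  # distinct span: [131, 161) bp
FUZZY_MIN <- 161L     # fuzzy span: [161, Inf) bp

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             type = character(), condition = character(),
             stringency = numeric(), n_probes = integer(),
             stringsAsFactors = FALSE)
}

#' Call nucleosome regions on one chromosome track at one stringency level
#'
#' A probe qualifies iff the minimum over its replicates is `>= threshold`
#' (inclusive). Consecutive means adjacent in track order with a
#' start-to-start gap of at most `max_probe_gap` bp; runs of fewer than
#' `min_run` qualifying probes emit nothing. The region interval runs from
#' the first qualifying probe start to the last qualifying probe start plus
#' `probe_pitch - 1`. Spans below 131 bp (possible with irregular pitch)
#' are discarded and counted in the `discarded` attribute.
#'
#' @param track a `probe_track` (one chromosome, sorted by position).
#' @param threshold stringency level (log2 enrichment).
#' @param probe_pitch tile width claimed by each probe (bp, default 35).
#' @param max_probe_gap maximum start-to-start gap within a run (default 50).
#' @param min_run minimum qualifying probes per region (default 4).
#' @param condition condition label stored on the regions.
#' @return region data.frame (`chrom start end type condition stringency
#'   n_probes`) with attribute `discarded` = number of sub-131-bp spans
#'   dropped.
#' @export
call_regions <- function(track, threshold, probe_pitch = 35,
                         max_probe_gap = 50, min_run = 4,
                         condition = "control") {
  if (nrow(track) == 0) {
    out <- empty_regions()
    attr(out, "discarded") <- 0L
    return(out)
  }
  if (is.unsorted(track$position, strictly = TRUE))
    stop("track positions must be strictly increasing")
  vals <- probe_values(track)
  qualifies <- apply(vals, 1, min) >= threshold

  # break runs at non-qualifying probes and at tiling gaps > max_probe_gap
  gap_break <- c(FALSE, diff(track$position) > max_probe_gap)
  run_id <- cumsum(!qualifies | gap_break)
  idx <- which(qualifies)
  out <- empty_regions()
  discarded <- 0L
  if (length(idx) > 0) {
    runs <- split(idx, run_id[idx])
    keep <- vapply(runs, length, integer(1)) >= min_run
    runs <- runs[keep]
    if (length(runs) > 0) {
      start <- vapply(runs, function(i) track$position[i[1]], numeric(1))
      end <- vapply(runs, function(i) track$position[i[length(i)]],
                    numeric(1)) + probe_pitch - 1
      n_probes <- vapply(runs, length, integer(1))
      span <- end - start + 1
      type <- ifelse(span >= FUZZY_MIN, "fuzzy",
              ifelse(span >= DISTINCT_MIN, "distinct", NA_character_))
      discarded <- sum(is.na(type))
      ok <- !is.na(type)
      out <- data.frame(chrom = rep(track$chrom[1], sum(ok)),
                        start = as.integer(start[ok]),
                        end = as.integer(end[ok]), type = type[ok],
                        condition = rep(condition, sum(ok)),
                        stringency = rep(threshold, sum(ok)),
                        n_probes = n_probes[ok], stringsAsFactors = FALSE)
      rownames(out) <- NULL
    }
  }
  attr(out, "discarded") <- discarded
  out
}

#' Call regions across all chromosomes of a condition
#' @param tracks named list of `probe_track` keyed by chromosome.
#' @inheritParams call_regions
#' @return combined region data.frame.
#' @export
call_regions_all <- function(tracks, threshold, probe_pitch = 35,
                             max_probe_gap = 50, min_run = 4,
                             condition = "control") {
  parts <- lapply(tracks, call_regions, threshold = threshold,
                  probe_pitch = probe_pitch, max_probe_gap = max_probe_gap,
                  min_run = min_run, condition = condition)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_regions()
  attr(out, "discarded") <- sum(vapply(parts, attr, integer(1), "discarded"))
  out
}

#' Stringency sweep over levels, conditions, types and chromosomes
#'
#' Calls regions in both conditions at every stringency level and tabulates
#' one dataset per (level, condition, type, chromosome) cell: with the seven
#' default levels, two conditions, two types and five chromosomes that is
#' 140 datasets.
#'
#' @param tracks_control,tracks_treated named lists of `probe_track`,
#'   keyed by the same chromosomes.
#' @param levels stringency thresholds (default [stringency_levels()]).
#' @param probe_pitch,max_probe_gap,min_run see [call_regions()].
#' @return list with `regions` (all called regions, all levels/conditions)
#'   and `summary` (full grid, one row per dataset, with `n_regions` and
#'   `bases` covered).
#' @export
stringency_sweep <- function(tracks_control, tracks_treated,
                             levels = stringency_levels(),
                             probe_pitch = 35, max_probe_gap = 50,
                             min_run = 4) {
  chroms <- sort(names(tracks_control))
  if (!setequal(chroms, names(tracks_treated)))
    stop("control and treated tracks cover different chromosome sets")
  conds <- list(control = tracks_control, treated = tracks_treated)
  regions <- list()
  for (lev in levels) {
    for (cd in names(conds)) {
      regions[[length(regions) + 1L]] <- call_regions_all(
        conds[[cd]], lev, probe_pitch = probe_pitch,
        max_probe_gap = max_probe_gap, min_run = min_run, condition = cd)
    }
  }
  regions <- do.call(rbind, c(regions, list(make.row.names = FALSE)))
  grid <- expand.grid(stringency = levels, condition = names(conds),
                      type = c("distinct", "fuzzy"), chrom = chroms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_regions <- 0L
  grid$bases <- 0L
  if (nrow(regions) > 0) {
    key <- function(df) paste(df$stringency, df$condition, df$type, df$chrom)
    agg_n <- tapply(rep(1L, nrow(regions)), key(regions), sum)
    agg_b <- tapply(regions$end - regions$start + 1L, key(regions), sum)
    m <- match(key(grid), names(agg_n))
    grid$n_regions[!is.na(m)] <- as.integer(agg_n[m[!is.na(m)]])
    grid$bases[!is.na(m)] <- as.integer(agg_b[m[!is.na(m)]])
  }
  list(regions = regions, summary = grid)
}

#' Chromosome bp per called nucleosome
#'
#' Defined as chromosome size divided by the number of called regions
#' (distinct + fuzzy). `per_base = TRUE` instead divides by the bases
#' covered. Zero regions yield `Inf` with a warning.
#'
#' @param chromosome_length chromosome size in bp.
#' @param regions region data.frame for one (condition, level).
#' @param per_base divide by covered bases instead of region count.
#' @return bp per nucleosome (numeric scalar).
#' @export
coverage_per_nucleosome <- function(chromosome_length, regions,
                                    per_base = FALSE) {
  if (chromosome_length <= 0) stop("chromosome_length must be positive")
  denom <- if (per_base) sum(regions$end - regions$start + 1) else
    nrow(regions)
  if (denom == 0) {
    warning("no regions: coverage per nucleosome is undefined (Inf)")
    return(Inf)
  }
  chromosome_length / denom
}
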