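# Base-resolution comparison of control vs SA-treated region sets.
#
# A base is "depleted" when occupied only in control, "enriched" when
# occupied only after treatment, and "common" when occupied in both;
# remodeled bases = total occupied bases - common bases. Comparison is at
# base resolution, not region identity, so a shifted nucleosome contributes
# both depleted and enriched bases; region type (distinct/fuzzy) is dropped
# before comparison.

regions_to_iranges <- function(regions) {
  split(IRanges::IRanges(start = regions$start, end = regions$end),
        regions$chrom)
}

iranges_to_regions <- function(ir_by_chrom) {
  parts <- lapply(names(ir_by_chrom), function(ch) {
    ir <- ir_by_chrom[[ch]]
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = ch, start = BiocGenerics::start(ir),
               end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

#' Merge overlapping/adjacent regions within each chromosome
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @return merged region data.frame, sorted, pairwise disjoint.
#' @export
merge_regions <- function(regions) {
  iranges_to_regions(lapply(regions_to_iranges(regions), IRanges::reduce))
}

region_bases <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  sum(regions$end - regions$start + 1L)
}

assert_disjoint <- function(regions, label) {
  ir <- regions_to_iranges(regions)
  bad <- vapply(ir, function(x)
    sum(BiocGenerics::width(IRanges::reduce(x))) != sum(BiocGenerics::width(x)),
    logical(1))
  if (any(bad))
    stop(label, ": overlapping intervals within one input on chromosome(s) ",
         paste(names(ir)[bad], collapse = ", "),
         "; merge the input first (merge_regions)")
  invisible(TRUE)
}

#' Partition control vs treated occupancy into depleted/enriched/common bases
#'
#' Exact base-level set algebra per chromosome: `depleted` = control-only
#' bases, `enriched` = treated-only bases, `common` = intersection. The
#' three sets are pairwise disjoint and their union is the union of the two
#' inputs; remodeled bases = total - common.
#'
#' @param regions_control,regions_sa region data.frames, each internally
#'   non-overlapping per chromosome (see [merge_regions()]).
#' @return object of class `remodeling_partition`: list with `depleted`,
#'   `enriched`, `common` region data.frames and a `totals` table (bases per
#'   class per chromosome plus a genome row, including `remodeled` and
#'   `total` = union bases).
#' @export
compare_conditions <- function(regions_control, regions_sa) {
  assert_disjoint(regions_control, "control regions")
  assert_disjoint(regions_sa, "treated regions")
  chroms <- sort(unique(c(regions_control$chrom, regions_sa$chrom)))
  empty <- IRanges::IRanges()
  ctrl <- regions_to_iranges(regions_control)
  trt <- regions_to_iranges(regions_sa)
  dep <- list(); enr <- list(); com <- list()
  for (ch in chroms) {
    a <- IRanges::reduce(ctrl[[ch]] %||% empty)
    b <- IRanges::reduce(trt[[ch]] %||% empty)
    dep[[ch]] <- BiocGenerics::setdiff(a, b)
    enr[[ch]] <- BiocGenerics::setdiff(b, a)
    com[[ch]] <- BiocGenerics::intersect(a, b)
  }
  depleted <- iranges_to_regions(dep)
  enriched <- iranges_to_regions(enr)
  common <- iranges_to_regions(com)
  per_chrom <- do.call(rbind, lapply(chroms, function(ch) {
    d <- sum(BiocGenerics::width(dep[[ch]]))
    e <- sum(BiocGenerics::width(enr[[ch]]))
    c0 <- sum(BiocGenerics::width(com[[ch]]))
    data.frame(chrom = ch, depleted = d, enriched = e, common = c0,
               total = d + e + c0, remodeled = d + e,
               stringsAsFactors = FALSE)
  }))
  genome <- data.frame(chrom = "genome",
                       depleted = sum(per_chrom$depleted),
                       enriched = sum(per_chrom$enriched),
                       common = sum(per_chrom$common),
                       total = sum(per_chrom$total),
                       remodeled = sum(per_chrom$remodeled),
                       stringsAsFactors = FALSE)
  structure(list(depleted = depleted, enriched = enriched, common = common,
                 totals = rbind(per_chrom, genome)),
            class = "remodeling_partition")
}

#' Genome-wide remodeling fractions
#'
#' Expresses a [compare_conditions()] partition as percentages of the
#' genome: `pct_nor` (nucleosome-occupied under either condition, the union),
#' `pct_common` (occupied under both) and `pct_unique = pct_nor -
#' pct_common` (gains or loses a nucleosome on treatment).
#'
#' @param partition a `remodeling_partition`.
#' @param genome_size named numeric vector of chromosome sizes in bp
#'   (names matching the partition's chromosomes), or a single total size.
#' @return data.frame with one row per chromosome plus a `genome` row and
#'   columns `pct_nor`, `pct_common`, `pct_unique`.
#' @export
genome_remodeling_summary <- function(partition, genome_size) {
  tot <- partition$totals
  if (length(genome_size) == 1 && is.null(names(genome_size))) {
    sizes <- c(genome = unname(genome_size))
    tot <- tot[tot$chrom == "genome", , drop = FALSE]
  } else {
    sizes <- c(genome_size, genome = sum(genome_size))
  }
  m <- match(tot$chrom, names(sizes))
  if (anyNA(m))
    stop("missing genome size for chromosome(s): ",
         paste(tot$chrom[is.na(m)], collapse = ", "))
  size <- as.numeric(sizes[m])
  if (any(tot$total > size))
    stop("partition bases exceed the stated genome size")
  data.frame(chrom = tot$chrom,
             pct_nor = 100 * tot$total / size,
             pct_common = 100 * tot$common / size,
             pct_unique = 100 * (tot$total - tot$common) / size,
             stringsAsFactors = FALSE)
}
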