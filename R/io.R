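# Readers and writers for the pipeline's plain-text interchange formats:
# probe tracks (TSV), gene tables (TSV), region sets (native TSV + BED6),
# promoter sequences (FASTA).

#' Construct a probe track for one chromosome
#'
#' A probe track holds the ordered probe start positions of a tiling array
#' and one log2 enrichment value per replicate, for one condition.
#'
#' @param chrom chromosome identifier.
#' @param position 1-based probe start positions.
#' @param values numeric matrix, one row per probe, one column per replicate.
#' @return data.frame of class `probe_track` with columns `chrom`,
#'   `position`, `rep1`..`repN` and attribute `replicate_count`.
#' @export
probe_track <- function(chrom, position, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(position))
    stop("values must have one row per probe")
  if (any(duplicated(position)))
    stop("duplicate probe position(s) on chromosome ", chrom, ": ",
         paste(utils::head(position[duplicated(position)], 3), collapse = ", "))
  o <- order(position)
  df <- data.frame(chrom = rep(as.character(chrom), length(position)),
                   position = as.integer(position[o]),
                   stringsAsFactors = FALSE)
  colnames(values) <- paste0("rep", seq_len(ncol(values)))
  df <- cbind(df, as.data.frame(values[o, , drop = FALSE]))
  rownames(df) <- NULL
  attr(df, "replicate_count") <- ncol(values)
  class(df) <- c("probe_track", "data.frame")
  df
}

#' Replicate columns of a probe track as a matrix
#' @param track a `probe_track`.
#' @return numeric matrix (probes x replicates).
#' @export
probe_values <- function(track) {
  as.matrix(track[, grep("^rep[0-9]+$", names(track)), drop = FALSE])
}

#' Read probe tracks from a tab-separated file
#'
#' Expected format: header line, then columns
#' `chrom  position  rep1 ... repN`, one condition per file. Probes are
#' returned sorted by position; rows with non-numeric values are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param replicate_count expected number of replicate columns (default 3).
#' @return named list of `probe_track`, keyed by chromosome.
#' @export
read_probe_track <- function(path, replicate_count = 3) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  need <- 2 + replicate_count
  if (ncol(raw) < need)
    stop(path, ": expected at least ", need, " columns (chrom, position, ",
         replicate_count, " replicates), found ", ncol(raw))
  raw <- raw[, seq_len(need)]
  num <- suppressWarnings(
    lapply(raw[-1], function(col) as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) )
    if (length(bad) > 0)
      stop(path, ": non-numeric value in column ", names(raw)[j + 1],
           " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " (file line ", bad[1] + 1, ")")
  }
  chrom <- trimws(raw[[1]])
  pos <- num[[1]]
  vals <- do.call(cbind, num[-1])
  out <- lapply(split(seq_along(chrom), chrom), function(i) {
    probe_track(chrom[i[1]], pos[i], vals[i, , drop = FALSE])
  })
  out[order(names(out))]
}

#' Write probe tracks to a tab-separated file
#' @param tracks named list of `probe_track` (or a single track).
#' @param path output path.
#' @export
write_probe_track <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' TSV with header `gene_id chrom strand tss start_codon stop_codon
#' mrna_end` (TAIR10 tabular-derived). Strand codes are normalized; the
#' coordinate ordering invariant (TSS before start codon before stop codon
#' before mRNA end, in transcription direction) is enforced.
#'
#' @param path file path.
#' @return data.frame, one row per gene.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("gene_id", "chrom", "strand", "tss", "start_codon",
            "stop_codon", "mrna_end")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0)
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  g <- g[, need]
  g$strand <- normalize_strand(g$strand)
  g$chrom <- as.character(g$chrom)
  validate_gene_table(g)
  g
}

validate_gene_table <- function(g) {
  fwd <- g$strand == "forward"
  ok <- ifelse(fwd,
    g$tss <= g$start_codon & g$start_codon <= g$stop_codon &
      g$stop_codon <= g$mrna_end,
    g$tss >= g$start_codon & g$start_codon >= g$stop_codon &
      g$stop_codon >= g$mrna_end)
  if (!all(ok))
    stop("gene coordinate ordering violated for: ",
         paste(utils::head(g$gene_id[!ok], 5), collapse = ", "))
  invisible(g)
}

#' Write a gene coordinate table
#' @param genes gene table data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a native 1-based region table
#'
#' Columns: `chrom start end` plus any of `type condition stringency
#' n_probes` that were written.
#'
#' @param path file path.
#' @return region data.frame.
#' @export
read_regions_tsv <- function(path) {
  r <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (any(r$start > r$end)) stop(path, ": region with start > end")
  r$chrom <- as.character(r$chrom)
  r
}

#' Write a native 1-based region table
#' @param regions region data.frame (`chrom`, `start`, `end`, ...).
#' @param path output path.
#' @export
write_regions_tsv <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write regions as BED6 (0-based half-open)
#'
#' `name` carries the region type, `score` the stringency level times 100
#' (rounded), `strand` is `"."`.
#'
#' @param regions region data.frame with 1-based inclusive `start`/`end`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = if ("type" %in% names(regions)) regions$type else "region",
    score = if ("stringency" %in% names(regions))
      round(regions$stringency * 100) else 0L,
    strand = ".",
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive regions
#' @param path BED file path.
#' @return region data.frame with `chrom`, `start`, `end`, `type`,
#'   `stringency` recovered from the BED fields.
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]), start = bed[[2]] + 1L,
             end = bed[[3]],
             type = if (ncol(bed) >= 4) bed[[4]] else "region",
             stringency = if (ncol(bed) >= 5) bed[[5]] / 100 else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write promoter sequences as FASTA
#' @param seqs named character vector or `DNAStringSet`; names are gene ids.
#' @param path output path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}
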