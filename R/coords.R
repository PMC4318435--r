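# Coordinate arithmetic. All internal coordinates are 1-based inclusive
# (TAIR convention); BED export converts to 0-based half-open.

#' Normalize a strand vocabulary to "forward"/"reverse"
#'
#' Accepts `+`/`-`, `F`/`R`, `fwd`/`rev`, `forward`/`reverse`
#' (case-insensitive) and maps them onto the internal vocabulary.
#'
#' @param strand character vector of strand codes.
#' @return character vector of `"forward"`/`"reverse"`.
#' @export
normalize_strand <- function(strand) {
  s <- tolower(trimws(as.character(strand)))
  out <- ifelse(s %in% c("+", "f", "fwd", "forward"), "forward",
         ifelse(s %in% c("-", "r", "rev", "reverse"), "reverse", NA_character_))
  if (anyNA(out)) {
    bad <- unique(strand[is.na(out)])
    stop("unrecognized strand code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Convert a genomic position to a signed TSS-relative offset
#'
#' Negative offsets are upstream of the transcription start site, positive
#' offsets downstream, on either strand. The TSS base itself maps to 0.
#'
#' @param position 1-based genomic position(s).
#' @param tss 1-based TSS position on the same chromosome.
#' @param strand strand code (any form accepted by [normalize_strand()]).
#' @return integer vector of signed bp offsets.
#' @examples
#' to_tss_relative(6242491, 6242463, "reverse") # -28, upstream TATA-box
#' @export
to_tss_relative <- function(position, tss, strand) {
  strand <- normalize_strand(strand)
  off <- position - tss
  rev <- rep_len(strand == "reverse", length(off))
  off[rev] <- -off[rev]
  off
}

#' Convert a signed TSS-relative offset back to a genomic position
#'
#' Exact inverse of [to_tss_relative()] on both strands.
#'
#' @param offset signed bp offset (negative = upstream).
#' @inheritParams to_tss_relative
#' @return 1-based genomic position(s).
#' @export
from_tss_relative <- function(offset, tss, strand) {
  strand <- normalize_strand(strand)
  pos <- tss + offset
  rev <- rep_len(strand == "reverse", length(pos))
  pos[rev] <- (tss - offset)[rev]
  pos
}

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive bounds; vectors are recycled.
#' @return integer length(s), `end - start + 1`.
#' @examples
#' interval_length(6241704, 6243463) # 1760
#' @export
interval_length <- function(start, end) {
  if (is.data.frame(start) || is.list(start)) {
    end <- start$end
    start <- start$start
  }
  if (any(start > end)) stop("invalid interval: start > end")
  as.integer(end - start + 1L)
}

#' Promoter interval upstream of a gene's TSS
#'
#' Returns the `length`-bp interval immediately upstream of the TSS on the
#' gene's strand: `[tss - length, tss - 1]` for forward genes and
#' `[tss + 1, tss + length]` for reverse genes, clipped to
#' `[1, chrom_length]` with a warning when the chromosome end is hit.
#'
#' @param gene a one-row data frame (or list) with `chrom`, `tss`, `strand`.
#' @param length promoter length in bp (default 1000).
#' @param chrom_length chromosome length for clipping (default unbounded).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
promoter_interval <- function(gene, length = 1000, chrom_length = Inf) {
  strand <- normalize_strand(gene$strand)
  tss <- gene$tss
  if (strand == "forward") {
    start <- tss - length
    end <- tss - 1
  } else {
    start <- tss + 1
    end <- tss + length
  }
  if (end < 1 || start > chrom_length)
    stop("gene ", gene$gene_id %||% "?",
         ": no upstream room for a promoter interval")
  if (start < 1 || end > chrom_length) {
    warning("promoter interval clipped at chromosome bounds for gene ",
            gene$gene_id %||% "?")
    start <- max(start, 1)
    end <- min(end, chrom_length)
  }
  data.frame(chrom = as.character(gene$chrom), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
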