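#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases the input and converts T to U. Characters outside
#' \code{A,C,G,U,N} are rejected with the (1-based) position of the first
#' offender, so annotation errors surface early rather than as silent
#' mis-scored duplexes downstream.
#'
#' @param raw A single non-empty character string (DNA or RNA, any case).
#' @param allow_gap Also admit \code{-} (for alignment rows).
#' @return The normalized sequence over \code{A,C,G,U,N} (plus \code{-} if
#'   \code{allow_gap}).
#' @export
normalize_rna <- function(raw, allow_gap = FALSE) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (nchar(raw) == 0L) stop("sequence is empty")
  x <- chartr("t", "u", toupper(raw))
  x <- chartr("T", "U", x)
  alphabet <- c("A", "C", "G", "U", "N", if (allow_gap) "-")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  x
}

#' Construct a genomic segment
#'
#' A named stretch of (plus-strand, transcript-orientation) RNA belonging to
#' one species. All cluster coordinates are 0-based half-open offsets into
#' \code{sequence}.
#'
#' @param id Segment identifier.
#' @param sequence Nucleotide string; normalized via [normalize_rna()].
#' @param species Species label.
#' @return An object of class \code{genomic_segment}.
#' @export
genomic_segment <- function(id, sequence, species = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seg <- structure(
    list(id = id, sequence = normalize_rna(sequence), species = species),
    class = "genomic_segment"
  )
  seg
}

#' @export
print.genomic_segment <- function(x, ...) {
  cat(sprintf("<genomic_segment> %s [%s], %d nt\n",
              x$id, x$species, nchar(x$sequence)))
  invisible(x)
}

segment_length <- function(segment) nchar(segment$sequence)

#' Construct an exon interval
#'
#' @param start 0-based inclusive start offset.
#' @param end Exclusive end offset; must satisfy \code{start < end}.
#' @param index 1-based ordinal of the exon within its cluster. Gaps in the
#'   index sequence are allowed and represent exons lost in a species
#'   (orthologs keep their ancestral numbering rather than being renumbered).
#' @param kind \code{"variable"} or \code{"constitutive"}.
#' @return A one-row data frame with columns start, end, index, kind.
#' @export
exon_interval <- function(start, end, index, kind = c("variable", "constitutive")) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("exon interval requires 0 <= start < end")
  }
  data.frame(start = start, end = end, index = as.integer(index),
             kind = kind, stringsAsFactors = FALSE)
}

#' Assemble a variable-exon cluster
#'
#' A tandem array of variable exons inside one genomic segment, flanked by
#' constitutive exons. Variable exons must be non-overlapping and sorted by
#' start, lie strictly between the flanks, and stay within the segment.
#'
#' @param segment A [genomic_segment()].
#' @param cluster_label One of \code{exon4, exon6, exon9, exon17, other}.
#' @param variable_exons Data frame of exon intervals (rbind of
#'   [exon_interval()] rows), all \code{kind == "variable"}.
#' @param flank5,flank3 Constitutive flank intervals (one-row data frames).
#' @return An object of class \code{exon_cluster}.
#' @export
exon_cluster <- function(segment, cluster_label, variable_exons, flank5, flank3) {
  stopifnot(inherits(segment, "genomic_segment"))
  cluster_label <- match.arg(cluster_label,
                             c("exon4", "exon6", "exon9", "exon17", "other"))
  ve <- variable_exons
  if (nrow(ve) < 1L) stop("cluster needs at least one variable exon")
  if (is.unsorted(ve$start, strictly = TRUE)) stop("variable exons must be sorted by start")
  if (any(ve$end[-nrow(ve)] > ve$start[-1L])) stop("variable exons overlap")
  L <- segment_length(segment)
  if (any(ve$start < 0L) || any(ve$end > L)) stop("exon outside segment")
  if (flank5$end > ve$start[1L]) stop("5' flank must end before first variable exon")
  if (ve$end[nrow(ve)] > flank3$start) stop("last variable exon must end before 3' flank")
  if (flank3$end > L) stop("3' flank outside segment")
  structure(
    list(segment = segment, cluster_label = cluster_label,
         variable_exons = ve, flank5 = flank5, flank3 = flank3),
    class = "exon_cluster"
  )
}

#' @export
print.exon_cluster <- function(x, ...) {
  cat(sprintf("<exon_cluster> %s [%s]: %d variable exons in %d nt\n",
              x$cluster_label, x$segment$species, nrow(x$variable_exons),
              segment_length(x$segment)))
  invisible(x)
}

exon_name <- function(cluster, index) {
  sprintf("%s.%d", sub("^exon", "", cluster$cluster_label), index)
}

#' Introns between consecutive variable exons
#'
#' Returns the half-open gaps between consecutive variable exons, in order.
#' Zero-length introns (abutting exons) are retained and flagged in the
#' \code{zero_length} column rather than dropped, with a warning.
#'
#' @param cluster An [exon_cluster()].
#' @param include_flanks Also include the flanking introns (5' flank to
#'   first exon, last exon to 3' flank) as first/last rows.
#' @return Data frame with columns start, end, length, after_index,
#'   zero_length.
#' @export
introns_of <- function(cluster, include_flanks = FALSE) {
  ve <- cluster$variable_exons
  starts <- ve$end[-nrow(ve)]
  ends <- ve$start[-1L]
  after <- ve$index[-nrow(ve)]
  if (include_flanks) {
    starts <- c(cluster$flank5$end, starts, ve$end[nrow(ve)])
    ends <- c(ve$start[1L], ends, cluster$flank3$start)
    after <- c(0L, after, ve$index[nrow(ve)])
  }
  out <- data.frame(start = starts, end = ends, length = ends - starts,
                    after_index = after, zero_length = (ends - starts) == 0L)
  if (any(out$zero_length)) {
    warning(sprintf("%d zero-length intron(s) (abutting exons)", sum(out$zero_length)))
  }
  out
}

#' Count mutually exclusive isoforms across clusters
#'
#' The number of distinct mRNAs is the product of variable-exon counts over
#' the clusters (one exon chosen per cluster). Computed exactly: if the
#' product exceeds the exact-double range (2^53) it is returned as a decimal
#' string from long multiplication.
#'
#' @param cluster_sizes Vector of positive integers (variable exons per
#'   cluster).
#' @return The exact product, numeric when exactly representable, otherwise
#'   a character string.
#' @examples
#' isoform_count(c(10, 38, 36, 2)) # 27360, the S. oryzae Dscam1 repertoire
#' @export
isoform_count <- function(cluster_sizes) {
  if (length(cluster_sizes) == 0L) stop("need at least one cluster size")
  sizes <- as.numeric(cluster_sizes)
  if (any(is.na(sizes)) || any(sizes < 1) || any(sizes != floor(sizes))) {
    stop("cluster sizes must be integers >= 1")
  }
  p <- prod(sizes)
  if (p < 2^53) return(p)
  # exact long multiplication in base 1e4
  digits <- c(1)
  for (s in sizes) {
    digits <- digits * s
    carry <- 0
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% 1e4
      carry <- v %/% 1e4
    }
    while (carry > 0) {
      digits <- c(digits, carry %% 1e4)
      carry <- carry %/% 1e4
    }
  }
  n <- length(digits)
  paste0(digits[n], paste(sprintf("%04d", rev(digits[-n])), collapse = ""))
}

#' Reverse complement of an RNA string
#'
#' @param x Normalized RNA string (gaps and N pass through; N stays N,
#'   \code{-} stays \code{-}).
#' @return The reverse complement (A<->U, G<->C).
#' @export
revcomp_rna <- function(x) {
  chartr("ACGUN-", "UGCAN-", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

subseq_rna <- function(segment, start, end) {
  substr(segment$sequence, start + 1L, end)
}
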