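#' Write genomic segments to FASTA
#'
#' The species label travels in the header as \code{id species=<label>} so a
#' round trip preserves it.
#'
#' @param segments A [genomic_segment()] or list of them.
#' @param path Output file.
#' @export
write_segment_fasta <- function(segments, path) {
  if (inherits(segments, "genomic_segment")) segments <- list(segments)
  seqs <- Biostrings::RNAStringSet(vapply(segments, function(s) s$sequence, ""))
  names(seqs) <- vapply(segments, function(s) sprintf("%s species=%s", s$id, s$species), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read genomic segments from FASTA
#'
#' @param path FASTA file. Headers of the form \code{id species=<label>} are
#'   split back into id and species.
#' @return List of [genomic_segment()] objects.
#' @export
read_segment_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    sp <- sub(".*species=(\\S+).*", "\\1", header)
    if (identical(sp, header)) sp <- "unknown"
    id <- sub("\\s.*$", "", header)
    genomic_segment(id, as.character(seqs[[i]]), species = sp)
  })
}

#' Write a cluster's exon annotation as GFF3
#'
#' Internal 0-based half-open coordinates are converted to 1-based inclusive
#' GFF3. Variable exons carry an \code{exon_index} attribute; flanks are
#' emitted with \code{exon_kind=constitutive}.
#'
#' @param cluster An [exon_cluster()].
#' @param path Output file.
#' @export
write_cluster_gff3 <- function(cluster, path) {
  ve <- cluster$variable_exons
  all_ex <- rbind(
    data.frame(start = cluster$flank5$start, end = cluster$flank5$end,
               index = cluster$flank5$index, kind = "constitutive"),
    ve[, c("start", "end", "index", "kind")],
    data.frame(start = cluster$flank3$start, end = cluster$flank3$end,
               index = cluster$flank3$index, kind = "constitutive")
  )
  gr <- GenomicRanges::GRanges(
    seqnames = cluster$segment$id,
    ranges = IRanges::IRanges(start = all_ex$start + 1L, end = all_ex$end),
    strand = "+",
    type = "exon",
    exon_index = as.character(all_ex$index),
    exon_kind = all_ex$kind,
    cluster_label = cluster$cluster_label,
    species = cluster$segment$species
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a cluster annotation from GFF3
#'
#' Inverse of [write_cluster_gff3()]. Features on the minus strand are
#' reverse-complemented into transcript orientation on ingest (the segment is
#' flipped and coordinates remapped), so downstream code always sees
#' plus-strand RNA.
#'
#' @param path GFF3 file with \code{exon} features carrying
#'   \code{exon_index} and \code{exon_kind} attributes.
#' @param segment The [genomic_segment()] the annotation refers to.
#' @return An [exon_cluster()].
#' @export
read_cluster_gff3 <- function(path, segment) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("GFF3 contains no exon features: ", path)
  if (is.null(gr$exon_kind) || is.null(gr$exon_index)) {
    stop("GFF3 exon features must carry exon_index and exon_kind attributes")
  }
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (all(minus) && length(gr) > 0L) {
    L <- segment_length(segment)
    segment <- genomic_segment(segment$id, revcomp_rna(segment$sequence),
                               species = segment$species)
    new_start <- L - GenomicRanges::end(gr) + 1L
    new_end <- L - GenomicRanges::start(gr) + 1L
    GenomicRanges::ranges(gr) <- IRanges::IRanges(start = new_start, end = new_end)
  } else if (any(minus)) {
    stop("mixed-strand exon annotation is not supported")
  }
  df <- data.frame(
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    index = as.integer(gr$exon_index),
    kind = as.character(gr$exon_kind)
  )
  df <- df[order(df$start), ]
  label <- if (!is.null(gr$cluster_label)) as.character(gr$cluster_label)[1L] else "other"
  const <- df[df$kind == "constitutive", ]
  ve <- df[df$kind == "variable", ]
  if (nrow(const) < 2L) stop("GFF3 must contain 5' and 3' constitutive flank exons")
  if (nrow(ve) < 1L) stop("GFF3 contains no variable exons")
  exon_cluster(segment, label, ve,
               flank5 = const[1L, ], flank3 = const[nrow(const), ])
}
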