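#' Construct a cross-species alignment
#'
#' @param species Character vector of row labels (>= 2 rows).
#' @param seqs Character vector of equal-length gapped sequences over
#'   \code{A,C,G,U,N,-} (T is converted to U).
#' @return Object of class \code{rna_alignment} with a row-major character
#'   matrix \code{mat}.
#' @export
rna_alignment <- function(species, seqs) {
  stopifnot(length(species) == length(seqs), length(seqs) >= 2L)
  seqs <- vapply(seqs, normalize_rna, "", allow_gap = TRUE, USE.NAMES = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  if (lens[1L] == 0L) stop("alignment has zero columns")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- species
  structure(list(species = species, mat = mat, length = ncol(mat)),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("<rna_alignment> %d species x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read an aligned FASTA file as an alignment
#' @param path Aligned FASTA.
#' @return [rna_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  rna_alignment(sub("\\s.*$", "", names(seqs)), as.character(seqs))
}

#' Read a Clustal-format alignment
#' @param path Clustal file (e.g. Clustal Omega output).
#' @return [rna_alignment()].
#' @export
read_alignment_clustal <- function(path) {
  lines <- readLines(path)
  lines <- lines[-1L]                        # header line
  lines <- lines[nzchar(trimws(lines))]
  keep <- grepl("^\\S+\\s+\\S+", lines) & !grepl("^\\s", lines)
  lines <- lines[keep]
  ids <- sub("\\s.*$", "", lines)
  seqs <- sub("\\s+\\d*$", "", sub("^\\S+\\s+", "", lines))
  ord <- unique(ids)
  merged <- vapply(ord, function(id) paste(seqs[ids == id], collapse = ""), "")
  rna_alignment(ord, unname(merged))
}

#' Write an alignment as aligned FASTA
#' @param aln An [rna_alignment()].
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- Biostrings::BStringSet(apply(aln$mat, 1L, paste, collapse = ""))
  names(seqs) <- aln$species
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

shannon_bits <- function(freqs) {
  f <- freqs[freqs > 0]
  -sum(f * log2(f))
}

#' Per-column conservation profile
#'
#' For each column: base frequencies among non-gap, non-N rows; gap
#' fraction; consensus base (most frequent, ties by the fixed order
#' A < C < G < U); and information content \code{2 - H} bits where H is the
#' Shannon entropy of the gap-excluded base distribution (uniform
#' background, as in standard sequence logos). All-gap columns get content
#' 0 and consensus \code{-}.
#'
#' @param aln An [rna_alignment()].
#' @return Data frame with columns \code{column, A, C, G, U, gap, bits,
#'   consensus}.
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  bases <- c("A", "C", "G", "U")
  nr <- nrow(aln$mat)
  out <- lapply(seq_len(ncol(aln$mat)), function(j) {
    col <- aln$mat[, j]
    gap_frac <- sum(col == "-") / nr
    informative <- col[col %in% bases]
    if (length(informative) == 0L) {
      freqs <- stats::setNames(rep(0, 4L), bases)
      bits <- 0
      cons <- "-"
    } else {
      counts <- table(factor(informative, levels = bases))
      freqs <- as.numeric(counts) / length(informative)
      names(freqs) <- bases
      bits <- 2 - shannon_bits(freqs)
      cons <- bases[which.max(freqs)]   # which.max -> first max, A<C<G<U
    }
    data.frame(column = j, A = freqs[["A"]], C = freqs[["C"]], G = freqs[["G"]],
               U = freqs[["U"]], gap = gap_frac, bits = bits,
               consensus = cons, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus sequence of an alignment
#'
#' Per-column most frequent base, ties broken by the fixed base order
#' A < C < G < U; columns with gap fraction > 0.5 are dropped.
#'
#' @param aln An [rna_alignment()].
#' @return RNA string (possibly shorter than the alignment).
#' @export
consensus_rna <- function(aln) {
  prof <- conservation_profile(aln)
  keep <- prof$gap <= 0.5 & prof$consensus != "-"
  paste(prof$consensus[keep], collapse = "")
}

#' Write a conservation profile as TSV
#' @param prof Result of [conservation_profile()].
#' @param path Output file.
#' @export
write_profile_tsv <- function(prof, path) {
  utils::write.table(prof, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Text sequence logo
#'
#' A terminal rendering of the profile: one row per column with a bar whose
#' length is proportional to information content.
#'
#' @param prof Result of [conservation_profile()].
#' @param width Bar width corresponding to 2 bits.
#' @return Character vector, one line per column.
#' @export
text_logo <- function(prof, width = 40L) {
  vapply(seq_len(nrow(prof)), function(i) {
    n <- round(prof$bits[i] / 2 * width)
    sprintf("%4d %s %5.2f %s", prof$column[i], prof$consensus[i], prof$bits[i],
            strrep("#", n))
  }, "")
}

#' Extract a column range of an alignment
#' @param aln An [rna_alignment()].
#' @param start,end 1-based inclusive column range.
#' @return [rna_alignment()] over those columns.
#' @export
alignment_slice <- function(aln, start, end) {
  rna_alignment(aln$species,
                apply(aln$mat[, start:end, drop = FALSE], 1L, paste, collapse = ""))
}

#' Map alignment columns to ungapped per-row coordinates
#'
#' @param aln An [rna_alignment()].
#' @param start,end 1-based inclusive alignment column range.
#' @return Data frame per species with 0-based half-open ungapped
#'   \code{start, end} of the residues covered by the range.
#' @export
ungapped_coords <- function(aln, start, end) {
  out <- lapply(seq_len(nrow(aln$mat)), function(r) {
    row <- aln$mat[r, ]
    nongap <- cumsum(row != "-")
    s <- if (start == 1L) 0L else nongap[start - 1L]
    data.frame(species = aln$species[r], start = as.integer(s),
               end = as.integer(nongap[end]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
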