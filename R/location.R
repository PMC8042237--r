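#' Classify a selector window's position relative to exons
#'
#' Pure set containment on annotated exon intervals, with no tolerance
#' window: a window fully inside any exon is \code{exonic}; a window that
#' overlaps exon sequence without being contained is \code{boundary}; a
#' window touching no exon is \code{intronic}. A window overlapping two
#' exons (possible only with tiny introns) is \code{boundary} with a
#' warning.
#'
#' @param window Numeric \code{c(start, end)}, 0-based half-open, non-empty.
#' @param exon One-row data frame (the window's own exon; kept in the
#'   signature for reporting symmetry — classification considers all exons).
#' @param exons Data frame of all exon intervals (columns start, end).
#' @return \code{"exonic"}, \code{"boundary"} or \code{"intronic"}.
#' @export
classify_location <- function(window, exon, exons) {
  ws <- window[[1L]]; we <- window[[2L]]
  if (!(ws < we)) stop("window must be non-empty")
  contained <- exons$start <= ws & we <= exons$end
  if (any(contained)) return("exonic")
  overlap <- pmax(ws, exons$start) < pmin(we, exons$end)
  if (sum(overlap) >= 2L) {
    warning("selector window overlaps two exons; classifying as boundary")
    return("boundary")
  }
  if (any(overlap)) return("boundary")
  "intronic"
}

#' Fractions of introns shorter than thresholds
#'
#' Strict less-than comparison (an intron of exactly 150 nt does not count
#' as "< 150"); zero-length introns are counted.
#'
#' @param x An [exon_cluster()] (internal introns between consecutive
#'   variable exons are used) or a numeric vector of intron lengths.
#' @param thresholds Positive integer thresholds (nt).
#' @return Named numeric vector, fraction of introns with length < t.
#' @export
intron_length_fractions <- function(x, thresholds = c(50L, 150L)) {
  stopifnot(all(thresholds > 0))
  lengths <- if (inherits(x, "exon_cluster")) {
    if (nrow(x$variable_exons) < 2L) stop("cluster has no internal introns")
    suppressWarnings(introns_of(x)$length)
  } else {
    as.numeric(x)
  }
  if (length(lengths) == 0L) stop("no introns to summarize")
  stats::setNames(vapply(thresholds, function(t) mean(lengths < t), 0),
                  as.character(thresholds))
}

#' Cluster-level location report
#'
#' @param hits Result of [scan_cluster()] (or any data frame with a
#'   \code{location_class} column).
#' @param cluster The [exon_cluster()] the hits belong to.
#' @param thresholds Intron-length thresholds (nt).
#' @return List with per-class counts and fractions (over classified
#'   exons), intron lengths, and threshold fractions.
#' @export
location_report <- function(hits, cluster, thresholds = c(50L, 150L)) {
  classes <- hits$location_class[!is.na(hits$location_class)]
  counts <- table(factor(classes, levels = c("exonic", "boundary", "intronic")))
  fractions <- if (length(classes) > 0L) as.list(counts / length(classes)) else NULL
  lengths <- if (nrow(cluster$variable_exons) >= 2L) {
    suppressWarnings(introns_of(cluster)$length)
  } else numeric(0)
  list(
    class_counts = as.list(counts),
    class_fractions = fractions,
    n_classified = length(classes),
    intron_lengths = lengths,
    intron_fraction_below = if (length(lengths) > 0L) {
      as.list(intron_length_fractions(lengths, thresholds))
    } else NULL
  )
}
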