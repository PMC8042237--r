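#' Scoring parameters for intermolecular duplex alignment
#'
#' A transparent additive scheme standing in for a thermodynamic energy
#' model: stacking and loop entropies are ignored and each legal pair earns
#' a stability-ordered reward (GC three hydrogen bonds, AU two, GU wobble
#' one). Docking/selector inference depends on complementarity *ranking*
#' across candidate windows, not on absolute free energies, so a monotone
#' scheme suffices and keeps the optimum exactly checkable against
#' exhaustive enumeration.
#'
#' Gap runs (bulges/loops) cost \code{gap_open} for the first gapped base
#' and \code{gap_extend} for each further base; runs on the two strands
#' between consecutive pairs are penalized independently.
#'
#' @param score_GC,score_AU,score_GU Per-pair rewards, must satisfy
#'   \code{score_GC >= score_AU >= score_GU > 0}.
#' @param gap_open,gap_extend Non-positive affine gap penalties.
#' @param min_core_len Minimum length of the contiguous paired block
#'   ("core region") for a duplex to count as a genuine stem.
#' @return List of class \code{pair_params}.
#' @export
pair_params <- function(score_GC = 3, score_AU = 2, score_GU = 1,
                        gap_open = -4, gap_extend = -2, min_core_len = 8) {
  stopifnot(score_GC >= score_AU, score_AU >= score_GU, score_GU > 0,
            gap_open <= 0, gap_extend <= 0, min_core_len >= 1)
  structure(list(score_GC = score_GC, score_AU = score_AU, score_GU = score_GU,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_core_len = as.integer(min_core_len)),
            class = "pair_params")
}

#' Classify a base juxtaposition
#'
#' @param a,b Single bases from \code{A,C,G,U,N} (gap \code{-} also maps to
#'   \code{"none"}).
#' @return One of \code{"GC","CG","AU","UA","GU","UG","none"}; anything
#'   involving N is \code{"none"}.
#' @export
pair_type <- function(a, b) {
  key <- paste0(a, b)
  types <- c(GC = "GC", CG = "CG", AU = "AU", UA = "UA", GU = "GU", UG = "UG")
  out <- unname(types[key])
  ifelse(is.na(out), "none", out)
}

#' Predict the optimal RNA-RNA duplex between two strands
#'
#' Maximum-score local alignment of \code{a} against the reverse of \code{b}
#' in which the only aligned columns are legal base pairs (Watson-Crick or
#' GU wobble) scored by \code{params}; illegal juxtapositions are forbidden,
#' not penalized, and bulges/loops incur affine gap costs. Intramolecular
#' structure is ignored (pure hybridization). The empty duplex (score 0) is
#' allowed. Ties are broken toward more pairs, then the 5'-most start on
#' \code{a}.
#'
#' @param a,b Normalized RNA strings (5' to 3'). Positions holding N cannot
#'   pair.
#' @param params A [pair_params()].
#' @return Object of class \code{duplex}: \code{pairs} (two-column matrix of
#'   1-based positions, column 1 increasing in \code{a}, column 2 decreasing
#'   in \code{b}), \code{score}, and \code{core} (see [duplex_core()]).
#' @export
duplex_fold <- function(a, b, params = pair_params()) {
  a <- normalize_rna(a); b <- normalize_rna(b)
  res <- duplex_fold_cpp(a, b, params$score_GC, params$score_AU, params$score_GU,
                         params$gap_open, params$gap_extend)
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  d <- structure(list(pairs = pairs, score = res$score, core = NULL,
                      a = a, b = b), class = "duplex")
  d$core <- duplex_core(d, params$min_core_len)
  d
}

#' @export
print.duplex <- function(x, ...) {
  cat(sprintf("<duplex> score %.1f, %d pairs, core %s\n", x$score, nrow(x$pairs),
              if (is.null(x$core)) "absent"
              else sprintf("%d nt (a:%d-%d, b:%d-%d)", x$core$length,
                           x$core$a_start, x$core$a_end, x$core$b_start, x$core$b_end)))
  invisible(x)
}

#' Locate the core region of a duplex
#'
#' The core region is the longest run of contiguous pairs (consecutive on
#' both strands, no bulges). Ties are broken toward the 5'-most run on
#' strand \code{a}. Runs shorter than \code{min_core_len} yield \code{NULL},
#' signalling a sub-threshold hit.
#'
#' @param d A [duplex_fold()] result.
#' @param min_core_len Minimum acceptable run length.
#' @return \code{NULL}, or a list with 1-based inclusive spans
#'   \code{a_start, a_end, b_start, b_end} and \code{length}.
#' @export
duplex_core <- function(d, min_core_len = 8) {
  p <- d$pairs
  if (nrow(p) == 0L) return(NULL)
  run_id <- cumsum(c(1L, diff(p[, 1L]) != 1L | diff(p[, 2L]) != -1L))
  lens <- tabulate(run_id)
  best <- which.max(lens)  # first maximal run = 5'-most on a
  if (lens[best] < min_core_len) return(NULL)
  idx <- which(run_id == best)
  list(a_start = unname(p[idx[1L], 1L]), a_end = unname(p[idx[length(idx)], 1L]),
       b_start = unname(p[idx[length(idx)], 2L]), b_end = unname(p[idx[1L], 2L]),
       length = lens[best])
}

#' Render a duplex as a two-line text pairing diagram
#'
#' Strand \code{a} 5'->3' over strand \code{b} 3'->5', with \code{|} for
#' Watson-Crick pairs and \code{:} for GU wobble across the paired region.
#'
#' @param d A duplex.
#' @return Character vector of three lines.
#' @export
duplex_text <- function(d) {
  p <- d$pairs
  if (nrow(p) == 0L) return(c("(empty duplex)", "", ""))
  achars <- strsplit(d$a, "")[[1L]]
  bchars <- strsplit(d$b, "")[[1L]]
  # walk paired region with bulges spelled out
  top <- character(0); mid <- character(0); bot <- character(0)
  for (k in seq_len(nrow(p))) {
    if (k > 1L) {
      ga <- seq_len(p[k, 1L] - p[k - 1L, 1L] - 1L)
      for (g in ga + p[k - 1L, 1L]) { top <- c(top, achars[g]); mid <- c(mid, " "); bot <- c(bot, "-") }
      gb <- seq_len(p[k - 1L, 2L] - p[k, 2L] - 1L)
      for (g in p[k - 1L, 2L] - gb) { top <- c(top, "-"); mid <- c(mid, " "); bot <- c(bot, bchars[g]) }
    }
    pt <- pair_type(achars[p[k, 1L]], bchars[p[k, 2L]])
    top <- c(top, achars[p[k, 1L]])
    mid <- c(mid, if (pt %in% c("GU", "UG")) ":" else "|")
    bot <- c(bot, bchars[p[k, 2L]])
  }
  c(paste0("5' ", paste(top, collapse = ""), " 3'"),
    paste0("   ", paste(mid, collapse = "")),
    paste0("3' ", paste(bot, collapse = ""), " 5'"))
}

#' Serialize a duplex to JSON
#'
#' @param d A duplex.
#' @return JSON string with pairs (1-based), score and core.
#' @export
duplex_json <- function(d) {
  jsonlite::toJSON(list(
    pairs = if (nrow(d$pairs)) unname(apply(d$pairs, 1L, as.list)) else list(),
    score = d$score,
    core = d$core
  ), auto_unbox = TRUE, digits = NA)
}
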