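#' Join docking-site and selector alignments through a pairing map
#'
#' @param docking_aln,selector_aln [rna_alignment()] objects with identical
#'   species rows in the same order.
#' @param pairing_map Two-column matrix/data frame of 1-based columns
#'   (docking column, selector column) from a reference duplex; must be
#'   strictly monotone (docking increasing, selector decreasing:
#'   antiparallel).
#' @return Object of class \code{paired_alignment}.
#' @export
paired_alignment <- function(docking_aln, selector_aln, pairing_map) {
  stopifnot(inherits(docking_aln, "rna_alignment"),
            inherits(selector_aln, "rna_alignment"))
  if (!identical(docking_aln$species, selector_aln$species)) {
    stop("docking and selector alignments must have identical species rows")
  }
  pm <- as.matrix(pairing_map)
  if (nrow(pm) == 0L) stop("pairing map is empty")
  colnames(pm) <- c("docking_col", "selector_col")
  if (any(pm[, 1L] < 1L) || any(pm[, 1L] > docking_aln$length) ||
      any(pm[, 2L] < 1L) || any(pm[, 2L] > selector_aln$length)) {
    stop("pairing map column out of bounds")
  }
  if (nrow(pm) > 1L && (any(diff(pm[, 1L]) <= 0L) || any(diff(pm[, 2L]) >= 0L))) {
    stop("pairing map must be strictly monotone (antiparallel)")
  }
  structure(list(docking = docking_aln, selector = selector_aln, map = pm),
            class = "paired_alignment")
}

#' Classify the evolution of one paired column
#'
#' Rules, in precedence order: any gap or N in either partner makes the
#' column \code{gapped}; any species whose juxtaposition is not a legal
#' pair makes it \code{broken}; all species showing the same Watson-Crick
#' pair type is \code{conserved_pair}; two or more distinct Watson-Crick
#' types present (both partners changed between some species pair) is
#' \code{compensatory}; a mixture of Watson-Crick and GU/UG wobble only —
#' or exclusively wobble — is \code{intermediate_wobble}.
#'
#' The strict broken rule (one breaking species condemns the column) can be
#' relaxed with \code{lenient}: species breaking the pair are dropped from
#' the verdict as long as they are fewer than \code{lenient_frac} of the
#' rows.
#'
#' @param bases_docking,bases_selector Per-species bases (same length >= 2)
#'   from \code{A,C,G,U,N,-}.
#' @param lenient Tolerate a minority of breaking species.
#' @param lenient_frac Maximum tolerated breaking fraction (exclusive).
#' @return List with \code{verdict} and per-species \code{types}.
#' @export
classify_pair_column <- function(bases_docking, bases_selector,
                                 lenient = FALSE, lenient_frac = 0.2) {
  if (length(bases_docking) != length(bases_selector)) {
    stop("row-count mismatch between docking and selector bases")
  }
  if (length(bases_docking) < 2L) stop("need at least two species")
  types <- pair_type(bases_docking, bases_selector)
  gapped <- bases_docking %in% c("-", "N") | bases_selector %in% c("-", "N")
  if (any(gapped)) {
    return(list(verdict = "gapped", types = types))
  }
  broken <- types == "none"
  if (any(broken)) {
    if (!lenient || mean(broken) >= lenient_frac || all(broken)) {
      return(list(verdict = "broken", types = types))
    }
    types_eff <- types[!broken]
  } else {
    types_eff <- types
  }
  wc <- types_eff[types_eff %in% c("GC", "CG", "AU", "UA")]
  wob <- types_eff[types_eff %in% c("GU", "UG")]
  verdict <- if (length(unique(wc)) >= 2L) {
    "compensatory"
  } else if (length(wob) > 0L) {
    "intermediate_wobble"
  } else {
    "conserved_pair"
  }
  list(verdict = verdict, types = types)
}

#' Per-column verdicts for a paired alignment
#'
#' @param pa A [paired_alignment()].
#' @param lenient,lenient_frac See [classify_pair_column()].
#' @return Data frame: docking_col, selector_col, verdict, and one
#'   pair-type column per species.
#' @export
covariation_verdicts <- function(pa, lenient = FALSE, lenient_frac = 0.2) {
  out <- lapply(seq_len(nrow(pa$map)), function(k) {
    dc <- pa$map[k, 1L]; sc <- pa$map[k, 2L]
    res <- classify_pair_column(pa$docking$mat[, dc], pa$selector$mat[, sc],
                                lenient, lenient_frac)
    df <- data.frame(docking_col = dc, selector_col = sc,
                     verdict = res$verdict, stringsAsFactors = FALSE)
    for (i in seq_along(pa$docking$species)) {
      df[[pa$docking$species[i]]] <- res$types[i]
    }
    df
  })
  do.call(rbind, out)
}

VERDICT_LEVELS <- c("conserved_pair", "compensatory", "intermediate_wobble",
                    "broken", "gapped")

#' Summarize covariation over a paired alignment
#'
#' Counts and fractions per verdict, plus the "pairing maintained"
#' fraction: (conserved + compensatory + wobble) / non-gapped columns.
#' If a core-region restriction is supplied, the same tallies are also
#' computed over pairing-map entries whose docking column lies in the core.
#'
#' @param pa A [paired_alignment()].
#' @param core Optional 1-based inclusive docking-column range
#'   \code{c(start, end)} of the duplex core region.
#' @param lenient,lenient_frac See [classify_pair_column()].
#' @return List with \code{verdicts} (data frame), \code{counts},
#'   \code{fractions}, \code{maintained_fraction},
#'   \code{n_informative} (non-gapped columns), \code{note}
#'   ("no informative columns" when everything is gapped), and \code{core}
#'   (same tallies restricted to the core, or NULL).
#' @export
covariation_summary <- function(pa, core = NULL, lenient = FALSE,
                                lenient_frac = 0.2) {
  v <- covariation_verdicts(pa, lenient, lenient_frac)
  tally <- function(verdicts) {
    counts <- table(factor(verdicts, levels = VERDICT_LEVELS))
    n_inf <- sum(counts) - counts[["gapped"]]
    maintained <- if (n_inf > 0) {
      (counts[["conserved_pair"]] + counts[["compensatory"]] +
         counts[["intermediate_wobble"]]) / n_inf
    } else NA_real_
    list(counts = as.list(counts),
         fractions = if (n_inf > 0) as.list(counts / n_inf) else NULL,
         maintained_fraction = maintained,
         n_informative = unname(n_inf))
  }
  full <- tally(v$verdict)
  out <- list(verdicts = v, counts = full$counts, fractions = full$fractions,
              maintained_fraction = full$maintained_fraction,
              n_informative = full$n_informative,
              note = if (full$n_informative == 0) "no informative columns" else NULL,
              core = NULL)
  if (!is.null(core)) {
    in_core <- v$docking_col >= core[1L] & v$docking_col <= core[2L]
    out$core <- tally(v$verdict[in_core])
  }
  out
}

#' Render a paired alignment with verdict glyphs
#'
#' Text rendering in the style of published docking/selector figures:
#' docking consensus over selector consensus with one glyph per paired
#' column (\code{|} conserved, \code{*} compensatory, \code{:} wobble
#' intermediate, \code{x} broken, \code{.} gapped).
#'
#' @param pa A [paired_alignment()].
#' @param lenient,lenient_frac See [classify_pair_column()].
#' @return Character vector of three lines.
#' @export
covariation_text <- function(pa, lenient = FALSE, lenient_frac = 0.2) {
  v <- covariation_verdicts(pa, lenient, lenient_frac)
  dcons <- conservation_profile(pa$docking)$consensus
  scons <- conservation_profile(pa$selector)$consensus
  glyph <- c(conserved_pair = "|", compensatory = "*",
             intermediate_wobble = ":", broken = "x", gapped = ".")
  c(paste0("docking  5' ", paste(dcons[v$docking_col], collapse = ""), " 3'"),
    paste0("            ", paste(glyph[v$verdict], collapse = "")),
    paste0("selector 3' ", paste(scons[v$selector_col], collapse = ""), " 5'"))
}
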