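#' Find candidate docking sites in an aligned flanking intron
#'
#' Slides windows of every length in \code{[win_min, win_max]} across the
#' alignment, scoring each by the mean per-column information content over
#' non-majority-gap columns, and returns the non-overlapping top-scoring
#' windows above \code{min_bits}. Ties are broken toward longer windows,
#' then the 5'-most.
#'
#' @param aln An [rna_alignment()] of the orthologous flanking intron across
#'   >= 2 species.
#' @param side \code{"upstream_of_cluster"} or \code{"downstream_of_cluster"}.
#' @param win_min,win_max Window length bounds (nt). Docking sites in
#'   figures of this literature are short elements; 15-40 nt covers them.
#' @param min_bits Discovery threshold on mean information content
#'   (max 2.0 = invariant). 1.5 demands strong but not strict invariance.
#' @param max_sites Maximum number of non-overlapping sites to return.
#' @return List of \code{docking_site} objects, sorted by score, possibly
#'   empty. Each has alignment-coordinate \code{aln_start, aln_end} (1-based
#'   inclusive), \code{per_species} ungapped coordinates (0-based
#'   half-open), \code{consensus}, \code{mean_bits}, \code{scope}
#'   (provisional \code{"clade_specific"}), \code{species_set} and
#'   \code{side}.
#' @export
find_docking_sites <- function(aln, side = c("downstream_of_cluster", "upstream_of_cluster"),
                               win_min = 15L, win_max = 40L, min_bits = 1.5,
                               max_sites = 3L) {
  side <- match.arg(side)
  stopifnot(inherits(aln, "rna_alignment"))
  prof <- conservation_profile(aln)
  good <- prof$gap <= 0.5
  bits <- ifelse(good, prof$bits, 0)
  L <- length(bits)
  if (L < win_min) return(list())
  cb <- cumsum(c(0, bits))
  cg <- cumsum(c(0, as.numeric(good)))
  cand <- NULL
  for (w in seq(win_min, min(win_max, L))) {
    s <- seq_len(L - w + 1L)
    ngood <- cg[s + w] - cg[s]
    score <- ifelse(ngood > 0, (cb[s + w] - cb[s]) / ngood, NA_real_)
    keep <- !is.na(score) & score >= min_bits
    if (any(keep)) {
      cand <- rbind(cand, data.frame(start = s[keep], w = w, score = score[keep]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0L) return(list())
  cand <- cand[order(-cand$score, -cand$w, cand$start), ]
  chosen <- list(); occupied <- rep(FALSE, L)
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[k]; e <- s + cand$w[k] - 1L
    if (any(occupied[s:e])) next
    occupied[s:e] <- TRUE
    chosen[[length(chosen) + 1L]] <- cand[k, ]
    if (length(chosen) >= max_sites) break
  }
  lapply(chosen, function(row) {
    s <- row$start; e <- row$start + row$w - 1L
    slice <- alignment_slice(aln, s, e)
    structure(list(
      side = side, aln_start = s, aln_end = e,
      per_species = ungapped_coords(aln, s, e),
      consensus = consensus_rna(slice),
      mean_bits = row$score,
      scope = "clade_specific",
      species_set = aln$species
    ), class = "docking_site")
  })
}

#' @export
print.docking_site <- function(x, ...) {
  cat(sprintf("<docking_site> %s cols %d-%d (%.2f bits, %s: %s)\n  consensus %s\n",
              x$side, x$aln_start, x$aln_end, x$mean_bits, x$scope,
              paste(x$species_set, collapse = ","), x$consensus))
  invisible(x)
}

row_window_identity <- function(aln, site) {
  cols <- site$aln_start:site$aln_end
  prof <- conservation_profile(alignment_slice(aln, site$aln_start, site$aln_end))
  keep <- prof$gap <= 0.5 & prof$consensus != "-"
  cons <- prof$consensus[keep]
  vapply(seq_len(nrow(aln$mat)), function(r) {
    if (!length(cons)) return(0)
    mean(aln$mat[r, cols][keep] == cons)
  }, 0)
}

row_overall_agreement <- function(aln) {
  prof <- conservation_profile(aln)
  cons <- prof$consensus
  vapply(seq_len(nrow(aln$mat)), function(r) mean(aln$mat[r, ] == cons), 0)
}

subset_alignment <- function(aln, species) {
  idx <- match(species, aln$species)
  rna_alignment(aln$species[idx],
                apply(aln$mat[idx, , drop = FALSE], 1L, paste, collapse = ""))
}

#' Partition species by docking-site scope
#'
#' Attempts discovery on the full species set; when it fails, or leaves
#' species uncovered, greedily drops the species with the worst agreement
#' to the column consensus and retries, then recurses on the leftover
#' species — mirroring the manual comparative workflow that separates a
#' main clade from species carrying their own site variant. A site covering
#' at least half of the input species is labelled \code{clade_specific};
#' smaller groups are \code{species_specific}. A single-species input is
#' \code{species_specific} by definition. Species covered by no site are
#' listed under \code{unresolved}.
#'
#' @param aln Flanking-intron [rna_alignment()] over all species.
#' @param side Passed to [find_docking_sites()].
#' @param win_min,win_max,min_bits,max_sites Discovery parameters.
#' @param cover_min_identity Minimum per-row identity to the site consensus
#'   for a species to count as covered by the site.
#' @param candidate_ranker Optional function(list of docking_site) -> one
#'   docking_site or NULL, used to choose among same-subset candidates
#'   (e.g. by selector support) and to veto candidates that are conserved
#'   but not docking-like (returning NULL). Default takes the top-scoring
#'   candidate. When the ranker vetoes every candidate, discovery retries
#'   at a relaxed threshold to locate the group-splitting window (a site
#'   shared by only part of the species scores low on the mixed alignment)
#'   and recurses on the covered subset.
#' @return List with \code{sites} (list of docking_site with filled
#'   \code{scope}/\code{species_set}) and \code{unresolved} (character).
#' @export
partition_by_scope <- function(aln, side = "downstream_of_cluster",
                               win_min = 15L, win_max = 40L, min_bits = 1.5,
                               max_sites = 3L, cover_min_identity = 0.7,
                               candidate_ranker = NULL) {
  n_input <- length(aln$species)
  sites <- list(); unresolved <- character(0)
  pool <- aln$species

  pick <- function(cands) {
    if (length(cands) == 0L) return(NULL)
    if (is.null(candidate_ranker)) cands[[1L]] else candidate_ranker(cands)
  }

  attempt <- function(spp) {
    kept <- spp
    repeat {
      if (length(kept) < 2L) return(NULL)
      sub <- subset_alignment(aln, kept)
      site <- pick(find_docking_sites(sub, side, win_min, win_max, min_bits,
                                      max_sites))
      if (!is.null(site)) {
        ident <- row_window_identity(sub, site)
        covered <- kept[ident >= cover_min_identity]
        if (length(covered) < 2L) return(NULL)
        if (length(covered) < length(kept)) return(attempt(covered))
        site$species_set <- covered
        site$per_species <- site$per_species[site$per_species$species %in% covered, ]
        return(site)
      }
      # every strong window was vetoed (or none existed): a site carried by
      # only part of the species scores low on the mixed alignment, so look
      # for it at a relaxed threshold and recurse on the species it covers
      if (!is.null(candidate_ranker)) {
        relaxed <- pick(find_docking_sites(sub, side, win_min, win_max,
                                           min_bits * 0.6, max_sites))
        if (!is.null(relaxed)) {
          covered <- kept[row_window_identity(sub, relaxed) >= cover_min_identity]
          if (length(covered) >= 2L && length(covered) < length(kept)) {
            return(attempt(covered))
          }
        }
      }
      worst <- kept[which.min(row_overall_agreement(sub))]
      kept <- setdiff(kept, worst)
    }
  }

  while (length(pool) > 0L) {
    if (length(pool) == 1L) {
      if (n_input == 1L) {
        # vacuous conservation: report the 5'-most max-length window
        row <- paste(aln$mat[match(pool, aln$species), ], collapse = "")
        w <- min(win_max, nchar(row))
        sites[[length(sites) + 1L]] <- structure(list(
          side = side, aln_start = 1L, aln_end = w,
          per_species = data.frame(species = pool, start = 0L, end = w),
          consensus = substr(gsub("-", "", row), 1L, w),
          mean_bits = 2.0, scope = "species_specific", species_set = pool
        ), class = "docking_site")
      } else {
        unresolved <- c(unresolved, pool)
      }
      break
    }
    site <- attempt(pool)
    if (is.null(site)) { unresolved <- c(unresolved, pool); break }
    site$scope <- if (n_input > 1L && length(site$species_set) >= ceiling(n_input / 2)) {
      "clade_specific"
    } else "species_specific"
    sites[[length(sites) + 1L]] <- site
    pool <- setdiff(pool, site$species_set)
  }
  list(sites = sites, unresolved = unresolved)
}

#' Tabulate docking sites
#'
#' @param sites List of \code{docking_site} objects.
#' @return Data frame (one row per site per species) suitable for TSV
#'   export; alignment spans 1-based inclusive, genomic spans 1-based
#'   inclusive for readability.
#' @export
docking_sites_table <- function(sites) {
  if (length(sites) == 0L) {
    return(data.frame(side = character(0), aln_start = integer(0),
                      aln_end = integer(0), species = character(0),
                      start = integer(0), end = integer(0),
                      consensus = character(0), mean_bits = numeric(0),
                      scope = character(0)))
  }
  do.call(rbind, lapply(sites, function(s) {
    data.frame(side = s$side, aln_start = s$aln_start, aln_end = s$aln_end,
               species = s$per_species$species,
               start = s$per_species$start + 1L, end = s$per_species$end,
               consensus = s$consensus, mean_bits = s$mean_bits,
               scope = s$scope, stringsAsFactors = FALSE)
  }))
}
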