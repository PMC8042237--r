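#' Scan geometry for selector discovery
#'
#' Which side of each variable exon is searched, and against which docking
#' site. \code{downstream_selector}: a single docking site downstream of
#' the cluster pairs with selectors downstream of each exon (exon-4-like).
#' \code{upstream_selector}: a single upstream docking site pairs with
#' selectors upstream of each exon (exon-6-like; selectors may intrude into
#' the exon, so \code{allow_exonic} defaults to TRUE there). \code{bidirectional}:
#' the upstream docking site pairs with downstream selectors and the
#' downstream docking site with upstream selectors (exon-9-like dual
#' pairing).
#'
#' @param mode One of \code{"downstream_selector"}, \code{"upstream_selector"},
#'   \code{"bidirectional"}.
#' @param search_span Maximum nt beyond the exon boundary to scan
#'   (truncated at the neighboring exon).
#' @param allow_exonic Permit windows extending into the exon. Default TRUE
#'   for \code{upstream_selector}, FALSE otherwise.
#' @return List of class \code{scan_geometry}.
#' @export
scan_geometry <- function(mode = c("downstream_selector", "upstream_selector",
                                   "bidirectional"),
                          search_span = 500L, allow_exonic = NULL) {
  mode <- match.arg(mode)
  stopifnot(search_span > 0L)
  if (is.null(allow_exonic)) allow_exonic <- mode == "upstream_selector"
  structure(list(mode = mode, search_span = as.integer(search_span),
                 allow_exonic = allow_exonic),
            class = "scan_geometry")
}

selector_directions <- function(geometry) {
  switch(geometry$mode,
         downstream_selector = "downstream",
         upstream_selector = "upstream",
         bidirectional = c("upstream", "downstream"))
}

# docking side whose site pairs with selectors on `direction` side of exons
partner_site_side <- function(geometry, direction) {
  if (geometry$mode == "bidirectional") {
    if (direction == "downstream") "upstream_of_cluster" else "downstream_of_cluster"
  } else {
    if (direction == "downstream") "downstream_of_cluster" else "upstream_of_cluster"
  }
}

# search region (0-based half-open) on `direction` side of exon row `k`
scan_region <- function(cluster, k, direction, geometry, win_max) {
  ve <- cluster$variable_exons
  ex <- ve[k, ]
  if (direction == "downstream") {
    lo <- ex$end
    hi <- if (k < nrow(ve)) ve$start[k + 1L] else cluster$flank3$start
    hi <- min(hi, ex$end + geometry$search_span)
    if (geometry$allow_exonic) lo <- max(ex$start, ex$end - win_max)
  } else {
    hi <- ex$start
    lo <- if (k > 1L) ve$end[k - 1L] else cluster$flank5$end
    lo <- max(lo, ex$start - geometry$search_span)
    if (geometry$allow_exonic) hi <- min(ex$end, ex$start + win_max)
  }
  c(lo, hi)
}

#' Find the best selector for one variable exon
#'
#' Every window with length within \code{[site length - 5, site length + 10]}
#' inside the exon's search region is duplex-folded against the docking-site
#' consensus; the maximal-score window whose duplex has a valid core region
#' (contiguous paired block of at least \code{params$min_core_len}) and
#' score at least \code{min_score_per_nt} per docking-site nucleotide is
#' returned. Score ties go to the window
#' nearest the exon boundary, then the 5'-most.
#'
#' @param cluster An [exon_cluster()].
#' @param exon_index Index value of the variable exon to scan.
#' @param site A \code{docking_site} (its consensus is used).
#' @param direction \code{"upstream"} or \code{"downstream"}: which side of
#'   the exon holds the candidate selector.
#' @param geometry A [scan_geometry()].
#' @param params A [pair_params()].
#' @param min_score_per_nt Minimum acceptable duplex score per nucleotide
#'   of the docking-site consensus (the absolute threshold scales with the
#'   site length; 1.25/nt corresponds to score 30 for a 24-nt site, the
#'   null-calibrated default discussed in the package vignette). Below it
#'   the exon is reported as having no selector.
#' @return A \code{selector_hit} list, or \code{NULL} if no window
#'   qualifies.
#' @export
scan_exon <- function(cluster, exon_index, site, direction, geometry,
                      params = pair_params(), min_score_per_nt = 1.25) {
  ve <- cluster$variable_exons
  k <- match(exon_index, ve$index)
  if (is.na(k)) stop("no variable exon with index ", exon_index)
  site_len <- nchar(site$consensus)
  min_score <- min_score_per_nt * site_len
  wmin <- max(5L, site_len - 5L)
  wmax <- site_len + 10L
  reg <- scan_region(cluster, k, direction, geometry, wmax)
  if (reg[2L] - reg[1L] < wmin) return(NULL)
  region_seq <- subseq_rna(cluster$segment, reg[1L], reg[2L])
  scores <- scan_windows_cpp(site$consensus, region_seq, wmin, wmax,
                             params$score_GC, params$score_AU, params$score_GU,
                             params$gap_open, params$gap_extend)
  idx <- which(!is.na(scores) & scores >= min_score, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  ends <- idx[, 1L]                         # window end, exclusive, in region
  lens <- idx[, 2L] + wmin - 1L
  starts <- ends - lens
  gstart <- reg[1L] + starts                # 0-based genomic
  gend <- reg[1L] + ends
  boundary <- if (direction == "downstream") ve$end[k] else ve$start[k]
  dist <- if (direction == "downstream") abs(gstart - boundary) else abs(boundary - gend)
  # ties: tightest window (no free flanks), then nearest the exon boundary,
  # then 5'-most
  ord <- order(-scores[idx], lens, dist, gstart)
  for (r in utils::head(ord, 50L)) {
    win_seq <- substr(region_seq, starts[r] + 1L, ends[r])
    d <- duplex_fold(site$consensus, win_seq, params)
    if (!is.null(d$core) && d$score >= min_score) {
      return(structure(list(
        exon_index = ve$index[k],
        direction = direction,
        site_side = site$side, site_scope = site$scope,
        window = c(start = unname(gstart[r]), end = unname(gend[r])),
        duplex = d, score = d$score,
        core_len = d$core$length, n_pairs = nrow(d$pairs),
        location_class = NA_character_
      ), class = "selector_hit"))
    }
  }
  NULL
}

site_for_species <- function(sites, species, side) {
  covering <- Filter(function(s) s$side == side && species %in% s$species_set, sites)
  if (length(covering) == 0L) return(NULL)
  specific <- Filter(function(s) s$scope == "species_specific", covering)
  if (length(specific) > 0L) specific[[1L]] else covering[[1L]]
}

#' Scan a whole cluster for selectors
#'
#' Runs [scan_exon()] for every variable exon under the geometry's
#' direction(s). In bidirectional mode each exon is scanned twice (upstream
#' window against the downstream docking site, downstream window against
#' the upstream docking site), forming the dual pairing map. When a species
#' is covered by both a clade-specific and a species-specific site, the
#' species-specific one takes precedence.
#'
#' @param cluster An [exon_cluster()].
#' @param sites List of \code{docking_site} objects.
#' @param geometry A [scan_geometry()].
#' @param params A [pair_params()].
#' @param min_score_per_nt See [scan_exon()].
#' @param directions Optional subset of the geometry's directions to scan
#'   (restricting a bidirectional run to one direction gives exactly the
#'   rows of the full dual run for that direction).
#' @return Data frame with one row per (exon, direction): species, cluster,
#'   exon_index, direction, found, 0-based half-open window, score,
#'   core_len, n_pairs, site_side, site_scope, location_class. A list
#'   column \code{hit} keeps the full \code{selector_hit} objects.
#' @export
scan_cluster <- function(cluster, sites, geometry, params = pair_params(),
                         min_score_per_nt = 1.25, directions = NULL) {
  if (length(sites) == 0L) stop("scan_cluster needs at least one docking site")
  ve <- cluster$variable_exons
  species <- cluster$segment$species
  rows <- list(); hits <- list()
  dirs <- directions %||% selector_directions(geometry)
  stopifnot(all(dirs %in% selector_directions(geometry)))
  for (direction in dirs) {
    side <- partner_site_side(geometry, direction)
    site <- site_for_species(sites, species, side)
    for (k in seq_len(nrow(ve))) {
      hit <- if (is.null(site)) NULL else {
        scan_exon(cluster, ve$index[k], site, direction, geometry, params, min_score_per_nt)
      }
      all_ex <- rbind(ve[, c("start", "end")],
                      cluster$flank5[, c("start", "end")],
                      cluster$flank3[, c("start", "end")])
      if (!is.null(hit)) {
        hit$location_class <- classify_location(hit$window, ve[k, ], all_ex)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, cluster = cluster$cluster_label,
        exon_index = ve$index[k], direction = direction,
        found = !is.null(hit),
        start = if (is.null(hit)) NA_integer_ else hit$window[["start"]],
        end = if (is.null(hit)) NA_integer_ else hit$window[["end"]],
        score = if (is.null(hit)) NA_real_ else hit$score,
        core_len = if (is.null(hit)) NA_integer_ else hit$core_len,
        n_pairs = if (is.null(hit)) NA_integer_ else hit$n_pairs,
        site_side = if (is.null(site)) NA_character_ else site$side,
        site_scope = if (is.null(site)) NA_character_ else site$scope,
        location_class = if (is.null(hit)) NA_character_ else hit$location_class,
        stringsAsFactors = FALSE
      )
      hits <- c(hits, list(hit))
    }
  }
  out <- do.call(rbind, rows)
  out$hit <- hits
  out
}

#' Human-readable selector hit table (1-based inclusive coordinates)
#' @param hits Result of [scan_cluster()].
#' @return Data frame without the list column, windows 1-based inclusive.
#' @export
selector_hits_table <- function(hits) {
  out <- hits[, setdiff(names(hits), "hit")]
  out$start <- out$start + 1L
  out
}
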