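`%||%` <- function(a, b) if (is.null(a)) b else a

side_key <- function(side) sub("_of_cluster", "", side)
side_full <- function(key) paste0(key, "_of_cluster")

intron_genomic_start <- function(cluster, key) {
  if (key == "upstream") cluster$flank5$end else {
    cluster$variable_exons$end[nrow(cluster$variable_exons)]
  }
}

# attach genomic windows (0-based half-open) to a site's per-species table
attach_genomic <- function(site, clusters, key) {
  ps <- site$per_species
  off <- vapply(ps$species, function(sp) intron_genomic_start(clusters[[sp]], key), 0L)
  ps$gstart <- ps$start + off
  ps$gend <- ps$end + off
  site$per_species <- ps
  site
}

# rank candidate docking windows by total selector support: the docking
# site is the conserved element complementary to many exon-adjacent
# windows, so candidates are scored by the summed best duplex score over
# all exons of one covered species, and the best-supported one wins.
# Candidates whose support falls below half of the acceptance threshold
# per exon are vetoed (returning NULL): a conserved block with no selector
# complementarity is itself a selector or other element, not a docking
# site.
support_ranker <- function(clusters, geometry, params, key,
                           min_score_per_nt = 1.25) {
  directions <- selector_directions(geometry)
  paired_dirs <- directions[vapply(directions, function(d) {
    side_key(partner_site_side(geometry, d)) == key
  }, TRUE)]
  function(cands) {
    if (length(cands) == 0L) return(NULL)
    support <- vapply(cands, function(site) {
      sp <- site$species_set[1L]
      cl <- clusters[[sp]]
      tot <- 0
      for (d in paired_dirs) {
        for (k in seq_len(nrow(cl$variable_exons))) {
          hit <- scan_exon(cl, cl$variable_exons$index[k], site, d,
                           geometry, params,
                           min_score_per_nt = min_score_per_nt)
          if (!is.null(hit)) tot <- tot + hit$score
        }
      }
      tot
    }, 0)
    n_exons <- nrow(clusters[[1L]]$variable_exons)
    floors <- vapply(cands, function(site) {
      0.5 * min_score_per_nt * nchar(site$consensus) * n_exons * length(paired_dirs)
    }, 0)
    ok <- support >= floors
    if (!any(ok)) return(NULL)
    support[!ok] <- -Inf
    cands[[which.max(support)]]
  }
}

#' Run the full docking/selector inference on one cluster
#'
#' Orchestrates the stages: docking-site discovery with scope partitioning
#' on the flanking-intron alignment(s), per-exon selector scanning in every
#' species, covariation classification of each docking-selector pairing
#' across the species covered by a site, selector location classification,
#' intron-length statistics, and isoform combinatorics. Inputs come either
#' from the synthetic generator (pass a [sim_config()] or
#' [simulate_cluster()] result) or from files read into clusters and
#' alignments by the caller.
#'
#' Machine outputs contain no timestamps, so two runs with the same seed
#' and configuration are byte-identical.
#'
#' @param sim A [sim_config()] or \code{cluster_sim}; mutually exclusive
#'   with \code{clusters}/\code{intron_alignments}.
#' @param clusters Named list (by species) of [exon_cluster()] objects.
#' @param intron_alignments List with elements \code{upstream} and/or
#'   \code{downstream}: [rna_alignment()] of the flanking introns.
#' @param geometry A [scan_geometry()]; defaults to the simulator's mode.
#' @param params A [pair_params()].
#' @param discovery List of discovery parameters (\code{win_min, win_max,
#'   min_bits, max_sites, cover_min_identity}).
#' @param min_score_per_nt Selector acceptance threshold per docking-site
#'   nucleotide (see [scan_exon()]).
#' @param cluster_sizes Variable-exon counts per cluster for the isoform
#'   product; defaults to this cluster's exon count alone.
#' @param out_dir If non-NULL, the report bundle is written there as
#'   TSV/JSON plus a markdown report.
#' @return A report bundle (list) with elements \code{sites},
#'   \code{unresolved}, \code{hits}, \code{covariation}, \code{location},
#'   \code{isoforms}, \code{geometry}, \code{parameters}.
#' @export
run_cluster_analysis <- function(sim = NULL, clusters = NULL,
                                 intron_alignments = NULL, geometry = NULL,
                                 params = pair_params(),
                                 discovery = list(), min_score_per_nt = 1.25,
                                 cluster_sizes = NULL, out_dir = NULL) {
  if (!is.null(sim)) {
    if (inherits(sim, "sim_config")) sim <- simulate_cluster(sim)
    stopifnot(inherits(sim, "cluster_sim"))
    clusters <- sim$species
    intron_alignments <- list(upstream = sim$alignments$intron_upstream,
                              downstream = sim$alignments$intron_downstream)
    geometry <- geometry %||% scan_geometry(mode = sim$config$geometry)
  }
  if (is.null(clusters) || length(clusters) == 0L) {
    stop("no clusters supplied: pass `sim` or `clusters`")
  }
  if (is.null(geometry)) stop("geometry must be supplied for file inputs")
  disc <- utils::modifyList(list(win_min = 15L, win_max = 40L, min_bits = 1.5,
                                 max_sites = 3L, cover_min_identity = 0.7),
                            discovery)

  directions <- selector_directions(geometry)
  keys <- unique(vapply(directions, function(d) {
    side_key(partner_site_side(geometry, d))
  }, ""))

  # stage 1: docking discovery with scope partitioning per needed side
  sites <- list(); unresolved <- character(0)
  for (key in keys) {
    aln <- intron_alignments[[key]]
    if (is.null(aln)) {
      stop(sprintf("missing %s flanking-intron alignment required by geometry", key))
    }
    part <- partition_by_scope(
      aln, side = side_full(key),
      win_min = disc$win_min, win_max = disc$win_max,
      min_bits = disc$min_bits, max_sites = disc$max_sites,
      cover_min_identity = disc$cover_min_identity,
      candidate_ranker = support_ranker(clusters, geometry, params, key,
                                        min_score_per_nt)
    )
    part$sites <- lapply(part$sites, attach_genomic, clusters = clusters, key = key)
    sites <- c(sites, part$sites)
    unresolved <- union(unresolved, part$unresolved)
  }
  if (length(sites) == 0L) stop("docking discovery found no site on any side")

  # stage 2: selector scan per species
  hits <- do.call(rbind, lapply(names(clusters), function(sp) {
    scan_cluster(clusters[[sp]], sites, geometry, params, min_score_per_nt)
  }))

  # stage 3: covariation per site group and exon
  covar <- list()
  for (site in sites) {
    spp <- site$species_set
    if (length(spp) < 2L) next
    key <- side_key(site$side)
    ps <- site$per_species
    dock_aln <- rna_alignment(spp, vapply(spp, function(sp) {
      subseq_rna(clusters[[sp]]$segment,
                 ps$gstart[ps$species == sp], ps$gend[ps$species == sp])
    }, "", USE.NAMES = FALSE))
    dcons <- consensus_rna(dock_aln)
    for (d in directions) {
      if (side_key(partner_site_side(geometry, d)) != key) next
      for (ex in unique(hits$exon_index)) {
        sub <- hits[hits$species %in% spp & hits$exon_index == ex &
                      hits$direction == d & hits$found, ]
        if (nrow(sub) < length(spp)) next
        # per-species windows can be trimmed differently by the scan; the
        # modal window is extracted from every species (windows share
        # coordinates under the no-indel alignment model)
        ws <- as.integer(names(which.max(table(sub$start))))
        we <- as.integer(names(which.max(table(sub$end))))
        if (we <= ws) next
        sel_aln <- rna_alignment(spp, vapply(spp, function(sp) {
          subseq_rna(clusters[[sp]]$segment, ws, we)
        }, "", USE.NAMES = FALSE))
        ref <- duplex_fold(dcons, consensus_rna(sel_aln), params)
        if (nrow(ref$pairs) == 0L) next
        pa <- paired_alignment(dock_aln, sel_aln, ref$pairs)
        core <- if (!is.null(ref$core)) c(ref$core$a_start, ref$core$a_end)
        covar[[sprintf("%s_exon%d_%s", key, ex, d)]] <- covariation_summary(pa, core)
      }
    }
  }
  agg <- NULL
  if (length(covar) > 0L) {
    counts <- Reduce(function(a, b) Map(`+`, a, b), lapply(covar, `[[`, "counts"))
    n_inf <- sum(unlist(counts)) - counts$gapped
    agg <- list(counts = counts,
                maintained_fraction = if (n_inf > 0) {
                  (counts$conserved_pair + counts$compensatory +
                     counts$intermediate_wobble) / n_inf
                } else NA_real_)
  }

  # stage 4: location and intron-length statistics (coordinates are shared
  # across species for simulated data; the first cluster is the reference)
  ref_cluster <- clusters[[1L]]
  location <- location_report(hits, ref_cluster)

  # stage 5: isoform combinatorics
  sizes <- cluster_sizes %||% nrow(ref_cluster$variable_exons)
  isoforms <- list(cluster_sizes = sizes, isoform_count = isoform_count(sizes))

  bundle <- list(
    sites = sites, unresolved = unresolved,
    hits = hits, covariation = list(per_pairing = covar, aggregate = agg),
    location = location, isoforms = isoforms,
    geometry = unclass(geometry),
    parameters = list(pair_params = unclass(params), discovery = disc,
                      min_score_per_nt = min_score_per_nt),
    species = names(clusters)
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

strip_covar <- function(cv) {
  lapply(cv, function(x) x[setdiff(names(x), "verdicts")])
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(docking_sites_table(bundle$sites), "docking_sites.tsv")
  tsv(selector_hits_table(bundle$hits), "selector_hits.tsv")
  verd_list <- lapply(names(bundle$covariation$per_pairing), function(nm) {
    v <- bundle$covariation$per_pairing[[nm]]$verdicts
    if (is.null(v)) return(NULL)
    cbind(pairing = nm, v)
  })
  verd_list <- Filter(Negate(is.null), verd_list)
  # per-species pair-type columns differ between site groups: fill with NA
  all_cols <- unique(unlist(lapply(verd_list, names)))
  verd <- do.call(rbind, lapply(verd_list, function(v) {
    for (m in setdiff(all_cols, names(v))) v[[m]] <- NA_character_
    v[, all_cols]
  }))
  if (!is.null(verd)) tsv(verd, "covariation.tsv")
  il <- bundle$location$intron_lengths
  if (length(il) > 0L) tsv(data.frame(intron = seq_along(il), length = il),
                           "intron_lengths.tsv")
  js <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows",
                         null = "null")
  }
  js(lapply(bundle$sites, function(s) {
    list(coordinate_system = "0-based half-open",
         side = s$side, scope = s$scope, species = s$species_set,
         consensus = s$consensus, mean_bits = s$mean_bits,
         aln_start = s$aln_start - 1L, aln_end = s$aln_end,
         per_species = s$per_species)
  }), "docking_sites.json")
  js(list(coordinate_system = "0-based half-open",
          per_pairing = strip_covar(bundle$covariation$per_pairing),
          aggregate = bundle$covariation$aggregate),
     "covariation_summary.json")
  js(bundle$location, "location.json")
  js(list(geometry = bundle$geometry, parameters = bundle$parameters,
          species = bundle$species, unresolved = bundle$unresolved,
          isoforms = bundle$isoforms,
          n_hits = sum(bundle$hits$found),
          n_scans = nrow(bundle$hits)), "summary.json")
  writeLines(render_report(bundle), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a human-readable report from an analysis bundle
#'
#' Deterministic markdown: docking sites with their scope and species,
#' a per-species overview of docking scope and per-direction selector
#' recovery (a dual-pairing overview in bidirectional mode), location and
#' intron statistics, and the isoform product.
#'
#' @param bundle Result of [run_cluster_analysis()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  lines <- c("# Docking-site / selector analysis", "",
             sprintf("Geometry: %s; species: %s", bundle$geometry$mode,
                     paste(bundle$species, collapse = ", ")), "",
             "## Docking sites", "")
  for (s in bundle$sites) {
    lines <- c(lines, sprintf("- %s (%s, %.2f bits): `%s` [%s]",
                              s$side, s$scope, s$mean_bits, s$consensus,
                              paste(s$species_set, collapse = ", ")))
  }
  for (sp in bundle$unresolved) {
    lines <- c(lines, sprintf("- %s: unresolved (no docking site at any threshold)", sp))
  }
  lines <- c(lines, "", "## Per-species pairing overview", "",
             "| species | upstream docking | downstream docking | upstream selectors | downstream selectors |",
             "|---|---|---|---|---|")
  h <- bundle$hits
  for (sp in bundle$species) {
    scope_of <- function(key) {
      for (s in bundle$sites) {
        if (side_key(s$side) == key && sp %in% s$species_set) return(s$scope)
      }
      if (sp %in% bundle$unresolved) "unresolved" else "-"
    }
    frac <- function(d) {
      sub <- h[h$species == sp & h$direction == d, ]
      if (nrow(sub) == 0L) return("-")
      sprintf("%d/%d", sum(sub$found), nrow(sub))
    }
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", sp,
                              scope_of("upstream"), scope_of("downstream"),
                              frac("upstream"), frac("downstream")))
  }
  if (sum(h$found) == 0L) {
    lines <- c(lines, "", "No selector sequences were found in any species.")
  }
  lf <- bundle$location$intron_fraction_below
  lines <- c(lines, "", "## Location and intron statistics", "",
             sprintf("Classified selectors: %d (exonic %s, boundary %s, intronic %s)",
                     bundle$location$n_classified,
                     bundle$location$class_counts$exonic,
                     bundle$location$class_counts$boundary,
                     bundle$location$class_counts$intronic))
  if (!is.null(lf)) {
    lines <- c(lines, sprintf("Intron fraction below %s nt: %.3f",
                              names(lf), unlist(lf)))
  }
  agg <- bundle$covariation$aggregate
  if (!is.null(agg)) {
    lines <- c(lines, "", "## Covariation", "",
               sprintf("Columns: %d conserved, %d compensatory, %d wobble intermediates, %d broken, %d gapped; pairing maintained fraction %.3f",
                       agg$counts$conserved_pair, agg$counts$compensatory,
                       agg$counts$intermediate_wobble, agg$counts$broken,
                       agg$counts$gapped, agg$maintained_fraction))
  }
  lines <- c(lines, "", sprintf("Isoform product over cluster sizes (%s): %s",
                                paste(bundle$isoforms$cluster_sizes, collapse = " x "),
                                format(bundle$isoforms$isoform_count, scientific = FALSE)))
  lines
}
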