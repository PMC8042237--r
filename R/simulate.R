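BASES <- c("A", "C", "G", "U")
WC <- c(A = "U", U = "A", G = "C", C = "G")

#' Configuration for the synthetic exon-cluster simulator
#'
#' Defines the generative conditions under which the pipeline is exercised:
#' a tandem array of variable exons with short, right-skewed internal
#' introns; one or two planted 24-nt docking sites in the flanking introns;
#' one planted selector per variable exon (the reverse complement of its
#' partner docking site) placed intronically, across the exon boundary, or
#' inside the exon; and a star phylogeny of species evolved by per-site
#' substitution — deep divergence in neutral intron background, weak
#' purifying-selection divergence in exons, and an explicit
#' compensatory / wobble-intermediate / pairing-break event mix at paired
#' columns.
#'
#' Intron lengths are a two-component lognormal mixture (short component
#' around 47 nt, long around 300 nt, 0.8 short weight), tuned so about
#' 80 percent of internal introns fall below 150 nt and about 45 percent
#' below 50 nt, as observed in Coleoptera exon 6 clusters;
#' [intron_below_target()] gives the analytic target for any threshold. The default mixed location weights
#' (0.56/0.32/0.12 intronic/boundary/exonic) emulate the published
#' D. ponderosae exon-6 selector distribution.
#'
#' @param n_exons Number of variable exons (>= 1).
#' @param n_species Number of species (>= 2).
#' @param exon_len_range Uniform range of variable-exon lengths (nt).
#' @param const_exon_len Constitutive flank exon length (nt).
#' @param intron_short_meanlog,intron_short_sdlog,intron_long_meanlog,intron_long_sdlog,intron_short_weight
#'   Lognormal mixture for internal intron lengths.
#' @param flank_intron_len Length of the two cluster-flanking introns that
#'   house the docking sites (background plus element).
#' @param docking_len Planted docking-site length (nt).
#' @param geometry Pairing geometry mode (see [scan_geometry()]).
#' @param selector_offset_policy \code{"intronic"}, \code{"boundary"},
#'   \code{"exonic"} or \code{"mixed"} (draw per selector from
#'   \code{mixed_weights}).
#' @param mixed_weights Named weights for the mixed policy.
#' @param sub_rate_background Per-site substitution probability in neutral
#'   intron background (per species from the ancestor). The default 0.5
#'   emulates deep, effectively unalignable intronic divergence across a
#'   clade; conserved elements must stand out against it.
#' @param sub_rate_exon Per-site substitution probability inside exons
#'   (purifying selection).
#' @param p_compensatory,p_wobble Per-column per-species probabilities of a
#'   Watson-Crick-preserving double substitution and of a single
#'   substitution to a G-U/U-G intermediate, drawn at the docking-site
#'   column level (a docking base change propagates to every selector's
#'   partner base — a compensatory change is necessarily shared).
#' @param p_break Per-column per-species per-exon probability of a
#'   pairing-breaking substitution on the selector side.
#' @param force_break_exons Exon indices whose selectors break at every
#'   paired column (p_break = 1 for them).
#' @param docking_scope_plan NULL (all species share each docking site) or
#'   a list of integer vectors partitioning \code{1:n_species}; the first
#'   group keeps the ancestral site, later groups get independent variants
#'   (applied to the upstream site in bidirectional mode, else to the
#'   single site).
#' @param species_names Optional labels (default sp1..spN).
#' @param seed Integer RNG seed; identical seed and config give
#'   byte-identical output.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_exons = 10L, n_species = 6L,
                       exon_len_range = c(120L, 180L),
                       const_exon_len = 150L,
                       intron_short_meanlog = log(47), intron_short_sdlog = 0.45,
                       intron_long_meanlog = log(300), intron_long_sdlog = 0.35,
                       intron_short_weight = 0.8,
                       flank_intron_len = 348L,
                       docking_len = 24L,
                       geometry = c("downstream_selector", "upstream_selector",
                                    "bidirectional"),
                       selector_offset_policy = c("intronic", "boundary",
                                                  "exonic", "mixed"),
                       mixed_weights = c(intronic = 0.56, boundary = 0.32,
                                         exonic = 0.12),
                       sub_rate_background = 0.5,
                       sub_rate_exon = 0.02,
                       p_compensatory = 0.01, p_wobble = 0.005, p_break = 0.005,
                       force_break_exons = integer(0),
                       docking_scope_plan = NULL,
                       species_names = NULL,
                       seed = 1L) {
  geometry <- match.arg(geometry)
  selector_offset_policy <- match.arg(selector_offset_policy)
  stopifnot(n_exons >= 1L, n_species >= 2L, docking_len >= 10L,
            p_compensatory >= 0, p_wobble >= 0, p_break >= 0,
            p_compensatory + p_wobble + p_break <= 1,
            sub_rate_background >= 0, sub_rate_background <= 1,
            sub_rate_exon >= 0, sub_rate_exon <= 1,
            intron_short_weight >= 0, intron_short_weight <= 1)
  if (is.null(species_names)) species_names <- sprintf("sp%d", seq_len(n_species))
  stopifnot(length(species_names) == n_species)
  if (!is.null(docking_scope_plan)) {
    flat <- sort(unlist(docking_scope_plan))
    if (!identical(as.integer(flat), seq_len(n_species))) {
      stop("docking_scope_plan must partition 1:n_species")
    }
  }
  structure(mget(names(formals(sim_config))), class = "sim_config")
}

#' Analytic fraction of internal introns below a length threshold
#'
#' The generative target implied by the intron-length mixture (ignoring
#' rounding and the rare widening applied when a selector cannot fit).
#'
#' @param cfg A [sim_config()].
#' @param t Threshold (nt).
#' @return Probability that a sampled intron length is below \code{t}.
#' @export
intron_below_target <- function(cfg, t = 150) {
  cfg$intron_short_weight *
    stats::plnorm(t, cfg$intron_short_meanlog, cfg$intron_short_sdlog) +
    (1 - cfg$intron_short_weight) *
    stats::plnorm(t, cfg$intron_long_meanlog, cfg$intron_long_sdlog)
}

rand_rna <- function(n) sample(BASES, n, replace = TRUE)

planted_sides <- function(geometry) {
  switch(geometry,
         downstream_selector = "downstream",
         upstream_selector = "upstream",
         bidirectional = c("upstream", "downstream"))
}

# docking side paired by selectors on `direction` side of exons
sim_partner_side <- function(geometry, direction) {
  if (geometry == "bidirectional") {
    if (direction == "downstream") "upstream" else "downstream"
  } else direction
}

sim_location_class <- function(ws, we, exons) {
  if (any(exons$start <= ws & we <= exons$end)) return("exonic")
  if (any(pmax(ws, exons$start) < pmin(we, exons$end))) return("boundary")
  "intronic"
}

#' Simulate an exon cluster with planted docking/selector architecture
#'
#' Builds an ancestral cluster, plants docking site(s) and per-exon
#' selectors according to the geometry, evolves each species independently
#' from the ancestor (star phylogeny, no indels — the true cross-species
#' alignment is therefore the identity and is emitted directly), and
#' returns per-species clusters, ready-made alignments of the flanking
#' introns and planted elements, and a complete truth record (planted
#' windows, per-column evolutionary events and verdicts, per-selector
#' location classes, species-to-docking-variant assignment, any intron
#' widened to fit its selector).
#'
#' @param cfg A [sim_config()].
#' @return List of class \code{cluster_sim} with elements \code{config},
#'   \code{species} (list of [exon_cluster()]), \code{alignments} and
#'   \code{truth}.
#' @export
simulate_cluster <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_exons
  L <- cfg$docking_len
  sides <- planted_sides(cfg$geometry)
  sel_dirs <- selector_directions(scan_geometry(mode = cfg$geometry))

  exon_lens <- sample(seq(cfg$exon_len_range[1L], cfg$exon_len_range[2L]),
                      n, replace = TRUE)

  # per-selector placement policy and offsets (drawn before intron sizing)
  draw_policy <- function() {
    if (cfg$selector_offset_policy != "mixed") return(cfg$selector_offset_policy)
    sample(names(cfg$mixed_weights), 1L, prob = cfg$mixed_weights)
  }
  placements <- list()
  for (direction in sel_dirs) {
    for (x in seq_len(n)) {
      pol <- draw_policy()
      off <- switch(pol,
                    intronic = sample(3:12, 1L),
                    boundary = sample(5:(L - 5L), 1L),
                    exonic = sample(0:5, 1L))
      placements[[paste(x, direction)]] <- list(exon = x, direction = direction,
                                                policy = pol, off = off)
    }
  }
  intron_need <- function(pl) {
    # nt of intron consumed on the exon-adjacent end
    switch(pl$policy, intronic = pl$off + L, boundary = L - pl$off, exonic = 0L)
  }

  # internal intron lengths from the mixture, widened to fit selectors
  raw_intron <- function(k) {
    comp <- stats::runif(k) < cfg$intron_short_weight
    len <- ifelse(comp,
                  stats::rlnorm(k, cfg$intron_short_meanlog, cfg$intron_short_sdlog),
                  stats::rlnorm(k, cfg$intron_long_meanlog, cfg$intron_long_sdlog))
    pmax(10L, as.integer(round(len)))
  }
  intron_lens <- if (n > 1L) raw_intron(n - 1L) else integer(0)
  adjustments <- NULL
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      need <- 0L
      pd <- placements[[paste(i, "downstream")]]
      pu <- placements[[paste(i + 1L, "upstream")]]
      nd <- if (!is.null(pd)) intron_need(pd) else 0L
      nu <- if (!is.null(pu)) intron_need(pu) else 0L
      need <- nd + nu + if (nd > 0L && nu > 0L) 4L else 0L
      if (intron_lens[i] < need) {
        adjustments <- rbind(adjustments,
                             data.frame(after_index = i,
                                        requested = intron_lens[i],
                                        final = need))
        intron_lens[i] <- need
      }
    }
  }

  # assemble ancestral coordinates (0-based half-open)
  pos <- 0L
  flank5 <- exon_interval(pos, pos + cfg$const_exon_len, 0L, "constitutive")
  pos <- pos + cfg$const_exon_len + cfg$flank_intron_len
  ve <- NULL
  for (x in seq_len(n)) {
    ve <- rbind(ve, exon_interval(pos, pos + exon_lens[x], x, "variable"))
    pos <- pos + exon_lens[x]
    if (x < n) pos <- pos + intron_lens[x]
  }
  pos <- pos + cfg$flank_intron_len
  flank3 <- exon_interval(pos, pos + cfg$const_exon_len, n + 1L, "constitutive")
  total_len <- pos + cfg$const_exon_len

  # docking windows inside the flanking introns
  docking <- list()
  if ("upstream" %in% sides) {
    off <- sample(20:60, 1L)
    s <- flank5$end + off
    docking$upstream <- c(start = s, end = s + L)
  }
  if ("downstream" %in% sides) {
    off <- sample(20:60, 1L)
    e <- flank3$start - off
    docking$downstream <- c(start = e - L, end = e)
  }

  # selector windows
  selectors <- NULL
  for (pl in placements) {
    ex <- ve[pl$exon, ]
    if (pl$direction == "downstream") {
      ws <- switch(pl$policy,
                   intronic = ex$end + pl$off,
                   boundary = ex$end - pl$off,
                   exonic = ex$end - pl$off - L)
    } else {
      ws <- switch(pl$policy,
                   intronic = ex$start - pl$off - L,
                   boundary = ex$start + pl$off - L,
                   exonic = ex$start + pl$off)
    }
    we <- ws + L
    all_ex <- rbind(ve[, c("start", "end")], flank5[, c("start", "end")],
                    flank3[, c("start", "end")])
    selectors <- rbind(selectors, data.frame(
      exon_index = pl$exon, direction = pl$direction,
      partner_side = sim_partner_side(cfg$geometry, pl$direction),
      start = ws, end = we, policy = pl$policy,
      location_class = sim_location_class(ws, we, all_ex),
      stringsAsFactors = FALSE))
  }

  # ancestral sequence with planted elements
  anc <- rand_rna(total_len)
  site_seq <- list()
  for (side in sides) {
    w <- docking[[side]]
    site_seq[[side]] <- anc[(w[["start"]] + 1L):w[["end"]]]
  }
  write_selector <- function(chars, sel_row, dock_chars) {
    rc <- rev(unname(WC[dock_chars]))
    chars[(sel_row$start + 1L):sel_row$end] <- rc
    chars
  }
  for (r in seq_len(nrow(selectors))) {
    anc <- write_selector(anc, selectors[r, ], site_seq[[selectors$partner_side[r]]])
  }

  # docking-variant groups (scope plan)
  plan <- cfg$docking_scope_plan
  if (is.null(plan)) plan <- list(seq_len(cfg$n_species))
  scope_side <- if (cfg$geometry == "bidirectional") "upstream" else sides[1L]
  group_variants <- lapply(seq_along(plan), function(g) {
    if (g == 1L) site_seq[[scope_side]] else rand_rna(L)
  })
  species_group <- integer(cfg$n_species)
  for (g in seq_along(plan)) species_group[plan[[g]]] <- g

  # position-role masks
  role <- rep("background", total_len)
  for (ex in list(flank5, flank3)) role[(ex$start + 1L):ex$end] <- "exon"
  for (x in seq_len(nrow(ve))) role[(ve$start[x] + 1L):ve$end[x]] <- "exon"
  for (side in sides) {
    w <- docking[[side]]
    role[(w[["start"]] + 1L):w[["end"]]] <- "paired"
  }
  for (r in seq_len(nrow(selectors))) {
    role[(selectors$start[r] + 1L):selectors$end[r]] <- "paired"
  }

  # selector partner position for docking offset dc (0-based): antiparallel
  partner_pos <- function(sel_row, dc) sel_row$start + (L - 1L - dc)

  events <- list(); clusters <- list()
  species_chars <- list()
  for (s in seq_len(cfg$n_species)) {
    sp <- cfg$species_names[s]
    chars <- anc
    g <- species_group[s]
    if (g > 1L) {
      w <- docking[[scope_side]]
      chars[(w[["start"]] + 1L):w[["end"]]] <- group_variants[[g]]
      for (r in which(selectors$partner_side == scope_side)) {
        chars <- write_selector(chars, selectors[r, ], group_variants[[g]])
      }
    }
    # site-level events (compensatory / wobble), shared across exons
    for (side in sides) {
      w <- docking[[side]]
      sel_rows <- which(selectors$partner_side == side)
      for (dc in 0:(L - 1L)) {
        dpos <- w[["start"]] + dc + 1L
        D <- chars[dpos]
        u <- stats::runif(1L)
        ev <- if (u < cfg$p_compensatory) "compensatory"
              else if (u < cfg$p_compensatory + cfg$p_wobble) "wobble" else "none"
        if (ev == "compensatory") {
          D2 <- sample(setdiff(BASES, D), 1L)
          chars[dpos] <- D2
          for (r in sel_rows) chars[partner_pos(selectors[r, ], dc) + 1L] <- WC[[D2]]
        } else if (ev == "wobble") {
          if (D == "A") chars[dpos] <- "G"
          else if (D == "C") chars[dpos] <- "U"
          else if (D == "G") for (r in sel_rows) chars[partner_pos(selectors[r, ], dc) + 1L] <- "U"
          else for (r in sel_rows) chars[partner_pos(selectors[r, ], dc) + 1L] <- "G"
        }
        Dcur <- chars[dpos]
        # per-exon pairing breaks on the selector side
        for (r in sel_rows) {
          pb <- if (selectors$exon_index[r] %in% cfg$force_break_exons) 1 else cfg$p_break
          broke <- pb > 0 && stats::runif(1L) < pb
          spos <- partner_pos(selectors[r, ], dc) + 1L
          if (broke) {
            illegal <- BASES[pair_type(Dcur, BASES) == "none"]
            chars[spos] <- if (length(illegal) == 1L) illegal else sample(illegal, 1L)
          }
          events[[length(events) + 1L]] <- data.frame(
            species = sp, side = side, exon_index = selectors$exon_index[r],
            column = dc + 1L,
            event = if (broke) "break" else ev,
            pair_type = pair_type(Dcur, chars[spos]),
            stringsAsFactors = FALSE)
        }
      }
    }
    # background and exon substitutions
    for (rl in c("background", "exon")) {
      rate <- if (rl == "background") cfg$sub_rate_background else cfg$sub_rate_exon
      idx <- which(role == rl)
      if (rate > 0 && length(idx) > 0L) {
        hit <- idx[stats::runif(length(idx)) < rate]
        if (length(hit) > 0L) {
          shift <- sample(1:3, length(hit), replace = TRUE)
          chars[hit] <- BASES[(match(chars[hit], BASES) - 1L + shift) %% 4L + 1L]
        }
      }
    }
    species_chars[[sp]] <- chars
    seg <- genomic_segment(sprintf("%s_cluster", sp), paste(chars, collapse = ""),
                           species = sp)
    clusters[[sp]] <- exon_cluster(seg, "other", ve, flank5, flank3)
  }
  events <- do.call(rbind, events)

  # truth verdicts per (group, side, exon, column), simulator's own tally
  verdicts <- NULL
  for (g in seq_along(plan)) {
    spp <- cfg$species_names[plan[[g]]]
    if (length(spp) < 2L) next
    for (side in sides) {
      w <- docking[[side]]
      for (r in which(selectors$partner_side == side)) {
        for (dc in 0:(L - 1L)) {
          dposs <- w[["start"]] + dc + 1L
          sposs <- partner_pos(selectors[r, ], dc) + 1L
          tps <- vapply(spp, function(sp) {
            pair_type(species_chars[[sp]][dposs], species_chars[[sp]][sposs])
          }, "")
          wc <- tps[tps %in% c("GC", "CG", "AU", "UA")]
          verdict <- if (any(tps == "none")) "broken"
          else if (length(unique(wc)) >= 2L) "compensatory"
          else if (any(tps %in% c("GU", "UG"))) "intermediate_wobble"
          else "conserved_pair"
          verdicts <- rbind(verdicts, data.frame(
            group = g, side = side, exon_index = selectors$exon_index[r],
            column = dc + 1L, verdict = verdict, stringsAsFactors = FALSE))
        }
      }
    }
  }

  window_aln <- function(ws, we, spp = cfg$species_names) {
    rna_alignment(spp, vapply(spp, function(sp) {
      paste(species_chars[[sp]][(ws + 1L):we], collapse = "")
    }, "", USE.NAMES = FALSE))
  }
  alignments <- list(docking = list(), selectors = list())
  if ("upstream" %in% sides) {
    alignments$intron_upstream <- window_aln(flank5$end, ve$start[1L])
    w <- docking$upstream
    alignments$docking$upstream <- window_aln(w[["start"]], w[["end"]])
  }
  if ("downstream" %in% sides) {
    alignments$intron_downstream <- window_aln(ve$end[n], flank3$start)
    w <- docking$downstream
    alignments$docking$downstream <- window_aln(w[["start"]], w[["end"]])
  }
  for (r in seq_len(nrow(selectors))) {
    key <- sprintf("exon%d_%s", selectors$exon_index[r], selectors$direction[r])
    alignments$selectors[[key]] <- window_aln(selectors$start[r], selectors$end[r])
  }

  truth <- list(
    docking = docking,
    docking_groups = do.call(rbind, lapply(seq_along(plan), function(g) {
      data.frame(group = g, species = cfg$species_names[plan[[g]]],
                 side = scope_side,
                 sequence = paste(group_variants[[g]], collapse = ""),
                 stringsAsFactors = FALSE)
    })),
    selectors = selectors,
    events = events,
    verdicts = verdicts,
    intron_adjustments = adjustments
  )

  structure(list(config = cfg, species = clusters, alignments = alignments,
                 truth = truth),
            class = "cluster_sim")
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat(sprintf("<cluster_sim> %d exons x %d species, %s geometry, seed %d\n",
              x$config$n_exons, x$config$n_species, x$config$geometry,
              x$config$seed))
  invisible(x)
}

#' Write simulator output to disk
#'
#' Emits one FASTA and one GFF3 per species, aligned FASTA for the flanking
#' introns and planted elements, and the truth record as JSON.
#'
#' @param sim A [simulate_cluster()] result.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$species)) {
    cl <- sim$species[[sp]]
    write_segment_fasta(cl$segment, file.path(dir, sprintf("%s.fasta", sp)))
    write_cluster_gff3(cl, file.path(dir, sprintf("%s.gff3", sp)))
  }
  for (nm in c("intron_upstream", "intron_downstream")) {
    if (!is.null(sim$alignments[[nm]])) {
      write_alignment_fasta(sim$alignments[[nm]], file.path(dir, sprintf("%s.aln.fasta", nm)))
    }
  }
  truth <- sim$truth
  truth$docking <- lapply(truth$docking, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
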