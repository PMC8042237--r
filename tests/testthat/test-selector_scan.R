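# docking_site stub for scan tests (only consensus/side/scope are used)
make_site <- function(consensus, side = "downstream_of_cluster",
                      scope = "clade_specific", species = "sp1") {
  structure(list(side = side, aln_start = 1L, aln_end = nchar(consensus),
                 per_species = data.frame(species = species, start = 0L,
                                          end = nchar(consensus)),
                 consensus = consensus, mean_bits = 2, scope = scope,
                 species_set = species),
            class = "docking_site")
}

zero_cfg <- function(...) {
  sim_config(sub_rate_background = 0, sub_rate_exon = 0, p_compensatory = 0,
             p_wobble = 0, p_break = 0, ...)
}

truth_site_consensus <- function(sim, side) {
  w <- sim$truth$docking[[side]]
  subseq_rna(sim$species[[1L]]$segment, w[["start"]], w[["end"]])
}

test_that("a planted perfect-complement selector is returned exactly", {
  sim <- simulate_cluster(zero_cfg(seed = 201))
  site <- make_site(truth_site_consensus(sim, "downstream"))
  cl <- sim$species$sp1
  geom <- scan_geometry("downstream_selector")
  for (k in seq_len(nrow(sim$truth$selectors))) {
    tr <- sim$truth$selectors[k, ]
    hit <- scan_exon(cl, tr$exon_index, site, "downstream", geom)
    expect_false(is.null(hit))
    expect_equal(unname(hit$window), c(tr$start, tr$end))
    expect_equal(hit$n_pairs, 24L)
  }
})

test_that("a selector with two substitutions still localizes (>= 80% overlap)", {
  set.seed(202)
  sim <- simulate_cluster(zero_cfg(seed = 202))
  cl <- sim$species$sp1
  tr <- sim$truth$selectors[3L, ]
  chars <- strsplit(cl$segment$sequence, "")[[1L]]
  for (pos in tr$start + c(5L, 15L)) {
    chars[pos + 1L] <- sample(setdiff(RNA_BASES, chars[pos + 1L]), 1L)
  }
  seg2 <- genomic_segment(cl$segment$id, paste(chars, collapse = ""), "sp1")
  cl2 <- exon_cluster(seg2, "other", cl$variable_exons, cl$flank5, cl$flank3)
  site <- make_site(truth_site_consensus(sim, "downstream"))
  hit <- scan_exon(cl2, tr$exon_index, site, "downstream",
                   scan_geometry("downstream_selector"))
  expect_false(is.null(hit))
  expect_gte(window_overlap(unname(hit$window), c(tr$start, tr$end)), 0.8)
})

test_that("exons with no planted selector come back empty almost always", {
  # scanning against an unrelated site: nothing complementary is planted
  set.seed(299)
  absent <- 0L
  for (seed in 1:20) {
    sim <- simulate_cluster(sim_config(seed = 300 + seed, n_species = 2))
    decoy <- make_site(random_rna(24))
    hit <- scan_exon(sim$species$sp1, 5L, decoy, "downstream",
                     scan_geometry("downstream_selector"))
    if (is.null(hit)) absent <- absent + 1L
  }
  expect_gte(absent, 18L)
})

test_that("bidirectional scans report both pairings, restriction halves them", {
  sim <- simulate_cluster(zero_cfg(seed = 203, geometry = "bidirectional"))
  sites <- list(
    make_site(truth_site_consensus(sim, "upstream"), "upstream_of_cluster"),
    make_site(truth_site_consensus(sim, "downstream"), "downstream_of_cluster")
  )
  geom <- scan_geometry("bidirectional")
  hits <- scan_cluster(sim$species$sp1, sites, geom)
  expect_equal(nrow(hits), 20L)
  expect_equal(sum(hits$direction == "upstream"), 10L)
  expect_equal(sum(hits$direction == "downstream"), 10L)
  expect_true(all(hits$found))
  # windows match planted truth in both directions
  for (i in seq_len(nrow(hits))) {
    tr <- sim$truth$selectors[
      sim$truth$selectors$exon_index == hits$exon_index[i] &
        sim$truth$selectors$direction == hits$direction[i], ]
    expect_equal(c(hits$start[i], hits$end[i]), c(tr$start, tr$end))
  }
  down_only <- scan_cluster(sim$species$sp1, sites, geom,
                            directions = "downstream")
  expect_equal(nrow(down_only), 10L)
  # equivalence: the restricted run reproduces the full run's rows
  full_down <- hits[hits$direction == "downstream",
                    setdiff(names(hits), "hit")]
  rownames(full_down) <- NULL
  restricted <- down_only[, setdiff(names(down_only), "hit")]
  rownames(restricted) <- NULL
  expect_equal(restricted, full_down)
})

test_that("a single-exon cluster yields one row per direction", {
  sim1 <- simulate_cluster(zero_cfg(seed = 204, n_exons = 1))
  site <- make_site(truth_site_consensus(sim1, "downstream"))
  h1 <- scan_cluster(sim1$species$sp1, list(site),
                     scan_geometry("downstream_selector"))
  expect_equal(nrow(h1), 1L)
  sim2 <- simulate_cluster(zero_cfg(seed = 205, n_exons = 1,
                                    geometry = "bidirectional"))
  sites2 <- list(
    make_site(truth_site_consensus(sim2, "upstream"), "upstream_of_cluster"),
    make_site(truth_site_consensus(sim2, "downstream"), "downstream_of_cluster")
  )
  h2 <- scan_cluster(sim2$species$sp1, sites2, scan_geometry("bidirectional"))
  expect_equal(nrow(h2), 2L)
})

test_that("reported hits satisfy the duplex invariants and core threshold", {
  p <- pair_params()
  sim <- simulate_cluster(sim_config(seed = 206))
  site <- make_site(truth_site_consensus(sim, "downstream"))
  for (sp in names(sim$species)) {
    hits <- scan_cluster(sim$species[[sp]], list(site),
                         scan_geometry("downstream_selector"), p)
    for (i in which(hits$found)) {
      d <- hits$hit[[i]]$duplex
      expect_gte(hits$score[i], 30)
      core <- duplex_core(d, p$min_core_len)
      expect_false(is.null(core))
      expect_gte(core$length, p$min_core_len)
      if (nrow(d$pairs) > 1L) {
        expect_true(all(diff(d$pairs[, 1L]) > 0))
        expect_true(all(diff(d$pairs[, 2L]) < 0))
      }
      # window inside the exon's allowed search region
      ve <- sim$species[[sp]]$variable_exons
      k <- match(hits$exon_index[i], ve$index)
      expect_gte(hits$start[i], ve$end[k])
      lim <- if (k < nrow(ve)) ve$start[k + 1L] else sim$species[[sp]]$flank3$start
      expect_lte(hits$end[i], lim)
    }
  }
})

test_that("species-specific sites take precedence over clade sites", {
  s_clade <- make_site(strrep("G", 24), species = c("sp1", "sp2", "sp3"))
  s_spec <- make_site(strrep("A", 24), scope = "species_specific",
                      species = c("sp1"))
  sim <- simulate_cluster(zero_cfg(seed = 207))
  geom <- scan_geometry("downstream_selector")
  # internal helper drives the choice made by scan_cluster
  pick <- mxepair:::site_for_species(list(s_clade, s_spec), "sp1",
                                     "downstream_of_cluster")
  expect_identical(pick$scope, "species_specific")
  pick2 <- mxepair:::site_for_species(list(s_clade, s_spec), "sp2",
                                      "downstream_of_cluster")
  expect_identical(pick2$scope, "clade_specific")
  expect_null(mxepair:::site_for_species(list(s_clade), "spX",
                                         "downstream_of_cluster"))
})
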