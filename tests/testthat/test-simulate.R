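test_that("the structural contract holds: windows, files and truth agree", {
  cfg <- sim_config(n_exons = 10, n_species = 6, geometry = "bidirectional",
                    seed = 7)
  sim <- simulate_cluster(cfg)
  expect_length(sim$species, 6L)
  tr <- sim$truth
  expect_equal(sum(tr$selectors$direction == "upstream"), 10L)
  expect_equal(sum(tr$selectors$direction == "downstream"), 10L)
  expect_false(is.null(tr$docking$upstream))
  expect_false(is.null(tr$docking$downstream))
  # planted selectors really are reverse complements in group-1 species
  g1 <- tr$docking_groups$species[tr$docking_groups$group == 1][1L]
  # use a zero-rate copy so sequences are unevolved
  sim0 <- simulate_cluster(sim_config(n_exons = 10, n_species = 6,
                                      geometry = "bidirectional", seed = 7,
                                      sub_rate_background = 0, sub_rate_exon = 0,
                                      p_compensatory = 0, p_wobble = 0, p_break = 0))
  seg <- sim0$species[[1L]]$segment
  for (k in seq_len(nrow(sim0$truth$selectors))) {
    sel <- sim0$truth$selectors[k, ]
    w <- sim0$truth$docking[[sel$partner_side]]
    dock_seq <- subseq_rna(seg, w[["start"]], w[["end"]])
    expect_identical(subseq_rna(seg, sel$start, sel$end), revcomp_rna(dock_seq))
  }
  # emitted files: one FASTA + GFF3 per species, alignments, truth JSON
  dir <- withr::local_tempdir()
  write_sim_output(sim, dir)
  expect_length(list.files(dir, pattern = "\\.fasta$"), 8L)  # 6 species + 2 intron alignments
  expect_length(list.files(dir, pattern = "\\.gff3$"), 6L)
  expect_true(file.exists(file.path(dir, "truth.json")))
  for (sp in names(sim$species)) {
    expect_true(file.exists(file.path(dir, sprintf("%s.gff3", sp))))
    back <- read_cluster_gff3(file.path(dir, sprintf("%s.gff3", sp)),
                              sim$species[[sp]]$segment)
    expect_equal(back$variable_exons$start, sim$species[[sp]]$variable_exons$start)
  }
})

test_that("zero rates reproduce the ancestor in every species", {
  cfg <- sim_config(seed = 11, sub_rate_background = 0, sub_rate_exon = 0,
                    p_compensatory = 0, p_wobble = 0, p_break = 0)
  sim <- simulate_cluster(cfg)
  seqs <- vapply(sim$species, function(cl) cl$segment$sequence, "")
  expect_length(unique(seqs), 1L)
  expect_true(all(sim$truth$verdicts$verdict == "conserved_pair"))
})

test_that("a designated always-breaking exon is broken at every column", {
  cfg <- sim_config(seed = 12, force_break_exons = 4L)
  sim <- simulate_cluster(cfg)
  v <- sim$truth$verdicts
  expect_true(all(v$verdict[v$exon_index == 4L] == "broken"))
  ev <- sim$truth$events
  expect_true(all(ev$event[ev$exon_index == 4L] == "break"))
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(seed = 13, geometry = "bidirectional", n_species = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_output(simulate_cluster(cfg), d1)
  write_sim_output(simulate_cluster(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted verdict counts survive the classifier end to end", {
  # the simulator's own per-column tally must match covariation_summary run
  # on the true (simulation-emitted) alignments, exactly
  grid <- expand.grid(pc = c(0, 0.1, 0.3), pw = c(0, 0.1, 0.3),
                      pb = c(0, 0.1, 0.3))
  set.seed(777)
  picks <- grid[sample(nrow(grid), 12), ]
  seeds <- 800 + seq_len(nrow(picks))
  for (i in seq_len(nrow(picks))) {
    cfg <- sim_config(seed = seeds[i], n_exons = 4, n_species = 4,
                      p_compensatory = picks$pc[i], p_wobble = picks$pw[i],
                      p_break = picks$pb[i])
    sim <- simulate_cluster(cfg)
    L <- cfg$docking_len
    for (side in names(sim$truth$docking)) {
      dock_aln <- sim$alignments$docking[[side]]
      sels <- sim$truth$selectors[sim$truth$selectors$partner_side == side, ]
      for (k in seq_len(nrow(sels))) {
        key <- sprintf("exon%d_%s", sels$exon_index[k], sels$direction[k])
        pa <- paired_alignment(dock_aln, sim$alignments$selectors[[key]],
                               cbind(1:L, L:1))
        got <- table(factor(covariation_verdicts(pa)$verdict,
                            levels = mxepair:::VERDICT_LEVELS))
        v <- sim$truth$verdicts
        want <- table(factor(
          v$verdict[v$side == side & v$exon_index == sels$exon_index[k]],
          levels = mxepair:::VERDICT_LEVELS))
        expect_equal(as.vector(got), as.vector(want),
                     info = sprintf("seed %d %s", seeds[i], key))
      }
    }
  }
})

test_that("short-intron fraction converges to the analytic target", {
  cfg <- sim_config(seed = 15, n_exons = 500, n_species = 2,
                    sub_rate_background = 0)
  sim <- simulate_cluster(cfg)
  frac <- unname(intron_length_fractions(sim$species[[1L]], 150)[1L])
  expect_lt(abs(frac - intron_below_target(cfg, 150)), 0.05)
})

test_that("introns too small for their selector are widened and recorded", {
  cfg <- sim_config(seed = 16, geometry = "bidirectional",
                    intron_short_meanlog = log(15), intron_short_sdlog = 0.1,
                    intron_short_weight = 1)
  sim <- simulate_cluster(cfg)
  adj <- sim$truth$intron_adjustments
  expect_false(is.null(adj))
  expect_true(all(adj$final > adj$requested))
  intr <- suppressWarnings(introns_of(sim$species[[1L]]))
  expect_equal(intr$length[adj$after_index], adj$final)
})

test_that("the docking scope plan assigns variant sites to species groups", {
  cfg <- sim_config(seed = 17, geometry = "bidirectional",
                    docking_scope_plan = list(1:4, 5:6))
  sim <- simulate_cluster(cfg)
  dg <- sim$truth$docking_groups
  expect_equal(sort(unique(dg$group)), c(1L, 2L))
  expect_setequal(dg$species[dg$group == 2], c("sp5", "sp6"))
  expect_length(unique(dg$sequence), 2L)
  # group-2 species carry the variant at the planned (upstream) window
  w <- sim$truth$docking$upstream
  sim0 <- simulate_cluster(sim_config(seed = 17, geometry = "bidirectional",
                                      docking_scope_plan = list(1:4, 5:6),
                                      sub_rate_background = 0, sub_rate_exon = 0,
                                      p_compensatory = 0, p_wobble = 0,
                                      p_break = 0))
  w0 <- sim0$truth$docking$upstream
  var_seq <- unique(dg$sequence[dg$group == 2])
  expect_identical(
    subseq_rna(sim0$species$sp5$segment, w0[["start"]], w0[["end"]]),
    unique(sim0$truth$docking_groups$sequence[sim0$truth$docking_groups$group == 2]))
})
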