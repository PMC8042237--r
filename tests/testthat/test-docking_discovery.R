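# A planted-block alignment: each species row is independent random
# background except for a shared (lightly diverged) block at a fixed offset.
planted_alignment <- function(n_species = 6L, bg_len = 300L, block_len = 24L,
                              at = 150L, divergence = 0.02, block = NULL) {
  if (is.null(block)) block <- sample(RNA_BASES, block_len, replace = TRUE)
  rows <- vapply(seq_len(n_species), function(s) {
    bg <- sample(RNA_BASES, bg_len, replace = TRUE)
    b <- block
    mut <- which(stats::runif(block_len) < divergence)
    for (i in mut) b[i] <- sample(setdiff(RNA_BASES, b[i]), 1L)
    bg[(at + 1L):(at + block_len)] <- b
    paste(bg, collapse = "")
  }, "")
  list(aln = rna_alignment(sprintf("sp%d", seq_len(n_species)), rows),
       truth = c(at, at + block_len))
}

test_that("a planted conserved block is recovered from randomized background", {
  set.seed(101)
  hits <- 0L
  for (rep in 1:20) {
    pl <- planted_alignment()
    sites <- find_docking_sites(pl$aln, "downstream_of_cluster")
    expect_gt(length(sites), 0L)
    top <- sites[[1L]]
    ov <- window_overlap(c(top$aln_start - 1L, top$aln_end), pl$truth)
    if (ov >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("uniform random alignments rarely yield a site at min_bits 1.5", {
  set.seed(103)
  fp <- 0L
  for (rep in 1:20) {
    rows <- vapply(1:6, function(s) paste(sample(RNA_BASES, 300, TRUE), collapse = ""), "")
    aln <- rna_alignment(sprintf("sp%d", 1:6), rows)
    if (length(find_docking_sites(aln, "downstream_of_cluster", min_bits = 1.5)) > 0L) {
      fp <- fp + 1L
    }
  }
  expect_lte(fp, 1L)
})

test_that("identical rows score 2.0 everywhere and sites are 5'-most non-overlapping", {
  row <- paste(rep(c("A", "C", "G", "U"), 25), collapse = "")
  aln <- rna_alignment(c("a", "b", "c"), rep(row, 3))
  sites <- find_docking_sites(aln, "upstream_of_cluster", win_min = 15,
                              win_max = 40, min_bits = 1.5, max_sites = 2)
  expect_length(sites, 2L)
  expect_equal(sites[[1L]]$mean_bits, 2)
  expect_equal(sites[[2L]]$mean_bits, 2)
  # longest windows first, 5'-most, non-overlapping
  expect_equal(sites[[1L]]$aln_start, 1L)
  expect_equal(sites[[1L]]$aln_end, 40L)
  expect_equal(sites[[2L]]$aln_start, 41L)
  # mutual non-overlap and score order hold in general
  set.seed(104)
  pl <- planted_alignment(divergence = 0)
  many <- find_docking_sites(pl$aln, "downstream_of_cluster", min_bits = 0.2,
                             max_sites = 5)
  if (length(many) > 1L) {
    spans <- t(vapply(many, function(s) c(s$aln_start, s$aln_end), c(1L, 1L)))
    for (i in seq_len(nrow(spans) - 1L)) {
      expect_gte(many[[i]]$mean_bits, many[[i + 1L]]$mean_bits)
      for (j in (i + 1L):nrow(spans)) {
        expect_true(spans[i, 2L] < spans[j, 1L] || spans[j, 2L] < spans[i, 1L])
      }
    }
  }
})

test_that("per-species ungapped coordinates account for gaps", {
  aln <- rna_alignment(c("a", "b"), c("AC--GGGGGGGGGGGGGGGGGG",
                                      "ACGUGGGGGGGGGGGGGGGGGG"))
  co <- ungapped_coords(aln, 5L, 10L)
  expect_equal(co$start, c(2L, 4L))
  expect_equal(co$end, c(8L, 10L))
})

test_that("scope partitioning separates a main clade from a variant pair", {
  set.seed(105)
  ok <- 0L
  for (rep in 1:5) {
    blockX <- sample(RNA_BASES, 24, TRUE)
    blockY <- sample(RNA_BASES, 24, TRUE)
    rows <- vapply(1:6, function(s) {
      bg <- sample(RNA_BASES, 300, TRUE)
      b <- if (s <= 4) blockX else blockY
      bg[151:174] <- b
      paste(bg, collapse = "")
    }, "")
    aln <- rna_alignment(sprintf("sp%d", 1:6), rows)
    part <- partition_by_scope(aln, "upstream_of_cluster")
    scopes <- vapply(part$sites, function(s) s$scope, "")
    sizes <- vapply(part$sites, function(s) length(s$species_set), 0L)
    if (length(part$sites) == 2L &&
        setequal(part$sites[[which(scopes == "clade_specific")]]$species_set,
                 sprintf("sp%d", 1:4)) &&
        setequal(part$sites[[which(scopes == "species_specific")]]$species_set,
                 sprintf("sp%d", 5:6))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 4L)
})

test_that("a single shared motif yields one clade-specific site", {
  set.seed(106)
  pl <- planted_alignment()
  part <- partition_by_scope(pl$aln, "downstream_of_cluster")
  expect_length(part$sites, 1L)
  expect_identical(part$sites[[1L]]$scope, "clade_specific")
  expect_setequal(part$sites[[1L]]$species_set, sprintf("sp%d", 1:6))
  expect_length(part$unresolved, 0L)
})

test_that("single-species input is species-specific by definition", {
  set.seed(107)
  aln <- structure(list(species = "only",
                        mat = matrix(sample(RNA_BASES, 100, TRUE), nrow = 1,
                                     dimnames = list("only", NULL)),
                        length = 100L),
                   class = "rna_alignment")
  part <- partition_by_scope(aln, "downstream_of_cluster")
  expect_length(part$sites, 1L)
  expect_identical(part$sites[[1L]]$scope, "species_specific")
  expect_identical(part$sites[[1L]]$species_set, "only")
})
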