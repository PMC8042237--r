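test_that("column verdict rules match their defining patterns", {
  # all species keep the same Watson-Crick pair
  expect_identical(classify_pair_column(c("A", "A"), c("U", "U"))$verdict,
                   "conserved_pair")
  # AU -> GC: both partners changed, pairing maintained
  expect_identical(classify_pair_column(c("A", "G"), c("U", "C"))$verdict,
                   "compensatory")
  # AU with a GU intermediate
  expect_identical(classify_pair_column(c("A", "G"), c("U", "U"))$verdict,
                   "intermediate_wobble")
  # A-G is not a pair: broken, not wobble
  expect_identical(classify_pair_column(c("A", "A"), c("U", "G"))$verdict,
                   "broken")
  # any gap or N silences the column
  expect_identical(classify_pair_column(c("A", "-"), c("U", "U"))$verdict,
                   "gapped")
  expect_identical(classify_pair_column(c("A", "N"), c("U", "U"))$verdict,
                   "gapped")
  # exclusively wobble columns are intermediates too
  expect_identical(classify_pair_column(c("G", "G"), c("U", "U"))$verdict,
                   "intermediate_wobble")
  expect_error(classify_pair_column(c("A", "A"), c("U")), "mismatch")
  expect_error(classify_pair_column("A", "U"), "two species")
})

test_that("verdicts agree with an independent re-implementation, exhaustively", {
  sym <- c("A", "C", "G", "U", "-")
  combos2 <- expand.grid(d1 = sym, d2 = sym, s1 = sym, s2 = sym,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos2))) {
    d <- c(combos2$d1[i], combos2$d2[i])
    s <- c(combos2$s1[i], combos2$s2[i])
    expect_identical(classify_pair_column(d, s)$verdict,
                     naive_column_verdict(d, s),
                     info = paste(c(d, s), collapse = ""))
  }
  # three species, sampled densely rather than fully enumerated
  set.seed(401)
  for (rep in 1:2000) {
    d <- sample(sym, 3, replace = TRUE)
    s <- sample(sym, 3, replace = TRUE)
    expect_identical(classify_pair_column(d, s)$verdict,
                     naive_column_verdict(d, s),
                     info = paste(c(d, s), collapse = ""))
  }
})

test_that("verdicts are invariant to species order and docking/selector swap", {
  set.seed(402)
  sym <- c("A", "C", "G", "U", "-")
  for (rep in 1:500) {
    n <- sample(2:4, 1)
    d <- sample(sym, n, replace = TRUE)
    s <- sample(sym, n, replace = TRUE)
    v <- classify_pair_column(d, s)$verdict
    perm <- sample(n)
    expect_identical(classify_pair_column(d[perm], s[perm])$verdict, v)
    expect_identical(classify_pair_column(s, d)$verdict, v)
  }
})

test_that("the lenient flag tolerates a small breaking minority", {
  d <- c("A", "A", "A", "A", "A", "A")
  s <- c("U", "U", "U", "U", "U", "C")   # one break among six
  expect_identical(classify_pair_column(d, s)$verdict, "broken")
  expect_identical(classify_pair_column(d, s, lenient = TRUE)$verdict,
                   "conserved_pair")
  # breaking fraction at the threshold is still broken
  s2 <- c("U", "U", "U", "U", "C", "C")  # 2/6 > 0.2? no, 1/3 >= 0.2
  expect_identical(classify_pair_column(d, s2, lenient = TRUE)$verdict,
                   "broken")
})

make_pa <- function(dock_rows, sel_rows) {
  nd <- nchar(dock_rows[1L])
  paired_alignment(
    rna_alignment(c("x", "y"), dock_rows),
    rna_alignment(c("x", "y"), sel_rows),
    cbind(seq_len(nd), nd:1)
  )
}

test_that("summaries tally planted column verdicts exactly", {
  # 4 conserved + 1 compensatory + 1 wobble + 1 broken + 1 gapped,
  # constructed column by column (selector read antiparallel)
  dock <- c("AAAAAAAA", "AAAAGGAA")
  sel_pairs <- list(c("U", "U"), c("U", "U"), c("U", "U"), c("U", "U"),
                    c("U", "C"), c("U", "U"), c("U", "G"), c("-", "A"))
  sel <- vapply(1:2, function(r) {
    paste(rev(vapply(sel_pairs, `[[`, "", r)), collapse = "")
  }, "")
  pa <- make_pa(dock, sel)
  s <- covariation_summary(pa)
  expect_equal(s$counts$conserved_pair, 4L)
  expect_equal(s$counts$compensatory, 1L)
  expect_equal(s$counts$intermediate_wobble, 1L)
  expect_equal(s$counts$broken, 1L)
  expect_equal(s$counts$gapped, 1L)
  expect_equal(s$n_informative, 7L)
  expect_equal(s$maintained_fraction, 6 / 7)
  # core restriction re-tallies the subset
  s_core <- covariation_summary(pa, core = c(1L, 4L))
  expect_equal(s_core$core$counts$conserved_pair, 4L)
  expect_equal(s_core$core$maintained_fraction, 1)
})

test_that("fully conserved pairings give maintained fraction 1", {
  pa <- make_pa(c("GGCC", "GGCC"), c("GGCC", "GGCC"))
  expect_equal(covariation_summary(pa)$maintained_fraction, 1)
})

test_that("all-gapped pairings report no informative columns", {
  pa <- make_pa(c("----", "AAAA"), c("UUUU", "UUUU"))
  s <- covariation_summary(pa)
  expect_identical(s$note, "no informative columns")
  expect_true(is.na(s$maintained_fraction))
})

test_that("paired alignments validate their construction", {
  d <- rna_alignment(c("x", "y"), c("AAAA", "AAAA"))
  s <- rna_alignment(c("x", "y"), c("UUUU", "UUUU"))
  s_bad <- rna_alignment(c("x", "z"), c("UUUU", "UUUU"))
  expect_error(paired_alignment(d, s_bad, cbind(1:2, 2:1)), "identical species")
  expect_error(paired_alignment(d, s, cbind(integer(0), integer(0))), "empty")
  expect_error(paired_alignment(d, s, cbind(1:2, 1:2)), "monotone")
  expect_error(paired_alignment(d, s, cbind(c(1, 9), c(2, 1))), "bounds")
  expect_s3_class(paired_alignment(d, s, cbind(1:4, 4:1)), "paired_alignment")
})

test_that("covariation text rendering carries one glyph per paired column", {
  pa <- make_pa(c("AAAAGAGA", "AAAAGGGA"),
                c("UCUCUUUU", "ACCCUUUU"))
  txt <- covariation_text(pa)
  expect_length(txt, 3L)
  glyphs <- sub("^\\s+", "", txt[2L])
  expect_equal(nchar(glyphs), 8L)
})
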