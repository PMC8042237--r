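# Independent oracles and small utilities shared across tests.

RNA_BASES <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")

# Brute-force optimal duplex score: enumerate every antiparallel
# non-crossing pair set (any k-subset of positions of A matched, in order,
# against the reverse of a k-subset of B), score pairs plus independent
# affine gap runs between consecutive pairs, local semantics (flanks free).
# Feasible for |A|,|B| <= 8. Deliberately enumeration-based, sharing no
# logic with the dynamic program it checks.
oracle_duplex_score <- function(a, b, p) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  val <- c(GC = p$score_GC, CG = p$score_GC, AU = p$score_AU,
           UA = p$score_AU, GU = p$score_GU, UG = p$score_GU)
  sc <- matrix(-Inf, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    t <- pair_type(A[i], B[j])
    if (t != "none") sc[i, j] <- val[[t]]
  }
  gap_cost <- function(k) ifelse(k <= 0, 0, p$gap_open + (k - 1) * p$gap_extend)
  best <- 0
  for (k in seq_len(min(n, m))) {
    SA <- utils::combn(n, k, simplify = FALSE)
    SB <- utils::combn(m, k, simplify = FALSE)
    for (sa in SA) for (sb in SB) {
      jb <- rev(sb)  # j strictly decreasing in original B coordinates
      s <- sum(sc[cbind(sa, jb)])
      if (!is.finite(s)) next
      if (k > 1L) {
        s <- s + sum(gap_cost(diff(sa) - 1L)) + sum(gap_cost(diff(sb) - 1L))
      }
      if (s > best) best <- s
    }
  }
  best
}

# Containment-tolerant overlap between two half-open windows: intersection
# over the smaller window, so a fully-conserved sub-window of the planted
# element still counts as localized.
window_overlap <- function(w, truth) {
  inter <- max(0, min(w[2L], truth[2L]) - max(w[1L], truth[1L]))
  inter / min(w[2L] - w[1L], truth[2L] - truth[1L])
}

# Straightforward re-implementation of the column verdict rules, written
# against the rule list rather than the package code path.
naive_column_verdict <- function(dock, sel) {
  wc_of <- c(A = "U", U = "A", G = "C", C = "G")
  n <- length(dock)
  if (any(dock %in% c("-", "N")) || any(sel %in% c("-", "N"))) return("gapped")
  legal <- function(d, s) {
    (wc_of[[d]] == s) || (d == "G" && s == "U") || (d == "U" && s == "G")
  }
  types <- character(n)
  for (i in seq_len(n)) {
    if (!legal(dock[i], sel[i])) return("broken")
    types[i] <- paste0(dock[i], sel[i])
  }
  wc <- types[types %in% c("GC", "CG", "AU", "UA")]
  if (length(unique(wc)) >= 2L) return("compensatory")
  if (any(types %in% c("GU", "UG"))) return("intermediate_wobble")
  "conserved_pair"
}

# Selector recovery rate of a pipeline run against simulator truth.
selector_recovery <- function(bundle, sim, min_overlap = 0.8) {
  h <- bundle$hits
  truth <- sim$truth$selectors
  ok <- vapply(seq_len(nrow(h)), function(i) {
    t <- truth[truth$exon_index == h$exon_index[i] &
                 truth$direction == h$direction[i], ]
    if (!h$found[i]) return(FALSE)
    window_overlap(c(h$start[i], h$end[i]), c(t$start, t$end)) >= min_overlap
  }, TRUE)
  mean(ok)
}

# Docking localization of the supported site against simulator truth.
docking_overlap <- function(bundle, sim, side = "downstream") {
  truth <- sim$truth$docking[[side]]
  site <- Filter(function(s) side_of(s) == side, bundle$sites)[[1L]]
  ps <- site$per_species
  window_overlap(c(ps$gstart[1L], ps$gend[1L]),
                 c(truth[["start"]], truth[["end"]]))
}

side_of <- function(site) sub("_of_cluster", "", site$side)
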