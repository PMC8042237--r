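---
title: "Inferring docking-site/selector RNA pairings in mutually exclusive exon clusters"
author: "mxepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring docking-site/selector RNA pairings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxepair)
```

## The biological model

In tandem arrays of duplicated ("variable") exons such as the insect
*Dscam1* exon 4, 6 and 9 clusters, exactly one exon of the array is spliced
into each mature mRNA. The prevailing mechanistic model is competition for
an RNA-RNA interaction: a single conserved intronic element flanking the
cluster (the *docking site*) can base-pair with one of several *selector*
sequences, one near each variable exon and each complementary to the
docking site. Whichever selector wins the competition designates its exon
for inclusion. Three geometries occur:

* **downstream pairing** (exon-4-like): one docking site downstream of the
  last variable exon, selectors downstream of each exon;
* **upstream pairing** (exon-6-like): one docking site upstream of the
  first variable exon, selectors upstream of each exon — and where the
  intervening introns are very short, selectors intrude into the exon
  boundary or the exon itself;
* **bidirectional (dual) pairing** (exon-9-like): docking sites on both
  flanks, the upstream site pairing with *downstream* selectors and the
  downstream site with *upstream* selectors.

Because selection acts on the *pairing* rather than on the primary
sequence, docking sites may be conserved only within a clade, or replaced
entirely in single lineages (species-specific variants), while the duplex
itself — including compensatory double substitutions and G-U wobble
intermediates at paired positions — is maintained.

`mxepair` implements the full inference chain for annotated clusters:
conservation-based docking-site discovery, complementarity-based selector
scanning under all three geometries, covariation classification across
species, selector location classification, intron-length statistics and
isoform combinatorics, together with a synthetic cluster generator that
plants all of these structures with known truth.

## The duplex model

Candidate selector windows are evaluated with an intermolecular,
antiparallel, non-crossing duplex alignment: a local alignment of the
docking sequence against the reverse of the window in which the only
aligned columns are legal pairs (GC/CG, AU/UA, GU/UG) and everything else
must be bridged by gaps. Illegal juxtapositions are forbidden rather than
penalized, so every alignment is a set of base pairs plus bulges/loops.

The scoring is a deliberately transparent additive scheme rather than a
nearest-neighbor free-energy model: `score_GC = 3`, `score_AU = 2`,
`score_GU = 1` per pair (ordered by pair stability), and affine gap runs
costing `gap_open = -4` for the first gapped base plus `gap_extend = -2`
for each additional base, with runs on the two strands penalized
independently. Selector inference depends on the *ranking* of candidate
windows by complementarity, not on absolute free energies, and an additive
scheme has a decisive advantage for verification: the optimum is exactly
checkable against brute-force enumeration of all antiparallel non-crossing
pairings (the test suite does this for hundreds of random short strand
pairs, plus property tests for symmetry, monotonicity under extension, and
full pairing against exact reverse complements). All values are
configurable through `pair_params()`.

The *core region* of a duplex is its longest run of contiguous pairs (no
bulge on either strand); ties go to the 5'-most run on the docking strand.
A reported selector must have a core of at least `min_core_len = 8`
pairs — shorter stems arise constantly by chance (a run of eight legal
pairs between random 24-nt and 500-nt sequences has expectation above
one) and are not evidence of a maintained interaction.

Positions holding `N` can never pair. The dynamic program is implemented
in C++; a score-only variant evaluates every window of every length in one
pass per window end, which keeps whole-cluster scans fast.

## Acceptance threshold for selectors

The field's literature gives no numeric threshold separating a genuine
selector stem from background complementarity, so the threshold here is an
explicit tunable with a calibrated default. Under the default scoring, the
best local duplex between a random 24-nt site and a random 500-nt search
region scores about 21 on average (99th percentile around 30), while
planted near-complementary selectors score 55-70. The default threshold is
therefore 1.25 per docking-site nucleotide (`min_score_per_nt`), i.e. a
score of 30 for a 24-nt site. Expressing it per nucleotide matters because
discovery may legitimately return a fully conserved *sub-window* of a
docking element; an absolute cutoff calibrated for 24 nt would silently
reject every true partner of a 15-nt consensus.

## Conservation profiling and docking-site discovery

Cross-species alignments are profiled per column: base frequencies among
non-gap rows (N excluded as missing), gap fraction, consensus base (ties
broken by the fixed order A < C < G < U), and information content
$2 - H$ bits with $H$ the Shannon entropy of the gap-excluded base
distribution — the uniform-background convention of standard sequence
logos. Columns that are mostly gaps (fraction > 0.5) are dropped from
consensus sequences and window scores.

Docking-site discovery slides windows of 15-40 nt across the aligned
flanking intron and scores each by mean per-column information content,
returning non-overlapping windows above `min_bits = 1.5` (2.0 is
invariance; 1.5 demands strong but not strict conservation, i.e. a
"relatively conserved" element). Ties prefer longer windows, then the
5'-most. Both bounds and the threshold are configurable; none of them is a
published value.

Conservation alone cannot identify the docking site, for a structural
reason: the flanking intron that carries the docking site also carries the
nearest exon's selector, which is just as conserved (it is the complement
of a docking site). The pipeline therefore validates candidates by
*selector support*: each conserved window is used to scan every variable
exon's search region, and the candidate whose summed duplex scores are
highest wins. A candidate with essentially no selector support is vetoed
outright — a conserved block that is complementary to nothing is not a
docking site. This mirrors how such elements are identified in practice:
the docking site is defined by its complementarity to many selectors.

### Clade- versus species-specific sites

When discovery on the full species set fails, or covers only part of the
species (per-row identity to the window consensus below 0.7), the
partitioning procedure isolates the covered subset and recurses on the
rest. Two search aids are used, both heuristic and documented as such:

* greedy dropping of the species with the worst overall agreement to the
  column consensus, retrying until a site passes or fewer than two species
  remain;
* when every strong window was vetoed for lacking selector support, a
  retry at 0.6 x `min_bits`: a site carried by only part of the species
  scores low on the mixed alignment, so the group-splitting window is
  visible only below the normal threshold. The relaxed window is used only
  to identify the covered subset; the reported site is re-discovered on
  that subset at full stringency.

A site covering at least half of the input species is labelled
`clade_specific`, smaller groups `species_specific`, and a single-species
input is species-specific by definition. Species covered by no site at any
stage are reported as unresolved rather than forced into a group.

## Covariation classification

For each paired column of a docking/selector alignment pair (joined by the
pairing map of a reference duplex), the per-species pair types determine a
verdict, applied in precedence order:

1. any gap or N in either partner: **gapped**;
2. any species whose juxtaposition is not a legal pair: **broken**;
3. all species the same Watson-Crick type: **conserved_pair**;
4. two or more distinct Watson-Crick types (both partners changed between
   some species pair, e.g. A-U in one species and G-C in another):
   **compensatory**;
5. Watson-Crick mixed with G-U/U-G only, or exclusively wobble:
   **intermediate_wobble**.

The precedence order is this package's formalization — published figures
shade such columns by eye without stating one. Two readings of
"evolutionary intermediate" exist (wobble alongside an observed canonical
pair, or wobble alone); rule 5 covers both. By default a single breaking
species condemns the column (strict); `lenient = TRUE` drops breaking
species from the verdict while they are fewer than 20% of rows. The rule
table is verified in the tests against an independent re-implementation,
exhaustively over all two-species base combinations and densely for three
species. The summary statistic "pairing maintained fraction" is
(conserved + compensatory + wobble) / non-gapped columns, reported both
over the whole map and restricted to the duplex core.

## Selector location and intron statistics

A selector window is `exonic` if contained in any annotated exon,
`boundary` if it overlaps exon sequence without being contained, and
`intronic` otherwise — pure set containment on the annotation, with no
distance tolerance, which is the only definition the annotation itself can
support. A window overlapping two exons (possible only with tiny introns)
is boundary, with a warning. Intron-length fractions use strict
less-than comparison ("< 150 nt") and count zero-length introns; only
internal introns between consecutive variable exons are counted, not the
docking-site-bearing flanks.

## The synthetic generator

`simulate_cluster()` emulates the study conditions end to end: an
ancestral cluster of `n_exons` variable exons (120-180 nt) flanked by
constitutive exons, 348-nt flanking introns housing a 24-nt docking site
per geometry side, one selector per exon (the exact reverse complement of
its partner site) placed intronically, across the boundary, or inside the
exon, and `n_species` species evolved independently from the ancestor.

Generator defaults are the package's fixed study conditions:

* **Internal intron lengths**: a lognormal mixture, short component
  median 47 nt (sdlog 0.45, weight 0.8) and long component median 300 nt
  (sdlog 0.35). Analytically this puts 80% of introns below 150 nt and
  44% below 50 nt, emulating the published Coleoptera exon-6 cluster
  statistics (82% and 45%). `intron_below_target()` returns the analytic
  value for any threshold. Introns too short to hold their selector are
  widened to fit and the adjustment recorded in the truth.
* **Background divergence** (`sub_rate_background = 0.5` per site per
  species): neutral intron sequence at cross-clade distances is close to
  alignment saturation, which is precisely why conserved elements stand
  out; a background as conserved as the elements would make
  conservation-based discovery information-free.
* **Exon divergence** (`sub_rate_exon = 0.02`): purifying selection.
* **Paired-column events**: per species and column, a compensatory
  double substitution with probability 0.01 (the docking base changes and
  every selector's partner base follows — a compensatory change is
  necessarily shared across the cluster, since the docking site is one
  sequence), a wobble intermediate with probability 0.005 (the single
  substitution that turns the current Watson-Crick pair into G-U or U-G),
  and per exon a pairing break with probability 0.005 (a selector-side
  substitution to a non-pairing base). The total, about 2% per column per
  species, is the "element divergence" of the default conditions.
* **Docking scope plan**: optionally, a partition of the species into
  groups, each later group carrying an independent random site variant
  (applied to the upstream site in bidirectional mode), with all dependent
  selectors rewritten to match — the generative analogue of
  species-specific docking sites.
* **Mixed location weights** 0.56/0.32/0.12 for intronic/boundary/exonic,
  matching the published *D. ponderosae* exon-6 selector distribution.

Species evolve on a star phylogeny with no indels, so the true
cross-species alignment is the identity and is emitted directly; the
simulator also emits FASTA, GFF3, flanking-intron alignments and a truth
record (planted windows, per-column events and verdicts, location classes,
group assignments). Identical seed and configuration give byte-identical
output, and the planted per-verdict column counts match
`covariation_summary()` on the emitted alignments exactly — an end-to-end
bookkeeping conservation that the tests check across the event-rate grid.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: indel evolution and alignment error (real
orthologous introns must be aligned, and misalignment degrades both
discovery and covariation), phylogenetic correlation between species
(shared branches make apparent covariation non-independent), compositional
bias and repeats, splice-site constraints overlapping selector positions,
and any coupling between pairing strength and actual splicing outcome.
Recovery rates here measure the inference machinery under a model whose
assumptions are exactly the method's own; they are upper bounds, not field
performance estimates.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 and human-readable
  tables are 1-based inclusive; machine JSON carries a
  `coordinate_system` label.
* Minus-strand annotations are reverse-complemented into transcript
  orientation on ingest; all sequences are plus-strand RNA after
  normalization (T to U, case-folded, alphabet enforced with the position
  of the first illegal character reported).
* Duplex tie-breaking is deterministic: maximal score, then maximal pair
  count, then 5'-most start on the docking strand. Window ties in the
  scan prefer the tightest window (a perfect-complement selector is
  returned exactly, without free flanks), then the window nearest the
  exon boundary, then the 5'-most.
* Abutting exons produce zero-length introns, which are retained, flagged
  and counted; empty clusters, empty alignments, all-gap columns and
  all-gapped pairing maps are rejected or reported
  ("no informative columns") rather than silently scored.
* Isoform products are computed exactly; beyond 2^53 they switch to long
  multiplication and return a decimal string.
* Missing orthologs keep their ancestral exon numbering (index gaps, no
  renumbering).

## Problem sizes

The test suite and the acceptance script exercise: duplex optimality on
hundreds of random strand pairs of length up to 8 (where exhaustive
enumeration over all pairings is feasible); planted-structure recovery on
50 simulated clusters at the default conditions (10 exons, 6 species) plus
10 bidirectional clusters; covariation bookkeeping across 20 simulations
spanning event rates in {0, 0.1, 0.3}; exon-6-like statistics pooled over
20 simulations; and byte-level determinism of two identical pipeline runs.
These sizes give stable estimates for every reported rate while keeping a
full run in minutes on one CPU.

## Known limitations

* The duplex model ignores intramolecular structure within either strand
  (pure hybridization) and all thermodynamic context (stacking, loop
  entropies, temperature). Competing hairpins within long introns could
  suppress a pairing this model ranks highly.
* Discovery assumes the docking site lies in the *flanking* introns, as
  in the three published geometries; an internal docking element would
  require scanning every intron.
* Scope partitioning is greedy and heuristic; with many small variant
  groups or low coverage identity it can leave species unresolved that a
  global optimization would group.
* The covariation classifier is phylogeny-free: it treats species as
  independent observations, so shared ancestry inflates apparent
  conservation (tree-aware statistics are out of scope by design).
* Real-genome percentages quoted from the literature (82%/45% intron
  fractions, 85%/56%/7% location splits) depend on genome annotations that
  are not shipped here; the package reproduces them only in the sense
  that its generator is calibrated to them and its statistics recover the
  generator's targets.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 901, geometry = "bidirectional",
                  docking_scope_plan = list(1:4, 5:6))
bundle <- run_cluster_analysis(sim = cfg, out_dir = "exon9_run")
cat(render_report(bundle), sep = "\n")
```

The written bundle contains `docking_sites.tsv`/`.json`,
`selector_hits.tsv`, `covariation.tsv`, `covariation_summary.json`,
`location.json`, `intron_lengths.tsv`, `summary.json` and `report.md`;
re-running with the same configuration reproduces every file byte for
byte.
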