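#!/usr/bin/env Rscript
# Exon-6-like analysis: short internal introns force many selectors out of
# the intron and into the exon boundary or the exon itself. Measures the
# intron-length distribution and the selector location-class split on the
# exon-6-like synthetic cluster, and compares them with the generator's
# analytic targets.

suppressPackageStartupMessages(library(mxepair))

cfg <- sim_config(seed = 601, geometry = "upstream_selector",
                  selector_offset_policy = "mixed", n_exons = 25, n_species = 6)
sim <- simulate_cluster(cfg)
bundle <- run_cluster_analysis(sim = sim, out_dir = "results/exon6_like")

lens <- suppressWarnings(introns_of(sim$species[[1L]])$length)
fr <- intron_length_fractions(lens, c(50, 150))
cat(sprintf("introns: n=%d, median %d nt; %.0f%% < 50 nt (target %.0f%%), %.0f%% < 150 nt (target %.0f%%)\n",
            length(lens), as.integer(stats::median(lens)),
            100 * fr[["50"]], 100 * intron_below_target(cfg, 50),
            100 * fr[["150"]], 100 * intron_below_target(cfg, 150)))

cl <- table(bundle$hits$location_class[bundle$hits$found])
tot <- sum(cl)
cat(sprintf("selector locations (found %d/%d): intronic %.0f%%, boundary %.0f%%, exonic %.0f%%\n",
            sum(bundle$hits$found), nrow(bundle$hits),
            100 * cl[["intronic"]] / tot, 100 * cl[["boundary"]] / tot,
            100 * cl[["exonic"]] / tot))
plc <- table(sim$truth$selectors$location_class)
cat(sprintf("planted locations: intronic %d, boundary %d, exonic %d\n",
            plc[["intronic"]], plc[["boundary"]], plc[["exonic"]]))
cat("bundle written to results/exon6_like\n")
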