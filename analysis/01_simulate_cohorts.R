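#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts used by the downstream analyses:
#   (a) a cross-sectional comparison cohort: 56 case subjects (condition A,
#       emulating insulin resistance) vs 18 controls (condition B), with
#       10 edges carrying a true connectivity deficit of 0.3 z in the cases;
#   (b) a two-arm randomized pre/post cohort (20 subjects per arm) where the
#       treated arm's post-intervention connectivity gains 0.3 z at 8 edges.
# Both use a 32-region parcellation (496 edges), 116 volumes at TR 3 s.
# Everything is derived from one master seed; rerunning reproduces the same
# files byte for byte.

suppressPackageStartupMessages(library(fccontrast))

master_seed <- 20240L
out_root <- "results/cohorts"

meta <- make_parcellation(32L, seed = master_seed)

# Cross-sectional: cases have WEAKER connectivity at the affected edges
# (negative A-minus-B gap), mirroring a deficit phenotype.
cs_inj <- data.frame(edge_i = as.integer(2 * (0:9)),
                     edge_j = as.integer(2 * (0:9) + 1L),
                     delta_z = -0.3)
cs_design <- synthetic_design(
  meta = meta, base_z = 0.15, injections = cs_inj,
  arms = list(kind = "cross_sectional", n_a = 56L, n_b = 18L),
  n_timepoints = 116L, tr_seconds = 3.0, ar_coef = 0.3, seed = master_seed)
message("simulating cross-sectional cohort: 56 cases vs 18 controls ...")
invisible(simulate_cohort(cs_design, out_dir = file.path(out_root, "cross_sectional")))

# RCT: treatment adds 0.3 z at 8 edges in the treated arm's post scans.
rct_inj <- data.frame(edge_i = as.integer(2 * (0:7)),
                      edge_j = as.integer(2 * (0:7) + 1L),
                      delta_z = 0.3)
rct_design <- synthetic_design(
  meta = meta, base_z = 0.15, injections = rct_inj,
  arms = list(kind = "rct", n_per_arm = 20L),
  n_timepoints = 116L, tr_seconds = 3.0, ar_coef = 0.3, seed = master_seed + 1L)
message("simulating RCT cohort: 20 treated vs 20 control, pre/post ...")
invisible(simulate_cohort(rct_design, out_dir = file.path(out_root, "rct")))

message("cohorts written under ", out_root)
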