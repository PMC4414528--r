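#!/usr/bin/env Rscript
# Morphometric analysis of vascular-ring cross-sections: decompose a change
# in vascular-bundle number between two cohorts into its spacing (vascular
# unit size) and total cell-number contributions, and test each variable with
# the exact Wilcoxon rank-sum test.
#
# No measured cohorts ship with the package, so this driver runs the pipeline
# on synthetic cohorts with planted effects (labelled synthetic throughout):
# a reference cohort of 24 plants (V ~ 8, lambda ~ 10) against a mutant-like
# cohort of 18 plants with fewer, wider-spaced bundles (V ~ 6, lambda ~ 12),
# mirroring the cohort sizes of a typical wild-type/quadruple-mutant
# comparison.
#
# Outputs (results/):
#   synthetic_cohort.csv   per-unit tidy table (plant_id, group, unit_size)
#   morphometrics.json     group comparison: medians, deltas, contributions,
#                          Wilcoxon p-values

library(auxinring)
dir.create("results", showWarnings = FALSE)

wt <- make_cohort(24, median_V = 8, median_lambda = 10,
                  dispersion_V = 1, dispersion_lambda = 1.5, seed = 11)
mut <- make_cohort(18, median_V = 6, median_lambda = 12,
                   dispersion_V = 1, dispersion_lambda = 1.5, seed = 12)
write_sections_csv(list(reference = wt, mutant = mut),
                   "results/synthetic_cohort.csv")

groups <- read_sections_csv("results/synthetic_cohort.csv")
gc <- decompose_change(groups$reference, groups$mutant)
print(gc)

cat(sprintf("\nSpacing (unit-size) change explains %.1f%% of the bundle-number
change; the ring cell-number change explains the remaining %.1f%%.\n",
            gc$contribution_spacing_pct, gc$contribution_cellnumber_pct))
cat("The planted noiseless split for these medians is 66.67% / 33.33%.\n")

jsonlite::write_json(
  list(medians = as.data.frame(gc$medians),
       deltas = as.list(gc$deltas),
       fractional = as.list(gc$fractional),
       contribution_spacing_pct = gc$contribution_spacing_pct,
       contribution_cellnumber_pct = gc$contribution_cellnumber_pct,
       wilcoxon_p = as.list(gc$p_values)),
  "results/morphometrics.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/morphometrics.json\n")
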