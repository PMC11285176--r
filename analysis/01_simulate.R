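#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds (a) a digital breast phantom: ellipsoidal lesions with known FROC
# parameters in homogeneous tissue, an air slab for noise measurement, and
# Rician noise at the protocol's averaging schedule; (b) a paired two-group
# lesion cohort (73 benign / 105 malignant, two sequences per lesion) drawn
# from the bundled reference moments. Everything downstream reads these
# files, so this is the only stage that generates data.

suppressPackageStartupMessages(library(frocdwi))
dir.create("results", showWarnings = FALSE)
seed <- 20260922L

protocol <- protocol_14b()
message("Protocol: ", length(protocol$b_values), " b-values, max ",
        max(protocol$b_values), " s/mm2")

phantom <- default_phantom_spec(noise_sigma = 1, seed = seed)  # 1% of S0
sim <- simulate_phantom(phantom)
write_series(sim$series, "results/phantom_series.nii.gz")
write_mask(sim$maps$label, "results/phantom_labels.nii.gz")
message("Phantom: ", paste(phantom$grid_shape, collapse = "x"),
        " grid, ", length(phantom$lesions), " lesions, sigma = ",
        phantom$noise_sigma, " (S0 = 100)")

cohort <- simulate_cohort(cohort_spec(seed = seed))
write_cohort(cohort, "results/cohort.csv")
message("Cohort: ", nrow(cohort) / 2, " lesions x 2 sequences written")
for (s in unique(cohort$sequence)) {
  cs <- cohort[cohort$sequence == s & cohort$group == "malignant", ]
  message(sprintf("  %s malignant D: %.2f +/- %.2f um2/ms",
                  s, mean(cs$D), sd(cs$D)))
}
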