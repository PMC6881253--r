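#!/usr/bin/env Rscript
# Recovery of a prescribed flanking-charge/affinity law from synthetic
# motif sets: every entry shares the p21-like core QTSMTDFY and only the
# flank charge varies, ln(KD) = a + b * NCPR + noise.
#
# Finds: at zero noise the regression returns the generating (a, b)
# exactly with R^2 = 1; at realistic noise the slope is recovered within
# its OLS sampling error.

suppressPackageStartupMessages(library(pipflank))
dir.create("results", showWarnings = FALSE)

set0 <- gen_motif_set(50, a = -13, b = -16, sigma = 0, seed = 1)
fit0 <- feature_affinity_regression(set0$ncpr, set0$kd_molar, "ncpr")
cat(sprintf("zero noise: slope %.3f, intercept %.3f, R^2 %.6f\n",
            fit0$slope, fit0$intercept, fit0$r_squared))

fits <- do.call(rbind, lapply(1:25, function(s) {
  tab <- gen_motif_set(50, a = -13, b = -16, sigma = 0.5, seed = s)
  f <- feature_affinity_regression(tab$ncpr, tab$kd_molar, "ncpr")
  f$seed <- s
  f
}))
write_report(fits, "results/charge_affinity_law_fits.tsv")
cat(sprintf("sigma 0.5, n = 50, 25 seeds: slope %.2f +/- %.2f, R^2 %.2f\n",
            mean(fits$slope), sd(fits$slope), mean(fits$r_squared)))
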