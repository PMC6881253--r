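#!/usr/bin/env Rscript
# Helicity of the free peptides from their mean Calpha secondary chemical
# shifts, and the (absent) correlation between preformed structure and
# binding affinity.
#
# Finds: helicities of 9, 0, 6.3, 1 and 3.8 percent across the panel, and
# R^2 = 0.19 for mean SCS against ln(KD) - preformed helicity does not
# predict PCNA affinity.

suppressPackageStartupMessages(library(pipflank))
dir.create("results", showWarnings = FALSE)

aff <- pcna_affinity_table()
spr <- aff[aff$method %in% c("SPR_steady", "SPR_kinetic"), ]
spr$helicity_percent <- vapply(spr$mean_scs_ppm, helicity_table_value,
                               numeric(1))
write_report(
  spr[, c("ligand", "method", "kd_molar", "mean_scs_ppm",
          "helicity_percent")],
  "results/helicity_table.tsv"
)
print(as.data.frame(spr[, c("ligand", "kd_molar", "mean_scs_ppm",
                            "helicity_percent")]))

fit <- feature_affinity_regression(spr$mean_scs_ppm, spr$kd_molar,
                                   feature_name = "mean_scs_ppm")
write_report(fit, "results/scs_affinity_regression.tsv")
cat(sprintf("mean SCS vs ln(KD): R^2 = %.2f (n = %d, p = %.2f)\n",
            fit$r_squared, fit$n_points, fit$p_value))

# thermodynamic decomposition of the p21 ITC affinity
row <- aff[aff$ligand == "p21_143_157" & aff$method == "ITC", ]
th <- thermodynamics(row$kd_molar, dh = row$dH_kJ * 1000, temp_K = row$temp_K)
cat(sprintf("p21 ITC: KD %.1f nM -> dG %.1f kJ/mol, -TdS %.0f kJ/mol\n",
            row$kd_molar * 1e9, th[["dG"]] / 1000, th[["minus_TdS"]] / 1000))
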