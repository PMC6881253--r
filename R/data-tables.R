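# Published peptide constructs and measured affinities used throughout the
# analyses. Sequences and measured values are transcribed from the printed
# experimental record of the study this pipeline reanalyses: all peptides
# except the UNG2 variant were N-terminally acetylated and C-terminally
# amidated; SPR was run at pH 7.4, NMR at pH 6.3 and ITC at pH 7.4, all at
# 25 C (Spd1 NMR at 4 C).

#' Peptide constructs of the PCNA-ligand panel
#'
#' The measured peptide panel: canonical PIP-boxes (FEN1, MSH6, an UNG2
#' variant), the p21 PIP-degron and its flank-charge variants, the
#' degenerate Spd1 degron and an APIM peptide. `motif_start`/`motif_end`
#' give the 8-residue PIP span (5-residue core for the APIM) within each
#' sequence.
#'
#' @return tibble with `name`, `sequence`, `n_cap`, `c_cap`, `motif_start`,
#'   `motif_end`, `motif_class`.
#' @export
pcna_peptide_panel <- function() {
  tibble::tribble(
    ~name, ~sequence, ~n_cap, ~c_cap, ~motif_start, ~motif_end, ~motif_class,
    "p21_143_157", "RQTSMTDFYHSKRRL", TRUE, TRUE, 2L, 9L, "pip_degron",
    "p21_140_157", "RKRRQTSMTDFYHSKRRL", TRUE, TRUE, 5L, 12L, "pip_degron",
    "p21_140_164", "RKRRQTSMTDFYHSKRRLIFSKRKP", TRUE, TRUE, 5L, 12L, "pip_degron",
    "S1", "SESSQTSMTDFYHSKRRL", TRUE, TRUE, 5L, 12L, "pip_degron",
    "S2", "RKRRQTSMTDFYHSESSL", TRUE, TRUE, 5L, 12L, "pip_degron",
    "D1.2", "SESSQTSMTDFYHSESSL", TRUE, TRUE, 5L, 12L, "pip_degron",
    "p21_Q144A", "RKRRATSMTDFYHSKRRL", TRUE, TRUE, 5L, 12L, "unknown",
    "FEN1", "TQGRLDDFFKVTGSL", TRUE, TRUE, 2L, 9L, "pip_box",
    "MSH6", "RQSTLYSFFPKSPAL", TRUE, TRUE, 2L, 9L, "pip_box",
    "UNG2", "MIGQKTLYSFFTPSP", FALSE, FALSE, 4L, 11L, "pip_box",
    "APIM", "MDRWLVKW", TRUE, TRUE, 3L, 7L, "apim",
    "Spd1", "IQGSLMDVGMRVRKS", FALSE, FALSE, 2L, 9L, "pip_degron"
  )
}

#' Measured affinities and NMR helicity summaries of the ligand panel
#'
#' SPR steady-state/kinetic dissociation constants and mean Calpha
#' secondary chemical shifts for the five NMR-characterized ligands, plus
#' the ITC affinities of the p21 flank-charge series (only the three
#' wild-type-flank variants have printed KDs; the p21 ITC row also carries
#' the full thermodynamic decomposition in kJ/mol).
#'
#' @return tibble with `ligand`, `method`, `kd_molar`, `kd_se_molar`,
#'   `mean_scs_ppm`, `dH_kJ`, `minus_TdS_kJ`, `dG_kJ`, `n`, `temp_K`,
#'   `ph`.
#' @export
pcna_affinity_table <- function() {
  tibble::tribble(
    ~ligand, ~method, ~kd_molar, ~kd_se_molar, ~mean_scs_ppm,
    ~dH_kJ, ~minus_TdS_kJ, ~dG_kJ, ~n, ~temp_K, ~ph,
    "p21_143_157", "SPR_kinetic", 8.0e-8, 3.4e-10, 0.29,
    NA, NA, NA, NA, 298.15, 7.4,
    "p21_143_157", "ITC", 6.7e-8, 9.0e-9, 0.29,
    -230, 190, -40, 3, 298.15, 7.4,
    "MSH6", "SPR_steady", 2.9e-6, 2.0e-7, -0.11,
    NA, NA, NA, NA, 298.15, 7.4,
    "APIM", "SPR_steady", 1.1e-5, 5.2e-7, 0.20,
    NA, NA, NA, NA, 298.15, 7.4,
    "UNG2", "SPR_steady", 3.4e-5, 4.2e-6, 0.03,
    NA, NA, NA, NA, 298.15, 7.4,
    "FEN1", "SPR_steady", 4.5e-5, 7.3e-6, 0.12,
    NA, NA, NA, NA, 298.15, 7.4,
    "p21_140_157", "ITC", 2.7e-8, 1.1e-8, NA,
    NA, NA, NA, 3, 298.15, 7.4,
    "p21_140_164", "ITC", 6.4e-9, 2.8e-9, NA,
    NA, NA, NA, 3, 298.15, 7.4
  )
}

#' Published kinetic constants of the p21/PCNA interaction
#'
#' The one ligand for which individual SPR rate constants could be
#' extracted: kon = 1.7e6 1/(M s), koff = 0.14 1/s, KD = koff/kon = 80 nM.
#'
#' @return named list `kon`, `koff`, `kd`.
#' @export
p21_kinetics <- function() {
  list(kon = 1.7e6, koff = 0.14, kd = 0.14 / 1.7e6)
}
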