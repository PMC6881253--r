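# Seeded generators emulating every instrument input the pipeline
# consumes, with known ground truth so each fit can be tested by parameter
# recovery. Noise is Gaussian with a standard deviation given relative to
# the signal scale (max absolute model value); identical parameters and
# seed give bit-identical output.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Simulate a steady-state SPR concentration series
#'
#' Responses from the steady-state model at a twofold serial dilution
#' around the half-saturation point, plus Gaussian noise.
#'
#' @param kd dissociation constant (M).
#' @param rmax maximum response (RU).
#' @param n stoichiometry.
#' @param conc concentration grid (M); default 8 twofold steps spanning KD.
#' @param sigma_rel noise sd relative to the maximum response.
#' @param seed RNG seed.
#' @return tibble with `conc_M`, `Rss_RU`.
#' @export
gen_steady_state <- function(kd, rmax = 100, n = 1,
                             conc = kd * 2^seq(-3, 4), sigma_rel = 0,
                             seed = NULL) {
  stopifnot(kd > 0, sigma_rel >= 0)
  mu <- spr_steady_state_model(conc, 1 / kd, rmax, n)
  noise <- with_seed(seed, stats::rnorm(length(mu), 0, sigma_rel * max(mu)))
  tibble::tibble(conc_M = conc, Rss_RU = mu + noise)
}

#' Simulate a single-cycle SPR sensorgram
#'
#' Piecewise-analytic 1:1 time course over a sequential-injection schedule
#' (by default five twofold dilutions, 90 s contact, 225 s dissociation)
#' plus Gaussian noise.
#'
#' @param kon,koff,rmax true kinetic parameters.
#' @param conc_final final (highest) injected concentration (M).
#' @param schedule injection schedule; default [spr_schedule()].
#' @param hz sampling rate (1/s).
#' @param sigma_rel noise sd relative to the maximum response.
#' @param seed RNG seed.
#' @return list with `series` (tibble `t_s`, `R_RU`) and `schedule`.
#' @export
gen_sensorgram <- function(kon, koff, rmax = 100, conc_final = NULL,
                           schedule = NULL, hz = 1, sigma_rel = 0,
                           seed = NULL) {
  if (is.null(schedule)) {
    if (is.null(conc_final)) conc_final <- 4 * koff / kon
    schedule <- spr_schedule(conc_final)
  }
  t_s <- seq(0, max(schedule$end_s), by = 1 / hz)
  mu <- spr_kinetic_model(t_s, schedule, kon, koff, rmax)
  noise <- with_seed(seed, stats::rnorm(length(mu), 0, sigma_rel * max(mu)))
  list(series = tibble::tibble(t_s = t_s, R_RU = mu + noise),
       schedule = schedule)
}

#' Simulate a reverse-titration ITC isotherm
#'
#' Heats from the one-set-of-sites model at the stated cell/syringe design
#' plus Gaussian noise and a constant dilution offset.
#'
#' @param n,kd,dh true stoichiometry, dissociation constant (M) and
#'   enthalpy (J/mol).
#' @param v0 cell volume (L).
#' @param cell_M,syringe_M cell (peptide) and syringe (trimer)
#'   concentrations (M).
#' @param inj_vol_L injection volumes (L); default 19 x 2 uL.
#' @param offset_J constant dilution heat per injection (J).
#' @param sigma_rel noise sd relative to the largest heat.
#' @param seed RNG seed.
#' @param temp_K temperature (K).
#' @return an [itc_experiment()] carrying simulated `heats_J`.
#' @export
gen_itc <- function(n = 3, kd = 67e-9, dh = -230e3, v0 = 200e-6,
                    cell_M = 10e-6, syringe_M = 40e-6,
                    inj_vol_L = rep(2e-6, 19), offset_J = 0, sigma_rel = 0,
                    seed = NULL, temp_K = 298.15) {
  exp0 <- itc_experiment(v0, cell_M, syringe_M, inj_vol_L, temp_K = temp_K)
  mu <- itc_one_site_model(exp0, n, 1 / kd, dh, offset_J)
  noise <- with_seed(seed,
                     stats::rnorm(length(mu), 0, sigma_rel * max(abs(mu))))
  exp0$heats_J <- mu + noise
  exp0
}

#' Simulate a chemical-shift table with a prescribed helicity
#'
#' Observed Calpha shifts are the random-coil reference plus
#' `3.2 * helicity_fraction` ppm on the helical span (plus noise) and the
#' coil value elsewhere, inverting the helicity scale.
#'
#' @param seq peptide sequence.
#' @param helicity_fraction fraction in `[0, 1]`.
#' @param span integer indices of the helical span; default all residues.
#' @param noise_sd Gaussian noise sd (ppm).
#' @param seed RNG seed.
#' @param ref coil reference from [coil_reference()].
#' @return tibble shift table (`index`, `aa`, `nucleus`, `ppm`,
#'   `assigned`).
#' @export
gen_shift_profile <- function(seq, helicity_fraction, span = NULL,
                              noise_sd = 0, seed = NULL,
                              ref = coil_reference()) {
  stopifnot(helicity_fraction >= 0, helicity_fraction <= 1)
  res <- assert_aa_string(seq, what = "seq")
  n <- length(res)
  if (is.null(span)) span <- seq_len(n)
  coil <- vapply(seq_len(n), function(i) random_coil_shift(seq, i, "CA", ref),
                 numeric(1))
  mu <- coil + ifelse(seq_len(n) %in% span, 3.2 * helicity_fraction, 0)
  noise <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  tibble::tibble(index = seq_len(n), aa = res, nucleus = "CA",
                 ppm = mu + noise, assigned = TRUE)
}

# deterministically place charged residues in an S/G backbone to hit a
# target integer net charge exactly
random_flank <- function(len, target_charge) {
  if (abs(target_charge) > len) {
    stop("target charge exceeds flank length", call. = FALSE)
  }
  backbone <- sample(c("S", "G"), len, replace = TRUE)
  k <- abs(target_charge)
  if (k > 0) {
    pos <- sample.int(len, k)
    pool <- if (target_charge > 0) c("K", "R") else c("E", "D")
    backbone[pos] <- sample(pool, k, replace = TRUE)
  }
  paste(backbone, collapse = "")
}

#' Simulate a motif set with a prescribed charge-affinity law
#'
#' Every entry carries the same p21-like core motif (QTSMTDFY) with random
#' flanks of prescribed integer net charge, emulating a design in which
#' only the flanking charge varies; affinities follow
#' `ln(KD) = a + b * NCPR + N(0, sigma)` with NCPR computed in integer
#' mode (His neutral) over the motif plus flanks.
#'
#' @param n_entries number of motifs (>= 3).
#' @param a,b,sigma parameters of the affinity law. Defaults emulate a
#'   four-orders-of-magnitude affinity span across flank charges.
#' @param charge_range integer range of total flank net charge to draw
#'   from (uniform).
#' @param flank_len flank length on each side.
#' @param seed RNG seed.
#' @return motif table (tibble) with `context_seq`, spans, `kd_molar` and
#'   a `ncpr` column carrying the generating feature.
#' @export
gen_motif_set <- function(n_entries, a = -13, b = -16, sigma = 0.5,
                          charge_range = c(-4, 6), flank_len = 7,
                          seed = NULL) {
  if (n_entries < 3L) stop("need n_entries >= 3", call. = FALSE)
  stopifnot(sigma >= 0)
  core <- "QTSMTDFY"
  with_seed(seed, {
    charges <- sample(seq(charge_range[1L], charge_range[2L]), n_entries,
                      replace = TRUE)
    pick <- function(v) v[sample.int(length(v), 1L)]
    rows <- lapply(seq_len(n_entries), function(i) {
      # split the target charge between the two flanks
      zl <- if (charges[i] >= 0) pick(0:charges[i]) else -pick(0:(-charges[i]))
      zr <- charges[i] - zl
      left <- random_flank(flank_len, zl)
      right <- random_flank(flank_len, zr)
      seq_full <- paste0(left, core, right)
      cp <- ncpr_window(seq_full, flank_len + 1L, flank_len + nchar(core),
                        flank_len = flank_len, mode = "integer")
      ln_kd <- a + b * cp$ncpr + stats::rnorm(1, 0, sigma)
      tibble::tibble(
        protein_id = sprintf("synthetic_%03d", i), species = "synthetic",
        context_seq = seq_full, motif_start = flank_len + 1L,
        motif_end = flank_len + nchar(core), declared_class = "pip_degron",
        evidence_code = "B", kd_molar = exp(ln_kd), measure_ph = 7.4,
        measure_temp_K = 298.15, disorder_call = "D", disorder_avg = 0.9,
        ncpr = cp$ncpr
      )
    })
    do.call(rbind, rows)
  })
}
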