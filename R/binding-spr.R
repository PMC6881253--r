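# SPR binding models: steady-state response with stoichiometry, and the
# piecewise-analytic 1:1 Langmuir solution for single-cycle kinetics
# (sequential injections without surface regeneration), plus their
# nonlinear least-squares fits.

#' Construct an affinity record
#'
#' One ligand/method pair with its equilibrium and, where available,
#' kinetic and thermodynamic parameters. Energies are in J/mol.
#'
#' @param ligand ligand identifier.
#' @param method one of `"SPR_steady"`, `"SPR_kinetic"`, `"ITC"`.
#' @param kd_molar dissociation constant (M); `kd_se` its standard error.
#' @param kon,koff rate constants (1/(M s), 1/s) for kinetic fits.
#' @param dH enthalpy (J/mol); `n` stoichiometry; `temp_K` temperature;
#'   `ph` pH.
#' @param rmax fitted maximum response (RU) for SPR fits.
#' @param warning_flag optional character tag (e.g. `"unreliable_fit"`).
#' @return one-row tibble with derived `ka`, `dG` and `minus_TdS`.
#' @export
affinity_record <- function(ligand, method, kd_molar, kd_se = NA_real_,
                            kon = NA_real_, koff = NA_real_, dH = NA_real_,
                            n = NA_real_, temp_K = 298.15, ph = NA_real_,
                            rmax = NA_real_, warning_flag = NA_character_) {
  stopifnot(kd_molar > 0)
  if (is.finite(kon) && is.finite(koff)) {
    stopifnot(abs(kd_molar - koff / kon) <= 1e-9 * kd_molar)
  }
  thermo <- thermodynamics(kd_molar, dH, temp_K)
  tibble::tibble(
    ligand = ligand, method = method, kd_molar = kd_molar, kd_se = kd_se,
    ka = 1 / kd_molar, kon = kon, koff = koff, dH = dH,
    dG = thermo[["dG"]], minus_TdS = thermo[["minus_TdS"]],
    n = n, temp_K = temp_K, ph = ph, rmax = rmax,
    warning_flag = warning_flag
  )
}

#' SPR steady-state response
#'
#' `Rss = KA * c * Rmax / (KA * c * n + 1)` where `c` is the analyte
#' concentration, `n` the binding stoichiometry and `Rmax` the predicted
#' maximum response.
#'
#' @param conc analyte concentration (M), vectorized.
#' @param ka association constant (1/M).
#' @param rmax maximum response (RU).
#' @param n stoichiometry.
#' @return steady-state response (RU).
#' @export
spr_steady_state_model <- function(conc, ka, rmax, n = 1) {
  stopifnot(ka > 0, rmax > 0, n > 0)
  ka * conc * rmax / (ka * conc * n + 1)
}

#' Fit a steady-state SPR concentration series
#'
#' Nonlinear least squares of the steady-state model, parameterized in
#' log(KA) for conditioning, with `n` fixed (KA, Rmax and n are not jointly
#' identifiable from the steady-state curve alone). KD = 1/KA is reported
#' with its asymptotic standard error.
#'
#' @param series tibble/data frame with columns `conc_M` and `Rss_RU`.
#' @param n fixed stoichiometry.
#' @param ligand identifier carried into the record.
#' @param ph,temp_K measurement conditions.
#' @return an [affinity_record()]; on non-convergence or a KD far outside
#'   the measured concentration range the record carries
#'   `warning_flag = "unreliable_fit"` and a warning is signalled.
#' @export
spr_steady_state_fit <- function(series, n = 1, ligand = NA_character_,
                                 ph = NA_real_, temp_K = 298.15) {
  conc <- series$conc_M
  rss <- series$Rss_RU
  if (length(conc) < 4L) stop("need >= 4 concentration points", call. = FALSE)
  if (max(conc) / min(conc) < 4) {
    stop("concentration series must span at least 4-fold", call. = FALSE)
  }
  start <- list(log_ka = log(1 / stats::median(conc)),
                rmax = max(rss) * n * 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rss ~ spr_steady_state_model(conc, exp(log_ka), rmax, n),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("unreliable fit: steady-state model did not converge")
    return(affinity_record(ligand, "SPR_steady", kd_molar = stats::median(conc),
                           n = n, temp_K = temp_K, ph = ph,
                           warning_flag = "unreliable_fit"))
  }
  est <- stats::coef(fit)
  kd <- exp(-est[["log_ka"]])
  # delta method: se(KD) = KD * se(log KA)
  se_logka <- tryCatch(summary(fit)$coefficients["log_ka", "Std. Error"],
                       error = function(e) NA_real_)
  flag <- NA_character_
  if (kd < min(conc) / 100 || kd > max(conc) * 100) {
    warning("unreliable fit: KD outside the measured concentration window")
    flag <- "unreliable_fit"
  }
  affinity_record(ligand, "SPR_steady", kd_molar = kd, kd_se = kd * se_logka,
                  n = n, temp_K = temp_K, ph = ph,
                  rmax = est[["rmax"]], warning_flag = flag)
}

#' Single-cycle injection schedule
#'
#' Sequential injections of twofold serial dilutions in order of increasing
#' concentration, each with a fixed contact time followed by a dissociation
#' interval, with no regeneration in between.
#'
#' @param conc_final final (highest) analyte concentration (M).
#' @param n_inj number of injections.
#' @param contact_s contact (association) time per injection, seconds.
#' @param dissociation_s dissociation time after each injection, seconds.
#' @param dilution_factor serial dilution factor between injections.
#' @return tibble with `start_s`, `end_s`, `conc_M` covering the
#'   alternating association/dissociation intervals.
#' @export
spr_schedule <- function(conc_final, n_inj = 5, contact_s = 90,
                         dissociation_s = 225, dilution_factor = 2) {
  conc <- conc_final / dilution_factor^((n_inj - 1):0)
  start <- (seq_len(n_inj) - 1L) * (contact_s + dissociation_s)
  assoc <- tibble::tibble(start_s = start, end_s = start + contact_s,
                          conc_M = conc)
  diss <- tibble::tibble(start_s = start + contact_s,
                         end_s = start + contact_s + dissociation_s,
                         conc_M = 0)
  out <- rbind(assoc, diss)
  out[order(out$start_s), , drop = FALSE]
}

#' Piecewise-analytic 1:1 Langmuir sensorgram
#'
#' Integrates `dR/dt = kon * c * (Rmax - R) - koff * R` across the
#' injection schedule: within each interval the concentration is constant,
#' so `R(t) = Req + (R0 - Req) * exp(-(kon c + koff) (t - t0))` with
#' `Req = kon c Rmax / (kon c + koff)`; the solution is continuous at
#' interval boundaries (no regeneration between injections).
#'
#' @param times sample times (s), increasing.
#' @param schedule tibble from [spr_schedule()].
#' @param kon association rate (1/(M s)).
#' @param koff dissociation rate (1/s).
#' @param rmax maximum response (RU).
#' @param r0 response at the start of the cycle (RU).
#' @return response (RU) at `times`.
#' @export
spr_kinetic_model <- function(times, schedule, kon, koff, rmax, r0 = 0) {
  stopifnot(kon > 0, koff > 0, rmax > 0)
  out <- numeric(length(times))
  r_curr <- r0
  for (k in seq_len(nrow(schedule))) {
    t0 <- schedule$start_s[k]
    t1 <- schedule$end_s[k]
    conc <- schedule$conc_M[k]
    kobs <- kon * conc + koff
    req <- kon * conc * rmax / kobs
    sel <- times >= t0 & (times < t1 | k == nrow(schedule))
    out[sel] <- req + (r_curr - req) * exp(-kobs * (times[sel] - t0))
    r_curr <- req + (r_curr - req) * exp(-kobs * (t1 - t0))
  }
  out
}

#' Global kinetic fit of a single-cycle sensorgram
#'
#' Fits kon, koff and Rmax (log-parameterized) by nonlinear least squares
#' over the full time course; KD = koff/kon.
#'
#' @param series tibble with columns `t_s` and `R_RU`.
#' @param schedule injection schedule from [spr_schedule()].
#' @param ligand,ph,temp_K carried into the record.
#' @param koff_limit koff (1/s) above which rates are flagged as beyond the
#'   instrument's reliable resolution.
#' @return an [affinity_record()] with `kon`, `koff` and `rmax`; signals a
#'   warning and flags the record when rates are too fast or the fit does
#'   not converge.
#' @export
spr_kinetic_fit <- function(series, schedule, ligand = NA_character_,
                            ph = NA_real_, temp_K = 298.15, koff_limit = 1) {
  if (length(unique(schedule$conc_M[schedule$conc_M > 0])) < 2L) {
    stop("need a time course with >= 2 injection cycles", call. = FALSE)
  }
  t_s <- series$t_s
  r <- series$R_RU
  cmax <- max(schedule$conc_M)
  start <- list(log_kon = log(1e5), log_koff = log(0.05),
                log_rmax = log(max(abs(r)) + 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ spr_kinetic_model(t_s, schedule, exp(log_kon), exp(log_koff),
                            exp(log_rmax)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("kinetic fit did not converge (rates may be too fast to quantify)")
    return(affinity_record(ligand, "SPR_kinetic", kd_molar = cmax,
                           temp_K = temp_K, ph = ph,
                           warning_flag = "non_convergence"))
  }
  est <- exp(stats::coef(fit))
  kon <- est[["log_kon"]]
  koff <- est[["log_koff"]]
  flag <- NA_character_
  if (koff > koff_limit) {
    warning("dissociation too fast to be reliably quantified (koff > ",
            koff_limit, " 1/s)")
    flag <- "too_fast"
  }
  affinity_record(ligand, "SPR_kinetic", kd_molar = koff / kon,
                  kon = kon, koff = koff, temp_K = temp_K, ph = ph,
                  rmax = est[["log_rmax"]], warning_flag = flag)
}
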