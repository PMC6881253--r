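# Reverse-titration ITC with a one-set-of-sites (Wiseman) model: the cell
# holds the peptide and the syringe the PCNA trimer, whose three identical
# pockets give a site concentration of n x [trimer]. Cell concentrations
# follow an exact stepwise displaced-volume dilution recursion.

#' Construct an ITC experiment
#'
#' @param v0 cell volume (L).
#' @param cell_M initial cell-species (peptide) concentration (M).
#' @param syringe_M syringe-species (trimer) concentration (M).
#' @param inj_vol_L vector of injection volumes (L).
#' @param heats_J optional vector of integrated heats per injection (J).
#' @param temp_K temperature (K).
#' @return an `itc_experiment` list.
#' @export
itc_experiment <- function(v0 = 200e-6, cell_M, syringe_M, inj_vol_L,
                           heats_J = NULL, temp_K = 298.15) {
  stopifnot(v0 > 0, cell_M > 0, syringe_M > 0, all(inj_vol_L > 0))
  if (!is.null(heats_J)) {
    stopifnot(length(heats_J) == length(inj_vol_L), all(is.finite(heats_J)))
  }
  structure(
    list(v0 = v0, cell_M = cell_M, syringe_M = syringe_M,
         inj_vol_L = inj_vol_L, heats_J = heats_J, temp_K = temp_K),
    class = "itc_experiment"
  )
}

#' Total cell concentrations after each injection (displaced-volume model)
#'
#' Each injection of volume dV displaces an equal volume of the
#' pre-injection cell contents, so after injection i:
#' `[cell species] <- [cell species] * (1 - dV/V0)` and
#' `[titrant] <- [titrant] * (1 - dV/V0) + [syringe] * dV/V0`.
#' This is the exact stepwise recursion, not the exponential approximation.
#'
#' @param exp an [itc_experiment()].
#' @return tibble with `injection`, `cell_total_M` and `titrant_total_M`.
#' @export
itc_cell_totals <- function(exp) {
  n_inj <- length(exp$inj_vol_L)
  cell <- numeric(n_inj)
  titr <- numeric(n_inj)
  c_curr <- exp$cell_M
  t_curr <- 0
  for (i in seq_len(n_inj)) {
    f <- exp$inj_vol_L[i] / exp$v0
    c_curr <- c_curr * (1 - f)
    t_curr <- t_curr * (1 - f) + exp$syringe_M * f
    cell[i] <- c_curr
    titr[i] <- t_curr
  }
  tibble::tibble(injection = seq_len(n_inj), cell_total_M = cell,
                 titrant_total_M = titr)
}

#' Equilibrium bound-complex concentration (one set of sites)
#'
#' Solves the mass-action quadratic for the complex B between total ligand
#' P and total sites S with dissociation constant Kd:
#' `B^2 - B (P + S + Kd) + P S = 0`, taking the root in `[0, min(P, S)]`.
#'
#' @param p_total total ligand (cell species) concentration (M).
#' @param s_total total site concentration (M).
#' @param kd dissociation constant (M).
#' @return bound concentration (M), vectorized.
#' @export
itc_bound <- function(p_total, s_total, kd) {
  b <- p_total + s_total + kd
  disc <- b^2 - 4 * p_total * s_total
  if (any(disc < 0)) stop("numerical guard: negative discriminant",
                          call. = FALSE)
  # subtraction-safe root: the smaller root of the quadratic
  2 * p_total * s_total / (b + sqrt(disc))
}

#' Predicted heats per injection for the one-set-of-sites model
#'
#' After each injection the total cell concentrations are updated by the
#' displaced-volume recursion, the bound complex is solved with site
#' concentration `n x [titrant in cell]`, and the injection heat is
#' `dH * V0 * (B_i - B_{i-1} * (1 - dV_i/V0)) + offset`, the second term
#' accounting for complex expelled with the displaced volume.
#'
#' @param exp an [itc_experiment()].
#' @param n stoichiometry (ligands per titrant molecule).
#' @param ka association constant (1/M).
#' @param dh binding enthalpy (J/mol of ligand bound).
#' @param offset constant per-injection dilution heat (J).
#' @return numeric vector of predicted heats (J).
#' @export
itc_one_site_model <- function(exp, n, ka, dh, offset = 0) {
  stopifnot(n > 0, ka > 0)
  tot <- itc_cell_totals(exp)
  bound <- itc_bound(tot$cell_total_M, n * tot$titrant_total_M, 1 / ka)
  b_prev <- c(0, bound[-length(bound)])
  f <- exp$inj_vol_L / exp$v0
  dh * exp$v0 * (bound - b_prev * (1 - f)) + offset
}

#' Fit an ITC isotherm to the one-set-of-sites model
#'
#' Optionally subtracts a dilution baseline (the mean heat of the last
#' `baseline_k` injections, valid once the complex is saturated), then
#' least-squares fits (n, KA, dH) - or (KA, dH) with `fix_n` - and derives
#' the thermodynamic decomposition.
#'
#' @param exp an [itc_experiment()] carrying observed `heats_J`.
#' @param fix_n optional fixed stoichiometry; when absent and saturation is
#'   not reached the fit aborts with an error recommending `fix_n`.
#' @param baseline `"last_k"` to subtract the mean of the final
#'   `baseline_k` injections, `"none"` to fit a free constant offset.
#' @param baseline_k number of post-saturation injections for the baseline.
#' @param saturation_min minimum fraction of the cell species bound at the
#'   final injection for the fit to be considered saturated.
#' @param ligand,ph carried into the record.
#' @return an [affinity_record()] with `n`, `dH`, `dG` and `minus_TdS`.
#' @export
itc_fit <- function(exp, fix_n = NULL, baseline = c("last_k", "none"),
                    baseline_k = 3, saturation_min = 0.95,
                    ligand = NA_character_, ph = NA_real_) {
  baseline <- match.arg(baseline)
  q <- exp$heats_J
  if (is.null(q)) stop("experiment carries no observed heats", call. = FALSE)
  n_inj <- length(q)
  if (n_inj < 8L) stop("need >= 8 injections", call. = FALSE)

  q_fit <- q
  if (baseline == "last_k") {
    q_fit <- q - mean(q[(n_inj - baseline_k + 1L):n_inj])
  }
  exp_fit <- exp
  exp_fit$heats_J <- NULL

  q_scale <- max(abs(q_fit))
  n_free <- is.null(fix_n)
  model <- function(log_ka, dh, n, off) {
    itc_one_site_model(exp_fit, n, exp(log_ka), dh, off)
  }
  start <- list(log_ka = log(1 / (0.1 * exp$cell_M)),
                dh = sum(q_fit) / (exp$v0 * exp$cell_M))
  fit <- tryCatch({
    if (n_free && baseline == "last_k") {
      minpack.lm::nlsLM(q_fit ~ model(log_ka, dh, n, 0),
                        start = c(start, list(n = 2)),
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else if (n_free) {
      minpack.lm::nlsLM(q_fit ~ model(log_ka, dh, n, off),
                        start = c(start, list(n = 2, off = 0)),
                        lower = c(-Inf, -Inf, 1e-3, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else if (baseline == "last_k") {
      minpack.lm::nlsLM(q_fit ~ model(log_ka, dh, fix_n, 0), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(q_fit ~ model(log_ka, dh, fix_n, off),
                        start = c(start, list(off = 0)),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    stop("ITC fit did not converge", if (n_free) "; consider fixing n (fix_n)",
         call. = FALSE)
  }
  est <- stats::coef(fit)
  ka <- exp(est[["log_ka"]])
  n_hat <- if (n_free) est[["n"]] else fix_n
  # saturation check: fraction of the cell species bound at the last injection
  tot <- itc_cell_totals(exp_fit)
  last <- nrow(tot)
  b_last <- itc_bound(tot$cell_total_M[last],
                      n_hat * tot$titrant_total_M[last], 1 / ka)
  saturated <- b_last / tot$cell_total_M[last] >= saturation_min
  if (!saturated && n_free) {
    stop("saturation not reached; fit of n unreliable - supply fix_n",
         call. = FALSE)
  }
  se_logka <- tryCatch(summary(fit)$coefficients["log_ka", "Std. Error"],
                       error = function(e) NA_real_)
  kd <- 1 / ka
  affinity_record(ligand, "ITC", kd_molar = kd, kd_se = kd * se_logka,
                  dH = est[["dh"]], n = n_hat, temp_K = exp$temp_K, ph = ph)
}

#' Thermodynamic decomposition of a binding constant
#'
#' `dG = R T ln(KD)` (KD in M, R = 8.314 J/(mol K)) and
#' `-T dS = dG - dH`, so `dG = dH + (-T dS)` holds by construction.
#'
#' @param kd dissociation constant (M).
#' @param dh binding enthalpy (J/mol); may be NA.
#' @param temp_K temperature (K).
#' @return named vector `dG`, `minus_TdS` (J/mol).
#' @export
thermodynamics <- function(kd, dh = NA_real_, temp_K = 298.15) {
  stopifnot(kd > 0, temp_K > 0)
  dg <- GAS_CONSTANT_J * temp_K * log(kd)
  c(dG = dg, minus_TdS = dg - dh)
}
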