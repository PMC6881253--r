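test_that("steady-state response follows the closed form", {
  expect_equal(spr_steady_state_model(1e-7, ka = 1e7, rmax = 100, n = 1), 50)
  # c = 1/(KA n): half of the saturating response Rmax/n
  expect_equal(spr_steady_state_model(1 / (2e6 * 2), 2e6, 80, 2), 80 / 2 / 2)
  # large-c limit -> Rmax/n
  expect_equal(spr_steady_state_model(1e3, 1e6, 120, 3), 120 / 3,
               tolerance = 1e-8)
  # strictly increasing and concave in concentration
  conc <- seq(1e-8, 1e-5, length.out = 50)
  r <- spr_steady_state_model(conc, 1e6, 100, 1)
  expect_false(is.unsorted(r, strictly = TRUE))
  expect_true(all(diff(diff(r)) < 0))
})

test_that("steady-state fits recover KD and rescale-invariantly", {
  ss <- gen_steady_state(kd = 3e-6, rmax = 80, sigma_rel = 0)
  fit <- spr_steady_state_fit(ss)
  expect_equal(fit$kd_molar, 3e-6, tolerance = 1e-6)
  expect_equal(fit$rmax, 80, tolerance = 1e-6)

  # KD invariant to uniform response rescaling
  ss_scaled <- ss
  ss_scaled$Rss_RU <- ss$Rss_RU * 7.5
  expect_equal(spr_steady_state_fit(ss_scaled)$kd_molar, fit$kd_molar,
               tolerance = 1e-8)

  # flat responses are unidentifiable
  flat <- tibble::tibble(conc_M = c(1e-7, 1e-6, 1e-5, 1e-4),
                         Rss_RU = rep(50, 4))
  expect_warning(f <- spr_steady_state_fit(flat), "unreliable")
  expect_equal(f$warning_flag, "unreliable_fit")

  expect_error(spr_steady_state_fit(tibble::tibble(conc_M = c(1e-6, 2e-6),
                                                   Rss_RU = c(1, 2))),
               ">= 4")
})

test_that("kinetic sensorgrams are piecewise-exponential and consistent", {
  kin <- p21_kinetics()
  # constant concentration held to equilibrium plateaus at the steady state
  sched <- tibble::tibble(start_s = 0, end_s = 2000, conc_M = 1e-7)
  r_end <- spr_kinetic_model(2000, sched, kin$kon, kin$koff, rmax = 100)
  expect_equal(r_end, spr_steady_state_model(1e-7, kin$kon / kin$koff, 100, 1),
               tolerance = 1e-6)
  # dissociation from R0 decays as R0 exp(-koff t)
  sched2 <- rbind(sched, tibble::tibble(start_s = 2000, end_s = 2300,
                                        conc_M = 0))
  t_d <- seq(2000, 2300, by = 10)
  r_d <- spr_kinetic_model(t_d, sched2, kin$kon, kin$koff, 100)
  expect_equal(r_d, r_end * exp(-kin$koff * (t_d - 2000)), tolerance = 1e-9)
  # plateau concentration dependence is governed by KD = koff/kon
  sched_c <- function(c) tibble::tibble(start_s = 0, end_s = 2000, conc_M = c)
  r_at_kd <- spr_kinetic_model(2000, sched_c(kin$kd), kin$kon, kin$koff, 100)
  expect_equal(r_at_kd, 50, tolerance = 1e-4)
  # continuity across an injection boundary
  sched3 <- spr_schedule(2e-7)
  t_edge <- c(89.999999, 90.000001)
  r_edge <- spr_kinetic_model(t_edge, sched3, kin$kon, kin$koff, 100)
  expect_equal(diff(r_edge), 0, tolerance = 1e-4)
})

test_that("kinetic global fits recover the generating rates", {
  kin <- p21_kinetics()
  g <- gen_sensorgram(kin$kon, kin$koff, rmax = 100, conc_final = 2e-7,
                      sigma_rel = 0)
  fit <- spr_kinetic_fit(g$series, g$schedule)
  expect_equal(fit$kon, kin$kon, tolerance = 1e-4)
  expect_equal(fit$koff, kin$koff, tolerance = 1e-4)
  expect_equal(fit$kd_molar, kin$kd, tolerance = 1e-4)

  g2 <- gen_sensorgram(kin$kon, kin$koff, rmax = 100, conc_final = 2e-7,
                       sigma_rel = 0.02, seed = 101)
  fit2 <- spr_kinetic_fit(g2$series, g2$schedule)
  expect_equal(fit2$kd_molar, kin$kd, tolerance = 0.05)

  # a pure-noise trace cannot support rate constants
  set.seed(1)
  noise <- g$series
  noise$R_RU <- rnorm(nrow(noise))
  res <- tryCatch(
    suppressWarnings(spr_kinetic_fit(noise, g$schedule)),
    error = function(e) "error"
  )
  if (!identical(res, "error")) expect_false(is.na(res$warning_flag))
})

test_that("ITC dilution bookkeeping and quadratic match independent oracles", {
  # quadratic equals bisection on 1000 random parameter draws
  set.seed(7)
  for (i in 1:1000) {
    p <- 10^runif(1, -7, -3)
    s <- 10^runif(1, -7, -3)
    kd <- 10^runif(1, -10, -4)
    b <- itc_bound(p, s, kd)
    expect_lt(abs(b - bisect_bound(p, s, kd)) / max(b, 1e-300), 1e-10)
    expect_true(b >= 0 && b <= min(p, s))
  }
})

test_that("the one-set-of-sites model obeys its limits and conservation", {
  ex <- itc_experiment(v0 = 200e-6, cell_M = 10e-6, syringe_M = 40e-6,
                       inj_vol_L = rep(2e-6, 19))
  # stoichiometric (tight-binding) limit: cumulative heat equals
  # dH V0 min(n [titrant], [cell]) after correcting for expelled complex
  q_tight <- itc_one_site_model(ex, n = 3, ka = 1e15, dh = -230e3)
  tot <- itc_cell_totals(ex)
  b_final <- pmin(tot$cell_total_M, 3 * tot$titrant_total_M)
  f <- ex$inj_vol_L / ex$v0
  b_prev <- c(0, b_final[-length(b_final)])
  q_expect <- -230e3 * ex$v0 * (b_final - b_prev * (1 - f))
  expect_equal(q_tight, q_expect, tolerance = 1e-6)

  # inflection of the sigmoid sits near a trimer:peptide molar ratio of 1:3
  q <- itc_one_site_model(ex, n = 3, ka = 1 / 67e-9, dh = -230e3)
  ratio <- tot$titrant_total_M / tot$cell_total_M
  steepest <- which.min(diff(q) * sign(-230e3)) # largest heat drop-off
  expect_gt(ratio[steepest], 0.2)
  expect_lt(ratio[steepest], 0.55)

  # splitting one injection into two of half volume conserves total heat
  # (small injections, exact displaced-volume recursion)
  ex1 <- itc_experiment(v0 = 200e-6, cell_M = 10e-6, syringe_M = 40e-6,
                        inj_vol_L = rep(0.2e-6, 30))
  ex2 <- itc_experiment(v0 = 200e-6, cell_M = 10e-6, syringe_M = 40e-6,
                        inj_vol_L = c(rep(0.2e-6, 14), 0.1e-6, 0.1e-6,
                                      rep(0.2e-6, 15)))
  q1 <- sum(itc_one_site_model(ex1, 3, 1 / 67e-9, -230e3))
  q2 <- sum(itc_one_site_model(ex2, 3, 1 / 67e-9, -230e3))
  expect_equal(q1, q2, tolerance = 1e-6)
})

test_that("ITC fits recover truth and flag unsaturated titrations", {
  ex <- gen_itc(sigma_rel = 0)
  fit <- itc_fit(ex, baseline = "none")
  expect_equal(fit$kd_molar, 67e-9, tolerance = 1e-6)
  expect_equal(fit$n, 3, tolerance = 1e-6)
  expect_equal(fit$dH, -230e3, tolerance = 1e-6)
  # energy bookkeeping holds by construction
  expect_equal(fit$dG, fit$dH + fit$minus_TdS)

  # truncated pre-saturation isotherm: n cannot be fitted
  ex_trunc <- gen_itc(sigma_rel = 0, inj_vol_L = rep(2e-6, 8),
                      syringe_M = 10e-6)
  expect_error(itc_fit(ex_trunc, baseline = "none"), "fix_n|converge")
  # with n fixed the truncated fit proceeds
  fit_fix <- itc_fit(ex_trunc, fix_n = 3, baseline = "none")
  expect_equal(fit_fix$kd_molar, 67e-9, tolerance = 1e-3)

  expect_error(itc_fit(gen_itc(inj_vol_L = rep(2e-6, 5))), ">= 8")
})

test_that("recovery is accurate across seeded replicates at 1% noise", {
  kd_true <- 67e-9
  err_itc <- vapply(1:100, function(s) {
    e <- gen_itc(sigma_rel = 0.01, seed = s, offset_J = -1e-6)
    f <- itc_fit(e)
    abs(f$kd_molar - kd_true) / kd_true
  }, numeric(1))
  expect_lt(median(err_itc), 0.10)

  err_ss <- vapply(1:100, function(s) {
    ss <- gen_steady_state(kd = 3e-6, rmax = 100, sigma_rel = 0.01, seed = s)
    abs(spr_steady_state_fit(ss)$kd_molar - 3e-6) / 3e-6
  }, numeric(1))
  expect_lt(median(err_ss), 0.10)
})

test_that("thermodynamic decomposition matches the measured energetics", {
  expect_equal(unname(thermodynamics(1, dh = 0)[["dG"]]), 0)
  th <- thermodynamics(6.7e-8, dh = -230e3, temp_K = 298.15)
  expect_equal(th[["dG"]] / 1000, -40.9, tolerance = 0.01)
  expect_equal(th[["minus_TdS"]] / 1000, 189, tolerance = 0.01)
  # dG = dH + (-T dS) identically
  expect_equal(th[["dG"]], -230e3 + th[["minus_TdS"]])
})
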