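# Independent numerical oracles used across tests.

# mass-action root by bisection on (S - B)(P - B) = Kd * B
bisect_bound <- function(p_total, s_total, kd, tol = 1e-16) {
  f <- function(b) (s_total - b) * (p_total - b) - kd * b
  lo <- 0
  hi <- min(p_total, s_total)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# closed-form OLS via the normal equations
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L], r_squared = 1 - ss_res / ss_tot)
}

# a tiny hand-checkable motif table
toy_motif_set <- function() {
  rbind(
    motif_entry("full", context_seq = "AQTSMTDFYHSKRRA", motif_start = 2,
                motif_end = 9, declared_class = "pip_degron"),
    motif_entry("noQ", context_seq = "AETSMTDFYHSKRRA", motif_start = 2,
                motif_end = 9)
  )
}

panel_seq <- function(name) {
  p <- pcna_peptide_panel()
  p$sequence[p$name == name]
}
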