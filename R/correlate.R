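# Regressions between sequence features (mean secondary shift, NCPR) and
# ln(KD), with per-ligand averaging of duplicate affinities.

#' Average duplicate affinities per ligand
#'
#' Where multiple affinities exist for the same ligand, a single KD is
#' produced per ligand: the arithmetic mean on the KD scale by default, or
#' the geometric mean.
#'
#' @param records tibble with columns `ligand` and `kd_molar`.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return tibble with one `kd_molar` per `ligand` (input order of first
#'   appearance preserved).
#' @export
average_affinities <- function(records, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  stopifnot(nrow(records) >= 1L, all(records$kd_molar > 0))
  lig <- unique(records$ligand)
  kd <- vapply(lig, function(l) {
    x <- records$kd_molar[records$ligand == l]
    if (method == "arithmetic") mean(x) else exp(mean(log(x)))
  }, numeric(1))
  tibble::tibble(ligand = lig, kd_molar = unname(kd))
}

#' Ordinary least squares of a sequence feature against ln(KD)
#'
#' Regresses `ln(KD)` (natural log, KD in molar) on the feature value by
#' OLS. R-squared is symmetric under exchanging regressor and response;
#' the p-value is the two-sided F test of the slope.
#'
#' @param feature numeric feature values (e.g. mean Calpha secondary shift,
#'   NCPR).
#' @param kd_molar dissociation constants (M), positive.
#' @param feature_name label carried into the result.
#' @return one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_points`, `feature`, `transform` (`"ln KD, KD in M"`).
#' @export
feature_affinity_regression <- function(feature, kd_molar,
                                        feature_name = "feature") {
  stopifnot(length(feature) == length(kd_molar))
  if (length(feature) < 3L) stop("need >= 3 points", call. = FALSE)
  if (any(kd_molar <= 0)) stop("kd_molar must be positive", call. = FALSE)
  y <- log(kd_molar)
  if (stats::var(feature) == 0 || stats::var(y) == 0) {
    stop("degenerate regression: zero variance in a variable", call. = FALSE)
  }
  fit <- stats::lm(y ~ feature)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # zero-noise synthetic inputs fit perfectly; the summary is still exact
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = unname(p),
    n_points = length(feature),
    feature = feature_name,
    transform = "ln KD, KD in M"
  )
}
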