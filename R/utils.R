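#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet (one-letter); '-' marks an alignment gap in
# curated motif tables.
AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

GAS_CONSTANT_J <- 8.314 # J/(mol K)

#' Round half away from zero
#'
#' Printed tables in the field round 0.5 up, while base R's `round()` rounds
#' to even. This helper reproduces the printed convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

split_residues <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

assert_aa_string <- function(seq, allow_gap = FALSE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  ok <- AA_CANONICAL
  if (allow_gap) ok <- c(ok, "-")
  res <- split_residues(seq)
  bad <- setdiff(unique(res), ok)
  if (length(bad) > 0L) {
    stop(what, " contains non-canonical letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
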