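# Secondary chemical shifts against a random-coil reference and conversion
# of the mean Calpha secondary shift to percent helicity on the 3.2-ppm
# scale (a fully helical residue window corresponds to a mean Calpha
# secondary shift of 3.2 ppm).

#' Random-coil chemical-shift reference shipped with the package
#'
#' Baseline coil shifts per residue type for the Calpha and carbonyl carbon
#' nuclei, plus simplified nearest-neighbour correction terms. The tables
#' are generic coil values for disordered peptides at 25 C, pH 6.3
#' (synthetic/simplified provenance: they are representative textbook-level
#' values, not a transcription of any published coil library), which is
#' sufficient for secondary-shift arithmetic and for the synthetic
#' round-trip tests; measured helicities in this package derive from mean
#' secondary shifts, not from these baselines.
#'
#' @return list with `base` (tibble: residue, nucleus, shift_ppm) and
#'   `neighbors` (tibble: neighbor, side, nucleus, delta_ppm).
#' @export
coil_reference <- function() {
  base <- utils::read.delim(
    system.file("extdata", "random_coil_reference_synthetic.tsv",
                package = "pipflank"),
    stringsAsFactors = FALSE
  )
  nb <- utils::read.delim(
    system.file("extdata", "coil_neighbor_corrections_synthetic.tsv",
                package = "pipflank"),
    stringsAsFactors = FALSE
  )
  list(base = tibble::as_tibble(base), neighbors = tibble::as_tibble(nb))
}

#' Random-coil shift of one residue in sequence context
#'
#' Baseline value for the residue type plus nearest-neighbour corrections
#' from positions i-1 and i+1 where the shipped table provides them;
#' out-of-range neighbours at the chain termini contribute nothing, and a
#' neighbour identical to the central residue contributes nothing either
#' (its effect is folded into the tabulated baseline, so a homopolymer
#' interior position returns the baseline exactly).
#'
#' @param seq amino-acid string.
#' @param i 1-based residue index.
#' @param nucleus nucleus name covered by the reference (e.g. `"CA"`).
#' @param ref reference list from [coil_reference()].
#' @return coil shift in ppm.
#' @export
random_coil_shift <- function(seq, i, nucleus = "CA", ref = coil_reference()) {
  res <- assert_aa_string(seq, what = "seq")
  if (i < 1L || i > length(res)) stop("index out of range", call. = FALSE)
  if (!nucleus %in% unique(ref$base$nucleus)) {
    stop("unsupported nucleus: ", nucleus, call. = FALSE)
  }
  b <- ref$base$shift_ppm[ref$base$residue == res[i] &
                            ref$base$nucleus == nucleus]
  if (length(b) != 1L) {
    stop("reference does not cover residue ", res[i], " for ", nucleus,
         call. = FALSE)
  }
  corr <- 0
  nb <- ref$neighbors[ref$neighbors$nucleus == nucleus, , drop = FALSE]
  if (i > 1L && res[i - 1L] != res[i]) {
    hit <- nb$delta_ppm[nb$neighbor == res[i - 1L] & nb$side == "prev"]
    corr <- corr + sum(hit)
  }
  if (i < length(res) && res[i + 1L] != res[i]) {
    hit <- nb$delta_ppm[nb$neighbor == res[i + 1L] & nb$side == "next"]
    corr <- corr + sum(hit)
  }
  b + corr
}

#' Read a chemical-shift table
#'
#' Tab-separated with header columns `index`, `aa`, `nucleus`, `ppm`,
#' `assigned` (logical).
#'
#' @param path file path.
#' @return tibble shift table.
#' @export
read_shift_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "aa", "nucleus", "ppm", "assigned")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("shift table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$assigned <- as.logical(tab$assigned)
  dup <- duplicated(tab[, c("index", "nucleus")])
  if (any(dup)) stop("duplicate (index, nucleus) rows in shift table",
                     call. = FALSE)
  tibble::as_tibble(tab)
}

#' Secondary chemical shifts and derived helicity
#'
#' Subtracts the random-coil reference from observed shifts:
#' `delta(i) = obs(i) - coil(i)` for assigned residues; unassigned residues
#' carry no secondary shift and are excluded from the mean. The mean
#' Calpha secondary shift over the averaging window is converted to percent
#' helicity with [helicity_percent()].
#'
#' @param obs shift table (see [read_shift_table()]).
#' @param seq the peptide sequence the indices refer to.
#' @param ref coil reference from [coil_reference()].
#' @param window optional integer vector of residue indices to average over
#'   (e.g. the motif span); default all assigned Calpha residues.
#' @return list with `deltas` (tibble: index, aa, nucleus, delta_ppm),
#'   `mean_scs` (ppm, Calpha over the window) and `helicity_percent`.
#' @export
secondary_shifts <- function(obs, seq, ref = coil_reference(), window = NULL) {
  res <- assert_aa_string(seq, what = "seq")
  if (any(obs$index < 1L | obs$index > length(res))) {
    stop("shift table indices outside the sequence", call. = FALSE)
  }
  mism <- obs$aa != res[obs$index]
  if (any(mism)) {
    stop("residue-type mismatch between shift table and sequence at index ",
         paste(obs$index[mism], collapse = ", "), call. = FALSE)
  }
  keep <- obs[obs$assigned & is.finite(obs$ppm), , drop = FALSE]
  delta <- vapply(seq_len(nrow(keep)), function(k) {
    keep$ppm[k] - random_coil_shift(seq, keep$index[k], keep$nucleus[k], ref)
  }, numeric(1))
  deltas <- tibble::tibble(index = keep$index, aa = keep$aa,
                           nucleus = keep$nucleus, delta_ppm = delta)
  ca <- deltas[deltas$nucleus == "CA", , drop = FALSE]
  if (!is.null(window)) ca <- ca[ca$index %in% window, , drop = FALSE]
  mean_scs <- if (nrow(ca) == 0L) NA_real_ else mean(ca$delta_ppm)
  list(
    deltas = deltas,
    mean_scs = mean_scs,
    helicity_percent = if (is.na(mean_scs)) NA_real_
    else helicity_percent(mean_scs)
  )
}

#' Percent helicity from a mean Calpha secondary shift
#'
#' `max(0, mean_scs / 3.2) * 100`, capped at 100: a fully helical window
#' corresponds to a mean Calpha secondary shift of 3.2 ppm, and negative
#' means clamp to zero helicity.
#'
#' @param mean_scs mean Calpha secondary shift (ppm).
#' @return percent helicity in `[0, 100]` (unrounded).
#' @export
helicity_percent <- function(mean_scs) {
  stopifnot(is.finite(mean_scs))
  pmin(100, pmax(0, mean_scs / 3.2) * 100)
}

#' Table-style rounding of percent helicity
#'
#' Reproduces the mixed precision used when tabulating helicities: the raw
#' percentage is reported as an integer when it lies within 0.1 of an
#' integer, and otherwise rounded half-up to one decimal (so 9.0625 prints
#' as 9, 0.9375 as 1, 6.25 as 6.3 and 3.75 as 3.8).
#'
#' @inheritParams helicity_percent
#' @return rounded percent helicity.
#' @export
helicity_table_value <- function(mean_scs) {
  p <- helicity_percent(mean_scs)
  nearest <- round_half_up(p)
  if (abs(p - nearest) <= 0.1) nearest else round_half_up(p, 1)
}
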