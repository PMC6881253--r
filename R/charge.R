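# pH-dependent net charge and net charge per residue (NCPR) of peptides and
# of motif windows with configurable flanking lengths.

#' Default side-chain and terminal pKa values
#'
#' Standard biochemistry values; override any subset by name.
#'
#' @return named numeric vector with entries `D`, `E`, `C`, `Y`, `H`, `K`,
#'   `R`, `Nterm`, `Cterm`.
#' @export
default_pka <- function() {
  c(D = 3.65, E = 4.25, C = 8.3, Y = 10.1, H = 6.0, K = 10.5, R = 12.5,
    Nterm = 8.0, Cterm = 3.55)
}

ACIDIC_AA <- c("D", "E", "C", "Y")
BASIC_AA <- c("H", "K", "R")

#' Fractional or integer charge of a single residue type at a given pH
#'
#' Fractional mode evaluates the Henderson-Hasselbalch titration:
#' acids carry `-1 / (1 + 10^(pKa - pH))`, bases `+1 / (1 + 10^(pH - pKa))`.
#' Integer mode assigns K/R = +1, D/E = -1 and treats His as neutral by
#' default (`his_charge` switches it to +1), matching common NCPR tools.
#'
#' @param aa character vector of one-letter residue codes.
#' @param ph solution pH.
#' @param pka_set named pKa table, see [default_pka()].
#' @param mode `"fractional"` or `"integer"`.
#' @param his_charge integer-mode charge for His (0 or 1).
#' @return numeric vector of charges in `[-1, 1]`.
#' @export
residue_charge <- function(aa, ph, pka_set = default_pka(),
                           mode = c("fractional", "integer"),
                           his_charge = 0) {
  mode <- match.arg(mode)
  bad <- setdiff(unique(aa), AA_CANONICAL)
  if (length(bad) > 0L) {
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "integer") {
    q <- numeric(length(aa))
    q[aa %in% c("K", "R")] <- 1
    q[aa %in% c("D", "E")] <- -1
    q[aa == "H"] <- his_charge
    return(q)
  }
  q <- numeric(length(aa))
  is_acid <- aa %in% ACIDIC_AA
  is_base <- aa %in% BASIC_AA
  q[is_acid] <- -1 / (1 + 10^(pka_set[aa[is_acid]] - ph))
  q[is_base] <- 1 / (1 + 10^(ph - pka_set[aa[is_base]]))
  q
}

#' Construct a peptide with terminal-cap flags at a stated pH
#'
#' @param sequence amino-acid string.
#' @param n_cap TRUE if N-terminally acetylated (no free amino group).
#' @param c_cap TRUE if C-terminally amidated (no free carboxyl group).
#' @param ph solution pH in (0, 14).
#' @return a `peptide_construct` list.
#' @export
peptide_construct <- function(sequence, n_cap = TRUE, c_cap = TRUE, ph = 7.4) {
  assert_aa_string(sequence, what = "sequence")
  if (!(ph > 0 && ph < 14)) stop("ph must be in (0, 14)", call. = FALSE)
  structure(
    list(sequence = sequence, n_cap = isTRUE(n_cap), c_cap = isTRUE(c_cap),
         ph = ph),
    class = "peptide_construct"
  )
}

terminal_charges <- function(n_cap, c_cap, ph, pka_set, mode) {
  qn <- qc <- 0
  if (!n_cap) {
    qn <- if (mode == "integer") 1 else 1 / (1 + 10^(ph - pka_set[["Nterm"]]))
  }
  if (!c_cap) {
    qc <- if (mode == "integer") -1 else -1 / (1 + 10^(pka_set[["Cterm"]] - ph))
  }
  c(nterm = qn, cterm = qc)
}

#' Net charge of a peptide construct
#'
#' Sum of residue charges plus the free terminal-group charges when the
#' corresponding cap flag is FALSE.
#'
#' @inheritParams residue_charge
#' @param p a [peptide_construct()].
#' @return net charge (elementary charges).
#' @export
net_charge <- function(p, mode = c("fractional", "integer"),
                       pka_set = default_pka(), his_charge = 0) {
  mode <- match.arg(mode)
  res <- split_residues(p$sequence)
  q <- residue_charge(res, p$ph, pka_set, mode, his_charge)
  sum(q) + sum(terminal_charges(p$n_cap, p$c_cap, p$ph, pka_set, mode))
}

#' NCPR over a motif window with flanking residues
#'
#' The window is the motif span extended by `flank_len` residues on each
#' side, truncated at the chain ends (truncation flags are reported). NCPR
#' is the window net charge divided by the effective window length. Free
#' terminal-group charges are added only when the window reaches the
#' corresponding chain end and that terminus is uncapped.
#'
#' @param full_seq parent amino-acid sequence.
#' @param motif_start,motif_end 1-based inclusive motif span.
#' @param flank_len number of flanking residues on each side (>= 0).
#' @param ph solution pH.
#' @param n_cap,c_cap terminal cap flags of the parent chain.
#' @inheritParams residue_charge
#' @return a `charge_profile` list: per-residue charges, `net`, `ncpr`,
#'   `window` (start, end, flank_len, left_truncated, right_truncated).
#' @export
ncpr_window <- function(full_seq, motif_start, motif_end, flank_len = 7L,
                        ph = 7.4, n_cap = TRUE, c_cap = TRUE,
                        mode = c("fractional", "integer"),
                        pka_set = default_pka(), his_charge = 0) {
  mode <- match.arg(mode)
  res <- assert_aa_string(full_seq, what = "full_seq")
  n <- length(res)
  if (motif_start < 1L || motif_end > n || motif_start > motif_end) {
    stop("motif span must lie inside full_seq", call. = FALSE)
  }
  if (flank_len < 0L) stop("flank_len must be >= 0", call. = FALSE)
  w_start <- max(1L, motif_start - flank_len)
  w_end <- min(n, motif_end + flank_len)
  window_res <- res[w_start:w_end]
  q <- residue_charge(window_res, ph, pka_set, mode, his_charge)
  term <- terminal_charges(
    n_cap = n_cap || w_start > 1L,   # an interior window has no free terminus
    c_cap = c_cap || w_end < n,
    ph = ph, pka_set = pka_set, mode = mode
  )
  net <- sum(q) + sum(term)
  len <- length(window_res)
  structure(
    list(
      residues = window_res, charges = q, net = net, ncpr = net / len,
      window = list(
        start = w_start, end = w_end, length = len, flank_len = flank_len,
        left_truncated = (motif_start - flank_len) < 1L,
        right_truncated = (motif_end + flank_len) > n
      )
    ),
    class = "charge_profile"
  )
}

#' Mean NCPR as a function of flanking length over a motif set
#'
#' For each flanking length, averages the window NCPR over only those
#' entries whose window is complete (untruncated on both sides); lengths
#' with no complete entry are reported as NA (undefined), not zero.
#'
#' @param entries tibble with columns `full_seq`, `motif_start`,
#'   `motif_end` and optionally `ph` (default 7.4 where absent).
#' @param flank_lens integer vector of flanking lengths.
#' @inheritParams ncpr_window
#' @return tibble with `flank_len`, `mean_ncpr`, `n_complete`.
#' @export
ncpr_flank_profile <- function(entries, flank_lens = 1:9,
                               mode = c("fractional", "integer"),
                               pka_set = default_pka(), his_charge = 0) {
  mode <- match.arg(mode)
  if (is.null(entries) || nrow(entries) == 0L) {
    stop("empty motif set", call. = FALSE)
  }
  ph <- if ("ph" %in% names(entries)) entries$ph else rep(7.4, nrow(entries))
  ph[is.na(ph)] <- 7.4
  rows <- lapply(flank_lens, function(fl) {
    vals <- vapply(seq_len(nrow(entries)), function(i) {
      cp <- ncpr_window(entries$full_seq[i], entries$motif_start[i],
                        entries$motif_end[i], flank_len = fl, ph = ph[i],
                        mode = mode, pka_set = pka_set,
                        his_charge = his_charge)
      if (cp$window$left_truncated || cp$window$right_truncated) NA_real_
      else cp$ncpr
    }, numeric(1))
    tibble::tibble(
      flank_len = fl,
      mean_ncpr = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
      n_complete = sum(!is.na(vals))
    )
  })
  do.call(rbind, rows)
}
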