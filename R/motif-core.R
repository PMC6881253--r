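# Motif coordinate assignment, classification and set-level statistics for
# PCNA-interacting short linear motifs (PIP-box, PIP-degron, APIM).
#
# Coordinate convention: the conserved Gln of the PIP-box is position 1 and
# the two aromatics are positions 7 and 8. Residues N-terminal of position 1
# carry negative coordinates (no position 0); residues C-terminal of
# position 8 are labelled +1, +2, ... The APIM five-residue core
# [K/R][F/Y/W][L/I/V/A][L/I/V/A][K/R] aligns to positions 6, 7, 8, +1, +2.
#
# Internally coordinates are stored on a gap-free integer scale: upstream
# residues are negative, the core window is 1..8, and downstream +k is
# stored as 8 + k. `coord_label()` converts to the display form.

# amino-acid classes used by the motif definitions
AA_ALIPHATIC <- c("L", "M", "I", "V")
AA_AROMATIC78 <- c("Y", "F", "W") # W included so APIM-aligned cores classify
AA_BASIC <- c("K", "R")
APIM_CORE_CLASSES <- list(
  AA_BASIC, c("F", "Y", "W"), c("L", "I", "V", "A"), c("L", "I", "V", "A"),
  AA_BASIC
)

#' Display label for an internal motif coordinate
#'
#' @param coord integer vector on the internal scale (negative upstream,
#'   1..8 core, 9, 10, ... for +1, +2, ...).
#' @return character vector of labels such as `"-2"`, `"1"`, `"+4"`.
#' @export
coord_label <- function(coord) {
  ifelse(coord > 8L, paste0("+", coord - 8L), as.character(coord))
}

#' Parse a motif-coordinate label back to the internal integer scale
#'
#' @param label character vector of labels (`"-1"`, `"3"`, `"+2"`, ...).
#' @return integer vector on the internal scale.
#' @export
coord_parse <- function(label) {
  plus <- startsWith(label, "+")
  out <- as.integer(sub("^\\+", "", label))
  out[plus] <- out[plus] + 8L
  if (any(out == 0L, na.rm = TRUE)) {
    stop("coordinate 0 does not exist in the motif numbering", call. = FALSE)
  }
  out
}

#' Construct a curated motif entry
#'
#' One row of the curated motif table: a short context sequence (at most 50
#' residues by the curation rule), the 1-based inclusive span of the motif
#' within it, and annotations.
#'
#' @param protein_id,species identifiers.
#' @param context_seq amino-acid string; `'-'` marks alignment gaps.
#' @param motif_start,motif_end 1-based inclusive span of the motif core
#'   (8 residues for PIP classes, the 5-residue core for APIM).
#' @param declared_class one of `"pip_box"`, `"pip_degron"`, `"apim"`,
#'   `"unknown"`.
#' @param evidence_code one of `"B"`, `"B*"`, `"C"`, `"CY"`.
#' @param kd_molar optional dissociation constant (M).
#' @param measure_ph,measure_temp_K optional measurement conditions.
#' @param disorder_call optional `"D"` or `"F"`; `disorder_avg` the average
#'   disorder propensity in `[0, 1]`.
#' @return a one-row [tibble::tibble] of class `motif_entry`.
#' @export
motif_entry <- function(protein_id, species = NA_character_, context_seq,
                        motif_start, motif_end,
                        declared_class = "unknown", evidence_code = "B",
                        kd_molar = NA_real_, measure_ph = NA_real_,
                        measure_temp_K = NA_real_,
                        disorder_call = NA_character_,
                        disorder_avg = NA_real_) {
  assert_aa_string(context_seq, allow_gap = TRUE, what = "context_seq")
  n <- nchar(context_seq)
  if (n > 50L) stop("context_seq exceeds the 50-residue curation limit", call. = FALSE)
  motif_start <- as.integer(motif_start)
  motif_end <- as.integer(motif_end)
  if (is.na(motif_start) || is.na(motif_end) ||
      motif_start < 1L || motif_end > n || motif_start > motif_end) {
    stop("motif span must lie inside context_seq", call. = FALSE)
  }
  declared_class <- match.arg(declared_class,
                              c("pip_box", "pip_degron", "apim", "unknown"))
  evidence_code <- match.arg(evidence_code, c("B", "B*", "C", "CY"))
  if (!is.na(kd_molar) && kd_molar <= 0) {
    stop("kd_molar must be positive when present", call. = FALSE)
  }
  out <- tibble::tibble(
    protein_id = protein_id, species = species, context_seq = context_seq,
    motif_start = motif_start, motif_end = motif_end,
    declared_class = declared_class, evidence_code = evidence_code,
    kd_molar = as.numeric(kd_molar), measure_ph = as.numeric(measure_ph),
    measure_temp_K = as.numeric(measure_temp_K),
    disorder_call = disorder_call, disorder_avg = as.numeric(disorder_avg)
  )
  class(out) <- c("motif_entry", class(out))
  out
}

#' Assign motif coordinates to every residue of a context sequence
#'
#' PIP-box and PIP-degron spans (8 residues) map start..end to coordinates
#' 1..8; the APIM 5-residue core maps to 6, 7, 8, +1, +2. All remaining
#' context residues are numbered contiguously outwards, skipping 0.
#'
#' @param entry a [motif_entry()] row (or any list with `context_seq`,
#'   `motif_start`, `motif_end`, `declared_class`).
#' @return a tibble with columns `context_index`, `residue`, `coord`
#'   (internal integer scale) and `label`, one row per context residue,
#'   strictly increasing in both index and coordinate.
#' @export
assign_positions <- function(entry) {
  seq <- entry$context_seq
  res <- split_residues(seq)
  n <- length(res)
  start <- entry$motif_start
  end <- entry$motif_end
  cls <- entry$declared_class %||% "unknown"
  span_len <- end - start + 1L
  if (identical(cls, "apim")) {
    if (span_len != 5L) {
      stop("invalid motif span: APIM core must be exactly 5 residues, got ",
           span_len, call. = FALSE)
    }
    anchor <- 6L # span start sits at coordinate 6
  } else {
    if (span_len != 8L) {
      stop("invalid motif span: PIP motifs must span exactly 8 residues, got ",
           span_len, call. = FALSE)
    }
    anchor <- 1L
  }
  # contiguous coordinates on a 0-free axis: walk outwards from the anchor
  coord_axis <- function(k) ifelse(k >= 1L, k, k - 1L) # insert the 0 gap
  raw <- anchor + (seq_len(n) - start) # would-be coordinates on a 0-full axis
  coord <- coord_axis(raw)
  tibble::tibble(
    context_index = seq_len(n),
    residue = res,
    coord = as.integer(coord),
    label = coord_label(as.integer(coord))
  )
}

residue_at <- function(pmap, coord) {
  hit <- pmap$residue[pmap$coord == coord]
  if (length(hit) == 0L) NA_character_ else hit
}

#' Classify a motif and report its canonicality feature flags
#'
#' Flags follow the canonical definitions: Gln at position 1; an aliphatic
#' (L/M/I/V) at 4; aromatics (Y/F/W) at 7 and 8; the PIP-degron's basic
#' residue at +4 and TD at 5-6; the APIM consensus at 6..+2.
#'
#' @param entry a [motif_entry()] row.
#' @param pmap the position map from [assign_positions()]; computed when
#'   omitted.
#' @return a list with `class` (one of `"pip_box"`, `"pip_degron"`,
#'   `"apim"`, `"unknown"`) and logical `flags`.
#' @export
classify_motif <- function(entry, pmap = assign_positions(entry)) {
  if (!any(pmap$coord %in% 1:8)) {
    stop("incomplete position map: no coordinates in 1..8", call. = FALSE)
  }
  at <- function(k) residue_at(pmap, k)
  flags <- c(
    has_Q1 = isTRUE(at(1L) == "Q"),
    has_hydrophobic4 = isTRUE(at(4L) %in% AA_ALIPHATIC),
    has_aromatic7 = isTRUE(at(7L) %in% AA_AROMATIC78),
    has_aromatic8 = isTRUE(at(8L) %in% AA_AROMATIC78),
    degron_basic_plus4 = isTRUE(at(12L) %in% AA_BASIC), # +4
    degron_TD56 = isTRUE(at(5L) == "T") && isTRUE(at(6L) == "D"),
    apim_consensus = all(vapply(seq_along(APIM_CORE_CLASSES), function(i) {
      isTRUE(at(5L + i) %in% APIM_CORE_CLASSES[[i]])
    }, logical(1)))
  )
  pip_anchors <- flags[["has_Q1"]] && flags[["has_hydrophobic4"]] &&
    flags[["has_aromatic7"]] && flags[["has_aromatic8"]]
  cls <- if (flags[["apim_consensus"]]) {
    "apim"
  } else if (pip_anchors && flags[["degron_basic_plus4"]]) {
    "pip_degron"
  } else if (pip_anchors) {
    "pip_box"
  } else {
    "unknown"
  }
  list(class = cls, flags = flags)
}

#' Degeneracy statistics over a curated motif set
#'
#' Counts, over all entries, how many motifs lack the initial Gln, lack an
#' aliphatic residue at position 4, and lack exactly one or both of the
#' aromatics at positions 7 and 8. Percentages are rounded half-up to
#' integers, the convention of the printed census.
#'
#' @param entries a motif table (tibble with the [motif_entry()] columns).
#' @return a list with `total`, a `counts` vector, a `fractions` vector and
#'   a `percent` vector (integer-rounded), each named
#'   `no_Q1`, `no_hydrophobic4`, `missing_one_aromatic`,
#'   `missing_both_aromatics`.
#' @export
motif_set_statistics <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0L) {
    stop("empty motif set", call. = FALSE)
  }
  flag_mat <- t(vapply(seq_len(nrow(entries)), function(i) {
    cl <- classify_motif(entries[i, ])
    miss_arom <- sum(!cl$flags[c("has_aromatic7", "has_aromatic8")])
    c(
      no_Q1 = !cl$flags[["has_Q1"]],
      no_hydrophobic4 = !cl$flags[["has_hydrophobic4"]],
      missing_one_aromatic = miss_arom == 1L,
      missing_both_aromatics = miss_arom == 2L
    )
  }, logical(4)))
  counts <- colSums(flag_mat)
  total <- nrow(entries)
  fractions <- counts / total
  list(
    total = total,
    counts = counts,
    fractions = fractions,
    percent = round_half_up(100 * fractions)
  )
}

#' Frequency and information-content matrix for a motif set (sequence logo)
#'
#' Residue frequencies at each requested motif coordinate over all entries
#' that cover it (alignment gaps excluded), with column information content
#' `log2(20) - H` in bits, where `H` is the Shannon entropy of the observed
#' frequencies. No small-sample correction is applied.
#'
#' @param entries a motif table.
#' @param coords integer coordinates on the internal scale (see
#'   [coord_parse()]); default the core window 1..8.
#' @return a list with `freq` (20 x length(coords) matrix), `information`
#'   (bits per coordinate) and `n_obs` per coordinate.
#' @export
build_logo <- function(entries, coords = 1:8) {
  counts <- matrix(0, nrow = 20L, ncol = length(coords),
                   dimnames = list(AA_CANONICAL, coord_label(coords)))
  for (i in seq_len(nrow(entries))) {
    pmap <- assign_positions(entries[i, ])
    for (j in seq_along(coords)) {
      aa <- residue_at(pmap, coords[j])
      if (!is.na(aa) && aa != "-") counts[aa, j] <- counts[aa, j] + 1
    }
  }
  n_obs <- colSums(counts)
  if (any(n_obs == 0)) {
    stop("undefined logo column: no observations at coordinate(s) ",
         paste(coord_label(coords[n_obs == 0]), collapse = ", "), call. = FALSE)
  }
  freq <- sweep(counts, 2, n_obs, "/")
  entropy <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(freq = freq, information = log2(20) - entropy, n_obs = n_obs)
}
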