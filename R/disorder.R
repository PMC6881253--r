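# Aggregation of externally produced per-residue disorder scores into a
# consensus call. Predictors are never executed here; score tracks arrive
# as files.

#' Construct a disorder track
#'
#' @param protein_id identifier.
#' @param scores numeric matrix, one column per predictor and one row per
#'   residue, values in `[0, 1]`; column names are predictor names.
#' @return a `disorder_track` list.
#' @export
disorder_track <- function(protein_id, scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("disorder scores must be finite and in [0, 1]; missing residues ",
         "are rejected, not imputed", call. = FALSE)
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("predictor", seq_len(ncol(scores)))
  }
  structure(list(protein_id = protein_id, scores = scores),
            class = "disorder_track")
}

#' Read per-residue disorder score tracks
#'
#' Tab-separated with header `protein_id`, `residue_index`, `predictor`,
#' `score`. Every predictor must cover every residue of a protein
#' (length mismatches are rejected).
#'
#' @param path file path.
#' @return named list of [disorder_track()] objects, one per protein.
#' @export
read_disorder_tracks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_index", "predictor", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("track file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$protein_id), function(d) {
    preds <- unique(d$predictor)
    idx <- sort(unique(d$residue_index))
    if (!identical(idx, seq_along(idx))) {
      stop("track alignment error: residue indices must be 1..n for ",
           d$protein_id[1L], call. = FALSE)
    }
    mat <- sapply(preds, function(p) {
      sub <- d[d$predictor == p, , drop = FALSE]
      if (nrow(sub) != length(idx)) {
        stop("track alignment error: predictor ", p, " covers ", nrow(sub),
             " of ", length(idx), " residues for ", d$protein_id[1L],
             call. = FALSE)
      }
      sub$score[order(sub$residue_index)]
    })
    disorder_track(d$protein_id[1L], mat)
  })
  out
}

#' Per-residue consensus disorder
#'
#' Mean score across predictors per residue; a residue is called
#' disordered when the mean is at or above 0.5 (inclusive threshold).
#'
#' @param track a [disorder_track()].
#' @return tibble with `residue_index`, `mean_score`, `disordered`.
#' @export
consensus_disorder <- function(track) {
  m <- rowMeans(track$scores)
  tibble::tibble(residue_index = seq_along(m), mean_score = m,
                 disordered = m >= 0.5)
}

#' Disorder annotation of a motif span
#'
#' Average consensus propensity over the motif residues, with the D/F call
#' (D iff the average is >= 0.5) and a consistency flag that is TRUE only
#' when every predictor's own motif-average falls on the same side of 0.5.
#'
#' @param track a [disorder_track()].
#' @param motif_start,motif_end 1-based inclusive span within the track.
#' @return list with `call` (`"D"` or `"F"`), `avg_propensity`,
#'   `per_predictor_means`, `consistent`.
#' @export
annotate_motif_disorder <- function(track, motif_start, motif_end) {
  n <- nrow(track$scores)
  if (motif_start < 1L || motif_end > n || motif_start > motif_end) {
    stop("motif span outside the track", call. = FALSE)
  }
  sub <- track$scores[motif_start:motif_end, , drop = FALSE]
  per_pred <- colMeans(sub)
  avg <- mean(rowMeans(sub))
  call <- if (avg >= 0.5) "D" else "F"
  list(
    call = call,
    avg_propensity = avg,
    per_predictor_means = per_pred,
    consistent = all(per_pred >= 0.5) || all(per_pred < 0.5)
  )
}
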