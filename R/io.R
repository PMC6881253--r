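# Readers and writers: FASTA, the curated motif table contract, and
# deterministic report output. All tables are tab-separated text.

MOTIF_TABLE_COLUMNS <- c(
  "protein_id", "species", "context_seq", "motif_start", "motif_end",
  "declared_class", "evidence_code", "kd_molar", "measure_ph",
  "measure_temp_K", "disorder_call", "disorder_avg"
)

#' Read named amino-acid sequences from FASTA
#'
#' Thin validating wrapper around Biostrings: record order and identifiers
#' are preserved, lowercase letters are uppercased with a warning, and
#' non-amino-acid alphabets are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta requires the Biostrings package", call. = FALSE)
  }
  raw <- readLines(path)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    warning("lowercase residues uppercased")
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    assert_aa_string(seqs[i], allow_gap = TRUE,
                     what = paste0("record '", names(seqs)[i], "'"))
  }
  seqs
}

#' Read a curated motif table
#'
#' Tab-separated with the column contract `protein_id`, `species`,
#' `context_seq`, `motif_start`, `motif_end`, `declared_class`,
#' `evidence_code`, `kd_molar`, `measure_ph`, `measure_temp_K`,
#' `disorder_call`, `disorder_avg`. Empty optional fields become NA, not
#' zero. Every row is validated through [motif_entry()]; a bad row is
#' reported by protein id and row number.
#'
#' @param path file path.
#' @return validated motif table (tibble).
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(MOTIF_TABLE_COLUMNS, names(tab))
  if (length(miss) > 0L) {
    stop("motif table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    tryCatch(
      motif_entry(
        protein_id = r$protein_id, species = r$species,
        context_seq = r$context_seq, motif_start = r$motif_start,
        motif_end = r$motif_end,
        declared_class = if (is.na(r$declared_class)) "unknown" else r$declared_class,
        evidence_code = r$evidence_code, kd_molar = r$kd_molar,
        measure_ph = r$measure_ph, measure_temp_K = r$measure_temp_K,
        disorder_call = r$disorder_call, disorder_avg = r$disorder_avg
      ),
      error = function(e) {
        stop("row ", i, " (", r$protein_id, "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  do.call(rbind, rows)
}

#' Write a motif table (round-trip safe)
#'
#' @param entries motif table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(entries, path) {
  write_report(entries[, MOTIF_TABLE_COLUMNS], path)
}

#' Deterministic tab-separated report writer
#'
#' Fixed float formatting (up to 10 significant digits, no scientific-
#' notation instability) and stable row order make the output byte-stable
#' for identical inputs.
#'
#' @param results data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  out <- as.data.frame(results)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(out[[j]], digits = 10, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under `extdata`; with no argument, lists them.
#' @return file path, or a vector of available names.
#' @export
pipflank_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pipflank")))
  }
  path <- system.file("extdata", file, package = "pipflank")
  if (identical(path, "")) stop("no such example file: ", file, call. = FALSE)
  path
}
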