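# File formats: FASTA (via seqinr) and the delimited dataset / prediction /
# report dialects. Dataset files are CSV with required columns
# (id, sequence, experimental_pi) and optional (fraction, modifications).

#' Read protein or peptide sequences from a FASTA file
#'
#' The id is the header token before the first whitespace; sequences are
#' normalized to uppercase. Duplicate ids, header-only records and illegal
#' residue characters are parse errors reporting the offending line.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("No such file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L || !any(startsWith(lines, ">"))) {
    abort_parse(sprintf("'%s' is empty or contains no FASTA records.", path))
  }
  hdr <- which(startsWith(lines, ">"))
  next_content <- c(hdr[-1], length(lines) + 1L)
  empty <- hdr[vapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, length.out = next_content[i] - hdr[i] - 1L)]
    length(body) == 0L || !any(nzchar(trimws(body)))
  }, TRUE)]
  if (length(empty) > 0L) {
    abort_parse(sprintf(
      "Header-only FASTA record at line %d of '%s'.", empty[1], path))
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort_parse(sprintf("Duplicate FASTA id '%s' in '%s' (header line %d).",
                        dup, path, hdr[which(ids == dup)[2]]))
  }
  seqs <- toupper(unlist(recs, use.names = FALSE))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "", fixed = TRUE)[[1]]),
                   AA_ALPHABET)
    if (length(bad) > 0L) {
      abort_parse(sprintf(
        "Illegal residue character(s) %s in record '%s' (header line %d) of '%s'.",
        paste(bad, collapse = ", "), ids[i], hdr[i], path))
    }
  }
  tibble(id = ids, sequence = seqs)
}

#' Write sequences to a FASTA file
#'
#' @param data Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  data <- as_tibble(data)
  if (!all(c("id", "sequence") %in% names(data))) {
    abort_validation("`data` must have columns `id` and `sequence`.")
  }
  seqinr::write.fasta(as.list(data$sequence), names = data$id,
                      file.out = path, nbchar = width)
  invisible(path)
}

#' Read a benchmark dataset from a delimited file
#'
#' Requires columns `id`, `sequence`, `experimental_pi`; optional `fraction`
#' and `modifications` (dialect of [parse_modifications()]). Null or
#' non-numeric experimental values are dropped with a reported count rather
#' than crashing; modification strings are validated strictly.
#'
#' @param path CSV file path.
#' @return Tibble of dataset records; the number of dropped null records is
#'   attached as attribute `n_null_dropped` and reported via a message.
#' @export
read_pi_dataset <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("id", "sequence", "experimental_pi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort_validation(sprintf("Dataset '%s' is missing required column(s): %s.",
                             path, paste(missing_cols, collapse = ", ")))
  }
  pi_num <- suppressWarnings(as.numeric(df$experimental_pi))
  keep <- is.finite(pi_num)
  n_null <- sum(!keep)
  if (n_null > 0L) {
    inform(sprintf(
      "read_pi_dataset: dropped %d record(s) with null or non-numeric experimental pI.",
      n_null))
  }
  out <- as_tibble(df[keep, ])
  out$experimental_pi <- pi_num[keep]
  out$sequence <- toupper(out$sequence)
  if ("modifications" %in% names(out)) {
    purrr::walk(out$modifications, parse_modifications)  # strict validation
  }
  attr(out, "n_null_dropped") <- n_null
  out
}

#' Write a dataset, with a FASTA file alongside
#'
#' Emits the same delimited dialect [read_pi_dataset()] reads, plus a
#' `.fasta` of the sequences next to it.
#'
#' @param data Dataset records.
#' @param path Output CSV path.
#' @param fasta Also write `<path>.fasta` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_pi_dataset <- function(data, path, fasta = TRUE) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  if (fasta) {
    write_fasta(data, paste0(tools::file_path_sans_ext(path), ".fasta"))
  }
  invisible(path)
}

#' Write prediction records
#'
#' Comma-separated with a header row; predicted pIs are printed to 2 decimals
#' by default (the field's reporting precision), or at full precision with
#' `full_precision = TRUE`.
#'
#' @param predictions Tibble from [predict_pi()].
#' @param path Output CSV path.
#' @param full_precision Keep full numeric precision.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, full_precision = FALSE) {
  out <- as_tibble(predictions)
  if (!full_precision && "predicted_pi" %in% names(out)) {
    out$predicted_pi <- round(out$predicted_pi, 2)
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}
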