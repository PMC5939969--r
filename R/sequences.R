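#' Construct a (possibly modified) peptide or protein sequence
#'
#' `modified_sequence()` is the universal input type of the charge model: a
#' residue string over the one-letter amino-acid alphabet plus optional
#' phosphorylation sites and an N-terminal acetylation flag. Lowercase input is
#' normalized to uppercase; the degenerate codes B, Z, X, U, O are accepted but
#' treated as non-ionizable throughout.
#'
#' @param residues Single character string of one-letter residue codes.
#' @param phospho_sites Integer vector of 1-based positions carrying a
#'   phosphate group. Each position must index an S, T or Y residue.
#' @param n_term_acetylated Logical flag; when `TRUE` the free alpha-amino
#'   group is absent and contributes no charge.
#' @return An object of class `modified_sequence`.
#' @examples
#' modified_sequence("SAMPLER", phospho_sites = 1)
#' modified_sequence("gggk", n_term_acetylated = TRUE)
#' @export
modified_sequence <- function(residues, phospho_sites = integer(),
                              n_term_acetylated = FALSE) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    abort_validation("`residues` must be a single non-NA character string.")
  }
  residues <- toupper(trimws(residues))
  if (nchar(residues) == 0L) {
    abort_validation("`residues` must contain at least one residue.")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "Illegal residue code(s) after normalization: %s.",
      paste(bad, collapse = ", ")))
  }
  phospho_sites <- sort(unique(as.integer(phospho_sites)))
  if (length(phospho_sites) > 0L) {
    if (any(is.na(phospho_sites)) ||
        any(phospho_sites < 1L | phospho_sites > length(chars))) {
      abort_validation("Phospho sites must lie within [1, sequence length].")
    }
    site_res <- chars[phospho_sites]
    if (!all(site_res %in% c("S", "T", "Y"))) {
      abort_validation(sprintf(
        "Phospho sites must index S, T or Y residues; found %s.",
        paste(unique(setdiff(site_res, c("S", "T", "Y"))), collapse = ", ")))
    }
  }
  if (!is.logical(n_term_acetylated) || length(n_term_acetylated) != 1L ||
      is.na(n_term_acetylated)) {
    abort_validation("`n_term_acetylated` must be TRUE or FALSE.")
  }
  structure(
    list(residues = residues,
         phospho_sites = phospho_sites,
         n_term_acetylated = n_term_acetylated),
    class = "modified_sequence")
}

#' @export
print.modified_sequence <- function(x, ...) {
  cat("<modified_sequence> ", x$residues, "\n", sep = "")
  if (length(x$phospho_sites) > 0L) {
    cat("  phospho sites: ", paste(x$phospho_sites, collapse = ", "), "\n",
        sep = "")
  }
  if (x$n_term_acetylated) cat("  N-terminally acetylated\n")
  invisible(x)
}

#' @export
format.modified_sequence <- function(x, ...) x$residues

# Coerce character / modified_sequence input to modified_sequence.
as_modified_sequence <- function(x, modifications = NULL) {
  if (inherits(x, "modified_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!is.null(modifications) && !is.na(modifications) &&
        nzchar(modifications)) {
      mods <- parse_modifications(modifications)
      return(modified_sequence(x, phospho_sites = mods$phospho_sites,
                               n_term_acetylated = mods$n_term_acetylated))
    }
    return(modified_sequence(x))
  }
  abort_validation("Expected a character sequence or a modified_sequence.")
}

#' Parse a modification annotation string
#'
#' The delimited dialect used in dataset tables: entries separated by `;`,
#' each either `phospho@<pos>` (1-based position of a phosphorylated S/T/Y)
#' or `acetyl@nterm` (N-terminal acetylation). Parsing is strict: unknown
#' entries are an error, never silently dropped.
#'
#' @param x Single annotation string (may be empty or `NA` for no
#'   modifications).
#' @return A list with elements `phospho_sites` (integer vector) and
#'   `n_term_acetylated` (flag).
#' @examples
#' parse_modifications("phospho@3;acetyl@nterm")
#' @export
parse_modifications <- function(x) {
  out <- list(phospho_sites = integer(), n_term_acetylated = FALSE)
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x))) {
    return(out)
  }
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  for (p in parts) {
    if (grepl("^phospho@[0-9]+$", p)) {
      out$phospho_sites <- c(out$phospho_sites,
                             as.integer(sub("^phospho@", "", p)))
    } else if (identical(p, "acetyl@nterm")) {
      out$n_term_acetylated <- TRUE
    } else {
      abort_parse(sprintf(
        "Unknown modification entry '%s'; expected 'phospho@<pos>' or 'acetyl@nterm'.",
        p))
    }
  }
  out$phospho_sites <- sort(unique(out$phospho_sites))
  out
}

#' Format modifications back to the annotation dialect
#'
#' Inverse of [parse_modifications()]; returns `""` for an unmodified
#' sequence.
#'
#' @param seq A `modified_sequence`.
#' @return Single annotation string.
#' @export
format_modifications <- function(seq) {
  seq <- as_modified_sequence(seq)
  parts <- character()
  if (length(seq$phospho_sites) > 0L) {
    parts <- c(parts, paste0("phospho@", seq$phospho_sites))
  }
  if (seq$n_term_acetylated) parts <- c(parts, "acetyl@nterm")
  paste(parts, collapse = ";")
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

seq_length <- function(seq) nchar(seq$residues)
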