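# Position-dependent pKa method: terminal pKas chosen by the identity of the
# first/last residue, and sidechain pKas optionally overridden by positional
# context (n-terminal / c-terminal / internal), all driven by a
# terminal_variant data table over a base pKa set. The algorithm is a single
# code path; the four shipped variants are pure data.

#' Enumerate ionizable groups under a terminal variant
#'
#' Like [enumerate_groups()], but the N-terminal pKa is selected by the
#' identity of residue 1 (falling back to the variant default), the
#' C-terminal pKa by the last residue, and sidechain groups at the first or
#' last position may take positional overrides from the variant's table, with
#' the base set's internal value as fallback.
#'
#' @param seq Character sequence or [modified_sequence()].
#' @param variant A `terminal_variant` or registered variant name
#'   (`default`, `expasy`, `calibrated`, `skoog`).
#' @return Group tibble as for [enumerate_groups()].
#' @examples
#' bjellqvist_groups("DGGK", "expasy")
#' @export
bjellqvist_groups <- function(seq, variant = "expasy") {
  seq <- as_modified_sequence(seq)
  variant <- get_terminal_variant(variant)
  base <- get_pka_set(variant$base_set)
  chars <- seq_chars(seq)
  n <- length(chars)

  term_pka <- function(map, residue) {
    if (residue %in% names(map)) map[[residue]] else map[["default"]]
  }
  positional <- variant$sidechain_positional
  pos_pka <- function(residue, context) {
    if (nrow(positional) > 0L) {
      hit <- positional$residue == residue & positional$position == context
      if (any(hit)) return(positional$pka[hit][1])
    }
    base$sidechain[[residue]]
  }

  rows <- list()
  if (!seq$n_term_acetylated) {
    rows[[length(rows) + 1L]] <-
      new_groups("n_term", chars[1], 1L, "base",
                 term_pka(variant$n_term_by_residue, chars[1]))
  }
  for (i in which(chars %in% names(base$sidechain))) {
    res <- chars[i]
    context <- if (i == 1L) "n-terminal" else if (i == n) "c-terminal" else "internal"
    rows[[length(rows) + 1L]] <-
      new_groups("sidechain", res, i, group_polarity(res, "sidechain"),
                 pos_pka(res, context))
  }
  rows[[length(rows) + 1L]] <-
    new_groups("c_term", chars[n], n, "acid",
               term_pka(variant$c_term_by_residue, chars[n]))
  rows[[length(rows) + 1L]] <- modification_group_rows(seq)
  dplyr::bind_rows(rows)
}

#' Solve the isoelectric point with position-dependent terminal pKas
#'
#' @inheritParams bjellqvist_groups
#' @param config A [solver_config()].
#' @return The pI (pH units).
#' @examples
#' solve_pi_bjellqvist("SAMPLER", "expasy")
#' @export
solve_pi_bjellqvist <- function(seq, variant = "expasy",
                                config = solver_config()) {
  solve_groups(bjellqvist_groups(seq, variant), config)
}
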