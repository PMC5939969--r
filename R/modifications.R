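# Charge effects of post-translational modifications. Phosphorylation adds a
# doubly ionizable acid at the site (default site pKas 1.2 and 6.5, from the
# bundled modification table, shared by phospho-S/T/Y); N-terminal
# acetylation removes the free alpha-amino group, so its basic contribution
# is omitted entirely.

#' Ionizable groups contributed by one phospho site
#'
#' @param seq A [modified_sequence()] with the site annotated.
#' @param site 1-based position; must be one of the sequence's phospho sites.
#' @return A two-row group tibble (both acids, default pKas 1.2 and 6.5).
#' @examples
#' phospho_groups(modified_sequence("ASAK", phospho_sites = 2), 2)
#' @export
phospho_groups <- function(seq, site) {
  seq <- as_modified_sequence(seq)
  if (!site %in% seq$phospho_sites) {
    abort_validation(sprintf(
      "Position %d is not an annotated phospho site of this sequence.", site))
  }
  site_pkas <- modification_pkas("phospho")
  new_groups("modification",
             paste0("phospho-", seq_chars(seq)[site]),
             site, site_pkas$polarity, site_pkas$pka)
}

#' Remove the N-terminal amine group from a group table
#'
#' Implements acetylation on an already-enumerated group collection: the
#' `n_term` row is dropped and every other group is unchanged. The group
#' enumerators apply this automatically when the sequence carries the
#' acetylation flag.
#'
#' @param groups Group tibble from [enumerate_groups()] or
#'   [bjellqvist_groups()].
#' @return The group tibble without the `n_term` row.
#' @export
apply_acetylation <- function(groups) {
  groups[groups$kind != "n_term", ]
}
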