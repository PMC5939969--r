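# Sequence-context corrections.
#
# Cofactor: additive pKa shifts applied once, before solving, to the
# carboxyl groups only (D/E sidechains and the C-terminus), summed over
# neighboring residues at signed offsets within +/-3.
#
# Branca: shifts for every ionizable group from ionizable neighbors up to 6
# residues away, each weighted by the neighbor's charged fraction at the
# current pH estimate, plus an additive carboxyl-count term on D/E groups —
# solved self-consistently by a damped fixed point initialized at the
# uncorrected iterative pI. Only defined for sequences with a tryptic (K/R)
# C-terminus.

#' Apply cofactor neighbor corrections to the group table
#'
#' For each Asp/Glu sidechain group and the C-terminal carboxyl, adds the
#' table's entry for every neighboring residue at signed offsets -3..+3
#' (offset 0 excluded; offsets outside the sequence clipped). All other
#' groups are returned unchanged. An all-zero (empty) table is the identity.
#'
#' @param seq Character sequence or [modified_sequence()].
#' @param base_set A `pka_set` or registered name supplying the uncorrected
#'   pKas.
#' @param table A `correction_table` with `method = "cofactor"`.
#' @return Group tibble with corrected `pka` values.
#' @export
cofactor_pkas <- function(seq, base_set = "emboss",
                          table = get_correction_table("cofactor")) {
  if (!inherits(table, "correction_table") || table$method != "cofactor") {
    abort_validation("`table` must be a correction_table with method 'cofactor'.")
  }
  seq <- as_modified_sequence(seq)
  groups <- enumerate_groups(seq, base_set)
  lookup <- correction_lookup(table)
  if (length(lookup) == 0L) return(groups)
  chars <- seq_chars(seq)
  n <- length(chars)
  target <- (groups$kind == "sidechain" & groups$residue %in% c("D", "E")) |
    groups$kind == "c_term"
  for (g in which(target)) {
    pos <- groups$position[g]
    offsets <- setdiff(-table$window:table$window, 0L)
    for (off in offsets) {
      j <- pos + off
      if (j < 1L || j > n) next
      key <- paste(chars[j], off, sep = "|")
      if (key %in% names(lookup)) {
        groups$pka[g] <- groups$pka[g] + lookup[[key]]
      }
    }
  }
  groups
}

#' Solve the isoelectric point with cofactor corrections
#'
#' @inheritParams cofactor_pkas
#' @param config A [solver_config()].
#' @return The pI (pH units).
#' @export
solve_pi_cofactor <- function(seq, base_set = "emboss",
                              table = get_correction_table("cofactor"),
                              config = solver_config()) {
  solve_groups(cofactor_pkas(seq, base_set, table), config)
}

#' Solve the isoelectric point with charged-fraction-weighted corrections
#'
#' Self-consistent scheme: (1) initialize the pH estimate at the uncorrected
#' iterative pI; (2) compute each ionizable group's charged fraction (the
#' absolute fractional charge) at the current estimate; (3) set each
#' effective pKa to the base pKa plus the sum over ionizable sidechain
#' neighbors within 6 residues of the table entry weighted by that neighbor's
#' charged fraction, plus the carboxyl-count term on D/E groups; (4) re-solve
#' and repeat until the estimate moves by less than the solver tolerance.
#' Updates are damped by 0.5 when the estimate oscillates.
#'
#' Only applicable to sequences whose last residue is K or R; other inputs
#' raise a `not_applicable` error (distinct from numerical failure).
#'
#' @inheritParams cofactor_pkas
#' @param table A `correction_table` with `method = "branca"`.
#' @param config A [solver_config()].
#' @return The converged pI (pH units).
#' @export
solve_pi_branca <- function(seq, base_set = "emboss",
                            table = get_correction_table("branca"),
                            config = solver_config()) {
  if (!inherits(table, "correction_table") || table$method != "branca") {
    abort_validation("`table` must be a correction_table with method 'branca'.")
  }
  seq <- as_modified_sequence(seq)
  chars <- seq_chars(seq)
  last <- chars[length(chars)]
  if (!last %in% c("K", "R")) {
    abort_not_applicable(sprintf(
      "The branca method requires a K or R C-terminal residue (tryptic peptide); got '%s'.",
      last))
  }
  base_groups <- enumerate_groups(seq, base_set)
  lookup <- correction_lookup(table)
  n_d <- sum(base_groups$kind == "sidechain" & base_groups$residue == "D")
  n_e <- sum(base_groups$kind == "sidechain" & base_groups$residue == "E")
  carboxyl <- carboxyl_term(table, n_d, n_e)

  ph_estimate <- solve_groups(base_groups, config)
  if (length(lookup) == 0L && carboxyl == 0) {
    # zero table: the fixed point is reached at the uncorrected pI
    return(ph_estimate)
  }

  is_sidechain <- base_groups$kind == "sidechain"
  is_carboxyl_target <- is_sidechain & base_groups$residue %in% c("D", "E")
  groups <- base_groups
  prev_delta <- NA_real_
  for (iteration in seq_len(config$max_iterations)) {
    # charged fraction = |fractional charge| of each group at the estimate,
    # under the current effective pKas
    frac <- abs(purrr::map2_dbl(groups$pka, groups$polarity == "base",
                                function(p, b) net_charge_fast(p, b,
                                                               ph_estimate)))
    new_pka <- base_groups$pka
    for (g in seq_len(nrow(groups))) {
      shift <- 0
      for (j in which(is_sidechain)) {
        if (j == g) next
        off <- groups$position[j] - groups$position[g]
        if (off == 0L || abs(off) > table$window) next
        key <- paste(groups$residue[j], off, sep = "|")
        if (key %in% names(lookup)) {
          shift <- shift + lookup[[key]] * frac[j]
        }
      }
      if (is_carboxyl_target[g]) shift <- shift + carboxyl
      new_pka[g] <- base_groups$pka[g] + shift
    }
    groups$pka <- pmin(pmax(new_pka, 1e-6), 14 - 1e-6)
    new_estimate <- solve_groups(groups, config)
    delta <- new_estimate - ph_estimate
    if (!is.na(prev_delta) && sign(delta) == -sign(prev_delta) &&
        prev_delta != 0) {
      new_estimate <- ph_estimate + 0.5 * delta  # damp oscillation
      delta <- new_estimate - ph_estimate
    }
    converged <- abs(delta) < config$tolerance
    ph_estimate <- new_estimate
    if (converged) return(ph_estimate)
    prev_delta <- delta
  }
  abort_convergence(sprintf(
    "Branca fixed point did not converge in %d iterations; last estimates %.6f and %.6f.",
    config$max_iterations, ph_estimate - (prev_delta %||% 0), ph_estimate))
}
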