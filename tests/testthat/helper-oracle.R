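# Independent reference implementations used to check the package. They are
# written from the definitions (term-by-term Henderson-Hasselbalch sums, grid
# argmin) and share no code with the solver path.

# Net charge by explicit per-group summation, vectorized over ph.
oracle_charge <- function(pka, polarity, ph) {
  out <- rep(0, length(ph))
  for (i in seq_along(pka)) {
    out <- out + if (polarity[i] == "base") {
      1 / (1 + 10^(ph - pka[i]))
    } else {
      -1 / (1 + 10^(pka[i] - ph))
    }
  }
  out
}

# Argmin of |net charge| over an exhaustive fine grid. A coarse pass brackets
# the sign change of the strictly decreasing charge function; because
# |charge| is unimodal with its minimum at the sign change, scanning the fine
# grid inside the bracket is identical to scanning it over the whole
# interval.
oracle_grid_pi <- function(groups, lo = 0, hi = 14, coarse = 0.01,
                           fine = 1e-5) {
  grid <- seq(lo, hi, by = coarse)
  ch <- oracle_charge(groups$pka, groups$polarity, grid)
  neg <- which(ch < 0)
  stopifnot(length(neg) > 0L, neg[1] > 1L)
  bracket <- seq(grid[neg[1] - 1L], grid[neg[1]], by = fine)
  bracket[which.min(abs(oracle_charge(groups$pka, groups$polarity, bracket)))]
}

# Random peptide fixtures; seeds are fixed per call site.
test_peptides <- function(n, seed, tryptic = TRUE, length_range = c(7L, 25L)) {
  random_peptides(n, length_range = length_range, tryptic = tryptic,
                  seed = seed)
}

# A synthetic diprotic pKa set: only the termini ionize.
diprotic_set <- function(n_term = 9, c_term = 3) {
  pka_set("diprotic-test", sidechain = numeric(), n_term = n_term,
          c_term = c_term, source = "synthetic test set")
}

zero_cofactor <- function() correction_table("cofactor")
zero_branca <- function() correction_table("branca")
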