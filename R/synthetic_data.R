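# Seeded synthetic datasets with the statistical structure of IEF peptide
# experiments and literature-collated protein pI tables, so the benchmark
# layer is fully testable without external downloads.

sample_sequence <- function(len, tryptic, composition = NULL) {
  if (is.null(composition)) {
    body <- sample(AA_STANDARD, len, replace = TRUE)
  } else {
    body <- sample(names(composition), len, replace = TRUE,
                   prob = composition)
  }
  if (tryptic) body[len] <- sample(c("K", "R"), 1L)
  paste(body, collapse = "")
}

#' Generate random peptide sequences
#'
#' Uniform composition over the 20 standard residues by default; with
#' `tryptic = TRUE` the last residue is K or R (trypsin specificity).
#'
#' @param n Number of sequences.
#' @param length_range Integer (min, max) residue counts.
#' @param tryptic Enforce a K/R C-terminus.
#' @param seed Integer seed.
#' @param composition Optional named probability vector over residues.
#' @return Character vector of sequences.
#' @export
random_peptides <- function(n, length_range = c(7L, 25L), tryptic = TRUE,
                            seed = 1L, composition = NULL) {
  withr::with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    vapply(lens, sample_sequence, "", tryptic = tryptic,
           composition = composition)
  })
}

#' Simulate an IEF-fractionated peptide dataset
#'
#' Emulates an OFF-GEL peptide experiment: tryptic random sequences, ground
#' truth from a chosen generating method, optional phospho / N-terminal
#' acetyl subpopulations applied at the stated rates, Gaussian per-record
#' measurement noise, and a fraction id given by binning the experimental pI
#' into `n_fractions` equal-width bins over `ph_range` (values outside the
#' range fall in the terminal bins). Deterministic per seed.
#'
#' @param n Number of peptides.
#' @param length_range (min, max) residue counts.
#' @param tryptic Enforce K/R C-termini.
#' @param method,parameter Generating method and its pKa set / variant.
#' @param noise_sd Gaussian SD of the measurement noise (pH units).
#' @param n_fractions Number of IEF fractions (default 15).
#' @param ph_range Fractionated pH range (default 3-10).
#' @param phospho_rate,acetyl_rate Fractions of peptides receiving one
#'   phospho site (on a random S/T/Y, when present) or N-terminal
#'   acetylation.
#' @param quantize_to_fraction Report the fraction midpoint instead of the
#'   noisy per-record value as `experimental_pi`.
#' @param composition Optional named residue-probability vector; the bundled
#'   vertebrate-like table is available as
#'   `get_property_table("composition_vertebrate")`. `NULL` (default) samples
#'   residues uniformly.
#' @param seed Integer seed.
#' @param config Solver configuration for the generating method.
#' @return Tibble of dataset records: `id`, `sequence`, `modifications`,
#'   `true_pi`, `experimental_pi`, `fraction`.
#' @export
simulate_peptides <- function(n = 1000L, length_range = c(7L, 25L),
                              tryptic = TRUE, method = "bjellqvist",
                              parameter = "expasy", noise_sd = 0.2,
                              n_fractions = 15L, ph_range = c(3, 10),
                              phospho_rate = 0, acetyl_rate = 0,
                              quantize_to_fraction = FALSE,
                              composition = NULL, seed = 1L,
                              config = solver_config()) {
  stopifnot(noise_sd >= 0, n_fractions >= 1L,
            phospho_rate >= 0, phospho_rate <= 1,
            acetyl_rate >= 0, acetyl_rate <= 1)
  withr::with_seed(seed, {
    records <- vector("list", n)
    i <- 1L
    while (i <= n) {
      len <- sample(length_range[1]:length_range[2], 1L)
      s <- sample_sequence(len, tryptic, composition)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      phospho <- integer()
      if (runif(1) < phospho_rate) {
        sty <- which(chars %in% c("S", "T", "Y"))
        if (length(sty) > 0L) phospho <- sty[sample.int(length(sty), 1L)]
      }
      acetyl <- runif(1) < acetyl_rate
      seq <- modified_sequence(s, phospho_sites = phospho,
                               n_term_acetylated = acetyl)
      truth <- tryCatch(solve_pi_method(seq, method, parameter, config),
                        ampholyte_error = function(e) NA_real_)
      if (is.na(truth)) next  # resample sequences the generator cannot solve
      records[[i]] <- tibble(
        id = sprintf("pep%05d", i),
        sequence = s,
        modifications = format_modifications(seq),
        true_pi = truth,
        experimental_pi = truth + rnorm(1L, 0, noise_sd))
      i <- i + 1L
    }
    out <- dplyr::bind_rows(records)
    breaks <- seq(ph_range[1], ph_range[2], length.out = n_fractions + 1L)
    idx <- pmin(pmax(findInterval(out$experimental_pi, breaks,
                                  rightmost.closed = TRUE), 1L), n_fractions)
    out$fraction <- sprintf("F%02d", idx)
    if (quantize_to_fraction) {
      mids <- (head(breaks, -1L) + breaks[-1L]) / 2
      out$experimental_pi <- mids[idx]
    }
    out
  })
}

#' Simulate a literature-collated protein pI table
#'
#' Emulates a curated protein database: random protein sequences with a
#' ground-truth pI, a rate-controlled subset carrying two or more discordant
#' experimental measurements drawn with a between-laboratory SD, and a small
#' wide-focalization-zone subset whose measurements span at least 3.5 pH
#' units. One output row per measurement; deterministic per seed.
#'
#' @param n Number of proteins.
#' @param length_range (min, max) residue counts.
#' @param method,parameter Generating method and pKa set.
#' @param multi_measurement_rate Fraction of proteins with >= 2 experimental
#'   values.
#' @param between_lab_sd SD of the measurement scatter around truth (pH
#'   units).
#' @param wide_zone_rate Fraction of proteins whose measurements are forced
#'   to span >= 3.5 pH units.
#' @param max_measurements Upper bound on measurements per multi-measured
#'   protein.
#' @param seed Integer seed.
#' @param config Solver configuration.
#' @return Tibble of dataset records: `id`, `sequence`, `true_pi`,
#'   `experimental_pi`, `n_measurements`, `wide_zone`.
#' @export
simulate_proteins <- function(n = 500L, length_range = c(60L, 300L),
                              method = "iterative", parameter = "emboss",
                              multi_measurement_rate = 0.5,
                              between_lab_sd = 1.0, wide_zone_rate = 0.02,
                              max_measurements = 6L, seed = 1L,
                              config = solver_config()) {
  stopifnot(multi_measurement_rate >= 0, multi_measurement_rate <= 1,
            wide_zone_rate >= 0, wide_zone_rate <= 1, between_lab_sd >= 0)
  withr::with_seed(seed, {
    records <- vector("list", n)
    i <- 1L
    while (i <= n) {
      len <- sample(length_range[1]:length_range[2], 1L)
      s <- sample_sequence(len, tryptic = FALSE)
      truth <- tryCatch(solve_pi_method(modified_sequence(s), method,
                                        parameter, config),
                        ampholyte_error = function(e) NA_real_)
      if (is.na(truth)) next
      multi <- runif(1) < multi_measurement_rate
      wide <- multi && runif(1) < wide_zone_rate / max(multi_measurement_rate,
                                                       1e-9)
      k <- if (multi) sample(2:max_measurements, 1L) else 1L
      vals <- truth + rnorm(k, 0, between_lab_sd)
      if (wide) {
        span <- 3.5 + abs(rnorm(1L, 0, 0.4))
        vals[1] <- truth - span / 2
        vals[2] <- truth + span / 2
      }
      vals <- pmin(pmax(vals, 0.5), 13.5)
      if (wide && (max(vals) - min(vals)) < span) {
        # clamping near the pH boundaries shrank the span; re-anchor low
        vals[1] <- 0.5
        vals[2] <- 0.5 + span
      }
      records[[i]] <- tibble(
        id = sprintf("prot%04d", i),
        sequence = s,
        true_pi = truth,
        experimental_pi = vals,
        n_measurements = k,
        wide_zone = wide)
      i <- i + 1L
    }
    dplyr::bind_rows(records)
  })
}
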