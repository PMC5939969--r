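# Henderson-Hasselbalch net-charge model: the computational core shared by
# every non-SVM method. A sequence is reduced to an ordered table of
# ionizable groups; the net charge at pH x is
#   sum over bases of 1 / (1 + 10^(x - pKa))  -
#   sum over acids of 1 / (1 + 10^(pKa - x)),
# continuous and strictly decreasing in x whenever at least one group exists.

group_polarity <- function(residue, kind) {
  if (kind == "n_term") return("base")
  if (kind == "c_term") return("acid")
  if (kind == "modification") return("acid")  # phospho groups are acids
  if (residue %in% BASIC_GROUPS) "base" else "acid"
}

new_groups <- function(kind, residue, position, polarity, pka) {
  tibble(kind = kind, residue = residue, position = as.integer(position),
         polarity = polarity, pka = as.numeric(pka))
}

#' Enumerate the ionizable groups of a sequence under a pKa set
#'
#' Produces one group per ionizable sidechain occurrence, plus the free
#' N-terminal amine (unless the sequence is N-terminally acetylated) and the
#' C-terminal carboxyl, in deterministic order: N-terminus, sidechains by
#' position, C-terminus, then modification groups by position. Phosphorylated
#' sites additionally contribute two acid groups each (default site pKas 1.2
#' and 6.5, from the bundled modification table). Residues without an entry
#' in the set's sidechain map are non-ionizable.
#'
#' @param seq Character sequence or [modified_sequence()].
#' @param pka_set A `pka_set` object or registered set name.
#' @return A tibble with columns `kind`, `residue`, `position`, `polarity`,
#'   `pka` — one row per titratable site.
#' @examples
#' enumerate_groups("KDE", "emboss")
#' @export
enumerate_groups <- function(seq, pka_set = "emboss") {
  seq <- as_modified_sequence(seq)
  if (is.character(pka_set)) pka_set <- get_pka_set(pka_set)
  chars <- seq_chars(seq)
  n <- length(chars)
  rows <- list()
  if (!seq$n_term_acetylated) {
    rows[[length(rows) + 1L]] <-
      new_groups("n_term", chars[1], 1L, "base", pka_set$n_term)
  }
  ion <- which(chars %in% names(pka_set$sidechain))
  for (i in ion) {
    res <- chars[i]
    rows[[length(rows) + 1L]] <-
      new_groups("sidechain", res, i, group_polarity(res, "sidechain"),
                 pka_set$sidechain[[res]])
  }
  rows[[length(rows) + 1L]] <-
    new_groups("c_term", chars[n], n, "acid", pka_set$c_term)
  rows[[length(rows) + 1L]] <- modification_group_rows(seq)
  dplyr::bind_rows(rows)
}

# The two acid groups contributed by each phospho site (modifications module).
modification_group_rows <- function(seq) {
  if (length(seq$phospho_sites) == 0L) {
    return(new_groups(character(), character(), integer(), character(),
                      numeric()))
  }
  site_pkas <- modification_pkas("phospho")
  chars <- seq_chars(seq)
  dplyr::bind_rows(lapply(seq$phospho_sites, function(pos) {
    new_groups("modification",
               paste0("phospho-", chars[pos]),
               pos,
               site_pkas$polarity,
               site_pkas$pka)
  }))
}

#' Net charge of a group collection at one or more pH values
#'
#' Evaluates the Henderson-Hasselbalch sum: each basic group contributes its
#' protonated fraction (+1 scaled), each acidic group minus its deprotonated
#' fraction. Vectorized over `ph`.
#'
#' @param groups Group tibble from [enumerate_groups()] (or any table with
#'   `polarity` and `pka` columns).
#' @param ph Numeric vector of pH values.
#' @return Numeric vector of net charges (elementary-charge units).
#' @examples
#' net_charge(enumerate_groups("KDE", "emboss"), ph = 7)
#' @export
net_charge <- function(groups, ph) {
  if (any(!is.finite(ph))) abort_validation("`ph` must be finite.")
  net_charge_fast(groups$pka, groups$polarity == "base", ph)
}

# Hot path shared by the solvers and the grid oracle: plain numeric vectors.
net_charge_fast <- function(pka, is_base, ph) {
  if (length(pka) == 0L) return(rep(0, length(ph)))
  pos <- pka[is_base]
  neg <- pka[!is_base]
  out <- numeric(length(ph))
  if (length(pos) > 0L) {
    out <- out + colSums(1 / (1 + 10^(outer(-pos, ph, `+`))))
  }
  if (length(neg) > 0L) {
    out <- out - colSums(1 / (1 + 10^(outer(neg, -ph, `+`))))
  }
  out
}

#' Titration curve of a sequence over a pH grid
#'
#' @param seq Character sequence or [modified_sequence()].
#' @param pka_set A `pka_set` or registered name.
#' @param ph_min,ph_max Grid bounds (pH units); `ph_min < ph_max`.
#' @param step Positive grid spacing.
#' @return A tibble of class `charge_profile` with columns `ph` (strictly
#'   increasing) and `charge` (non-increasing).
#' @examples
#' charge_profile("SAMPLER", "emboss", step = 0.5)
#' @export
charge_profile <- function(seq, pka_set = "emboss", ph_min = 0, ph_max = 14,
                           step = 0.01) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0) {
    abort_validation("`step` must be a single positive number.")
  }
  if (ph_min >= ph_max) {
    abort_validation("`ph_min` must be smaller than `ph_max`.")
  }
  grid <- seq(ph_min, ph_max, by = step)
  groups <- enumerate_groups(seq, pka_set)
  out <- tibble(ph = grid, charge = net_charge(groups, grid))
  class(out) <- c("charge_profile", class(out))
  out
}

#' @export
autoplot.charge_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ph, y = .data$charge)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "pH", y = "Net charge (e)")
}
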