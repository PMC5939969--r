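# Evaluation layer: squared Pearson correlation and RMSD between predicted
# and experimental pI, outlier flagging, per-fraction summaries, and the
# method x pKa-set leaderboard grid.

#' Squared Pearson correlation between experimental and predicted pI
#'
#' @param experimental,predicted Equal-length numeric vectors (length >= 3,
#'   both non-constant).
#' @return The square of the Pearson product-moment correlation.
#' @examples
#' pearson_r2(c(4, 6, 8), c(4, 6, 7))
#' @export
pearson_r2 <- function(experimental, predicted) {
  check_paired(experimental, predicted, min_n = 3L)
  if (sd(experimental) == 0 || sd(predicted) == 0) {
    abort_validation(
      "Correlation is undefined for a constant vector; refusing to report 0.")
  }
  cor(experimental, predicted)^2
}

#' Root-mean-square deviation between experimental and predicted pI
#'
#' @param experimental,predicted Equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((experimental - predicted)^2))`, in pH units.
#' @examples
#' rmsd(c(4, 5, 6), c(5, 6, 7))
#' @export
rmsd <- function(experimental, predicted) {
  check_paired(experimental, predicted, min_n = 1L)
  sqrt(mean((experimental - predicted)^2))
}

check_paired <- function(experimental, predicted, min_n) {
  if (length(experimental) != length(predicted)) {
    abort_validation(sprintf(
      "`experimental` (%d) and `predicted` (%d) must have equal length.",
      length(experimental), length(predicted)))
  }
  if (length(experimental) < min_n) {
    abort_validation(sprintf("At least %d paired values are required.", min_n))
  }
  if (any(!is.finite(experimental)) || any(!is.finite(predicted))) {
    abort_validation("Inputs must be finite; filter null values first.")
  }
  invisible(TRUE)
}

#' Flag outlier records
#'
#' A record is an outlier when its absolute residual meets or exceeds the
#' sample standard deviation of the *predicted* values:
#' `|experimental - predicted| >= SD(predicted)`. When the predictions are
#' constant (SD = 0), only strictly positive residuals flag, so a perfect
#' constant fit reports no outliers.
#'
#' @param experimental,predicted Equal-length numeric vectors (length >= 2).
#' @return Logical vector of flags.
#' @examples
#' flag_outliers(c(5, 7, 11), c(4, 6, 8))
#' @export
flag_outliers <- function(experimental, predicted) {
  check_paired(experimental, predicted, min_n = 2L)
  sd_pred <- sd(predicted)
  resid <- abs(experimental - predicted)
  if (sd_pred == 0) resid > 0 else resid >= sd_pred
}

#' The default method x pKa-set benchmark grid
#'
#' One row per method/parameter combination: the iterative method over the
#' nine classical pKa sets, the four terminal variants of the
#' position-dependent method, the cofactor and branca corrections, and the
#' SVR predictor — 16 combinations.
#'
#' @return Tibble with columns `method` and `parameter`.
#' @export
default_method_grid <- function() {
  dplyr::bind_rows(
    tibble(method = "svm", parameter = "default"),
    tibble(method = "iterative",
           parameter = c("grimsley", "rodwell", "thurlkill", "sillero",
                         "toseland", "emboss", "solomon", "lehninger",
                         "patrickios")),
    tibble(method = "bjellqvist",
           parameter = c("default", "expasy", "calibrated", "skoog")),
    tibble(method = "cofactor", parameter = "emboss"),
    tibble(method = "branca", parameter = "emboss"))
}

#' Benchmark prediction methods against experimental pIs
#'
#' Runs every grid combination over the dataset and reports, per combination,
#' the record count used, the failure count, signed Pearson r, squared
#' correlation, RMSD, outlier count, and the per-record residual table as a
#' list column. Records whose prediction fails (no isoelectric point, method
#' not applicable) are excluded pairwise and counted in `n_failed`, never
#' crashed on. Reports are sorted by ascending RMSD, then descending r2.
#'
#' @param data Data frame of dataset records: columns `id`, `sequence`,
#'   `experimental_pi`, optional `fraction` and `modifications`.
#' @param grid Tibble with columns `method`, `parameter` (default
#'   [default_method_grid()]).
#' @param svm_model Optional trained [train_pi_svm()] model; when absent, SVM
#'   rows report every record as failed (`not_applicable`).
#' @param config A [solver_config()].
#' @param modifications_aware Propagated to [predict_pi()].
#' @return A tibble of class `pi_benchmark` with one row per combination.
#' @export
run_grid <- function(data, grid = default_method_grid(), svm_model = NULL,
                     config = solver_config(), modifications_aware = TRUE) {
  data <- as_tibble(data)
  need <- c("id", "sequence", "experimental_pi")
  if (!all(need %in% names(data))) {
    abort_validation(sprintf("`data` must have columns %s.",
                             paste(need, collapse = ", ")))
  }
  keep <- is.finite(data$experimental_pi)
  n_null <- sum(!keep)
  if (n_null > 0L) {
    inform(sprintf("Dropped %d record(s) with null experimental pI.", n_null))
  }
  data <- data[keep, ]
  if (nrow(data) == 0L) {
    abort_validation("No records with a finite experimental pI survive filtering.")
  }
  if (!all(c("method", "parameter") %in% names(grid))) {
    abort_validation("`grid` must have columns `method` and `parameter`.")
  }

  reports <- purrr::pmap(grid, function(method, parameter) {
    preds <- if (method == "svm") {
      if (is.null(svm_model)) {
        tibble(id = data$id, method = "svm", pka_set = parameter,
               predicted_pi = NA_real_, failure_reason = "not_applicable")
      } else {
        predict(svm_model, data, modifications_aware = modifications_aware)
      }
    } else {
      predict_pi(data, method, parameter, config = config,
                 modifications_aware = modifications_aware)
    }
    ok <- !is.na(preds$predicted_pi)
    res <- tibble(id = data$id[ok],
                  fraction = if ("fraction" %in% names(data)) {
                    data$fraction[ok]
                  } else {
                    rep(NA_character_, sum(ok))
                  },
                  experimental = data$experimental_pi[ok],
                  predicted = preds$predicted_pi[ok])
    res$residual <- res$experimental - res$predicted
    metrics <- if (nrow(res) >= 3L &&
                   sd(res$experimental) > 0 && sd(res$predicted) > 0) {
      r <- cor(res$experimental, res$predicted)
      list(r = r, r2 = r^2)
    } else if (nrow(res) >= 1L && all(res$residual == 0)) {
      # exact self-benchmark with too little spread for a correlation
      list(r = 1, r2 = 1)
    } else {
      list(r = NA_real_, r2 = NA_real_)
    }
    res$outlier <- if (nrow(res) >= 2L) {
      flag_outliers(res$experimental, res$predicted)
    } else {
      rep(FALSE, nrow(res))
    }
    tibble(method = method, parameter = parameter,
           n = nrow(res), n_failed = sum(!ok),
           r = metrics$r, r2 = metrics$r2,
           rmsd = if (nrow(res) >= 1L) rmsd(res$experimental, res$predicted)
                  else NA_real_,
           n_outliers = sum(res$outlier),
           residuals = list(res))
  })
  out <- dplyr::arrange(dplyr::bind_rows(reports), .data$rmsd,
                        dplyr::desc(.data$r2))
  class(out) <- c("pi_benchmark", class(out))
  out
}

#' @export
tidy.pi_benchmark <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(as_tibble(x), "method", "parameter", "residuals"),
    "residuals")
}

#' @export
glance.pi_benchmark <- function(x, ...) {
  dplyr::select(as_tibble(x), -"residuals")
}

#' @export
autoplot.pi_benchmark <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experimental, y = .data$predicted,
                                   colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ paste(.data$method, .data$parameter, sep = " / ")) +
    ggplot2::labs(x = "Experimental pI", y = "Predicted pI",
                  colour = "Outlier")
}

#' Per-fraction summary of an IEF-fractionated dataset
#'
#' For each fraction: record count, mean and sample SD of the predicted pI
#' (SD reported as 0 with a `single_record` annotation when the fraction has
#' one record), and RMSD against the experimental values. Fractions are
#' ordered by the midpoint of their experimental pI values.
#'
#' @param data Dataset records with a `fraction` column.
#' @param predictions Prediction records from [predict_pi()] (matched on
#'   `id`).
#' @return Tibble with one row per fraction.
#' @export
per_fraction_summary <- function(data, predictions) {
  data <- as_tibble(data)
  if (!"fraction" %in% names(data)) {
    abort_validation("`data` must have a `fraction` column.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(data, "id", "fraction", "experimental_pi"),
    dplyr::select(predictions, "id", "predicted_pi"),
    by = "id")
  joined <- joined[!is.na(joined$predicted_pi) &
                     is.finite(joined$experimental_pi), ]
  out <- joined |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$predicted_pi),
      sd_predicted = ifelse(dplyr::n() > 1L, sd(.data$predicted_pi), 0),
      single_record = dplyr::n() == 1L,
      rmsd = sqrt(mean((.data$experimental_pi - .data$predicted_pi)^2)),
      midpoint = (max(.data$experimental_pi) + min(.data$experimental_pi)) / 2,
      .groups = "drop") |>
    dplyr::arrange(.data$midpoint)
  out
}
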