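# Retrainable support-vector-regression pI predictor. The value of the
# learning method is retrainability to a particular analytical setting, so
# the module is a pipeline — featurization spec, seeded train/validation
# split, small grid search, metadata — not a frozen set of weights.

FEATURE_SPEC_VERSION <- 1L

#' Feature specification for the SVR predictor
#'
#' Defines the fixed, versioned feature order: 20 residue frequencies
#' (optional), sequence length, a seed pI computed with the iterative method
#' under a named pKa set, sequence-mean values of named per-residue property
#' scales, and per-modification counts. Degenerate residue codes contribute
#' zero to composition and property means, which renormalize over standard
#' residues.
#'
#' @param use_composition Include the 20 residue frequencies.
#' @param use_length Include sequence length.
#' @param use_seed_pi Include the iterative-method pI as a feature.
#' @param seed_pka_set Name of the pKa set used for the seed pI.
#' @param property_tables Character vector of bundled property-scale names
#'   (see [get_property_table()]).
#' @param use_mod_counts Include phospho-site count and acetylation flag.
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(use_composition = TRUE, use_length = TRUE,
                         use_seed_pi = TRUE, seed_pka_set = "bjellqvist",
                         property_tables = c("hydropathy", "residue_mass"),
                         use_mod_counts = TRUE) {
  for (p in property_tables) get_property_table(p)  # validate names now
  structure(
    list(use_composition = use_composition,
         use_length = use_length,
         use_seed_pi = use_seed_pi,
         seed_pka_set = tolower(seed_pka_set),
         property_tables = property_tables,
         use_mod_counts = use_mod_counts,
         version = FEATURE_SPEC_VERSION),
    class = "feature_spec")
}

feature_names <- function(spec) {
  nm <- character()
  if (spec$use_composition) nm <- c(nm, paste0("comp_", AA_STANDARD))
  if (spec$use_length) nm <- c(nm, "length")
  if (spec$use_seed_pi) nm <- c(nm, "seed_pi")
  if (length(spec$property_tables) > 0L) {
    nm <- c(nm, paste0("prop_", spec$property_tables))
  }
  if (spec$use_mod_counts) nm <- c(nm, "n_phospho", "acetylated")
  nm
}

featurize_one <- function(seq, spec, config) {
  chars <- seq_chars(seq)
  std <- chars[chars %in% AA_STANDARD]
  if (length(std) == 0L) {
    abort_validation("Sequence has no standard residues to featurize.")
  }
  out <- numeric()
  if (spec$use_composition) {
    comp <- table(factor(std, levels = AA_STANDARD)) / length(std)
    out <- c(out, as.numeric(comp))
  }
  if (spec$use_length) out <- c(out, length(chars))
  if (spec$use_seed_pi) {
    seed <- tryCatch(solve_pi(seq, spec$seed_pka_set, config),
                     ampholyte_error = function(e) 7)
    out <- c(out, seed)
  }
  for (p in spec$property_tables) {
    tab <- get_property_table(p)
    out <- c(out, mean(tab[std]))
  }
  if (spec$use_mod_counts) {
    out <- c(out, length(seq$phospho_sites), as.numeric(seq$n_term_acetylated))
  }
  out
}

#' Compute the feature matrix for a table of sequences
#'
#' @param data Data frame with column `sequence` and optionally
#'   `modifications`, or a character vector of sequences.
#' @param spec A [feature_spec()].
#' @param config Solver configuration for the seed-pI feature.
#' @return Numeric matrix, one row per sequence, columns in the spec's fixed
#'   order.
#' @examples
#' featurize(data.frame(sequence = c("AAAA", "KDEK")), feature_spec())
#' @export
featurize <- function(data, spec = feature_spec(), config = solver_config()) {
  if (is.character(data)) data <- tibble(sequence = data)
  data <- as_tibble(data)
  if (nrow(data) == 0L) {
    return(matrix(numeric(), nrow = 0L, ncol = length(feature_names(spec)),
                  dimnames = list(NULL, feature_names(spec))))
  }
  mods <- if ("modifications" %in% names(data)) data$modifications else
    rep(NA_character_, nrow(data))
  rows <- purrr::map2(data$sequence, mods, function(s, m) {
    featurize_one(as_modified_sequence(s, m), spec, config)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names(spec)
  mat
}

#' Train the support-vector-regression pI predictor
#'
#' Fits an epsilon-insensitive RBF-kernel regression of experimental pI on
#' the feature matrix, with a seeded 80/20 train/validation split and a small
#' grid search over cost and gamma scored by validation RMSD. Deterministic
#' given the dataset order and `seed`.
#'
#' @param data Data frame with columns `sequence`, `experimental_pi`, and
#'   optionally `modifications`. At least 50 records are required — learning
#'   methods need a large training set and inherit its quality.
#' @param spec A [feature_spec()].
#' @param seed Integer seed controlling the split and grid search.
#' @param cost_grid,gamma_grid Hyperparameter candidates.
#' @param epsilon Epsilon of the insensitive loss.
#' @param config Solver configuration for the seed-pI feature.
#' @return An object of class `pi_svm` carrying the fitted model, the feature
#'   spec, and training metadata (n, seed, date, held-out RMSD, chosen
#'   hyperparameters).
#' @export
train_pi_svm <- function(data, spec = feature_spec(), seed = 1L,
                         cost_grid = c(10, 50), gamma_grid = c(0.003, 0.01),
                         epsilon = 0.05, config = solver_config()) {
  data <- as_tibble(data)
  need <- c("sequence", "experimental_pi")
  if (!all(need %in% names(data))) {
    abort_validation("`data` must have columns `sequence` and `experimental_pi`.")
  }
  if (nrow(data) < 50L) {
    abort_validation(sprintf(
      "Training requires at least 50 records (got %d); learning-based predictors depend on a large training dataset.",
      nrow(data)))
  }
  y <- data$experimental_pi
  if (any(!is.finite(y)) || any(y <= 0 | y >= 14)) {
    abort_validation("`experimental_pi` must be finite and in (0, 14).")
  }
  x <- featurize(data, spec, config)

  n <- nrow(x)
  idx_val <- withr::with_seed(seed,
    sort(sample.int(n, size = max(1L, floor(n * 0.2)))))
  idx_train <- setdiff(seq_len(n), idx_val)

  # constant feature columns (e.g. modification counts in unmodified data)
  # cannot be standardized; exclude them from scaling, not from the model
  scale_cols <- apply(x[idx_train, , drop = FALSE], 2, sd) > 0

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  scores <- purrr::pmap_dbl(grid, function(cost, gamma) {
    fit <- e1071::svm(x[idx_train, , drop = FALSE], y[idx_train],
                      type = "eps-regression", kernel = "radial",
                      cost = cost, gamma = gamma, epsilon = epsilon,
                      scale = scale_cols)
    pred <- predict(fit, x[idx_val, , drop = FALSE])
    sqrt(mean((pred - y[idx_val])^2))
  })
  best <- which.min(scores)
  fit <- e1071::svm(x[idx_train, , drop = FALSE], y[idx_train],
                    type = "eps-regression", kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    epsilon = epsilon, scale = scale_cols)
  structure(
    list(feature_spec = spec,
         kernel = "radial",
         hyperparameters = list(cost = grid$cost[best],
                                gamma = grid$gamma[best],
                                epsilon = epsilon),
         fit = fit,
         training_metadata = list(
           n = n, n_train = length(idx_train), n_validation = length(idx_val),
           seed = seed, date = format(Sys.Date()),
           holdout_rmsd = scores[best],
           grid = cbind(grid, rmsd = scores)),
         spec_version = FEATURE_SPEC_VERSION),
    class = "pi_svm")
}

#' Predict isoelectric points with a trained SVR model
#'
#' @param object A `pi_svm` model.
#' @param newdata Data frame with columns `id` (optional), `sequence`, and
#'   optionally `modifications`.
#' @param modifications_aware Ignore the `modifications` column when `FALSE`.
#' @param ... Unused.
#' @return A tibble of prediction records (`id`, `method`, `pka_set`,
#'   `predicted_pi`, `failure_reason`), order-preserving, predictions clipped
#'   to (0, 14).
#' @export
predict.pi_svm <- function(object, newdata, modifications_aware = TRUE, ...) {
  newdata <- as_tibble(newdata)
  if (!"sequence" %in% names(newdata)) {
    abort_validation("`newdata` must have a `sequence` column.")
  }
  if (!"id" %in% names(newdata)) {
    newdata$id <- as.character(seq_len(nrow(newdata)))
  }
  if (!modifications_aware) newdata$modifications <- NULL
  empty <- tibble(id = character(), method = character(),
                  pka_set = character(), predicted_pi = numeric(),
                  failure_reason = character())
  if (nrow(newdata) == 0L) return(empty)
  if (!identical(object$spec_version, FEATURE_SPEC_VERSION)) {
    abort_validation(sprintf(
      "Model feature-spec version %s does not match this package's version %s.",
      format(object$spec_version), format(FEATURE_SPEC_VERSION)))
  }
  mods <- if ("modifications" %in% names(newdata)) newdata$modifications else
    rep(NA_character_, nrow(newdata))
  preds <- purrr::map2(newdata$sequence, mods, function(s, m) {
    tryCatch({
      xi <- matrix(featurize_one(as_modified_sequence(s, m),
                                 object$feature_spec, solver_config()),
                   nrow = 1L,
                   dimnames = list(NULL, feature_names(object$feature_spec)))
      p <- as.numeric(predict(object$fit, xi))
      list(pi = min(max(p, 1e-6), 14 - 1e-6), reason = NA_character_)
    }, ampholyte_error = function(e) {
      list(pi = NA_real_, reason = failure_reason_of(e))
    })
  })
  tibble(id = newdata$id,
         method = "svm",
         pka_set = object$feature_spec$seed_pka_set,
         predicted_pi = purrr::map_dbl(preds, "pi"),
         failure_reason = purrr::map_chr(preds, "reason"))
}

#' @export
print.pi_svm <- function(x, ...) {
  md <- x$training_metadata
  cat("<pi_svm> RBF eps-regression, trained on", md$n_train, "sequences\n")
  cat(sprintf("  held-out RMSD %.3f on %d validation sequences (seed %d)\n",
              md$holdout_rmsd, md$n_validation, md$seed))
  cat(sprintf("  cost %g, gamma %g, epsilon %g\n",
              x$hyperparameters$cost, x$hyperparameters$gamma,
              x$hyperparameters$epsilon))
  invisible(x)
}

#' @rdname train_pi_svm
#' @param x A `pi_svm` model.
#' @export
glance.pi_svm <- function(x, ...) {
  md <- x$training_metadata
  tibble(n = md$n, n_train = md$n_train, n_validation = md$n_validation,
         seed = md$seed, holdout_rmsd = md$holdout_rmsd,
         kernel = x$kernel, cost = x$hyperparameters$cost,
         gamma = x$hyperparameters$gamma,
         epsilon = x$hyperparameters$epsilon)
}

#' @rdname train_pi_svm
#' @export
tidy.pi_svm <- function(x, ...) {
  as_tibble(x$training_metadata$grid)
}

#' Serialize / restore a trained SVR model
#'
#' Model files are self-describing: they embed the feature spec, metadata and
#' the feature-spec version, and [read_pi_model()] refuses to load a file
#' whose version does not match the installed package. The round trip
#' preserves predictions exactly.
#'
#' @param model A `pi_svm` model.
#' @param path File path.
#' @return `write_pi_model()` returns `path` invisibly; `read_pi_model()`
#'   returns the model.
#' @export
write_pi_model <- function(model, path) {
  stopifnot(inherits(model, "pi_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pi_model
#' @export
read_pi_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pi_svm")) {
    abort_validation("File does not contain a pi_svm model.")
  }
  if (!identical(model$spec_version, FEATURE_SPEC_VERSION)) {
    abort_validation(sprintf(
      "Model feature-spec version %s does not match this package's version %s; retrain the model.",
      format(model$spec_version), format(FEATURE_SPEC_VERSION)))
  }
  model
}
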