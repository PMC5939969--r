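test_that("featurization follows the fixed, versioned feature order", {
  spec <- feature_spec()
  nm <- colnames(featurize("AAAA", spec))
  expect_equal(length(nm),
               20 + 1 + 1 + length(spec$property_tables) + 2)

  x <- featurize("AAAA", spec)[1, ]
  expect_equal(unname(x[["comp_A"]]), 1)
  expect_equal(sum(x[paste0("comp_", c("A","C","D","E","F","G","H","I","K","L",
                                       "M","N","P","Q","R","S","T","V","W",
                                       "Y"))]), 1)
  expect_equal(unname(x[["length"]]), 4)

  # seed pI of a glycine-only peptide is the diprotic terminal midpoint of
  # whichever set seeds the feature
  seed_set <- get_pka_set(spec$seed_pka_set)
  g <- featurize("GGGG", spec)[1, ]
  expect_equal(unname(g[["seed_pi"]]), (seed_set$n_term + seed_set$c_term) / 2,
               tolerance = 1e-3)

  # mean-property aggregation of a length-2 sequence
  hyd <- get_property_table("hydropathy")
  two <- featurize("AV", spec)[1, ]
  expect_equal(unname(two[["prop_hydropathy"]]),
               mean(hyd[c("A", "V")]))

  # degenerate codes renormalize over the standard residues
  xz <- featurize("AXAZ", spec)[1, ]
  expect_equal(unname(xz[["comp_A"]]), 1)

  # modification counts
  md <- featurize(tibble::tibble(sequence = "ASTK",
                                 modifications = "phospho@2;acetyl@nterm"),
                  spec)[1, ]
  expect_equal(unname(md[["n_phospho"]]), 1)
  expect_equal(unname(md[["acetylated"]]), 1)

  expect_error(featurize("XXXX", spec), class = "ampholyte_error_validation")
})

test_that("training contracts: minimum size, finite targets, determinism", {
  small <- simulate_peptides(n = 10, seed = 1)
  expect_error(train_pi_svm(small, seed = 1),
               class = "ampholyte_error_validation")

  data <- simulate_peptides(n = 120, noise_sd = 0.1, seed = 5)
  bad <- data
  bad$experimental_pi[3] <- NA_real_
  expect_error(train_pi_svm(bad, seed = 1),
               class = "ampholyte_error_validation")

  m1 <- train_pi_svm(data, seed = 7)
  m2 <- train_pi_svm(data, seed = 7)
  test <- simulate_peptides(n = 30, noise_sd = 0.1, seed = 6)
  expect_identical(predict(m1, test)$predicted_pi,
                   predict(m2, test)$predicted_pi)
})

test_that("predictions are order-preserving, clipped, and empty-safe", {
  data <- simulate_peptides(n = 150, noise_sd = 0.1, seed = 9)
  model <- train_pi_svm(data, seed = 2)
  preds <- predict(model, data[1:20, ])
  expect_equal(preds$id, data$id[1:20])
  expect_true(all(preds$predicted_pi > 0 & preds$predicted_pi < 14))
  expect_equal(nrow(predict(model, data[0, ])), 0L)
})

test_that("held-out RMSD shrinks toward the noise floor as n grows", {
  big <- simulate_peptides(n = 800, noise_sd = 0.2, seed = 21)
  small <- simulate_peptides(n = 200, noise_sd = 0.2, seed = 22)
  m_big <- train_pi_svm(big, seed = 3)
  m_small <- train_pi_svm(small, seed = 3)
  expect_lte(m_big$training_metadata$holdout_rmsd,
             m_small$training_metadata$holdout_rmsd + 0.02)
  expect_lte(m_big$training_metadata$holdout_rmsd, 0.35)
})

test_that("a seed-pI-only model tracks the seeding method's predictions", {
  spec <- feature_spec(use_composition = FALSE, use_length = FALSE,
                       use_seed_pi = TRUE, property_tables = character(),
                       use_mod_counts = FALSE)
  data <- simulate_peptides(n = 300, method = "iterative",
                            parameter = "emboss", noise_sd = 0.05, seed = 31)
  model <- train_pi_svm(data, spec = spec, seed = 4)
  test <- simulate_peptides(n = 100, method = "iterative",
                            parameter = "emboss", noise_sd = 0.05, seed = 32)
  svm_pred <- predict(model, test)$predicted_pi
  iter_pred <- predict_pi(test, "iterative", "emboss")$predicted_pi
  expect_gte(cor(svm_pred, iter_pred, method = "spearman"), 0.95)
})

test_that("models retrain to their generating conditions", {
  train_a <- simulate_peptides(n = 400, method = "iterative",
                               parameter = "emboss", noise_sd = 0, seed = 41)
  train_b <- simulate_peptides(n = 400, method = "iterative",
                               parameter = "patrickios", noise_sd = 0,
                               seed = 42)
  test_a <- simulate_peptides(n = 150, method = "iterative",
                              parameter = "emboss", noise_sd = 0, seed = 43)
  test_b <- simulate_peptides(n = 150, method = "iterative",
                              parameter = "patrickios", noise_sd = 0,
                              seed = 44)
  m_a <- train_pi_svm(train_a, seed = 5)
  m_b <- train_pi_svm(train_b, seed = 5)
  rmsd_own_a <- rmsd(test_a$experimental_pi,
                     predict(m_a, test_a)$predicted_pi)
  rmsd_cross_a <- rmsd(test_a$experimental_pi,
                       predict(m_b, test_a)$predicted_pi)
  rmsd_own_b <- rmsd(test_b$experimental_pi,
                     predict(m_b, test_b)$predicted_pi)
  rmsd_cross_b <- rmsd(test_b$experimental_pi,
                       predict(m_a, test_b)$predicted_pi)
  expect_lt(rmsd_own_a, rmsd_cross_a)
  expect_lt(rmsd_own_b, rmsd_cross_b)
})

test_that("serialization round-trips preserve predictions and check versions", {
  data <- simulate_peptides(n = 150, noise_sd = 0.1, seed = 51)
  model <- train_pi_svm(data, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  write_pi_model(model, path)
  back <- read_pi_model(path)
  test <- data[1:25, ]
  expect_identical(predict(back, test)$predicted_pi,
                   predict(model, test)$predicted_pi)

  stale <- model
  stale$spec_version <- 999L
  saveRDS(stale, path)
  expect_error(read_pi_model(path), class = "ampholyte_error_validation")

  expect_s3_class(glance(model), "tbl_df")
  expect_true("holdout_rmsd" %in% names(glance(model)))
  expect_true(all(c("cost", "gamma", "rmsd") %in% names(tidy(model))))
})
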