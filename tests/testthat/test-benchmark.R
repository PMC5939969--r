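test_that("pearson_r2 matches hand computation and enforces its contract", {
  e <- c(4, 6, 8)
  p <- c(4, 6, 7)
  # hand computation: r = cov(e,p)/ (sd(e) sd(p)) with e=(4,6,8), p=(4,6,7)
  # cov = mean((e-6)*(p-17/3)) over n-1 = ( (-2)(-5/3) + 0 + (2)(4/3) ) / 2 = 3
  # var(e) = 4, var(p) = 7/3 => r^2 = 9 / (4 * 7/3) = 27/28
  expect_equal(pearson_r2(e, p), 27 / 28, tolerance = 1e-12)
  expect_equal(pearson_r2(e, e), 1, tolerance = 1e-12)
  expect_equal(pearson_r2(e, e + 1), 1, tolerance = 1e-12)  # shift-invariant
  expect_error(pearson_r2(c(5, 5, 5), p),
               class = "ampholyte_error_validation")
  expect_error(pearson_r2(c(4, 6), c(4, 6)),
               class = "ampholyte_error_validation")
})

test_that("rmsd matches hand computation and validates lengths", {
  expect_equal(rmsd(c(4, 5, 6), c(4, 5, 6)), 0)
  expect_equal(rmsd(c(4, 5, 6), c(5, 6, 7)), 1.0, tolerance = 1e-12)
  expect_equal(rmsd(c(4, 6), c(4, 8)), sqrt(2), tolerance = 1e-12)
  expect_error(rmsd(c(4, 5), c(4, 5, 6)),
               class = "ampholyte_error_validation")
})

test_that("outlier flags follow the SD-of-predictions rule", {
  # predicted (4,6,8): sample SD = 2; residuals (1,1,3) flag only the third
  expect_equal(flag_outliers(c(5, 7, 11), c(4, 6, 8)),
               c(FALSE, FALSE, TRUE))
  expect_equal(flag_outliers(c(4, 6, 8), c(4, 6, 8)), rep(FALSE, 3))
  # constant predictions equal to experimental: SD = 0 tie rule, no flags
  expect_equal(flag_outliers(c(5, 5), c(5, 5)), c(FALSE, FALSE))
  # constant predictions with any deviation flag strictly positive residuals
  expect_equal(flag_outliers(c(5, 6), c(5, 5)), c(FALSE, TRUE))
  expect_error(flag_outliers(5, 5), class = "ampholyte_error_validation")
})

test_that("the default grid covers the full method x parameter leaderboard", {
  grid <- default_method_grid()
  expect_equal(nrow(grid), 16L)
  labels <- paste(grid$method, grid$parameter)
  for (want in c("svm default", "iterative grimsley", "bjellqvist default",
                 "iterative rodwell", "bjellqvist calibrated",
                 "bjellqvist expasy", "iterative thurlkill", "cofactor emboss",
                 "iterative sillero", "iterative toseland", "iterative emboss",
                 "branca emboss", "bjellqvist skoog", "iterative solomon",
                 "iterative lehninger", "iterative patrickios")) {
    expect_true(want %in% labels, info = want)
  }
})

test_that("run_grid isolates failures, is deterministic, and cross-checks its metrics", {
  data <- simulate_peptides(n = 60, noise_sd = 0.1, seed = 61)
  grid <- tibble::tibble(method = c("bjellqvist", "iterative", "branca"),
                         parameter = c("expasy", "emboss", "emboss"))
  r1 <- run_grid(data, grid)
  r2 <- run_grid(data, grid)
  expect_identical(glance(r1), glance(r2))
  expect_true(all(r1$n + r1$n_failed == nrow(data)))

  # header metrics reproduce from the residual tables to 1e-12
  for (i in seq_len(nrow(r1))) {
    res <- r1$residuals[[i]]
    expect_equal(r1$rmsd[i], sqrt(mean(res$residual^2)), tolerance = 1e-12)
    expect_equal(r1$r2[i], cor(res$experimental, res$predicted)^2,
                 tolerance = 1e-12)
    expect_equal(r1$n_outliers[i],
                 sum(abs(res$residual) >= sd(res$predicted)))
  }

  # a dataset of non-tryptic C-termini: branca fails every record, counted
  glyc <- data
  glyc$sequence <- paste0(substr(glyc$sequence, 1,
                                 nchar(glyc$sequence) - 1), "G")
  rg <- run_grid(glyc, tibble::tibble(method = "branca", parameter = "emboss"))
  expect_equal(rg$n, 0L)
  expect_equal(rg$n_failed, nrow(glyc))

  # null experimental values are dropped with a message, not crashed on
  noisy <- data
  noisy$experimental_pi[1:3] <- NA_real_
  expect_message(r3 <- run_grid(noisy, grid[1, ]), "3")
  expect_equal(r3$n + r3$n_failed, nrow(data) - 3L)

  # an svm row without a model reports not-applicable failures
  rs <- run_grid(data, tibble::tibble(method = "svm", parameter = "default"))
  expect_equal(rs$n_failed, nrow(data))

  expect_error(run_grid(data[0, ], grid),
               class = "ampholyte_error_validation")
})

test_that("reports sort by rmsd ascending then r2 descending", {
  data <- simulate_peptides(n = 80, noise_sd = 0, seed = 62)
  r <- run_grid(data, tibble::tibble(
    method = c("iterative", "bjellqvist", "iterative"),
    parameter = c("patrickios", "expasy", "emboss")))
  expect_equal(r$parameter[1], "expasy")  # generating method: rmsd 0
  expect_true(!is.unsorted(r$rmsd))
})

test_that("per-fraction summaries partition the data and order by pI midpoint", {
  data <- simulate_peptides(n = 200, noise_sd = 0.15, seed = 63)
  preds <- predict_pi(data, "bjellqvist", "expasy")
  s <- per_fraction_summary(data, preds)
  expect_equal(sum(s$n), nrow(data))
  expect_true(!is.unsorted(s$midpoint))
  expect_true(all(s$sd_predicted[s$n == 1] == 0))
  expect_true(all(s$single_record == (s$n == 1)))
  expect_error(per_fraction_summary(dplyr::select(data, -"fraction"), preds),
               class = "ampholyte_error_validation")
})

test_that("tidy, glance and autoplot expose the report contents", {
  data <- simulate_peptides(n = 40, noise_sd = 0.1, seed = 64)
  r <- run_grid(data, tibble::tibble(method = "iterative",
                                     parameter = "emboss"))
  td <- tidy(r)
  expect_true(all(c("method", "parameter", "id", "experimental", "predicted",
                    "residual", "outlier") %in% names(td)))
  expect_equal(nrow(td), r$n[1])
  expect_false("residuals" %in% names(glance(r)))
  expect_s3_class(autoplot(r), "ggplot")
})
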