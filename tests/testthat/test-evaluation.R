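test_that("MAE and sMAPE reproduce hand-computed pair values", {
  perfect <- count_records(c("a", "b"), n = c(4, 9), n_hat = c(4, 9))
  expect_equal(count_mae(perfect), 0)
  expect_equal(count_smape(perfect), 0)

  two <- count_records(c("a", "b"), n = c(16, 72), n_hat = c(17, 63))
  expect_equal(count_mae(two), 5)
  expect_equal(count_smape(two), 100 * (1 / 33 + 9 / 135) / 2,
               tolerance = 1e-12)

  one <- count_records("c", n = 77, n_hat = 29)
  expect_equal(count_mae(one), 48)
  expect_equal(count_smape(one), 100 * 48 / 106, tolerance = 1e-12)

  # empty dish predicted empty: the 0/0 term contributes 0
  zz <- count_records("z", n = 0, n_hat = 0)
  expect_equal(count_smape(zz), 0)

  expect_error(count_mae(count_records(character(), numeric(),
                                       numeric())), "non-empty")
})

test_that("sMAPE is bounded in [0, 100] for non-negative counts", {
  set.seed(6)
  for (i in 1:20) {
    r <- count_records(paste0("i", 1:30), n = rpois(30, 20),
                       n_hat = pmax(0, rnorm(30, 20, 15)))
    s <- count_smape(r)
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
})

test_that("k-sigma coverage counts zero-sigma records only when exact", {
  r <- count_records(letters[1:4], n = c(10, 10, 10, 10),
                     n_hat = c(10.5, 12, 10, 11), sigma = c(1, 1, 0, 0))
  # covered: |0.5|<=1 yes; |2|<=1 no; sigma=0 exact yes; sigma=0 off no
  expect_equal(within_sigma_fraction(r, 1), 0.5)
  all_in <- count_records(letters[1:3], n = c(5, 6, 7),
                          n_hat = c(5.1, 6.2, 6.9), sigma = c(1, 1, 1))
  expect_equal(within_sigma_fraction(all_in, 1), 1)
  none <- count_records(letters[1:2], n = c(5, 6), n_hat = c(9, 1),
                        sigma = c(1, 1))
  expect_equal(within_sigma_fraction(none, 1), 0)
})

test_that("feature binning averages per bin and flags empty bins", {
  r <- count_records(letters[1:4], n = c(5, 5, 8, 8), n_hat = c(5, 5, 8, 8),
                     sigma = c(1, 1, 3, 3),
                     mean_colony_size = c(2, 3, 11, 12))
  tab <- bin_by_feature(r, "mean_colony_size", c(0, 5, 10, 15))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$mean_sigma[1], 1)
  expect_equal(tab$mean_sigma[3], 3)
  expect_true(tab$empty[2])
  expect_false(any(tab$empty[c(1, 3)]))
  expect_equal(tab$mean_sigma_per_colony[1], 1 / 5)

  same <- count_records(letters[1:3], n = 1:3, n_hat = 1:3, sigma = 2,
                        coverage = c(0.1, 0.5, 0.9))
  tab2 <- bin_by_feature(same, "coverage", c(0, 0.5, 1))
  expect_true(all(tab2$mean_sigma[!tab2$empty] == 2))

  all_one <- bin_by_feature(same, "coverage", c(0, 1))
  expect_equal(all_one$mean_sigma, mean(same$sigma))

  expect_error(bin_by_feature(same, "coverage", c(0, 0.5, 0.5)),
               "strictly increasing")
})

test_that("beta-coverage fits recover planted lines per size group", {
  set.seed(3)
  cov <- runif(40, 0.05, 0.6)
  sizes <- rep(c(3, 12), each = 20)
  r <- count_records(paste0("i", 1:40), n = 10, n_hat = 10,
                     beta = 1 + 2 * cov, coverage = cov,
                     mean_colony_size = sizes)
  fit <- beta_coverage_fit(r, c(0, 8, 16))
  expect_true(all(fit$fit_ok))
  expect_equal(fit$slope, c(2, 2), tolerance = 1e-10)
  expect_equal(fit$intercept, c(1, 1), tolerance = 1e-10)

  # constant beta gives slope 0
  rc <- r; rc$beta <- 1.1
  fitc <- beta_coverage_fit(rc, c(0, 8, 16))
  expect_equal(fitc$slope, c(0, 0), tolerance = 1e-10)

  # degenerate groups are flagged, not errors
  r1 <- count_records("solo", n = 1, n_hat = 1, beta = 1, coverage = 0.2,
                      mean_colony_size = 4)
  f1 <- beta_coverage_fit(r1, c(0, 8))
  expect_false(f1$fit_ok)
  r0 <- count_records(c("a", "b"), n = 1, n_hat = 1, beta = c(1, 1.2),
                      coverage = c(0.3, 0.3), mean_colony_size = c(4, 5))
  expect_false(beta_coverage_fit(r0, c(0, 8))$fit_ok)

  # noisy recovery within 3 standard errors
  set.seed(8)
  covn <- runif(60, 0, 1)
  rn <- count_records(paste0("n", 1:60), n = 1, n_hat = 1,
                      beta = 0.9 + 0.3 * covn + rnorm(60, 0, 0.02),
                      coverage = covn, mean_colony_size = 5)
  lmfit <- stats::lm(beta ~ coverage, data = rn)
  se <- summary(lmfit)$coefficients["coverage", "Std. Error"]
  got <- beta_coverage_fit(rn, c(0, 10))
  expect_lt(abs(got$slope - 0.3), 3 * se)
})

test_that("overall MAE equals the record-weighted mean of strata MAEs", {
  set.seed(10)
  r <- count_records(paste0("i", 1:50), n = sample(0:90, 50, TRUE),
                     n_hat = pmax(0, rnorm(50, 40, 20)), sigma = 1)
  rep50 <- metrics_report(r, strata_threshold = 50)
  tab <- rep50$stratified
  le <- tab[tab$stratum == "<=50 colonies", ]
  gt <- tab[tab$stratum == ">50 colonies", ]
  weighted <- (le$mae * le$n_images + gt$mae * gt$n_images) /
    (le$n_images + gt$n_images)
  expect_equal(rep50$mae, weighted, tolerance = 1e-12)

  low_only <- count_records(paste0("i", 1:5), n = 1:5, n_hat = 1:5)
  repl <- metrics_report(low_only, strata_threshold = 50)
  expect_true(repl$stratified$empty[repl$stratified$stratum == ">50 colonies"])
})

test_that("evaluation runs every method reproducibly with CSV self-consistency", {
  scenes <- tiny_scene_set(5, size = 32L, seed = 41L)
  m <- build_model(model_config(mode = "sndm", input_size = 32L, n_stages = 2L,
                                base_channels = 2L, dropout_rate = 0.2,
                                seed = 2L))
  csv <- withr::local_tempfile(fileext = ".csv")
  ev1 <- evaluate_model(m, scenes, "single", csv = csv)
  ev2 <- evaluate_model(m, scenes, "single")
  expect_identical(ev1$records$n_hat, ev2$records$n_hat)
  expect_equal(nrow(ev1$records), 5L)
  expect_true(all(ev1$records$sigma == 0))

  # metrics recomputed from the emitted CSV agree with the report
  back <- utils::read.csv(csv)
  expect_equal(mean(abs(back$n - back$n_hat)), ev1$report$mae,
               tolerance = 1e-9)
  num <- abs(back$n - back$n_hat); den <- abs(back$n + back$n_hat)
  expect_equal(100 * mean(ifelse(den == 0, 0, num / den)), ev1$report$smape,
               tolerance = 1e-9)

  evd1 <- evaluate_model(m, scenes, "mc_dropout",
                         dropout_cfg = dropout_config(r = 4L, seed = 5L))
  evd2 <- evaluate_model(m, scenes, "mc_dropout",
                         dropout_cfg = dropout_config(r = 4L, seed = 5L))
  expect_identical(evd1$records, evd2$records)
  expect_true(all(evd1$records$sigma >= 0))

  g <- glance(evd1)
  expect_equal(g$method, "mc_dropout")
  expect_identical(tidy(evd1), evd1$records)
})

test_that("a perfect oracle predictor yields zero MAE and sMAPE", {
  scenes <- tiny_scene_set(6, size = 32L, seed = 51L)
  truths <- vapply(scenes, function(s) annotation_count(s$annotation),
                   integer(1))
  r <- count_records(paste0("s", seq_along(truths)), n = truths,
                     n_hat = truths)
  rep0 <- metrics_report(r)
  expect_equal(rep0$mae, 0)
  expect_equal(rep0$smape, 0)
  expect_equal(rep0$within_1sigma, 1) # sigma 0 but predictions exact
})
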