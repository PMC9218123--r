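test_that("bootstrap subsets have size round(fraction * N), with replacement", {
  subs <- bootstrap_subsets(1:1000, bootstrap_config(seed = 5L))
  expect_length(subs, 20L)
  expect_true(all(lengths(subs) == 630L))

  one <- bootstrap_subsets("only", bootstrap_config(B = 3L, subset_fraction = 1))
  expect_true(all(vapply(one, identical, logical(1), y = "only")))

  expect_error(bootstrap_subsets(1:3, bootstrap_config(subset_fraction = 0.1)),
               "zero")

  # sampling with replacement produces duplicates at close to the exact rate:
  # P(all 6 of 10 distinct) = 10*9*8*7*6*5 / 10^6 ~ 0.1512
  subs2 <- bootstrap_subsets(1:10, bootstrap_config(B = 1000L,
                                                    subset_fraction = 0.6,
                                                    seed = 3L))
  has_dup <- vapply(subs2, anyDuplicated, integer(1)) > 0
  expect_true(any(has_dup))
  p_distinct <- prod(10:5) / 10^6
  expect_equal(mean(!has_dup), p_distinct, tolerance = 0.25) # ~3 sigma of MC
})

test_that("ensemble aggregation follows the population mean/variance formulas", {
  pred <- ensemble_predict(c(10, 12, 14))
  expect_equal(pred$mean_count, 12)
  expect_equal(pred$sigma_count, sqrt(8 / 3), tolerance = 1e-12)

  # brute-force oracle on random member lists
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(1:12, 1), 20, 5)
    p <- ensemble_predict(x)
    mu <- sum(x) / length(x)
    v <- sum((mu - x)^2) / length(x) # divisor B, not B-1
    expect_equal(p$mean_count, mu, tolerance = 1e-12)
    expect_equal(p$sigma_count^2, v, tolerance = 1e-12)
    expect_equal(p$sigma_count^2 * length(x), sum((mu - x)^2),
                 tolerance = 1e-9)
  }

  expect_equal(ensemble_predict(c(7, 7, 7))$sigma_count, 0)
  expect_equal(ensemble_predict(5)$sigma_count, 0)
  expect_equal(ensemble_predict(5)$mean_count, 5)
  expect_error(ensemble_predict(numeric(0)), "empty")
  expect_error(ensemble_predict(list()), "empty")

  # permuting members changes nothing
  x <- rnorm(8, 30, 4)
  p1 <- ensemble_predict(x)
  p2 <- ensemble_predict(rev(x))
  expect_equal(p1$mean_count, p2$mean_count)
  expect_equal(p1$sigma_count, p2$sigma_count)
})

test_that("map aggregation is consistent with scalar counts (pixel-sum linearity)", {
  set.seed(4)
  members <- lapply(1:5, function(i) fake_member(matrix(runif(64), 8, 8)))
  p <- ensemble_predict(members)
  expect_equal(mean(p$member_counts), count_from_map(p$mean_map),
               tolerance = 1e-12)
  expect_true(all(p$sigma_map >= 0))
  same <- ensemble_predict(rep(list(members[[1]]), 4))
  expect_true(all(same$sigma_map == 0))
  expect_equal(same$sigma_count, 0)
})

test_that("averaging B noisy replicates shrinks the squared error by ~1/B", {
  set.seed(123)
  B <- 20L
  v <- 4
  truth <- 50
  trials <- 2000L
  sq_err <- vapply(seq_len(trials), function(i) {
    members <- truth + rnorm(B, 0, sqrt(v))
    (ensemble_predict(members)$mean_count - truth)^2
  }, numeric(1))
  mse <- mean(sq_err)
  se <- stats::sd(sq_err) / sqrt(trials)
  expect_lt(abs(mse - v / B), 3 * se)
})

test_that("MC dropout prediction is seeded, degenerate without dropout", {
  m0 <- build_model(model_config(mode = "dm", input_size = 16L, n_stages = 2L,
                                 base_channels = 2L, dropout_rate = 0,
                                 seed = 3L))
  img <- array(0.6, dim = c(16, 16, 3))
  expect_warning(p0 <- mc_dropout_predict(m0, img, dropout_config(r = 3L)),
                 class = "sndm_no_dropout_warning")
  expect_equal(p0$sigma_count, 0)

  m <- build_model(model_config(mode = "dm", input_size = 16L, n_stages = 2L,
                                base_channels = 2L, dropout_rate = 0.3,
                                seed = 3L))
  p1 <- mc_dropout_predict(m, img, dropout_config(r = 5L, seed = 2L))
  p2 <- mc_dropout_predict(m, img, dropout_config(r = 5L, seed = 2L))
  expect_identical(p1$member_counts, p2$member_counts)
  expect_gt(p1$sigma_count, 0)
  expect_equal(p1$method, "mc_dropout")

  pr1 <- mc_dropout_predict(m, img, dropout_config(r = 1L, seed = 4L))
  expect_equal(pr1$sigma_count, 0)
  expect_equal(pr1$mean_count, pr1$member_counts[1])
})

test_that("bootstrap ensembles train reproducibly with independent members", {
  scenes <- tiny_scene_set(8, size = 32L, seed = 21L)
  recs <- prepare_training_set(scenes)
  m_cfg <- model_config(mode = "sndm", input_size = 32L, n_stages = 2L,
                        base_channels = 2L, dropout_rate = 0.1, seed = 1L)
  t_cfg <- train_config(learning_rate = 1e-3, max_epochs = 2L, patience = 5L)
  b_cfg <- bootstrap_config(B = 2L, seed = 17L)

  e1 <- bootstrap_train(recs, recs, m_cfg, t_cfg, b_cfg)
  expect_length(e1$members, 2L)
  w1 <- model_weights(e1$members[[1]]$model)
  w2 <- model_weights(e1$members[[2]]$model)
  expect_false(identical(w1, w2)) # fresh initialization per member

  e2 <- bootstrap_train(recs, recs, m_cfg, t_cfg, b_cfg)
  expect_identical(w1, model_weights(e2$members[[1]]$model))
  expect_identical(w2, model_weights(e2$members[[2]]$model))

  img <- scenes[[1]]$image
  p <- predict_bootstrap(e1, img)
  expect_equal(p$method, "bootstrap")
  expect_equal(p$mean_count, mean(p$member_counts))

  single <- bootstrap_train(recs, NULL, m_cfg, t_cfg,
                            bootstrap_config(B = 1L, seed = 3L))
  ps <- predict_bootstrap(single, img)
  expect_equal(ps$sigma_count, 0)
})
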