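test_that("model construction is deterministic and structurally correct", {
  cfg <- model_config(mode = "sndm", input_size = 32L, n_stages = 3L,
                      base_channels = 2L, seed = 42L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(model_weights(m1), model_weights(m2))

  d <- describe_model(m1)
  expect_equal(d$n_blocks, 5L)        # 3 encoder + 2 decoder
  expect_equal(d$n_side_outputs, 3L)  # 2 decoders + bottleneck

  # the full-scale stage layout: 11 blocks, 6 side outputs plus the fused map
  full <- model_config(mode = "sndm", input_size = 1024L, n_stages = 6L,
                       base_channels = 4L,
                       rsu_depths = c(5L, 4L, 3L, 2L, 2L, 1L,
                                      2L, 2L, 3L, 4L, 5L),
                       seed = 1L)
  df <- describe_model(build_model(full))
  expect_equal(df$n_blocks, 11L)
  expect_equal(df$n_side_outputs, 6L)

  expect_error(build_model(model_config(input_size = 30L, n_stages = 3L)),
               "divisible")
})

test_that("dm mode reports beta exactly 1 and zeroed weights give flat 0.5 maps", {
  cfg <- model_config(mode = "dm", input_size = 32L, n_stages = 2L,
                      base_channels = 2L, dropout_rate = 0, seed = 1L)
  m <- build_model(cfg)
  img <- array(0.5, dim = c(32, 32, 3))
  out <- predict_density(m, img)
  expect_identical(out$beta, 1)

  zero_model_weights(m)
  out0 <- predict_density(m, img, return_maps = TRUE)
  expect_true(all(out0$P0 == 0.5))
  expect_equal(out0$predicted_count, 32 * 32 / 2)
  for (P in out0$P) expect_true(all(P == 0.5))

  expect_error(predict_density(m, array(0, dim = c(16, 16, 3))), "32 x 32")
})

test_that("forward maps all share the output shape and lie strictly in (0,1)", {
  cfg <- model_config(mode = "sndm", input_size = 48L, n_stages = 3L,
                      base_channels = 2L, dropout_rate = 0, seed = 3L)
  m <- build_model(cfg)
  set.seed(8)
  img <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  out <- predict_density(m, img, return_maps = TRUE)
  expect_length(out$P, 4L) # fused + 3 side maps
  for (P in out$P) {
    expect_equal(dim(P), c(48L, 48L))
    expect_true(all(P > 0 & P < 1))
  }
  expect_true(is.finite(out$predicted_count) && out$predicted_count >= 0)
  expect_gt(out$beta, 0)
  expect_lt(out$beta, cfg$lambda)
})

test_that("beta = 1 surgery makes sndm output bit-identical to dm with shared trunk", {
  seed <- 99L
  dm <- build_model(model_config(mode = "dm", input_size = 32L, n_stages = 2L,
                                 base_channels = 2L, dropout_rate = 0.2,
                                 seed = seed))
  sn <- build_model(model_config(mode = "sndm", input_size = 32L, n_stages = 2L,
                                 base_channels = 2L, dropout_rate = 0.2,
                                 seed = seed))
  # trunk weights are drawn before the beta head, so they coincide exactly
  w_dm <- model_weights(dm)
  w_sn <- model_weights(sn)
  expect_identical(w_dm, w_sn[seq_along(w_dm)])

  set.seed(12)
  for (i in 1:3) {
    img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    out_dm <- predict_density(dm, img)
    out_sn <- predict_density(sn, img, beta_override = 1)
    expect_identical(out_sn$P0, out_dm$P0)
    expect_identical(out_sn$beta, 1)
  }
})

test_that("sigmoid rescaling is monotone in beta and matches its linearization", {
  S <- matrix(seq(-2, 2, length.out = 25), 5, 5)
  expect_equal(apply_normalization(S, 1), 1 / (1 + exp(-S)))
  expect_true(all(apply_normalization(matrix(0, 3, 3), 2.7) == 0.5))
  expect_error(apply_normalization(S, 0), "positive")
  expect_error(apply_normalization(S, -2), "positive")

  # small-argument linearization sigma(x) ~ 1/2 + x/4
  for (bs in seq(-0.02, 0.02, by = 0.004)) {
    expect_lt(abs(apply_normalization(matrix(bs / 1.2, 1, 1), 1.2) -
                    (0.5 + bs / 4)), 1e-4)
  }

  # counts from a fixed positive logit map increase strictly with beta
  Spos <- matrix(runif(64, 0.1, 2), 8, 8)
  counts <- vapply(c(0.5, 0.8, 1, 1.2, 1.5),
                   function(b) sum(apply_normalization(Spos, b)), numeric(1))
  expect_true(all(diff(counts) > 0))
  # while the zero map is invariant
  expect_equal(sum(apply_normalization(matrix(0, 8, 8), 0.5)),
               sum(apply_normalization(matrix(0, 8, 8), 1.5)))
})

test_that("beta head activation is the lambda-scaled sigmoid with its bound", {
  expect_equal(beta_activation_value(0), 0.75)          # 1.5 * sigmoid(0)
  expect_equal(beta_activation_value(20), 1.5, tolerance = 1e-8)
  expect_equal(beta_activation_value(-3, type = "relu"), 0)
  expect_equal(beta_activation_value(0.7, lambda = 2), 2 / (1 + exp(-0.7)))

  m <- build_model(model_config(mode = "sndm", input_size = 16L, n_stages = 2L,
                                base_channels = 2L, dropout_rate = 0, seed = 1L))
  img <- array(0.3, dim = c(16, 16, 3))
  fix_beta_preactivation(m, 0)
  expect_equal(predict_density(m, img)$beta, 0.75)
  fix_beta_preactivation(m, 20)
  expect_equal(predict_density(m, img)$beta, 1.5, tolerance = 1e-8)

  dm <- build_model(model_config(mode = "dm", input_size = 16L, n_stages = 2L,
                                 base_channels = 2L, seed = 1L))
  expect_error(fix_beta_preactivation(dm, 0), "no beta head")
})

test_that("freshly built sndm models start with beta at 1 (no correction prior)", {
  m <- build_model(model_config(mode = "sndm", input_size = 16L, n_stages = 2L,
                                base_channels = 2L, dropout_rate = 0, seed = 2L))
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_equal(predict_density(m, img)$beta, 1, tolerance = 1e-12)
})

test_that("checkpoints round-trip weights and config through a single file", {
  cfg <- model_config(mode = "sndm", input_size = 16L, n_stages = 2L,
                      base_channels = 2L, seed = 31L)
  m <- build_model(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(model_weights(m2), model_weights(m))
  expect_equal(m2$config$mode, "sndm")
  img <- array(0.2, dim = c(16, 16, 3))
  expect_identical(predict_density(m, img)$P0, predict_density(m2, img)$P0)
})
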