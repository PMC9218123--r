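test_that("box midpoints map to target-grid centers with rescaling", {
  ann <- manual_annotation(data.frame(x_min = 10, y_min = 10,
                                      x_max = 20, y_max = 20))
  ctr <- centers_from_bboxes(ann, c(64, 64))
  expect_equal(unname(ctr[1, ]), c(15, 15))

  expect_equal(nrow(centers_from_bboxes(manual_annotation(NULL), c(64, 64))), 0L)

  half <- manual_annotation(data.frame(x_min = 24, y_min = 24,
                                       x_max = 29, y_max = 32), size = 64L)
  # box center (x = 26.5, y = 28) at half resolution -> (row 14, col 13.25)
  ctr2 <- centers_from_bboxes(half, c(32, 32))
  expect_equal(unname(ctr2[1, ]), c(14, 13.25))

  bad <- manual_annotation(data.frame(x_min = 10, y_min = 10,
                                      x_max = 20, y_max = 20))
  bad$boxes$x_max <- 70 # beyond a 64 px image
  expect_error(centers_from_bboxes(bad, c(64, 64)), "invalid annotation")
})

test_that("rendered targets conserve unit mass per colony, even at edges", {
  k <- kernel_spec(sigma_blur = 2)
  z <- render_density_target(NULL, c(32, 32), k)
  expect_equal(sum(z$map), 0)
  expect_equal(z$count, 0)

  mid <- render_density_target(rbind(c(16, 16)), c(32, 32), k)
  expect_equal(sum(mid$map), 1, tolerance = 1e-6)

  edge <- render_density_target(rbind(c(1, 16)), c(32, 32), k)
  expect_equal(sum(edge$map), 1, tolerance = 1e-6)

  # oracle: dense truncated-kernel evaluation before/after renormalization
  brute <- function(center, shape, sigma, trunc_r) {
    m <- matrix(0, shape[1], shape[2])
    for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
      d2 <- (r - center[1])^2 + (c - center[2])^2
      if (d2 <= trunc_r^2) m[r + 1, c + 1] <- exp(-d2 / (2 * sigma^2))
    }
    m
  }
  raw <- brute(c(1, 16), c(32, 32), 2, 8)
  full_mass <- sum(brute(c(16, 16), c(32, 32), 2, 8))
  expect_lt(sum(raw), full_mass) # edge clipping removes mass before renorm
  expect_equal(edge$map, raw / sum(raw), tolerance = 1e-12)

  expect_error(render_density_target(rbind(c(40, 16)), c(32, 32), k),
               "outside")
})

test_that("conservation holds across random annotations including near-edge", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(0:25, 1)
    shape <- c(48, 48)
    centers <- if (n > 0) {
      cbind(runif(n, 0, 47), runif(n, 0, 47))
    } else NULL
    tg <- render_density_target(centers, shape, kernel_spec(sigma_blur = runif(1, 0.5, 3)))
    expect_lt(abs(count_from_map(tg) - n), 1e-5 * max(1, n))
  }
})

test_that("rendering is additive (superposition) and shift-equivariant", {
  k <- kernel_spec(sigma_blur = 1.5)
  A <- rbind(c(10, 12), c(20, 30))
  B <- rbind(c(30, 8), c(15, 40))
  both <- render_density_target(rbind(A, B), c(48, 48), k)
  sep <- render_density_target(A, c(48, 48), k)$map +
    render_density_target(B, c(48, 48), k)$map
  expect_equal(both$map, sep, tolerance = 1e-14)

  # integer shift away from edges translates the kernel bit-exactly
  m1 <- render_density_target(rbind(c(20, 20)), c(48, 48), k)$map
  m2 <- render_density_target(rbind(c(23, 25)), c(48, 48), k)$map
  expect_identical(m1[(20 - 7):(20 + 9), (20 - 7):(20 + 9)],
                   m2[(23 - 7):(23 + 9), (25 - 7):(25 + 9)])
})

test_that("counts are read off maps by summation with validation", {
  expect_equal(count_from_map(matrix(0, 8, 8)), 0)
  expect_equal(count_from_map(matrix(1 / 64, 8, 8)), 1)
  tg <- render_density_target(matrix(runif(32, 5, 40), 16, 2), c(48, 48),
                              kernel_spec(sigma_blur = 1))
  expect_equal(count_from_map(tg), 16, tolerance = 1e-5)
  expect_error(count_from_map(matrix(c(-0.1, 1), 1, 2)), "non-negative")
})

test_that("loss view clips to [eps, 1-eps] and warns on overlap saturation", {
  k <- kernel_spec(sigma_blur = 1.2)
  tg <- render_density_target(rbind(c(16, 16)), c(32, 32), k)
  eps <- 1e-6
  v <- expect_silent(loss_view(tg, eps))
  expect_true(all(v >= eps & v <= 1 - eps))
  # only sub-eps background pixels were touched
  changed <- which(v != tg$map)
  expect_true(all(tg$map[changed] < eps))

  # two coincident tight kernels saturate a pixel above 1; the oracle is
  # direct summation of the discretized truncated kernel
  tight <- kernel_spec(sigma_blur = 0.4)
  twin <- render_density_target(rbind(c(16, 16), c(16, 16)), c(32, 32), tight)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  d2 <- offs$dr^2 + offs$dc^2
  kern <- ifelse(d2 <= 1.6^2, exp(-d2 / (2 * 0.4^2)), 0)
  peak_oracle <- 2 * max(kern) / sum(kern)
  expect_gt(peak_oracle, 1.5)
  expect_equal(max(twin$map), peak_oracle, tolerance = 1e-12)
  expect_warning(v2 <- loss_view(twin, eps), class = "sndm_clip_warning")
  expect_equal(max(v2), 1 - eps)
  expect_equal(count_from_map(twin), 2, tolerance = 1e-6) # unclipped conserved

  expect_error(loss_view(tg, 0.6), "\\(0, 0.5\\)")
})

test_that("adaptive sigma follows the mean box side with a floor", {
  ann <- manual_annotation(data.frame(x_min = 20, y_min = 20,
                                      x_max = 36, y_max = 36)) # side 16
  tg <- density_target_from_annotation(ann, c(64, 64))
  expect_equal(tg$sigma, 4) # 0.25 * 16
  tgt_half <- density_target_from_annotation(ann, c(32, 32))
  expect_equal(tgt_half$sigma, 2) # side rescaled by 0.5
  expect_equal(tgt_half$scale_factor, 2)
  tiny <- manual_annotation(data.frame(x_min = 20, y_min = 20,
                                       x_max = 21, y_max = 21))
  expect_equal(density_target_from_annotation(tiny, c(64, 64))$sigma, 0.4)
})

test_that("density maps round-trip through float TIFF", {
  tg <- render_density_target(rbind(c(10, 12)), c(24, 24),
                              kernel_spec(sigma_blur = 1))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_density_map(tg, path)
  back <- read_density_map(path)
  expect_equal(back, tg$map, tolerance = 1e-6)

  # overlap-saturated targets (pixels above 1) survive via the scale sidecar
  twin <- render_density_target(rbind(c(10, 12), c(10, 12)), c(24, 24),
                                kernel_spec(sigma_blur = 0.4))
  expect_gt(max(twin$map), 1)
  write_density_map(twin, path)
  back2 <- read_density_map(path)
  expect_equal(back2, twin$map, tolerance = 1e-6)
  expect_equal(sum(back2), 2, tolerance = 1e-5)
})
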