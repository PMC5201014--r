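test_that("round selection keeps spheres and rejects elongated or split nuclei", {
  pop <- simulate_population(70, kind = c(rep("sphere", 50), rep("dumbbell", 20)),
                             seed = 42)
  kept <- select_round_nuclei(pop, seed = 3)
  expect_gte(sum(kept$kind == "sphere"), 45)
  expect_gte(mean(kept$kind == "sphere"), 0.85)
  # single clean sphere sampling is retained
  one <- simulate_population(1, seed = 5)
  expect_equal(nrow(select_round_nuclei(one, seed = 1)), 1)
  # a 2:1 laterally elongated nucleus is rejected
  set.seed(6)
  u <- unit_sphere_points(40)
  E <- cbind(2 * u[, 1], 1 * u[, 2], 1 * u[, 3])
  nuc <- make_nuclei(list(E), list(c(0, 0, 0)))
  expect_equal(nrow(select_round_nuclei(nuc, seed = 1)), 0)
})

test_that("normalized radial samples follow their definitions", {
  P <- rbind(c(0.8, 0, 0),   # purely lateral: x = 0
             c(0, 0, 1))     # at the pole of a unit-R sphere
  # force R = 1 by adding symmetric fill points at distance 1
  fill <- rbind(c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0), c(0.8, 0, 0) * 0 + c(1, 0, 0))
  nuc <- make_nuclei(list(rbind(P, fill)), list(c(0, 0, 0)))
  sam <- compute_samples(nuc)
  expect_equal(sam$x[1], 0)
  expect_equal(sam$d_over_R[1], 0.8 / mean(c(0.8, 1, 1, 1, 1, 1)), tolerance = 1e-12)
  expect_equal(sam$x[2], 1 / mean(c(0.8, 1, 1, 1, 1, 1)), tolerance = 1e-12)
  # axial stretch raises d/R near the poles relative to the equator
  set.seed(7)
  S <- unit_sphere_points(4000)
  St <- S; St[, 3] <- 1.3 * St[, 3]
  nucs <- make_nuclei(list(St), list(c(0, 0, 0)))
  sam2 <- compute_samples(nucs)
  expect_gt(mean(sam2$d_over_R[sam2$x > 0.8]), mean(sam2$d_over_R[sam2$x < 0.2]))
})

test_that("polynomial fit matches the normal-equations oracle and is exact on parabolas", {
  set.seed(8)
  x <- runif(50)
  y <- 0.3 * x^2 - 0.1 * x + 0.9 + rnorm(50, 0, 0.05)
  m <- fit_aberration(suppressWarnings(tibble::tibble(x = x, d_over_R = y))) |>
    suppressWarnings()
  oracle <- quad_ols(x, y)
  expect_equal(c(m$a, m$b, m$c), oracle, tolerance = 1e-10)
  # noise-free parabola is interpolated to machine precision
  y0 <- 0.26 * x^2 + 0.0029 * x + 0.81
  m0 <- suppressWarnings(fit_aberration(tibble::tibble(x = x, d_over_R = y0)))
  expect_equal(c(m0$a, m0$b, m0$c), c(0.26, 0.0029, 0.81), tolerance = 1e-10)
  # narrow x range is ill-conditioned by contract
  expect_error(fit_aberration(tibble::tibble(x = runif(200, 0.4, 0.6),
                                             d_over_R = rnorm(200, 1, 0.01))),
               "narrow")
})

test_that("unstretched spherical populations fit a flat polynomial", {
  # Monte-Carlo null with known centers: coefficients are numerically flat
  set.seed(9)
  sets <- lapply(1:20, function(i) unit_sphere_points(1000))
  nuc <- make_nuclei(sets, rep(list(c(0, 0, 0)), 20))
  m0 <- fit_aberration(compute_samples(nuc))
  expect_lt(abs(m0$a), 0.03)
  expect_lt(abs(m0$b), 0.03)
  # realistic population (centers estimated from ~22 detections): center noise
  # induces a spurious positive curvature (large |z| offsets imply inflated d),
  # a known property of the estimator; the intercept stays near 1
  pop <- simulate_population(60, seed = 9)
  m <- fit_aberration(compute_samples(select_round_nuclei(pop, seed = 2)))
  expect_gt(m$a, 0)
  expect_lt(abs(m$c - 1), 0.05)
})

test_that("stretch-fit-correct round trip flattens the distance distributions", {
  set.seed(10)
  n_nuc <- 20; npts <- 2000
  point_sets <- lapply(1:n_nuc, function(i) rlnorm(1, log(0.9), 0.12) * unit_sphere_points(npts))
  nuc <- make_nuclei(point_sets, rep(list(c(0, 0, 0)), n_nuc))
  ab <- nuc
  for (i in 1:n_nuc) {
    ab$detections[[i]] <- apply_axial_stretch(ab$detections[[i]], c(0, 0, 0),
                                              "polynomial", coef = c(0.26, 0.0029))
  }
  sam_pre <- compute_samples(ab)
  model <- fit_aberration(sam_pre)
  corr <- correct_detections(ab, model)
  # measure the correction transform against the known true centers so the
  # residual is not dominated by centroid estimation noise
  corr$center_x <- corr$center_y <- corr$center_z <- 0
  sam_post <- compute_samples(corr)
  pre_dev <- mean(abs(sam_pre$d_over_R - 1))
  post_dev <- mean(abs(sam_post$d_over_R - 1))
  expect_lt(post_dev, pre_dev)
  expect_lt(post_dev, 0.01)
  # per-axis normalized offset distributions agree within 5% after correction
  offs <- do.call(rbind, lapply(1:n_nuc, function(i) {
    Q <- as.matrix(corr$detections[[i]][, c("x", "y", "z")])
    ctr <- c(corr$center_x[i], corr$center_y[i], corr$center_z[i])
    sweep(Q, 2, ctr) / mean(sqrt(rowSums(sweep(Q, 2, ctr)^2)))
  }))
  ax_means <- colMeans(abs(offs))
  expect_lt(max(ax_means) / min(ax_means) - 1, 0.05)
  # lateral coordinates are bit-identical through correction
  expect_identical(corr$detections[[1]]$x, ab$detections[[1]]$x)
  expect_identical(corr$detections[[1]]$y, ab$detections[[1]]$y)
  # idempotence: refit on corrected data is flat
  m2 <- fit_aberration(sam_post)
  expect_lt(abs(m2$a), 0.03)
})

test_that("correction leaves equatorial detections in place and spans populations", {
  # x = 0 detections are unchanged by construction
  P <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0.7, 0.7, 0), c(-0.7, 0.7, 0), c(0.7, -0.7, 0), c(0, 0.9, 0))
  nuc <- make_nuclei(list(P), list(c(0, 0, 0)))
  model <- structure(list(a = 0.26, b = 0.0029, c = 0.81,
                          se = c(a = 0, b = 0, c = 0), rmse = 0, n_points = 1000),
                     class = "aberration_model")
  corr <- correct_detections(nuc, model)
  expect_equal(as.matrix(corr$detections[[1]][, c("x", "y", "z")]), P,
               ignore_attr = TRUE, tolerance = 1e-12)
  # a model fitted on round nuclei corrects a withheld dumbbell without error
  pop <- simulate_population(12, kind = "dumbbell", seed = 11)
  expect_no_error(correct_detections(pop, model))
})

test_that("aberration model JSON round trip preserves coefficients", {
  m <- structure(list(a = 0.26, b = 0.0029, c = 0.81, se = c(a = 1, b = 1, c = 1),
                      rmse = 0.02, n_points = 20000), class = "aberration_model")
  p <- file.path(withr::local_tempdir(), "model.json")
  write_aberration_model(m, p, instrument = "confocal-A")
  m2 <- read_aberration_model(p)
  expect_equal(c(m2$a, m2$b, m2$c, m2$rmse, m2$n_points),
               c(0.26, 0.0029, 0.81, 0.02, 20000))
})
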