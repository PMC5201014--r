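test_that("alignment maps landmarks and poles to their defining coordinates", {
  # one nucleus: center at origin-ish, nucleolus along -x
  det <- rbind(c(1, 0, 0), c(-0.8, 0, 0), c(0, 1, 0))
  nuc <- make_nuclei(list(det), list(c(0, 0, 0)),
                     nucleolus = list(c(-0.8, 0, 0)))
  ali <- align_population(nuc, "nucleolus", "npc")
  lms <- attr(ali, "aligned_landmarks")
  expect_equal(lms$landmark_s, -0.8)
  expect_equal(lms$landmark_r, 0)
  # detection at the far pole: (+d, 0); at the landmark: (-d, 0)
  expect_equal(ali$s[1], 1); expect_equal(ali$r[1], 0, tolerance = 1e-12)
  expect_equal(ali$s[2], -0.8); expect_equal(ali$r[2], 0, tolerance = 1e-12)
  expect_equal(ali$s[3], 0); expect_equal(ali$r[3], 1)
})

test_that("alignment is invariant to rigid motion of each nucleus", {
  set.seed(1)
  P <- unit_sphere_points(25)
  ctr <- c(0, 0, 0); nucp <- c(-0.6, 0, 0)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(4, 1, -2)
  P2 <- sweep(P %*% t(rot), 2, shift, `+`)
  nuc <- make_nuclei(list(P, P2), list(ctr, as.numeric(rot %*% ctr + shift)),
                     nucleolus = list(nucp, as.numeric(rot %*% nucp + shift)))
  ali <- align_population(nuc, "nucleolus", "npc")
  a1 <- ali[ali$nucleus_id == 1, ]; a2 <- ali[ali$nucleus_id == 2, ]
  expect_equal(a1$s, a2$s, tolerance = 1e-9)
  expect_equal(a1$r, a2$r, tolerance = 1e-9)
  # missing landmarks are skipped with a count
  nuc$nucleolus_x[2] <- NA
  ali2 <- align_population(nuc, "nucleolus", "npc")
  expect_equal(attr(ali2, "n_skipped"), 1L)
})

test_that("kde_map integrates to one, reflects at the axis, and peaks correctly", {
  set.seed(2)
  pts <- tibble::tibble(s = rnorm(400, 0, 0.5), r = abs(rnorm(400, 0.8, 0.3)),
                        weight = 1)
  map <- kde_map(pts, bandwidth = c(0.1, 0.1), pitch = 0.05)
  expect_equal(glance(map)$total_mass, 1, tolerance = 1e-3)
  expect_equal(glance(kde_map(pts, bandwidth = c(0.2, 0.2)))$total_mass, 1,
               tolerance = 1e-3)
  # reflection equals the brute-force KDE over the explicitly mirrored set
  h <- map$bandwidth
  for (q in list(c(0.2, 0.3), c(-0.5, 0.05), c(0, 1.2))) {
    i <- which.min(abs(map$s - q[1])); j <- which.min(abs(map$r - q[2]))
    brute <- brute_kde(map$s[i], map$r[j], c(pts$s, pts$s), c(pts$r, -pts$r),
                       h, w = rep(1 / 400, 800))
    expect_equal(map$density[i, j], brute, tolerance = 1e-9)
  }
  # single point mass with tiny bandwidth -> argmax at that cell
  one <- tibble::tibble(s = rep(0.72, 50), r = rep(0.41, 50), weight = 1)
  m1 <- kde_map(one, bandwidth = c(0.03, 0.03))
  am <- which(m1$density == max(m1$density), arr.ind = TRUE)[1, ]
  expect_lt(abs(m1$s[am[1]] - 0.72), 0.051)
  expect_lt(abs(m1$r[am[2]] - 0.41), 0.051)
})

test_that("a spherical-shell population yields a density ridge at radius 1", {
  pop <- simulate_population(60, radius_median = 1, radius_sdlog = 1e-6, seed = 3)
  # use true centers so the ridge is sharp
  pop$center_x <- pop$true_center_x
  pop$center_y <- pop$true_center_y
  pop$center_z <- pop$true_center_z
  ali <- align_population(pop, "nucleolus", "npc")
  map <- kde_map(ali, bandwidth = c(0.08, 0.08))
  df <- tidy(map)
  top <- df[order(-df$density), ][1:50, ]
  rho <- sqrt(top$s^2 + top$r^2)
  expect_lt(abs(median(rho) - 1), 0.1)
})

test_that("axial profiles are flat for isotropy and dip where depleted", {
  set.seed(4)
  P <- unit_sphere_points(10000)
  iso <- tibble::tibble(s = P[, 3], r = sqrt(P[, 1]^2 + P[, 2]^2))
  prof <- axial_density_profile(iso)
  expect_lt(diff(range(prof$density)), 0.35)
  # KS flatness: cos(theta) of an isotropic shell is uniform
  ks <- suppressWarnings(ks.test(iso$s / sqrt(iso$s^2 + iso$r^2), "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # injected depletion band becomes the profile minimum
  dep <- function(theta) ifelse(theta > 100 * pi / 180 & theta < 140 * pi / 180, 0.1, 1)
  pts <- sample_envelope_points(shape_spec("sphere", radius = 1), 8000,
                                density_profile = dep, seed = 5)
  ali <- tibble::tibble(s = pts$z, r = sqrt(pts$x^2 + pts$y^2))
  prof2 <- axial_density_profile(ali)
  min_bin <- prof2$theta_deg[which.min(prof2$density)]
  expect_gte(min_bin, 100); expect_lte(min_bin, 140)
  # degenerate single-pole input occupies one bin
  pole <- tibble::tibble(s = rep(1, 200), r = rep(0, 200))
  prof3 <- axial_density_profile(pole)
  expect_equal(sum(prof3$count > 0), 1)
})

test_that("median overlays compute the population medians", {
  nuclei <- tibble::tibble(nucleus_id = 1:4, volume = c(3, 3, 6, 6),
                           nucleolar_volume = c(1, 1, 1, 1))
  lms <- tibble::tibble(nucleus_id = 1:4, landmark_s = c(-0.5, -0.6, -0.5, -0.6),
                        landmark_r = 0)
  ov <- median_overlays(nuclei, lms)
  expect_equal(ov$median_radius_um,
               median((3 * c(3, 3, 6, 6) / (4 * pi))^(1 / 3)))
  expect_equal(ov$nucleolus_s, -0.55)
  # 3 um^3 median population: radius (9 / 4 pi)^(1/3) ~ 0.894
  nuc3 <- tibble::tibble(nucleus_id = 1:5, volume = rep(3, 5),
                         nucleolar_volume = rep(1, 5))
  ov3 <- median_overlays(nuc3, lms)
  expect_equal(ov3$median_radius_um, (3 * 3 / (4 * pi))^(1 / 3), tolerance = 1e-12)
})

test_that("size-sorted maps split volumes into balanced classes", {
  set.seed(6)
  pop <- simulate_population(180, seed = 7)
  pop$volume <- rep(c(1, 3, 9), each = 60) # three separated volume groups
  ali <- align_population(pop, "nucleolus", "npc")
  maps <- size_sorted_maps(pop, ali)
  cls <- attr(maps, "classes")
  expect_equal(as.integer(table(cls$size_class)), rep(60L, 3))
  expect_true(all(cls$size_class[pop$volume == 1] == "small"))
  expect_true(all(cls$size_class[pop$volume == 9] == "large"))
  # constant volumes: arbitrary but balanced split
  pop$volume <- 3
  maps2 <- size_sorted_maps(pop, ali)
  expect_equal(as.integer(table(attr(maps2, "classes")$size_class)), rep(60L, 3))
  # a small population still produces maps, with a warning
  small <- pop[1:60, ]
  ali_s <- align_population(small, "nucleolus", "npc")
  expect_warning(size_sorted_maps(small, ali_s), "150")
})

test_that("percentile conversion yields highest-density-region levels", {
  set.seed(8)
  pts <- tibble::tibble(s = rnorm(500, 0, 0.3), r = abs(rnorm(500, 0.5, 0.2)))
  map <- as_percentile(kde_map(pts))
  expect_true(all(map$percentile >= 0 & map$percentile <= 100))
  # the densest cell has the smallest percentile
  expect_equal(which.min(map$percentile), which.max(map$density))
})
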