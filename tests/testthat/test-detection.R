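test_that("a rendered spot is localized to well under the voxel size", {
  truth <- c(2.013, 1.507, 1.742)
  amp <- snr_to_amplitude(10, 20)
  st <- render_stack(tibble::tibble(x = truth[1], y = truth[2], z = truth[3],
                                    amplitude = amp),
                     extent = c(4, 4, 3), origin = c(0, 0, 0), seed = 7)
  det <- suppressWarnings(detect_spots(st))
  expect_equal(nrow(det), 1)
  err <- sqrt(sum((c(det$x_um, det$y_um, det$z_um) - truth)^2))
  expect_lt(err, 0.03)
  # detection is deterministic on a fixed stack
  det2 <- suppressWarnings(detect_spots(st))
  expect_identical(det, det2)
})

test_that("flat and empty images yield empty detection tables", {
  z <- voxel_stack(list(npc = array(0, c(12, 12, 6))), c(0.08, 0.08, 0.2))
  expect_equal(nrow(detect_spots(z)), 0)
  flat <- voxel_stack(list(npc = array(7, c(12, 12, 6))), c(0.08, 0.08, 0.2))
  expect_equal(nrow(detect_spots(flat)), 0)
})

test_that("well-separated spots stay separate; close ones merge", {
  amp <- snr_to_amplitude(10, 20)
  st <- render_stack(tibble::tibble(x = c(1.5, 2.5), y = c(1.5, 1.5),
                                    z = c(1, 1), amplitude = amp),
                     extent = c(4, 3, 2), origin = c(0, 0, 0), seed = 3)
  expect_equal(nrow(suppressWarnings(detect_spots(st, min_separation = 0.3))), 2)
  # a merge radius larger than the spacing collapses them to the brighter fit
  expect_equal(nrow(suppressWarnings(detect_spots(st, min_separation = 1.2))), 1)
})

test_that("single-linkage grouping separates nuclei and discards stragglers", {
  set.seed(21)
  s1 <- unit_sphere_points(22)
  s2 <- sweep(unit_sphere_points(22), 2, c(6, 0, 0), `+`)
  det <- tibble::tibble(x_um = c(s1[, 1], s2[, 1]), y_um = c(s1[, 2], s2[, 2]),
                        z_um = c(s1[, 3], s2[, 3]), amplitude = 1)
  nuc <- group_into_nuclei(det)
  expect_equal(nrow(nuc), 2)
  expect_equal(vapply(nuc$detections, nrow, 0L), c(22L, 22L))
  # permutation invariance
  perm <- sample(nrow(det))
  nuc_p <- group_into_nuclei(det[perm, ])
  expect_equal(nuc$center_x, nuc_p$center_x, tolerance = 1e-12)
  expect_equal(nuc$detections[[1]]$x_um, nuc_p$detections[[1]]$x_um)
  # too-small groups are discarded and reported
  few <- det[1:5, ]
  nuc0 <- group_into_nuclei(few)
  expect_equal(nrow(nuc0), 0)
  expect_equal(attr(nuc0, "report")$n_groups_discarded, 1L)
})

test_that("group centroids estimate sphere centers to ~0.1 um", {
  set.seed(22)
  errs <- replicate(30, {
    ctr <- runif(3, -2, 2)
    P <- sweep(unit_sphere_points(25), 2, ctr, `+`)
    det <- tibble::tibble(x_um = P[, 1], y_um = P[, 2], z_um = P[, 3], amplitude = 1)
    nuc <- group_into_nuclei(det)
    sqrt(sum((c(nuc$center_x, nuc$center_y, nuc$center_z) - ctr)^2))
  })
  expect_lt(median(errs), 0.35) # centroid error ~ R / sqrt(n) per axis
})

test_that("nucleolar segmentation recovers a rendered body and skips flat boxes", {
  amp <- snr_to_amplitude(10, 20)
  body <- list(center = c(2, 2, 1.6), radius = 0.7,
               nucleus_center = c(2.4, 2, 1.5), nucleus_radius = 0.9,
               intensity = 100)
  st <- render_stack(tibble::tibble(x = 2.4, y = 2, z = 1.5, amplitude = amp),
                     nucleolus = body, extent = c(4.8, 4, 3),
                     origin = c(0, 0, 0), seed = 4)
  truth <- attr(st, "ground_truth")$true_body_volume
  nuc <- make_nuclei(list(cbind(2.4, 2, 1.5)), list(c(2.4, 2, 1.5)))
  names(nuc$detections[[1]]) <- c("x", "y", "z")
  seg <- segment_nucleolus(st, nuc)
  expect_lt(abs(seg$nucleolar_volume - truth) / truth, 0.15)
  # centroid falls inside the body, on the nucleolar side of the center
  expect_lt(seg$nucleolus_x, 2.4)
  # uniform channel -> absent
  flat <- voxel_stack(list(npc = array(1, c(30, 30, 10)),
                           nucleolus = array(5, c(30, 30, 10))),
                      c(0.16, 0.16, 0.3))
  seg2 <- suppressMessages(segment_nucleolus(flat, nuc))
  expect_true(is.na(seg2$nucleolar_volume))
})

test_that("two-nucleus fields keep each nucleolus with its own nucleus", {
  amp <- snr_to_amplitude(10, 20)
  b1 <- list(center = c(1.6, 2, 1.5), radius = 0.5, intensity = 100)
  st <- render_stack(tibble::tibble(x = c(2, 7), y = c(2, 2), z = c(1.5, 1.5),
                                    amplitude = amp),
                     nucleolus = b1, extent = c(9, 4, 3), origin = c(0, 0, 0),
                     seed = 5)
  # add the second body by summing a second render into the same channel
  b2 <- list(center = c(7.5, 2, 1.5), radius = 0.5, intensity = 100)
  st2 <- render_stack(tibble::tibble(x = 7, y = 2, z = 1.5, amplitude = 0),
                      nucleolus = b2, extent = c(9, 4, 3), origin = c(0, 0, 0),
                      background = 0, noise = "none")
  st$channels$nucleolus <- st$channels$nucleolus + st2$channels$nucleolus
  nuc <- make_nuclei(list(cbind(2, 2, 1.5), cbind(7, 2, 1.5)),
                     list(c(2, 2, 1.5), c(7, 2, 1.5)))
  seg <- segment_nucleolus(st, nuc)
  expect_lt(abs(seg$nucleolus_x[1] - 1.6), 0.4)
  expect_lt(abs(seg$nucleolus_x[2] - 7.5), 0.4)
})

test_that("the SPB is the single bright outlier or nothing", {
  set.seed(30)
  P <- unit_sphere_points(22)
  base <- tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3], amplitude = 100)
  # one 10x outlier -> returned and removed
  d1 <- base; d1$amplitude[7] <- 1000
  nuc <- make_nuclei(list(as.matrix(d1[, 1:3])), list(c(0, 0, 0)))
  nuc$detections[[1]]$amplitude <- d1$amplitude
  out <- detect_spb(nuc)
  expect_equal(c(out$spb_x, out$spb_y, out$spb_z), unlist(P[7, ]),
               ignore_attr = TRUE)
  expect_equal(nrow(out$detections[[1]]), 21)
  # all equal -> absent, detections untouched
  nuc2 <- nuc; nuc2$detections[[1]]$amplitude <- 100
  out2 <- detect_spb(nuc2)
  expect_true(is.na(out2$spb_x))
  expect_equal(nrow(out2$detections[[1]]), 22)
  # two bright spots (duplicated SPB) -> absent
  nuc3 <- nuc; nuc3$detections[[1]]$amplitude[c(3, 9)] <- 500
  out3 <- detect_spb(nuc3)
  expect_true(is.na(out3$spb_x))
  expect_equal(nrow(out3$detections[[1]]), 22)
})

test_that("ellipsoid fits recover generating quadrics", {
  set.seed(31)
  u <- unit_sphere_points(60)
  E <- cbind(1.0 * u[, 1], 1.0 * u[, 2], 1.3 * u[, 3])
  f <- fit_ellipsoid(E)
  expect_equal(sort(f$radii), c(1, 1, 1.3), tolerance = 0.01)
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-6)
  # a sphere is an ellipsoid with equal axes, recovered wherever it sits
  S <- sweep(unit_sphere_points(40), 2, c(2, -1, 0.5), `+`)
  fs <- fit_ellipsoid(S)
  expect_equal(fs$radii, c(1, 1, 1), tolerance = 0.01)
  expect_equal(fs$center, c(2, -1, 0.5), tolerance = 0.01)
  # coplanar input errors
  flat <- cbind(runif(8), runif(8), 0)
  expect_error(fit_ellipsoid(flat))
  expect_error(fit_ellipsoid(cbind(runif(12), runif(12), 0)), "coplanar")
})

test_that("detector meets the 30 nm median accuracy bound on isolated spots", {
  # smaller replicate of the population-level accuracy property
  set.seed(32)
  amp <- snr_to_amplitude(10, 20)
  errs <- vapply(1:40, function(i) {
    p <- c(runif(1, 1.4, 2.6), runif(1, 1.4, 2.6), runif(1, 1.1, 1.9))
    st <- render_stack(tibble::tibble(x = p[1], y = p[2], z = p[3], amplitude = amp),
                       extent = c(4, 4, 3), origin = c(0, 0, 0), seed = 1000 + i)
    det <- suppressWarnings(detect_spots(st))
    sqrt(sum((c(det$x_um[1], det$y_um[1], det$z_um[1]) - p)^2))
  }, 0)
  expect_lte(median(errs), 0.03)
})
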