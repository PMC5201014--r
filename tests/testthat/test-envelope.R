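test_that("initial patches reproduce closed-form polyhedra", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- initial_patch(tet)
  expect_equal(nrow(m$triangles), 4)
  expect_equal(mesh_metrics(m)$volume, 1 / 6, tolerance = 1e-12)
  # regular tetrahedron, edge 1: V = 1 / (6 sqrt(2))
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  expect_equal(mesh_metrics(initial_patch(reg))$volume, 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  mm <- mesh_metrics(initial_patch(cube))
  expect_equal(mm$surface, 6)
  expect_equal(mm$volume, 1)
  # inscribed hull of sphere samples underestimates the ball
  set.seed(1)
  ms <- initial_patch(unit_sphere_points(200))
  expect_lt(mesh_metrics(ms)$volume, 4 * pi / 3)
  # degenerate input
  expect_error(initial_patch(cbind(runif(8), runif(8), 0)), "coplanar")
  expect_error(initial_patch(cbind(1:8, 2 * (1:8), 3 * (1:8))), "collinear")
})

test_that("mesh metrics are translation invariant and demand closed meshes", {
  set.seed(2)
  m <- initial_patch(unit_sphere_points(50))
  m2 <- m; m2$vertices <- sweep(m2$vertices, 2, c(5, -3, 2), `+`)
  expect_equal(mesh_metrics(m), mesh_metrics(m2), tolerance = 1e-9)
  open_mesh <- m; open_mesh$triangles <- m$triangles[-1, , drop = FALSE]
  expect_error(mesh_metrics(open_mesh), "closed")
})

test_that("interpolating subdivision retains vertices and quadruples triangles", {
  set.seed(3)
  m <- initial_patch(unit_sphere_points(30))
  r <- refine_spline(m, 3)
  expect_equal(nrow(r$triangles), 64 * nrow(m$triangles))
  expect_equal(r$vertices[seq_len(nrow(m$vertices)), ], m$vertices,
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_silent(nucmorph:::assert_closed(r$triangles))
  # the spline envelope systematically underestimates a sphere
  expect_lt(mesh_metrics(r)$volume, 4 * pi / 3)
  # icosahedron vertices survive unmoved
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
               c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
               c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  mi <- initial_patch(ico)
  ri <- refine_spline(mi, 3)
  expect_equal(ri$vertices[1:12, ], ico, ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("anchor refinement reconstructs spheres and behaves per point count", {
  # anchors of an exactly centred sphere stay on the sphere
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
               c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
               c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)) /
    sqrt(1 + phi^2)
  r1 <- refine_anchor(initial_patch(ico), c(0, 0, 0), 1)
  anchors <- r1$vertices[13:nrow(r1$vertices), ]
  expect_equal(sqrt(rowSums(anchors^2)), rep(1, 20), tolerance = 1e-12)
  # 50 exact sphere samples -> volume within 2% of the ball
  set.seed(4)
  P <- unit_sphere_points(50)
  ra <- refine_anchor(initial_patch(P), c(0, 0, 0), 3)
  expect_lt(abs(mesh_metrics(ra)$volume - 4 * pi / 3) / (4 * pi / 3), 0.02)
  # center outside errors
  expect_error(refine_anchor(initial_patch(P), c(5, 0, 0), 1), "inside")
})

test_that("anchor model accuracy improves with detection count", {
  set.seed(5)
  # median volume error decreases from n = 12 to n = 100
  verr <- function(n) {
    P <- unit_sphere_points(n)
    abs(mesh_metrics(refine_anchor(initial_patch(P), colMeans(P), 3))$volume -
          4 * pi / 3) / (4 * pi / 3)
  }
  errs <- sapply(c(12, 30, 100), function(n) median(replicate(25, verr(n))))
  expect_true(all(diff(errs) < 0))
  # the anchor model is far more accurate than the spline model at low n
  set.seed(6)
  P <- unit_sphere_points(15)
  v_anchor <- mesh_metrics(refine_anchor(initial_patch(P), colMeans(P), 3))$volume
  v_spline <- mesh_metrics(refine_spline(initial_patch(P), 3))$volume
  truth <- 4 * pi / 3
  expect_lt(abs(v_anchor - truth), abs(v_spline - truth))
})

test_that("sphericity follows its closed form and the isoperimetric bound", {
  expect_equal(sphericity(4 * pi, 4 * pi / 3), 1, tolerance = 1e-12)
  expect_equal(sphericity(6, 1), pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
  # 2:1:1 prolate spheroid, closed-form surface oracle
  a <- 1; c <- 2
  e <- sqrt(1 - a^2 / c^2)
  S <- 2 * pi * a^2 * (1 + c / (a * e) * asin(e))
  V <- 4 / 3 * pi * a^2 * c
  expect_equal(sphericity(S, V), 0.93, tolerance = 0.005)
  # every reconstructed mesh satisfies psi <= 1
  set.seed(6)
  for (n in c(12, 25, 60)) {
    P <- unit_sphere_points(n)
    g <- glance(refine_anchor(initial_patch(P), colMeans(P), 2))
    expect_lte(g$sphericity, 1 + 1e-9)
  }
})

test_that("cluster-mesh merging is exact for one mesh and additive when disjoint", {
  set.seed(7)
  m <- refine_anchor(initial_patch(unit_sphere_points(60)), c(0, 0, 0), 2)
  one <- merge_cluster_meshes(list(m))
  mm <- mesh_metrics(m)
  expect_identical(one$surface, mm$surface)
  expect_identical(one$volume, mm$volume)
  # disjoint unit spheres 4 um apart: volumes add, nothing subtracted
  P1 <- unit_sphere_points(150)
  m1 <- refine_anchor(initial_patch(P1), c(0, 0, 0), 2)
  P2 <- sweep(unit_sphere_points(150), 2, c(4, 0, 0), `+`)
  m2 <- refine_anchor(initial_patch(P2), c(4, 0, 0), 2)
  g <- merge_cluster_meshes(list(m1, m2), voxel_pitch = 0.04)
  expect_equal(g$intersection_volume, 0)
  expect_lt(abs(g$volume - 2 * 4 * pi / 3) / (2 * 4 * pi / 3), 0.02)
})

test_that("overlapping spheres merge to the analytic union volume", {
  set.seed(8)
  d <- 1
  m1 <- refine_anchor(initial_patch(unit_sphere_points(200)), c(0, 0, 0), 2)
  m2 <- refine_anchor(initial_patch(sweep(unit_sphere_points(200), 2, c(d, 0, 0), `+`)),
                      c(d, 0, 0), 2)
  g <- merge_cluster_meshes(list(m1, m2), voxel_pitch = 0.03)
  lens <- pi * (2 - d)^2 * (d^2 + 4 * d) / (12 * d)
  union_true <- 2 * 4 * pi / 3 - lens
  expect_lt(abs(g$volume - union_true) / union_true, 0.03)
  expect_gt(g$intersection_volume, 0)
  # buried surface was removed: total is less than the sum of both spheres
  expect_lt(g$surface, 2 * 4 * pi)
})

test_that("PLY export writes a valid ASCII mesh", {
  m <- initial_patch(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  p <- file.path(withr::local_tempdir(), "tet.ply")
  write_ply(m, p)
  lines <- readLines(p)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("^3 ", lines)), 4)
  expect_equal(length(lines), 9 + 4 + 4)
})
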