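#' Parametric nuclear-envelope shape
#'
#' Describes the geometry a synthetic nucleus is sampled from. Four families
#' cover the shapes a budding-yeast nucleus adopts through the cell cycle:
#' `sphere` (interphase), `ellipsoid` (early spindle elongation), `dumbbell`
#' (two overlapping/adjacent lobes, mitosis or alpha-factor arrest) and
#' `hourglass` (late anaphase: two lobes connected by a thin tube through the
#' bud neck). The shape's symmetry axis is +z before `orientation` is applied.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"dumbbell"`, `"hourglass"`.
#' @param radius sphere radius (um).
#' @param semi_axes length-3 ellipsoid semi-axes (um).
#' @param lobe_radii length-2 lobe radii (um) for dumbbell/hourglass.
#' @param separation distance between lobe centers (um).
#' @param tube_radius hourglass connecting-tube radius (um).
#' @param center length-3 center position (um).
#' @param orientation 3x3 rotation matrix applied to the canonical shape.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("sphere", "ellipsoid", "dumbbell", "hourglass"),
                       radius = 0.9, semi_axes = c(0.9, 0.9, 1.17),
                       lobe_radii = c(0.8, 0.8), separation = 1.8,
                       tube_radius = 0.25, center = c(0, 0, 0),
                       orientation = diag(3)) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3, all(is.finite(center)),
            is.matrix(orientation), all(dim(orientation) == c(3, 3)))
  spec <- list(kind = kind, center = as.numeric(center), orientation = orientation)
  spec$params <- switch(kind,
    sphere = {
      stopifnot(radius > 0)
      list(radius = radius)
    },
    ellipsoid = {
      stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
      list(semi_axes = as.numeric(semi_axes))
    },
    dumbbell = {
      stopifnot(length(lobe_radii) == 2, all(lobe_radii > 0), separation > 0)
      list(lobe_radii = as.numeric(lobe_radii), separation = separation)
    },
    hourglass = {
      # late anaphase spans the bud neck, so the default tube is long
      if (missing(separation)) separation <- 4.2
      if (missing(lobe_radii)) lobe_radii <- c(0.75, 0.75)
      stopifnot(length(lobe_radii) == 2, all(lobe_radii > 0), separation > 0,
                tube_radius > 0, tube_radius < min(lobe_radii),
                separation > lobe_radii[1] + lobe_radii[2])
      list(lobe_radii = as.numeric(lobe_radii), separation = separation,
           tube_radius = tube_radius)
    })
  structure(spec, class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat("<shape_spec>", x$kind, "\n")
  cat("  params:", paste(names(x$params),
                         vapply(x$params, function(p) paste(signif(p, 4), collapse = "x"), ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# exact (or near-exact) surface area / volume of a shape_spec
#' True surface and volume of a parametric shape
#'
#' Closed-form (spheres, spheroids, two-sphere unions) or high-accuracy
#' approximate (triaxial ellipsoids via the Thomsen formula, hourglass)
#' surface area and volume, used as ground truth by the test oracles.
#'
#' @param shape a [shape_spec()].
#' @return a list with `surface` (um^2), `volume` (um^3) and `exact` (logical).
#' @export
shape_true_geometry <- function(shape) {
  stopifnot(inherits(shape, "shape_spec"))
  p <- shape$params
  switch(shape$kind,
    sphere = list(surface = 4 * pi * p$radius^2,
                  volume = 4 / 3 * pi * p$radius^3, exact = TRUE),
    ellipsoid = {
      ax <- sort(p$semi_axes)
      v <- 4 / 3 * pi * prod(ax)
      if (abs(ax[1] - ax[2]) < 1e-12 && abs(ax[2] - ax[3]) < 1e-12) {
        list(surface = 4 * pi * ax[1]^2, volume = v, exact = TRUE)
      } else if (abs(ax[1] - ax[2]) < 1e-12) { # prolate: a = b < c
        a <- ax[1]; c <- ax[3]
        e <- sqrt(1 - a^2 / c^2)
        s <- 2 * pi * a^2 * (1 + c / (a * e) * asin(e))
        list(surface = s, volume = v, exact = TRUE)
      } else if (abs(ax[2] - ax[3]) < 1e-12) { # oblate: a < b = c
        c <- ax[1]; a <- ax[2]
        e <- sqrt(1 - c^2 / a^2)
        s <- 2 * pi * a^2 + pi * c^2 / e * log((1 + e) / (1 - e))
        list(surface = s, volume = v, exact = TRUE)
      } else {
        pw <- 1.6075 # Thomsen approximation, max error ~1.06%
        a <- ax[3]; b <- ax[2]; c <- ax[1]
        s <- 4 * pi * (((a * b)^pw + (a * c)^pw + (b * c)^pw) / 3)^(1 / pw)
        list(surface = s, volume = v, exact = FALSE)
      }
    },
    dumbbell = {
      r1 <- p$lobe_radii[1]; r2 <- p$lobe_radii[2]; d <- p$separation
      if (d >= r1 + r2) {
        list(surface = 4 * pi * (r1^2 + r2^2),
             volume = 4 / 3 * pi * (r1^3 + r2^3), exact = TRUE)
      } else {
        lens <- pi * (r1 + r2 - d)^2 *
          (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
        h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
        h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
        list(surface = 4 * pi * (r1^2 + r2^2) - 2 * pi * (r1 * h1 + r2 * h2),
             volume = 4 / 3 * pi * (r1^3 + r2^3) - lens, exact = TRUE)
      }
    },
    hourglass = {
      r1 <- p$lobe_radii[1]; r2 <- p$lobe_radii[2]
      d <- p$separation; rt <- p$tube_radius
      # tube attaches where the cylinder pierces each sphere
      z1 <- d / 2 - sqrt(r1^2 - rt^2)  # attachment plane near lobe 1 (+z lobe)
      z2 <- -d / 2 + sqrt(r2^2 - rt^2)
      len <- z1 - z2
      cap <- function(r) 2 * pi * r * (r - sqrt(r^2 - rt^2))
      capv <- function(r) { h <- r - sqrt(r^2 - rt^2); pi * h^2 * (3 * r - h) / 3 }
      list(surface = 4 * pi * (r1^2 + r2^2) - cap(r1) - cap(r2) + 2 * pi * rt * len,
           volume = 4 / 3 * pi * (r1^3 + r2^3) - capv(r1) - capv(r2) +
             pi * rt^2 * len,
           exact = FALSE)
    })
}

canonical_shape_points <- function(shape, n, density_profile) {
  p <- shape$params
  sample_sphere_dirs <- function(m) {
    g <- matrix(rnorm(3 * m), ncol = 3)
    g / sqrt(rowSums(g^2))
  }
  region_levels <- switch(shape$kind,
    sphere = "surface", ellipsoid = "surface",
    dumbbell = c("lobe1", "lobe2"),
    hourglass = c("lobe1", "lobe2", "tube"))
  # one candidate batch of m labelled points: columns x, y, z, region code
  draw_batch <- function(m) {
    switch(shape$kind,
      sphere = cbind(p$radius * sample_sphere_dirs(m), 1),
      ellipsoid = {
        u <- sample_sphere_dirs(m)
        a <- p$semi_axes[1]; b <- p$semi_axes[2]; c <- p$semi_axes[3]
        w <- sqrt((b * c * u[, 1])^2 + (a * c * u[, 2])^2 + (a * b * u[, 3])^2)
        keep <- runif(m) < w / max(b * c, a * c, a * b)
        cbind(a * u[keep, 1], b * u[keep, 2], c * u[keep, 3],
              rep(1, sum(keep)))
      },
      dumbbell = {
        r1 <- p$lobe_radii[1]; r2 <- p$lobe_radii[2]; d <- p$separation
        n1 <- stats::rbinom(1, m, r1^2 / (r1^2 + r2^2))
        c1 <- c(0, 0, d / 2); c2 <- c(0, 0, -d / 2)
        p1 <- sweep(r1 * sample_sphere_dirs(n1), 2, c1, `+`)
        p2 <- sweep(r2 * sample_sphere_dirs(m - n1), 2, c2, `+`)
        keep1 <- sqrt(rowSums(sweep(p1, 2, c2)^2)) > r2
        keep2 <- sqrt(rowSums(sweep(p2, 2, c1)^2)) > r1
        rbind(cbind(p1[keep1, , drop = FALSE], 1),
              cbind(p2[keep2, , drop = FALSE], 2))
      },
      hourglass = {
        r1 <- p$lobe_radii[1]; r2 <- p$lobe_radii[2]
        d <- p$separation; rt <- p$tube_radius
        z1 <- d / 2 - sqrt(r1^2 - rt^2); z2 <- -d / 2 + sqrt(r2^2 - rt^2)
        a1 <- 4 * pi * r1^2; a2 <- 4 * pi * r2^2
        at <- 2 * pi * rt * max(0, z1 - z2)
        comp <- sample.int(3, m, replace = TRUE, prob = c(a1, a2, at))
        pts <- matrix(NA_real_, m, 4)
        for (k in 1:3) {
          idx <- which(comp == k); if (!length(idx)) next
          if (k <= 2) {
            r <- c(r1, r2)[k]; cz <- c(d / 2, -d / 2)[k]
            q <- r * sample_sphere_dirs(length(idx))
            q[, 3] <- q[, 3] + cz
            # drop the cap that the tube attachment replaces
            inner <- if (k == 1) q[, 3] < z1 else q[, 3] > z2
            q[inner & (q[, 1]^2 + q[, 2]^2 < rt^2), ] <- NA
            pts[idx, ] <- cbind(q, k)
          } else {
            zz <- runif(length(idx), z2, z1)
            ang <- runif(length(idx), 0, 2 * pi)
            pts[idx, ] <- cbind(rt * cos(ang), rt * sin(ang), zz, 3)
          }
        }
        pts[stats::complete.cases(pts), , drop = FALSE]
      })
  }
  out <- matrix(numeric(0), ncol = 4)
  guard <- 0
  while (nrow(out) < n) {
    guard <- guard + 1
    if (guard > 2000) stop("rejection sampling failed to reach the requested n")
    batch <- draw_batch(max(64, 2 * (n - nrow(out))))
    if (!is.null(density_profile) && nrow(batch) > 0) {
      rr <- sqrt(rowSums(batch[, 1:3, drop = FALSE]^2))
      theta <- acos(pmin(1, pmax(-1, batch[, 3] / pmax(rr, 1e-12))))
      w <- density_profile(theta)
      batch <- batch[runif(length(w)) < w / max(1e-12, max(w)), , drop = FALSE]
    }
    # shuffle so truncation to n cannot bias multi-component shapes
    if (nrow(batch) > 1) batch <- batch[sample.int(nrow(batch)), , drop = FALSE]
    out <- rbind(out, batch)
  }
  out <- out[seq_len(n), , drop = FALSE]
  list(xyz = out[, 1:3, drop = FALSE],
       region = region_levels[out[, 4]])
}

#' Sample points uniformly on a parametric envelope surface
#'
#' Area-uniform sampling on the surface of a [shape_spec()], optionally
#' modulated by an angular density profile (e.g. to emulate the NPC depletion
#' observed at the nucleolar-nucleoplasmic interface). Every draw is
#' reproducible under a fixed `seed`; ground truth (shape, closed-form surface
#' and volume, per-point region labels) travels with the result.
#'
#' @param shape a [shape_spec()].
#' @param n number of points to sample (>= 4).
#' @param density_profile optional function of the polar angle theta (radians,
#'   0 = +axis pole, pi = -axis/nucleolar pole) returning relative weights;
#'   points are rejection-sampled against it.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a tibble with columns `x`, `y`, `z` (um) and `region`, carrying a
#'   `ground_truth` attribute.
#' @export
#' @examples
#' pts <- sample_envelope_points(shape_spec("sphere", radius = 1), 500, seed = 1)
#' mean(sqrt(pts$x^2 + pts$y^2 + pts$z^2)) # ~1
sample_envelope_points <- function(shape, n, density_profile = NULL, seed = NULL) {
  stopifnot(inherits(shape, "shape_spec"), n >= 4)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  cs <- canonical_shape_points(shape, n, density_profile)
  xyz <- cs$xyz %*% t(shape$orientation)
  xyz <- sweep(xyz, 2, shape$center, `+`)
  out <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        region = cs$region)
  geom <- shape_true_geometry(shape)
  attr(out, "ground_truth") <- list(
    shape = shape, seed = seed, n = n,
    true_surface = geom$surface, true_volume = geom$volume,
    surface_exact = geom$exact)
  out
}

#' Inject axial (z) aberration into point positions
#'
#' Emulates the apparent elongation along the optical axis caused by
#' refractive-index mismatch. `linear` mode multiplies axial offsets from the
#' center by a constant factor; `polynomial` mode displaces each point along z
#' so that its center distance d grows to d + (a*x^2 + b*x)*R, with
#' x = |z - z_center| / R — the exact inverse of the correction applied by
#' [correct_detections()].
#'
#' @param points tibble/data frame with `x`, `y`, `z` columns (um).
#' @param center length-3 nuclear center (um).
#' @param mode `"linear"` or `"polynomial"`.
#' @param factor axial magnification for linear mode.
#' @param coef length-2 `c(a, b)` polynomial coefficients for polynomial mode.
#' @param R normalizing radius; default mean center-to-point distance.
#' @return the input with displaced `z`, other columns untouched.
#' @export
apply_axial_stretch <- function(points, center, mode = c("linear", "polynomial"),
                                factor = 1.3, coef = c(0.26, 0.0029), R = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(center) == 3, all(c("x", "y", "z") %in% names(points)))
  dz <- points$z - center[3]
  if (mode == "linear") {
    points$z <- center[3] + factor * dz
    return(points)
  }
  dx <- points$x - center[1]; dy <- points$y - center[2]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (is.null(R)) R <- mean(d)
  x <- abs(dz) / R
  d_new <- d + (coef[1] * x^2 + coef[2] * x) * R
  lat2 <- dx^2 + dy^2
  dz_new <- sign(dz) * sqrt(pmax(d_new^2 - lat2, 0))
  points$z <- center[3] + dz_new
  points
}

# von Mises-Fisher sample about +z with concentration kappa (Wood 1994 inverse-cdf)
rvmf_z <- function(n, kappa) {
  if (kappa <= 0) {
    w <- runif(n, -1, 1)
  } else {
    u <- runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  ang <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  cbind(s * cos(ang), s * sin(ang), w)
}

#' Simulate a population of ground-truthed nuclei
#'
#' Draws per-nucleus radii from a log-normal, NPC counts from a Poisson around
#' a stated median (default 22, the typical number of diffraction-limited
#' peripheral spots per yeast nucleus), places a nucleolar centroid at a fixed
#' fractional offset on one side and a single bright SPB spot von
#' Mises-Fisher-concentrated about the opposite (anti-nucleolar) pole, and
#' samples NPC positions on the chosen envelope shape. Each nucleus gets an
#' independent random orientation.
#'
#' @param n_nuclei number of nuclei.
#' @param kind envelope shape per nucleus: a single kind or a vector recycled
#'   to length `n_nuclei` (see [shape_spec()]).
#' @param radius_median,radius_sdlog log-normal radius distribution (um);
#'   defaults give a median nuclear volume of ~3 um^3.
#' @param npc_median median NPC (cNPC spot) count per nucleus.
#' @param spb list: `present`, `kappa` (vMF concentration about the
#'   anti-nucleolar pole), `brightness` (amplitude multiple of the NPC
#'   amplitude median).
#' @param nucleolus list: `present`, `offset_frac` (centroid offset from the
#'   nuclear center as a fraction of R, along -axis), `volume_median`,
#'   `volume_sdlog` (um^3).
#' @param amplitude_meanlog,amplitude_sdlog log-normal NPC spot amplitudes (a.u.).
#' @param density_profile optional angular NPC density profile (see
#'   [sample_envelope_points()]).
#' @param seed integer master seed.
#' @return a nested nuclei tibble (one row per nucleus) with list-column
#'   `detections` (tibbles of `x`, `y`, `z`, `amplitude`, `role`, `region`),
#'   observable summaries (`center_*` = detection centroid) and ground-truth
#'   columns (`true_center_*`, `true_radius`, `true_surface`, `true_volume`,
#'   `spb_*`, `nucleolus_*`, `nucleolar_volume`, `kind`).
#' @export
simulate_population <- function(n_nuclei,
                                kind = "sphere",
                                radius_median = 0.894, radius_sdlog = 0.12,
                                npc_median = 22,
                                spb = list(present = TRUE, kappa = 5, brightness = 8),
                                nucleolus = list(present = TRUE, offset_frac = 0.55,
                                                 volume_median = 1.0, volume_sdlog = 0.25),
                                amplitude_meanlog = log(100), amplitude_sdlog = 0.3,
                                density_profile = NULL,
                                seed = NULL) {
  stopifnot(n_nuclei >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  kind <- rep_len(kind, n_nuclei)
  spb <- utils::modifyList(list(present = TRUE, kappa = 5, brightness = 8), spb)
  nucleolus <- utils::modifyList(
    list(present = TRUE, offset_frac = 0.55, volume_median = 1.0, volume_sdlog = 0.25),
    nucleolus)

  # lay cells out on a spaced 3D grid (one field of view), jittered
  side <- ceiling(n_nuclei^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_nuclei), , drop = FALSE]
  spacing <- 6 # um between neighboring nuclear centers

  rows <- vector("list", n_nuclei)
  for (i in seq_len(n_nuclei)) {
    R <- rlnorm(1, log(radius_median), radius_sdlog)
    n_npc <- max(12L, rpois(1, npc_median))
    rot <- random_rotation()
    ctr <- spacing * grid[i, ] + runif(3, -0.5, 0.5)
    shape <- switch(kind[i],
      sphere = shape_spec("sphere", radius = R, center = ctr, orientation = rot),
      ellipsoid = shape_spec("ellipsoid", semi_axes = R * c(1, 1, 1.3),
                             center = ctr, orientation = rot),
      dumbbell = shape_spec("dumbbell", lobe_radii = c(R, 0.85 * R),
                            separation = 2.2 * R, center = ctr, orientation = rot),
      hourglass = shape_spec("hourglass", lobe_radii = c(0.85 * R, 0.75 * R),
                             separation = 4.6 * R, tube_radius = 0.28 * R,
                             center = ctr, orientation = rot),
      stop("unknown shape kind: ", kind[i]))
    pts <- sample_envelope_points(shape, n_npc, density_profile = density_profile)
    det <- tibble::tibble(
      x = pts$x, y = pts$y, z = pts$z,
      amplitude = rlnorm(n_npc, amplitude_meanlog, amplitude_sdlog),
      role = "npc", region = pts$region)

    axis <- rot %*% c(0, 0, 1) # anti-nucleolar pole direction
    nuc_pos <- c(NA_real_, NA_real_, NA_real_); nuc_vol <- NA_real_
    if (isTRUE(nucleolus$present)) {
      nuc_pos <- ctr - nucleolus$offset_frac * R * as.numeric(axis)
      nuc_vol <- rlnorm(1, log(nucleolus$volume_median), nucleolus$volume_sdlog)
    }
    spb_pos <- c(NA_real_, NA_real_, NA_real_)
    if (isTRUE(spb$present)) {
      dir_c <- rvmf_z(1, spb$kappa)[1, ]
      dir_w <- as.numeric(rot %*% dir_c)
      spb_pos <- ctr + R * dir_w
      det <- dplyr::bind_rows(det, tibble::tibble(
        x = spb_pos[1], y = spb_pos[2], z = spb_pos[3],
        amplitude = spb$brightness * median(det$amplitude),
        role = "spb", region = "spb"))
    }
    geom <- shape_true_geometry(shape)
    rows[[i]] <- tibble::tibble(
      nucleus_id = i, cell_id = sprintf("cell%04d", i), timepoint = 0L,
      kind = kind[i],
      detections = list(det),
      center_x = mean(det$x[det$role == "npc"]),
      center_y = mean(det$y[det$role == "npc"]),
      center_z = mean(det$z[det$role == "npc"]),
      true_center_x = ctr[1], true_center_y = ctr[2], true_center_z = ctr[3],
      true_radius = R, true_surface = geom$surface, true_volume = geom$volume,
      axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
      spb_x = spb_pos[1], spb_y = spb_pos[2], spb_z = spb_pos[3],
      nucleolus_x = nuc_pos[1], nucleolus_y = nuc_pos[2], nucleolus_z = nuc_pos[3],
      nucleolar_volume = nuc_vol)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ground_truth") <- list(seed = seed, npc_median = npc_median,
                                    radius_median = radius_median,
                                    spb = spb, nucleolus = nucleolus)
  out
}

#' Convert a target peak signal-to-noise ratio to a spot amplitude
#'
#' Under Poisson statistics the peak SNR of a spot of amplitude A over a
#' background b is A / sqrt(A + b); this solves for A.
#'
#' @param snr target peak signal-to-noise ratio.
#' @param background mean background level (counts).
#' @return amplitude in counts.
#' @export
snr_to_amplitude <- function(snr, background) {
  (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
}

#' Render a synthetic multi-channel voxel stack
#'
#' Splat Gaussian point-spread blobs for each point-like emitter into an `npc`
#' channel, optionally add a solid nucleolar body (the intersection of a
#' nucleolar sphere with the nuclear sphere, the classic crescent) in a
#' `nucleolus` channel, then add Poisson noise.
#'
#' @param points tibble with `x`, `y`, `z` (um) and `amplitude` (counts).
#' @param nucleolus optional list describing the body: `center` (um triple),
#'   `radius` (um), `intensity` (counts), plus optionally `nucleus_center`,
#'   `nucleus_radius` to clip it to the nuclear interior.
#' @param psf length-2 `c(sigma_xy, sigma_z)` Gaussian PSF sigmas (um).
#' @param voxel_size length-3 `c(dx, dy, dz)` (um).
#' @param extent length-3 physical stack size (um); default covers the points
#'   with a 1 um margin.
#' @param origin physical position of the stack corner (um); default 0.
#' @param background mean background level (counts).
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed for the noise.
#' @return a [voxel_stack()] with a `ground_truth` attribute.
#' @export
render_stack <- function(points, nucleolus = NULL,
                         psf = c(0.10, 0.25), voxel_size = c(0.08, 0.08, 0.20),
                         extent = NULL, origin = c(0, 0, 0), background = 20,
                         noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(psf > 0), all(voxel_size > 0))
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(extent)) {
    lo <- c(min(points$x), min(points$y), min(points$z)) - 1
    hi <- c(max(points$x), max(points$y), max(points$z)) + 1
    origin <- lo
    extent <- hi - lo
  }
  dims <- pmax(4L, as.integer(ceiling(extent / voxel_size)))
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]

  img <- array(background, dims)
  for (i in seq_len(nrow(points))) {
    p <- c(points$x[i], points$y[i], points$z[i])
    a <- points$amplitude[i]
    ix <- which(abs(cx - p[1]) <= 4 * psf[1])
    iy <- which(abs(cy - p[2]) <= 4 * psf[1])
    iz <- which(abs(cz - p[3]) <= 4 * psf[2])
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(cx[ix] - p[1])^2 / (2 * psf[1]^2))
    gy <- exp(-(cy[iy] - p[2])^2 / (2 * psf[1]^2))
    gz <- exp(-(cz[iz] - p[3])^2 / (2 * psf[2]^2))
    img[ix, iy, iz] <- img[ix, iy, iz] + a * (gx %o% gy %o% gz)
  }
  channels <- list(npc = img)

  if (!is.null(nucleolus)) {
    body <- array(background, dims)
    d2 <- outer(outer((cx - nucleolus$center[1])^2, (cy - nucleolus$center[2])^2, `+`),
                (cz - nucleolus$center[3])^2, `+`)
    mask <- d2 <= nucleolus$radius^2
    if (!is.null(nucleolus$nucleus_center)) {
      dn2 <- outer(outer((cx - nucleolus$nucleus_center[1])^2,
                         (cy - nucleolus$nucleus_center[2])^2, `+`),
                   (cz - nucleolus$nucleus_center[3])^2, `+`)
      mask <- mask & dn2 <= nucleolus$nucleus_radius^2
    }
    body[mask] <- body[mask] + (nucleolus$intensity %||% 100)
    channels$nucleolus <- body
    true_body_volume <- sum(mask) * prod(voxel_size)
  } else {
    true_body_volume <- NA_real_
  }

  if (noise == "poisson") {
    for (ch in names(channels)) {
      channels[[ch]][] <- rpois(length(channels[[ch]]), pmax(channels[[ch]], 0))
    }
  }
  st <- voxel_stack(channels, voxel_size, origin = origin)
  attr(st, "ground_truth") <- list(
    points = points, nucleolus = nucleolus, psf = psf,
    background = background, seed = seed,
    true_body_volume = true_body_volume)
  st
}
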