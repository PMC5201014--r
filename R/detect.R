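#' Detect point-like spots in one channel of a voxel stack
#'
#' Finds local intensity maxima above a robust threshold (median + k * MAD),
#' then refines each candidate to sub-voxel precision by least-squares fitting
#' an anisotropic 3D Gaussian plus constant background over a 7 x 7 x 5 voxel
#' window. Nearby detections are merged (the brighter fit wins; ties broken by
#' lower residual, then lexicographic position), and the result is sorted by
#' descending amplitude. GFP-tagged nucleoporins make NPC clusters behave as
#' isolated emitters, so this is standard localization microscopy on a
#' confocal stack.
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name to detect in (default `"npc"`).
#' @param min_separation merge radius in um (default 0.3); must be at least
#'   one voxel.
#' @param threshold_k robust threshold factor k in median + k * MAD.
#' @param window integer half-widths `c(hx, hy, hz)` of the fit window.
#' @return a tibble with columns `channel`, `x_um`, `y_um`, `z_um`,
#'   `amplitude`, `background`, `sigma_xy_um`, `sigma_z_um`, `residual`,
#'   sorted by descending amplitude. Empty or flat images give zero rows.
#' @export
detect_spots <- function(stack, channel = "npc", min_separation = 0.3,
                         threshold_k = 5, window = c(3L, 3L, 2L)) {
  stopifnot(inherits(stack, "voxel_stack"), channel %in% names(stack$channels),
            min_separation >= min(stack$voxel_size))
  im <- stack$channels[[channel]]
  vs <- stack$voxel_size
  ax <- stack_axes(stack)
  empty <- tibble::tibble(channel = character(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric(),
                          amplitude = numeric(), background = numeric(),
                          sigma_xy_um = numeric(), sigma_z_um = numeric(),
                          residual = numeric())
  bg <- median(im)
  noise <- mad(im)
  thr <- bg + threshold_k * noise
  if (max(im) <= thr) return(empty)

  cand <- local_maxima_3d(im, thr)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-im[cand]), , drop = FALSE]

  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- tryCatch(
      fit_gaussian_3d(im, cand[i, ], vs, stack$origin, window),
      error = function(e) NULL)
    if (is.null(f)) {
      warning("spot fit diverged at voxel (", paste(cand[i, ], collapse = ","),
              "); candidate dropped", call. = FALSE)
      next
    }
    fits[[i]] <- f
  }
  fits <- dplyr::bind_rows(fits)
  if (nrow(fits) == 0) return(empty)

  # post-fit quality control: a real spot must rise above the noise floor and
  # have a PSF-scale width; isolated noise spikes fit with sub-voxel sigma
  fits <- fits[fits$amplitude > threshold_k * noise &
                 fits$sigma_xy_um >= 0.5 * vs[1] &
                 fits$sigma_z_um >= 0.5 * vs[3], ]
  if (nrow(fits) == 0) return(empty)

  # merge detections closer than min_separation, keeping the better fit
  ord <- order(-fits$amplitude, fits$residual, fits$x_um, fits$y_um, fits$z_um)
  fits <- fits[ord, ]
  keep <- rep(TRUE, nrow(fits))
  pos <- as.matrix(fits[, c("x_um", "y_um", "z_um")])
  for (i in seq_len(nrow(fits))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    if (length(prior)) {
      d <- sqrt(colSums((t(pos[prior, , drop = FALSE]) - pos[i, ])^2))
      if (any(d < min_separation)) keep[i] <- FALSE
    }
  }
  fits <- fits[keep, ]
  fits$channel <- channel
  fits <- fits[order(-fits$amplitude), ]
  dplyr::select(fits, "channel", dplyr::everything())
}

# indices (n x 3 matrix) of strict-ish local maxima above thr
local_maxima_3d <- function(im, thr) {
  d <- dim(im)
  is_max <- im > thr
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    shifted <- array(-Inf, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xi <- xs - sx; yi <- ys - sy; zi <- zs - sz
    okx <- xi >= 1 & xi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okz <- zi >= 1 & zi <= d[3]
    shifted[xs[okx], ys[oky], zs[okz]] <- im[xi[okx], yi[oky], zi[okz]]
    is_max <- is_max & (im >= shifted)
  }
  which(is_max, arr.ind = TRUE)
}

fit_gaussian_3d <- function(im, peak_idx, vs, origin, window) {
  peak_idx <- as.integer(unname(peak_idx))
  d <- dim(im)
  rng <- lapply(1:3, function(k) {
    max(1, peak_idx[k] - window[k]):min(d[k], peak_idx[k] + window[k])
  })
  sub <- im[rng[[1]], rng[[2]], rng[[3]]]
  cx <- origin[1] + (rng[[1]] - 0.5) * vs[1]
  cy <- origin[2] + (rng[[2]] - 0.5) * vs[2]
  cz <- origin[3] + (rng[[3]] - 0.5) * vs[3]
  gx <- expand.grid(x = cx, y = cy, z = cz)
  vals <- as.numeric(sub)
  loc_med <- median(vals)
  p0 <- c(x0 = origin[1] + (peak_idx[1] - 0.5) * vs[1],
          y0 = origin[2] + (peak_idx[2] - 0.5) * vs[2],
          z0 = origin[3] + (peak_idx[3] - 0.5) * vs[3],
          A = max(im[peak_idx[1], peak_idx[2], peak_idx[3]] - loc_med, 1e-6),
          b = loc_med, sxy = 1.3 * vs[1], sz = 1.3 * vs[3])
  lower <- c(min(cx), min(cy), min(cz), 0, 0, 0.3 * vs[1], 0.3 * vs[3])
  upper <- c(max(cx), max(cy), max(cz), Inf, Inf,
             diff(range(cx)) + vs[1], diff(range(cz)) + vs[3])
  resid_fn <- function(p) {
    g <- p[4] * exp(-((gx$x - p[1])^2 + (gx$y - p[2])^2) / (2 * p[6]^2) -
                      (gx$z - p[3])^2 / (2 * p[7]^2)) + p[5]
    vals - g
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  p <- fit$par
  if (!all(is.finite(unlist(p))) || p[["A"]] <= 0) stop("divergent fit")
  rms <- sqrt(mean(resid_fn(unlist(p))^2))
  tibble::tibble(x_um = p[["x0"]], y_um = p[["y0"]], z_um = p[["z0"]],
                 amplitude = p[["A"]], background = p[["b"]],
                 sigma_xy_um = p[["sxy"]], sigma_z_um = p[["sz"]],
                 residual = rms / p[["A"]])
}

#' Group detections into per-nucleus records
#'
#' Single-linkage clustering of detections at a physical linkage radius close
#' to the expected nuclear diameter. Groups with at least `min_detections`
#' members become nucleus records (center = detection centroid); smaller
#' groups are discarded and counted in the `report` attribute. Group labels
#' are assigned by lexicographic centroid order, so the result is invariant
#' to the input row order.
#'
#' @param detections tibble with `x_um`, `y_um`, `z_um` (and any extra
#'   columns, carried along).
#' @param linkage_radius single-linkage cut height in um (default 2.5,
#'   roughly one nuclear diameter).
#' @param min_detections minimum group size kept (default 8).
#' @return a nested nuclei tibble: `nucleus_id`, `cell_id`, `timepoint`,
#'   `detections` (list-column), `center_x`, `center_y`, `center_z`; with a
#'   `report` attribute counting discarded groups/detections.
#' @export
group_into_nuclei <- function(detections, linkage_radius = 2.5,
                              min_detections = 8) {
  pos_cols <- c("x_um", "y_um", "z_um")
  stopifnot(all(pos_cols %in% names(detections)))
  n <- nrow(detections)
  if (n == 0) {
    out <- tibble::tibble(nucleus_id = integer(), cell_id = character(),
                          timepoint = integer(), detections = list(),
                          center_x = numeric(), center_y = numeric(),
                          center_z = numeric())
    attr(out, "report") <- list(n_groups_discarded = 0L, n_detections_discarded = 0L)
    return(out)
  }
  labels <- if (n == 1) 1L else {
    hc <- hclust(dist(detections[, pos_cols]), method = "single")
    cutree(hc, h = linkage_radius)
  }
  groups <- split(seq_len(n), labels)
  sizes <- lengths(groups)
  kept <- groups[sizes >= min_detections]
  disc <- groups[sizes < min_detections]
  # deterministic ordering independent of input permutation
  if (length(kept)) {
    cents <- t(vapply(kept, function(idx) {
      colMeans(as.matrix(detections[idx, pos_cols]))
    }, numeric(3)))
    kept <- kept[order(cents[, 1], cents[, 2], cents[, 3])]
  }
  rows <- purrr::imap(kept, function(idx, i) {
    det <- detections[idx, ]
    det <- det[order(det$x_um, det$y_um, det$z_um), ]
    tibble::tibble(
      nucleus_id = as.integer(which(names(kept) == i)),
      cell_id = sprintf("cell%04d", which(names(kept) == i)),
      timepoint = 0L,
      detections = list(det),
      center_x = mean(det$x_um), center_y = mean(det$y_um),
      center_z = mean(det$z_um))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(nucleus_id = integer(), cell_id = character(),
                   timepoint = integer(), detections = list(),
                   center_x = numeric(), center_y = numeric(),
                   center_z = numeric())
  out$nucleus_id <- seq_len(nrow(out))
  out$cell_id <- sprintf("cell%04d", out$nucleus_id)
  attr(out, "report") <- list(n_groups_discarded = length(disc),
                              n_detections_discarded = sum(lengths(disc)))
  out
}

#' Segment the nucleolus around each nucleus
#'
#' Inside a bounding box centered on each nuclear center, voxels of the
#' nucleolus channel above an automatic Otsu threshold form the nucleolar
#' mask; the centroid is intensity-weighted and the volume is the mask voxel
#' count times the voxel volume. A contrast guard rejects boxes whose
#' foreground does not rise above the local noise (uniform channel -> absent
#' result, with a message).
#'
#' @param stack a [voxel_stack()] with a `nucleolus` channel.
#' @param nuclei nested nuclei tibble (from [group_into_nuclei()]).
#' @param box_halfwidth half-width of the bounding box in um.
#' @param contrast_min minimum (foreground - background) / MAD contrast.
#' @return `nuclei` with `nucleolus_x/y/z` and `nucleolar_volume` columns
#'   filled (NA where segmentation failed).
#' @export
segment_nucleolus <- function(stack, nuclei, box_halfwidth = 1.5,
                              contrast_min = 4) {
  stopifnot(inherits(stack, "voxel_stack"),
            "nucleolus" %in% names(stack$channels))
  im <- stack$channels[["nucleolus"]]
  ax <- stack_axes(stack)
  vox_vol <- prod(stack$voxel_size)
  res <- purrr::pmap(list(nuclei$center_x, nuclei$center_y, nuclei$center_z),
                     function(cx, cy, cz) {
    ix <- which(abs(ax[[1]] - cx) <= box_halfwidth)
    iy <- which(abs(ax[[2]] - cy) <= box_halfwidth)
    iz <- which(abs(ax[[3]] - cz) <= box_halfwidth)
    if (!length(ix) || !length(iy) || !length(iz))
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    box <- im[ix, iy, iz, drop = FALSE]
    rng <- range(box)
    if (diff(rng) <= 0) {
      message("flat nucleolus channel near (", signif(cx, 3), ", ",
              signif(cy, 3), ", ", signif(cz, 3), "); no mask")
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    }
    scaled <- (box - rng[1]) / diff(rng)
    thr <- EBImage::otsu(matrix(scaled, ncol = 1), range = c(0, 1))
    mask <- scaled > thr
    bg_vals <- box[!mask]
    if (!any(mask) ||
        (mean(box[mask]) - mean(bg_vals)) <= contrast_min * max(mad(bg_vals), 1e-9)) {
      message("no nucleolar foreground near (", signif(cx, 3), ", ",
              signif(cy, 3), ", ", signif(cz, 3), ")")
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    }
    w <- box[mask]
    idx <- which(mask, arr.ind = TRUE)
    ctr <- c(sum(ax[[1]][ix][idx[, 1]] * w), sum(ax[[2]][iy][idx[, 2]] * w),
             sum(ax[[3]][iz][idx[, 3]] * w)) / sum(w)
    c(ctr, sum(mask) * vox_vol)
  })
  m <- do.call(rbind, res)
  nuclei$nucleolus_x <- m[, 1]
  nuclei$nucleolus_y <- m[, 2]
  nuclei$nucleolus_z <- m[, 3]
  nuclei$nucleolar_volume <- m[, 4]
  nuclei
}

#' Identify the spindle pole body among a nucleus's detections
#'
#' The SPB shares the green channel with NPC spots but is much brighter. The
#' single detection whose amplitude exceeds `brightness_factor` times the
#' median amplitude is taken as the SPB and removed from the NPC list. If no
#' detection qualifies, or two or more do (duplicated SPB after S phase), the
#' result is absent and the NPC list is untouched — only nuclei with a single
#' qualifying spot are annotated, restricting SPB statistics to G1/early-S
#' cells.
#'
#' @param nuclei nested nuclei tibble; detections need an `amplitude` column.
#' @param brightness_factor amplitude multiple of the median (default 3).
#' @return `nuclei` with `spb_x/y/z` columns filled and the SPB row removed
#'   from `detections` where exactly one qualified.
#' @export
detect_spb <- function(nuclei, brightness_factor = 3) {
  xcol <- function(det) if ("x_um" %in% names(det)) "x_um" else "x"
  out <- nuclei
  out$spb_x <- out$spb_y <- out$spb_z <- NA_real_
  for (i in seq_len(nrow(out))) {
    det <- out$detections[[i]]
    med <- median(det$amplitude)
    hot <- which(det$amplitude > brightness_factor * med)
    if (length(hot) != 1) next
    xc <- xcol(det)
    cols <- c(xc, sub("x", "y", xc), sub("x", "z", xc))
    out$spb_x[i] <- det[[cols[1]]][hot]
    out$spb_y[i] <- det[[cols[2]]][hot]
    out$spb_z[i] <- det[[cols[3]]][hot]
    out$detections[[i]] <- det[-hot, ]
  }
  out
}

#' Least-squares ellipsoid fit of a detection cloud
#'
#' Algebraic fit of a general quadric constrained to an ellipsoid: solve the
#' linear least-squares system for the nine quadric coefficients, recover the
#' center, then require the centered quadratic form to be positive definite.
#'
#' @param points matrix or tibble of >= 9 points (columns x, y, z or
#'   x_um/y_um/z_um).
#' @return an object of class `ellipsoid_fit`: `center` (um), `radii`
#'   (semi-axes, um, decreasing), `rotation` (columns = axis directions),
#'   `rms` algebraic residual.
#' @export
fit_ellipsoid <- function(points) {
  P <- as_xyz_matrix(points)
  if (nrow(P) < 9) stop("ellipsoid fit needs at least 9 points")
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[3] < 1e-9 * sv[1]) stop("degenerate (coplanar) point cloud")
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  M <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  beta <- qr.solve(M, rep(1, nrow(P)))
  A <- matrix(c(beta[1], beta[4] / 2, beta[5] / 2,
                beta[4] / 2, beta[2], beta[6] / 2,
                beta[5] / 2, beta[6] / 2, beta[3]), 3, 3)
  b <- beta[7:9]
  ctr <- as.numeric(-solve(A, b) / 2)
  # f(c + y) = y'Ay + (c'Ac + b'c - 1) = 0  =>  y'Ay = 1 - c'Ac - b'c
  rhs <- 1 - as.numeric(t(ctr) %*% A %*% ctr) - sum(b * ctr)
  eg <- eigen(A / rhs, symmetric = TRUE)
  if (any(eg$values <= 0)) stop("fitted quadric is not an ellipsoid")
  radii <- 1 / sqrt(eg$values) # eigen returns decreasing values -> radii increasing
  ord <- order(radii, decreasing = TRUE)
  rot <- eg$vectors[, ord, drop = FALSE]
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  rms <- sqrt(mean((M %*% beta - 1)^2))
  structure(list(center = ctr, radii = radii[ord], rotation = rot, rms = rms),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat("<ellipsoid_fit> center (", paste(signif(x$center, 4), collapse = ", "),
      ") um; semi-axes", paste(signif(x$radii, 4), collapse = " x "), "um\n")
  invisible(x)
}

# accept x/y/z or x_um/y_um/z_um column names, or a bare 3-column matrix
as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 3)
    return(unname(points[, 1:3, drop = FALSE]))
  }
  nm <- names(points)
  cols <- if (all(c("x_um", "y_um", "z_um") %in% nm)) c("x_um", "y_um", "z_um")
          else if (all(c("x", "y", "z") %in% nm)) c("x", "y", "z")
          else stop("points need x/y/z or x_um/y_um/z_um columns")
  unname(as.matrix(points[, cols]))
}
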