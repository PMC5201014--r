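#' Align a population of nuclei on a common landmark axis
#'
#' Each nucleus is translated so its center sits at the origin and rotated so
#' the chosen secondary landmark (nucleolar centroid or SPB) falls on the
#' negative side of the axial coordinate; all azimuthal angles are pooled by
#' the cylindrical collapse onto the (s, r) half-plane. s is the signed
#' coordinate along the central axis (landmark at negative s, opposite pole
#' positive), r >= 0 the transverse radius.
#'
#' @param nuclei nested nuclei tibble with landmark columns.
#' @param secondary_landmark `"nucleolus"` or `"spb"`.
#' @param target `"npc"` (all NPC detections) or `"spb"` (one point per
#'   nucleus).
#' @return tibble with `nucleus_id`, `s`, `r`, `weight`; aligned per-nucleus
#'   landmark positions in the `aligned_landmarks` attribute and the number of
#'   skipped nuclei (missing landmark) in `n_skipped`.
#' @export
align_population <- function(nuclei, secondary_landmark = c("nucleolus", "spb"),
                             target = c("npc", "spb")) {
  secondary_landmark <- match.arg(secondary_landmark)
  target <- match.arg(target)
  lm_cols <- paste0(secondary_landmark, c("_x", "_y", "_z"))
  stopifnot(all(lm_cols %in% names(nuclei)))
  pts <- list(); lms <- list(); skipped <- 0L
  for (i in seq_len(nrow(nuclei))) {
    ctr <- c(nuclei$center_x[i], nuclei$center_y[i], nuclei$center_z[i])
    lmk <- as.numeric(nuclei[i, lm_cols])
    if (!all(is.finite(lmk))) { skipped <- skipped + 1L; next }
    u <- unit3(lmk - ctr)
    project <- function(P) {
      rel <- sweep(P, 2, ctr)
      proj <- as.numeric(rel %*% u)
      tibble::tibble(s = -proj,
                     r = sqrt(pmax(rowSums(rel^2) - proj^2, 0)))
    }
    tgt <- switch(target,
      npc = as_xyz_matrix(nuclei$detections[[i]]),
      spb = {
        spb <- c(nuclei$spb_x[i], nuclei$spb_y[i], nuclei$spb_z[i])
        if (!all(is.finite(spb))) { NULL } else rbind(spb)
      })
    if (is.null(tgt) || nrow(tgt) == 0) { skipped <- skipped + 1L; next }
    ali <- project(tgt)
    ali$nucleus_id <- nuclei$nucleus_id[i]
    ali$weight <- 1
    pts[[length(pts) + 1]] <- ali[, c("nucleus_id", "s", "r", "weight")]
    lmrow <- tibble::tibble(nucleus_id = nuclei$nucleus_id[i],
                            landmark_s = -vec3_norm(lmk - ctr), landmark_r = 0)
    if (all(c("spb_x", "spb_y", "spb_z") %in% names(nuclei))) {
      spb <- c(nuclei$spb_x[i], nuclei$spb_y[i], nuclei$spb_z[i])
      if (all(is.finite(spb))) {
        a <- project(rbind(spb))
        lmrow$spb_s <- a$s; lmrow$spb_r <- a$r
      } else { lmrow$spb_s <- NA_real_; lmrow$spb_r <- NA_real_ }
    }
    lms[[length(lms) + 1]] <- lmrow
  }
  out <- dplyr::bind_rows(pts)
  attr(out, "aligned_landmarks") <- dplyr::bind_rows(lms)
  attr(out, "n_skipped") <- skipped
  attr(out, "secondary_landmark") <- secondary_landmark
  out
}

#' Kernel density map over the aligned (s, r) half-plane
#'
#' Product-Gaussian kernel density estimate on the cylindrical-collapse
#' coordinates, with mass reflected across r = 0 (each point mirrored to -r)
#' so the estimate is unbiased at the axis. Bandwidths default to Silverman's
#' rule per coordinate. The returned grid integrates to ~1 over the
#' half-plane.
#'
#' @param points aligned points (tibble with `s`, `r`, optional `weight`).
#' @param bandwidth length-2 `c(h_s, h_r)` in um, or `NULL` for Silverman.
#' @param s_range,r_range grid extents in um.
#' @param pitch grid spacing in um (default 0.05).
#' @param landmark label carried into the result (`"nucleolus"`/`"spb"`).
#' @param min_points minimal number of points (default 50).
#' @return an object of class `density_map`: `density` (matrix s x r), `s`,
#'   `r`, `bandwidth`, `n_points`, `landmark`, `overlays`.
#' @export
kde_map <- function(points, bandwidth = NULL, s_range = c(-2.5, 2.5),
                    r_range = c(0, 2.5), pitch = 0.05,
                    landmark = attr(points, "secondary_landmark") %||% "nucleolus",
                    min_points = 50) {
  stopifnot(all(c("s", "r") %in% names(points)), nrow(points) >= min_points)
  w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
  w <- w / sum(w)
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::bw.nrd(points$s),
                   stats::bw.nrd(c(points$r, -points$r)))
  }
  if (any(bandwidth <= 0)) stop("bandwidth must be positive")
  s_grid <- seq(s_range[1], s_range[2], by = pitch)
  r_grid <- seq(r_range[1], r_range[2], by = pitch)
  Gs <- stats::dnorm(outer(s_grid, points$s, "-"), sd = bandwidth[1])
  Gr <- stats::dnorm(outer(r_grid, points$r, "-"), sd = bandwidth[2]) +
        stats::dnorm(outer(r_grid, -points$r, "-"), sd = bandwidth[2])
  dens <- (Gs * rep(w, each = length(s_grid))) %*% t(Gr)
  structure(list(density = dens, s = s_grid, r = r_grid,
                 bandwidth = bandwidth, n_points = nrow(points),
                 landmark = landmark, overlays = NULL),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d grid, %d points, landmark %s, bandwidth (%.3g, %.3g) um\n",
              length(x$s), length(x$r), x$n_points, x$landmark,
              x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

#' Convert a density map to cumulative-percentage levels
#'
#' Each grid cell is assigned the smallest percentage of total probability
#' mass contained in the highest-density region that includes it, the
#' "cumulative percentage" convention of population probability maps (the 50%
#' contour encloses half the detections).
#'
#' @param map a [kde_map()] result.
#' @return the map with an additional `percentile` matrix (0-100).
#' @export
as_percentile <- function(map) {
  stopifnot(inherits(map, "density_map"))
  d <- as.numeric(map$density)
  ord <- order(d, decreasing = TRUE)
  mass <- d[ord] / sum(d)
  pct <- numeric(length(d))
  pct[ord] <- 100 * cumsum(mass)
  map$percentile <- matrix(pct, nrow = nrow(map$density))
  map
}

#' NPC density along the central axis
#'
#' Bins the polar angle theta = atan2(r, s) (0 at the anti-nucleolar pole, pi
#' at the nucleolar pole) and normalizes counts by the solid angle of each
#' band and by the total, so an isotropic shell gives a flat profile at 1.
#'
#' @param points aligned points (`s`, `r`).
#' @param n_bins number of angular bins (default 18, i.e. 10 degrees each).
#' @param min_points minimal number of points (default 100).
#' @return a tibble of class `axial_profile`: `theta_deg` (bin midpoints),
#'   `count`, `density` (relative to isotropic).
#' @export
axial_density_profile <- function(points, n_bins = 18, min_points = 100) {
  stopifnot(all(c("s", "r") %in% names(points)), nrow(points) >= min_points)
  theta <- atan2(points$r, points$s)
  edges <- seq(0, pi, length.out = n_bins + 1)
  idx <- pmin(findInterval(theta, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, n_bins)
  solid <- 2 * pi * (cos(edges[-length(edges)]) - cos(edges[-1]))
  dens <- (counts / sum(counts)) / (solid / (4 * pi))
  out <- tibble::tibble(theta_deg = 180 / pi * (edges[-length(edges)] + edges[-1]) / 2,
                        count = counts, density = dens)
  class(out) <- c("axial_profile", class(out))
  out
}

#' Median population overlays for a density map
#'
#' Display annotations: the median nuclear radius (from per-nucleus volumes),
#' the median aligned nucleolar centroid, and a sphere-cap arc whose radius
#' matches the median nucleolar volume — a display-only approximation of the
#' median nucleolus.
#'
#' @param nuclei nuclei tibble with `volume` and `nucleolar_volume` columns.
#' @param aligned_landmarks tibble from the `aligned_landmarks` attribute of
#'   [align_population()].
#' @return a list of class `map_overlays`: `median_radius_um`,
#'   `nucleolus_s`, `nucleolus_r`, `nucleolus_radius_um`, `spb_s`, `spb_r`.
#' @export
median_overlays <- function(nuclei, aligned_landmarks) {
  med_radius <- if ("volume" %in% names(nuclei))
    median((3 * nuclei$volume / (4 * pi))^(1 / 3), na.rm = TRUE) else NA_real_
  nuc_vol <- if ("nucleolar_volume" %in% names(nuclei))
    median(nuclei$nucleolar_volume, na.rm = TRUE) else NA_real_
  structure(list(
    median_radius_um = med_radius,
    nucleolus_s = median(aligned_landmarks$landmark_s, na.rm = TRUE),
    nucleolus_r = median(aligned_landmarks$landmark_r, na.rm = TRUE),
    nucleolus_radius_um = if (is.finite(nuc_vol)) (3 * nuc_vol / (4 * pi))^(1 / 3) else NA_real_,
    spb_s = if ("spb_s" %in% names(aligned_landmarks))
      median(aligned_landmarks$spb_s, na.rm = TRUE) else NA_real_,
    spb_r = if ("spb_r" %in% names(aligned_landmarks))
      median(aligned_landmarks$spb_r, na.rm = TRUE) else NA_real_),
    class = "map_overlays")
}

#' Density maps by nuclear-size class
#'
#' Sorts nuclei into `n_classes` volume classes of equal size (ties broken by
#' stable input order) and builds one density map per class.
#'
#' @param nuclei nuclei tibble with a `volume` column.
#' @param aligned_points aligned points with `nucleus_id` (from
#'   [align_population()]).
#' @param n_classes number of classes (default 3: small/medium/large).
#' @param ... passed to [kde_map()].
#' @return named list of [kde_map()] results with a `classes` attribute
#'   (tibble `nucleus_id`, `volume`, `size_class`).
#' @export
size_sorted_maps <- function(nuclei, aligned_points, n_classes = 3, ...) {
  stopifnot("volume" %in% names(nuclei))
  if (nrow(nuclei) < 150)
    warning("fewer than 150 nuclei; size-class maps will be noisy", call. = FALSE)
  cls <- dplyr::ntile(rank(nuclei$volume, ties.method = "first"), n_classes)
  lab <- if (n_classes == 3) c("small", "medium", "large")
         else paste0("class", seq_len(n_classes))
  classes <- tibble::tibble(nucleus_id = nuclei$nucleus_id,
                            volume = nuclei$volume,
                            size_class = lab[cls])
  maps <- lapply(seq_len(n_classes), function(k) {
    ids <- classes$nucleus_id[cls == k]
    kde_map(dplyr::filter(aligned_points, .data$nucleus_id %in% ids), ...)
  })
  names(maps) <- lab
  attr(maps, "classes") <- classes
  maps
}
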