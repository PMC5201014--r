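#' Oriented central-axis frame of a nucleus
#'
#' The central axis runs from the nucleolar centroid through the nuclear
#' center; the frame's axis unit vector points away from the landmark, so an
#' SPB diametrically opposed to the nucleolus sits at angle 0.
#'
#' @param center nuclear center (um triple).
#' @param landmark landmark position (um triple): nucleolar centroid or SPB.
#' @param landmark_type `"nucleolus"` or `"spb"`.
#' @return an object of class `axis_frame`: `origin`, `axis` (unit),
#'   `landmark`, `landmark_type`.
#' @export
axis_frame <- function(center, landmark, landmark_type = c("nucleolus", "spb")) {
  landmark_type <- match.arg(landmark_type)
  stopifnot(length(center) == 3, length(landmark) == 3,
            all(is.finite(center)), all(is.finite(landmark)))
  structure(list(origin = as.numeric(center),
                 axis = unit3(as.numeric(center) - as.numeric(landmark)),
                 landmark = as.numeric(landmark),
                 landmark_type = landmark_type),
            class = "axis_frame")
}

#' Radial distances of detections to a reference
#'
#' `"center"` mode returns Euclidean distances to the nuclear center;
#' `"ellipsoid"` mode returns the signed distance to the closest point on a
#' fitted ellipsoid (positive outside), found by solving the closest-point
#' equation on the quadric per detection.
#'
#' @param points matrix/tibble of positions.
#' @param reference `"center"` or `"ellipsoid"`.
#' @param center nuclear center (required for `"center"` mode).
#' @param ellipsoid an [fit_ellipsoid()] result (required for `"ellipsoid"`).
#' @param tol closest-point solver tolerance (um).
#' @return numeric vector of distances (um), signed in ellipsoid mode.
#' @export
radial_distances <- function(points, reference = c("center", "ellipsoid"),
                             center = NULL, ellipsoid = NULL, tol = 1e-10) {
  reference <- match.arg(reference)
  P <- as_xyz_matrix(points)
  if (reference == "center") {
    stopifnot(length(center) == 3)
    return(sqrt(colSums((t(P) - center)^2)))
  }
  stopifnot(inherits(ellipsoid, "ellipsoid_fit"))
  Q <- sweep(P, 2, ellipsoid$center) %*% ellipsoid$rotation
  r <- ellipsoid$radii
  vapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    s2 <- sum((q / r)^2)
    if (s2 < 1e-24) return(-min(r)) # at the center
    f <- function(t) sum((q * r / (r^2 + t))^2) - 1
    lo <- -min(r)^2 * (1 - 1e-9)
    hi <- max(vec3_norm(q) * max(r), max(r)^2)
    while (f(hi) > 0) hi <- hi * 2
    t0 <- uniroot(f, c(lo, hi), tol = tol)$root
    xc <- q * r^2 / (r^2 + t0)
    sign(s2 - 1) * vec3_norm(q - xc)
  }, numeric(1))
}

#' Angle of the SPB from the central axis
#'
#' alpha = arccos(axis . unit(spb - origin)) in degrees; 0 when the SPB is
#' diametrically opposed to the nucleolus, 180 when it sits at the nucleolar
#' pole.
#'
#' @param frame an [axis_frame()].
#' @param spb SPB position (um triple), distinct from the frame origin.
#' @return angle in degrees, in `[0, 180]`.
#' @export
spb_axis_angle <- function(frame, spb) {
  stopifnot(inherits(frame, "axis_frame"), length(spb) == 3)
  v <- as.numeric(spb) - frame$origin
  if (vec3_norm(v) == 0) stop("SPB coincides with the frame origin")
  acos(pmin(1, pmax(-1, sum(frame$axis * unit3(v))))) * 180 / pi
}

#' SPB to nucleolar-centroid distances for a population
#'
#' @param nuclei nested nuclei tibble with `spb_*` and `nucleolus_*` columns.
#' @return tibble `nucleus_id`, `distance` (um); nuclei missing either
#'   landmark are skipped (count in the `n_skipped` attribute).
#' @export
spb_nucleolus_distance <- function(nuclei) {
  have <- stats::complete.cases(
    nuclei[, c("spb_x", "spb_y", "spb_z", "nucleolus_x", "nucleolus_y", "nucleolus_z")])
  d <- sqrt((nuclei$spb_x - nuclei$nucleolus_x)^2 +
            (nuclei$spb_y - nuclei$nucleolus_y)^2 +
            (nuclei$spb_z - nuclei$nucleolus_z)^2)
  out <- tibble::tibble(nucleus_id = nuclei$nucleus_id[have],
                        distance = d[have])
  attr(out, "n_skipped") <- sum(!have)
  out
}

#' Maximum radial-distance ratio along vs across the central axis
#'
#' In the aligned frame, the ratio of the largest absolute coordinate along
#' the axis to the largest absolute offset along one fixed transverse
#' direction; ~1 for a sphere, > 1 for an axially elongated nucleus.
#'
#' @param points matrix/tibble of >= 8 detection positions.
#' @param frame an [axis_frame()].
#' @return the unitless ratio.
#' @export
max_radial_ratio <- function(points, frame) {
  stopifnot(inherits(frame, "axis_frame"))
  P <- as_xyz_matrix(points)
  stopifnot(nrow(P) >= 8)
  rel <- sweep(P, 2, frame$origin)
  xprime <- rel %*% frame$axis
  e <- diag(3)[, which.min(abs(frame$axis))]
  v <- unit3(e - sum(e * frame$axis) * frame$axis)
  yprime <- rel %*% v
  max(abs(xprime)) / max(abs(yprime))
}

#' Empirical cumulative frequency curve
#'
#' Right-continuous empirical CDF evaluated on a grid, in percent.
#'
#' @param values numeric vector (>= 1 value).
#' @param grid query points; default the sorted unique values.
#' @return tibble with `value` and `cumulative_percent`.
#' @export
cumulative_frequency <- function(values, grid = NULL) {
  stopifnot(length(values) >= 1)
  if (is.null(grid)) grid <- sort(unique(values))
  tibble::tibble(value = grid,
                 cumulative_percent = 100 * stats::ecdf(values)(grid))
}

#' Per-nucleus spatial statistics table
#'
#' SPB distance from the center, angle from the central axis, SPB-nucleolus
#' distance and maximum radial-distance ratio, one row per nucleus; statistics
#' needing an absent landmark are NA.
#'
#' @param nuclei nested nuclei tibble with landmark columns.
#' @return tibble with `nucleus_id`, `cell_id`, `alpha_deg`, `spb_R_um`,
#'   `spb_nucleolus_um`, `max_radial_ratio`.
#' @export
nucleus_statistics <- function(nuclei) {
  rows <- purrr::map(seq_len(nrow(nuclei)), function(i) {
    ctr <- c(nuclei$center_x[i], nuclei$center_y[i], nuclei$center_z[i])
    nuc <- c(nuclei$nucleolus_x[i], nuclei$nucleolus_y[i], nuclei$nucleolus_z[i])
    spb <- c(nuclei$spb_x[i], nuclei$spb_y[i], nuclei$spb_z[i])
    has_nuc <- all(is.finite(nuc)); has_spb <- all(is.finite(spb))
    frame <- if (has_nuc) axis_frame(ctr, nuc, "nucleolus") else NULL
    tibble::tibble(
      nucleus_id = nuclei$nucleus_id[i],
      cell_id = nuclei$cell_id[i],
      alpha_deg = if (has_nuc && has_spb) spb_axis_angle(frame, spb) else NA_real_,
      spb_R_um = if (has_spb) vec3_norm(spb - ctr) else NA_real_,
      spb_nucleolus_um = if (has_nuc && has_spb) vec3_norm(spb - nuc) else NA_real_,
      max_radial_ratio = if (has_nuc && nrow(nuclei$detections[[i]]) >= 8)
        max_radial_ratio(nuclei$detections[[i]], frame) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
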