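#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an aberration model
#'
#' @param x an `aberration_model`.
#' @param ... unused.
#' @return one row per polynomial term: `term`, `estimate`, `std.error`.
#' @export
tidy.aberration_model <- function(x, ...) {
  tibble::tibble(term = c("x^2", "x", "(Intercept)"),
                 estimate = c(x$a, x$b, x$c),
                 std.error = unname(x$se[c("a", "b", "c")]))
}

#' @rdname tidy.aberration_model
#' @export
glance.aberration_model <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, n_points = x$n_points)
}

#' Tidy a cluster assignment
#'
#' @param x an `npc_clusters` object.
#' @param ... unused.
#' @return per-cluster centroids, sizes and within-cluster sums of squares.
#' @export
tidy.npc_clusters <- function(x, ...) {
  dplyr::mutate(x$centroids, within_ss = x$per_cluster_ss)
}

#' @rdname tidy.npc_clusters
#' @export
glance.npc_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, within_ss = x$within_ss, n_points = length(x$labels))
}

#' Tidy an envelope mesh
#'
#' @param x an `envelope_mesh`.
#' @param ... unused.
#' @return vertices as a tibble (`vertex`, `x`, `y`, `z`).
#' @export
tidy.envelope_mesh <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$vertices)),
                 x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3])
}

#' @rdname tidy.envelope_mesh
#' @export
glance.envelope_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  tibble::tibble(model = x$model, refinements = x$refinements,
                 n_vertices = nrow(x$vertices), n_triangles = nrow(x$triangles),
                 surface_um2 = m$surface, volume_um3 = m$volume,
                 sphericity = sphericity(m$surface, m$volume))
}

#' Tidy an ellipsoid fit
#'
#' @param x an `ellipsoid_fit`.
#' @param ... unused.
#' @return one row per semi-axis with center coordinates.
#' @export
tidy.ellipsoid_fit <- function(x, ...) {
  tibble::tibble(axis = 1:3, semi_axis_um = x$radii,
                 center_x = x$center[1], center_y = x$center[2],
                 center_z = x$center[3])
}

#' @rdname tidy.ellipsoid_fit
#' @export
glance.ellipsoid_fit <- function(x, ...) {
  tibble::tibble(rms = x$rms, axis_ratio = x$radii[1] / x$radii[3])
}

#' Tidy a density map into a long grid table
#'
#' @param x a `density_map`.
#' @param ... unused.
#' @return tibble with `s`, `r`, `density` (and `percentile` if present).
#' @export
tidy.density_map <- function(x, ...) {
  out <- tibble::tibble(s = rep(x$s, times = length(x$r)),
                        r = rep(x$r, each = length(x$s)),
                        density = as.numeric(x$density))
  if (!is.null(x$percentile)) out$percentile <- as.numeric(x$percentile)
  out
}

#' @rdname tidy.density_map
#' @export
glance.density_map <- function(x, ...) {
  # trapezoidal quadrature: the r = 0 boundary row carries half a cell
  ws <- rep(1, length(x$s)); ws[c(1, length(ws))] <- 0.5
  wr <- rep(1, length(x$r)); wr[c(1, length(wr))] <- 0.5
  mass <- as.numeric(ws %*% x$density %*% wr) *
    diff(x$s[1:2]) * diff(x$r[1:2])
  tibble::tibble(n_points = x$n_points, landmark = x$landmark,
                 bandwidth_s = x$bandwidth[1], bandwidth_r = x$bandwidth[2],
                 total_mass = mass)
}
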