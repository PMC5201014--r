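#' Triangulated closed envelope mesh
#'
#' @param vertices n x 3 numeric matrix of positions (um).
#' @param triangles m x 3 integer matrix of vertex indices (1-based),
#'   consistently oriented with outward normals.
#' @param model `"patch"`, `"spline"` or `"anchor"`.
#' @param refinements number of refinement passes already applied.
#' @param check validate that the mesh is closed (every edge shared by
#'   exactly two triangles).
#' @return an object of class `envelope_mesh`.
#' @export
envelope_mesh <- function(vertices, triangles, model = "patch",
                          refinements = 0L, check = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  stopifnot(ncol(vertices) == 3, all(triangles >= 1),
            all(triangles <= nrow(vertices)))
  if (check) assert_closed(triangles)
  structure(list(vertices = vertices, triangles = triangles,
                 model = model, refinements = as.integer(refinements)),
            class = "envelope_mesh")
}

#' @export
print.envelope_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  cat(sprintf("<envelope_mesh> %s (%d refinements): %d vertices, %d triangles, S = %.4g um^2, V = %.4g um^3\n",
              x$model, x$refinements, nrow(x$vertices), nrow(x$triangles),
              m$surface, m$volume))
  invisible(x)
}

edge_table <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

assert_closed <- function(triangles) {
  e <- edge_table(triangles)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  if (any(tab != 2))
    stop("mesh is not a closed manifold: ", sum(tab != 2),
         " edge(s) not shared by exactly 2 triangles")
  invisible(TRUE)
}

is_closed <- function(triangles) {
  e <- edge_table(triangles)
  all(table(paste(e[, 1], e[, 2])) == 2)
}

# convex-hull triangulation with escalating symbolic perturbation: large
# near-cospherical inputs (anchor refinement) occasionally defeat the plain
# incremental hull's fixed tolerance, so retry with a deterministic joggle
# until the result is a closed 2-manifold
hull_triangulation <- function(P) {
  for (j in c(0, 1e-8, 1e-7, 1e-6)) {
    tri <- .hull3d(P, j)
    if (is_closed(tri)) return(tri)
  }
  stop("convex hull triangulation failed to produce a closed surface")
}

#' Initial envelope patch: Delaunay surface of a detection cluster
#'
#' The first envelope configuration of a cluster is the polyhedral patch
#' connecting neighboring detections — for a star-shaped cluster of
#' envelope-bound points this is its convex hull, whose triangles are the
#' surface Delaunay triangulation. Vertices are the detections themselves.
#'
#' @param points matrix/tibble of >= 4 non-coplanar positions (um).
#' @return an `envelope_mesh` with `model = "patch"`.
#' @export
initial_patch <- function(points) {
  P <- as_xyz_matrix(points)
  if (nrow(P) < 4) stop("need at least 4 points")
  tri <- hull_triangulation(P)
  envelope_mesh(P, tri, model = "patch", refinements = 0L)
}

#' Surface and volume of a closed mesh
#'
#' Surface = sum of triangle areas; volume = |sum of signed tetrahedra against
#' the origin| (divergence theorem), invariant to translation for a closed
#' consistently oriented mesh.
#'
#' @param mesh an `envelope_mesh`.
#' @return list with `surface` (um^2) and `volume` (um^3).
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "envelope_mesh"))
  assert_closed(mesh$triangles)
  V <- mesh$vertices; Tm <- mesh$triangles
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE]
  c_ <- V[Tm[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  surface <- sum(sqrt(rowSums(cr^2))) / 2
  vol6 <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
              a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
              a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))
  list(surface = surface, volume = abs(vol6) / 6)
}

#' Interpolating subdivision refinement (spline envelope)
#'
#' Butterfly-style interpolating subdivision: original vertices are retained
#' unmoved and each edge gains a new vertex placed by the 8-point butterfly
#' stencil, quadrupling the triangle count per pass. Because the detected
#' spots stay the most distant points of the refined surface, this envelope
#' model systematically underestimates the size of a convex nucleus.
#'
#' @param mesh a closed `envelope_mesh`.
#' @param iterations number of subdivision passes (default 3).
#' @return refined `envelope_mesh` with `model = "spline"`.
#' @export
refine_spline <- function(mesh, iterations = 3) {
  stopifnot(inherits(mesh, "envelope_mesh"), iterations >= 1)
  V <- mesh$vertices; Tm <- mesh$triangles
  for (it in seq_len(iterations)) {
    res <- butterfly_once(V, Tm)
    V <- res$vertices; Tm <- res$triangles
  }
  envelope_mesh(V, Tm, model = "spline",
                refinements = mesh$refinements + iterations)
}

butterfly_once <- function(V, Tm) {
  nv <- nrow(V); nt <- nrow(Tm)
  # edge list with adjacency: each triangle contributes (edge, opposite vertex)
  ev <- rbind(Tm[, c(1, 2, 3)], Tm[, c(2, 3, 1)], Tm[, c(3, 1, 2)])
  a <- pmin(ev[, 1], ev[, 2]); b <- pmax(ev[, 1], ev[, 2]); opp <- ev[, 3]
  key <- paste(a, b)
  uk <- unique(key)
  eid <- match(key, uk)
  ne <- length(uk)
  if (length(eid) != 2 * ne) stop("mesh is not a closed manifold")
  # two opposite vertices per edge
  o1 <- integer(ne); o2 <- integer(ne)
  ea <- integer(ne); eb <- integer(ne)
  first <- !duplicated(eid)
  o1[eid[first]] <- opp[first]
  ea[eid[first]] <- a[first]; eb[eid[first]] <- b[first]
  o2[eid[!first]] <- opp[!first]
  # wing lookup: opposite vertex across edge (u, v) from the side away from w
  other_opp <- function(u, v, w) {
    k <- paste(pmin(u, v), pmax(u, v))
    id <- match(k, uk)
    out <- ifelse(o1[id] == w, o2[id], o1[id])
    # if w is not an opposite of (u,v) the mesh is irregular there; fall back
    bad <- o1[id] != w & o2[id] != w
    out[bad] <- o1[id][bad]
    out
  }
  e <- other_opp(ea, o1, eb); f <- other_opp(eb, o1, ea)
  g <- other_opp(ea, o2, eb); h <- other_opp(eb, o2, ea)
  newpts <- 0.5 * (V[ea, , drop = FALSE] + V[eb, , drop = FALSE]) +
    0.125 * (V[o1, , drop = FALSE] + V[o2, , drop = FALSE]) -
    0.0625 * (V[e, , drop = FALSE] + V[f, , drop = FALSE] +
              V[g, , drop = FALSE] + V[h, , drop = FALSE])
  V2 <- rbind(V, newpts)
  # midpoint index of edge (u, v)
  mid <- function(u, v) nv + match(paste(pmin(u, v), pmax(u, v)), uk)
  m12 <- mid(Tm[, 1], Tm[, 2]); m23 <- mid(Tm[, 2], Tm[, 3]); m31 <- mid(Tm[, 3], Tm[, 1])
  T2 <- rbind(cbind(Tm[, 1], m12, m31),
              cbind(Tm[, 2], m23, m12),
              cbind(Tm[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(vertices = V2, triangles = T2)
}

#' Anchor-point refinement (3D envelope model)
#'
#' Per pass, every surface triangle spawns one anchor point in the direction
#' from the cluster center to the triangle's mass center, at a distance equal
#' to the mean distance of the triangle's three vertices to the center; the
#' union of previous vertices and anchors is then re-triangulated by convex
#' hull. Three passes give enough points for a precise envelope. Anchors can
#' lie outside the detected point cloud, removing the spline model's
#' inscription bias; with very few detections (< 20) the off-center cluster
#' centroid makes this model slightly overestimate nuclear size.
#'
#' @param mesh a closed `envelope_mesh` (convex; typically [initial_patch()]).
#' @param center cluster center (um), strictly inside the mesh; by convention
#'   the centroid of the cluster's detections.
#' @param iterations number of refinement passes (default 3).
#' @return refined `envelope_mesh` with `model = "anchor"`.
#' @export
refine_anchor <- function(mesh, center, iterations = 3) {
  stopifnot(inherits(mesh, "envelope_mesh"), length(center) == 3)
  if (!point_inside_convex(mesh, rbind(center)))
    stop("center is not strictly inside the mesh")
  V <- mesh$vertices; Tm <- mesh$triangles
  for (it in seq_len(iterations)) {
    A <- V[Tm[, 1], , drop = FALSE]
    B <- V[Tm[, 2], , drop = FALSE]
    C <- V[Tm[, 3], , drop = FALSE]
    mc <- (A + B + C) / 3
    u <- sweep(mc, 2, center)
    u <- u / sqrt(rowSums(u^2))
    rbar <- (sqrt(rowSums(sweep(A, 2, center)^2)) +
             sqrt(rowSums(sweep(B, 2, center)^2)) +
             sqrt(rowSums(sweep(C, 2, center)^2))) / 3
    anchors <- sweep(u * rbar, 2, center, `+`)
    V <- rbind(V, anchors)
    Tm <- hull_triangulation(V)
  }
  envelope_mesh(V, Tm, model = "anchor",
                refinements = mesh$refinements + iterations)
}

# outward-oriented face planes of a convex mesh
mesh_planes <- function(mesh) {
  V <- mesh$vertices; Tm <- mesh$triangles
  A <- V[Tm[, 1], , drop = FALSE]
  B <- V[Tm[, 2], , drop = FALSE]
  C <- V[Tm[, 3], , drop = FALSE]
  u <- B - A; w <- C - A
  N <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  off <- rowSums(N * A)
  inner <- colMeans(V[unique(as.integer(Tm)), , drop = FALSE])
  s <- N %*% inner - off
  flip <- s > 0
  N[flip, ] <- -N[flip, ]
  off[flip] <- -off[flip]
  list(N = N, off = off)
}

# test points (m x 3) against a convex mesh; TRUE = strictly inside
point_inside_convex <- function(mesh, points, tol = 1e-9) {
  pl <- mesh_planes(mesh)
  scale <- max(abs(pl$off), 1)
  inside <- rep(TRUE, nrow(points))
  chunk <- max(1L, floor(2e7 / nrow(pl$N)))
  i <- 1L
  while (i <= nrow(points)) {
    j <- min(i + chunk - 1L, nrow(points))
    s <- points[i:j, , drop = FALSE] %*% t(pl$N)
    viol <- sweep(s, 2, pl$off) >= -tol * scale
    inside[i:j] <- rowSums(viol) == 0L
    i <- j + 1L
  }
  inside
}

#' Sphericity of a closed shape
#'
#' Ratio of the surface of the sphere having the measured volume to the
#' measured surface: Psi = pi^(1/3) (6 V)^(2/3) / S. Equals 1 for a sphere
#' and is < 1 for any other shape.
#'
#' @param surface surface area (um^2), > 0.
#' @param volume volume (um^3), > 0.
#' @return sphericity (unitless).
#' @export
sphericity <- function(surface, volume) {
  stopifnot(all(surface > 0), all(volume > 0))
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface
}

#' Merge per-cluster envelope meshes into whole-nucleus geometry
#'
#' A multi-cluster nucleus (dumbbell, hourglass) is the union of its cluster
#' envelopes. Total volume is the sum of mesh volumes minus the volume of
#' pairwise intersections (estimated by voxel counting at `voxel_pitch` inside
#' the overlapping bounding boxes); total surface is the sum of mesh surfaces
#' minus the area of faces buried inside another mesh (face-centroid test).
#' A single mesh passes through with its exact metrics.
#'
#' @param meshes list of 1-3 `envelope_mesh` objects (convex).
#' @param voxel_pitch voxel edge for intersection estimation (um).
#' @return a one-row tibble: `surface`, `volume`, `sphericity`, `n_clusters`,
#'   `intersection_volume`.
#' @export
merge_cluster_meshes <- function(meshes, voxel_pitch = 0.02) {
  if (inherits(meshes, "envelope_mesh")) meshes <- list(meshes)
  stopifnot(length(meshes) >= 1, length(meshes) <= 3)
  mets <- lapply(meshes, mesh_metrics)
  if (length(meshes) == 1) {
    return(tibble::tibble(surface = mets[[1]]$surface, volume = mets[[1]]$volume,
                          sphericity = sphericity(mets[[1]]$surface, mets[[1]]$volume),
                          n_clusters = 1L, intersection_volume = 0))
  }
  bboxes <- lapply(meshes, function(m) apply(m$vertices, 2, range))
  pair_vol <- function(ids) {
    lo <- apply(sapply(ids, function(i) bboxes[[i]][1, ]), 1, max)
    hi <- apply(sapply(ids, function(i) bboxes[[i]][2, ]), 1, min)
    if (any(hi <= lo)) return(0)
    gx <- seq(lo[1] + voxel_pitch / 2, hi[1], by = voxel_pitch)
    gy <- seq(lo[2] + voxel_pitch / 2, hi[2], by = voxel_pitch)
    gz <- seq(lo[3] + voxel_pitch / 2, hi[3], by = voxel_pitch)
    if (!length(gx) || !length(gy) || !length(gz)) return(0)
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    inside <- rep(TRUE, nrow(pts))
    for (i in ids) {
      inside[inside] <- point_inside_convex(meshes[[i]], pts[inside, , drop = FALSE])
      if (!any(inside)) return(0)
    }
    sum(inside) * voxel_pitch^3
  }
  pairs <- utils::combn(length(meshes), 2, simplify = FALSE)
  v_pairs <- sum(vapply(pairs, pair_vol, 0))
  v_triple <- if (length(meshes) == 3) pair_vol(1:3) else 0
  v_int <- v_pairs - v_triple

  # buried surface: faces whose centroid lies inside another mesh
  s_buried <- 0
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    A <- m$vertices[m$triangles[, 1], , drop = FALSE]
    B <- m$vertices[m$triangles[, 2], , drop = FALSE]
    C <- m$vertices[m$triangles[, 3], , drop = FALSE]
    cent <- (A + B + C) / 3
    u <- B - A; w <- C - A
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    areas <- sqrt(rowSums(cr^2)) / 2
    buried <- rep(FALSE, nrow(cent))
    for (j in seq_along(meshes)) {
      if (j == i) next
      buried <- buried | point_inside_convex(meshes[[j]], cent)
    }
    s_buried <- s_buried + sum(areas[buried])
  }
  surface <- sum(vapply(mets, `[[`, 0, "surface")) - s_buried
  volume <- sum(vapply(mets, `[[`, 0, "volume")) - v_int
  tibble::tibble(surface = surface, volume = volume,
                 sphericity = sphericity(surface, volume),
                 n_clusters = length(meshes), intersection_volume = v_int)
}

#' Reconstruct and quantify nuclear envelopes for a population
#'
#' For each nucleus: choose the number of clusters (1-3), partition the NPC
#' detections, build each cluster's initial patch, refine it with the chosen
#' envelope model, and merge cluster meshes into whole-nucleus surface,
#' volume and sphericity.
#'
#' @param nuclei nested nuclei tibble (corrected detections).
#' @param model `"anchor"` (3D anchor-point model, default) or `"spline"`.
#' @param iterations refinement passes per cluster (default 3).
#' @param seed integer seed for the clustering restarts.
#' @param voxel_pitch intersection voxel pitch in um (see
#'   [merge_cluster_meshes()]).
#' @param keep_meshes if `TRUE`, attach a `meshes` list-column.
#' @param force_k fix the cluster count instead of selecting it per nucleus;
#'   `force_k = 1` is the treatment for populations known to be interphase
#'   (single-lobed), where automatic selection would occasionally split a
#'   spherical nucleus.
#' @return `nuclei` with added columns `k`, `surface`, `volume`, `sphericity`,
#'   `intersection_volume`, `model`, and cluster labels stored in each
#'   detections tibble as `cluster_id`.
#' @export
fit_envelopes <- function(nuclei, model = c("anchor", "spline"), iterations = 3,
                          seed = 1, voxel_pitch = 0.02, keep_meshes = FALSE,
                          force_k = NULL) {
  model <- match.arg(model)
  seeds <- derive_seeds(seed, max(1, nrow(nuclei)))
  nuclei$k <- NA_integer_
  nuclei$surface <- nuclei$volume <- nuclei$sphericity <- NA_real_
  nuclei$intersection_volume <- NA_real_
  nuclei$model <- model
  if (keep_meshes) nuclei$meshes <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    det <- nuclei$detections[[i]]
    P <- as_xyz_matrix(det)
    if (nrow(P) < 4) next
    k <- if (!is.null(force_k)) as.integer(force_k)
         else if (nrow(P) >= 12) choose_k(P, seed = seeds[i]) else 1L
    asg <- kmeans_cluster(P, k, seed = seeds[i])
    det$cluster_id <- asg$labels
    nuclei$detections[[i]] <- det
    meshes <- vector("list", k)
    ok <- TRUE
    for (cl in seq_len(k)) {
      Q <- P[asg$labels == cl, , drop = FALSE]
      m <- tryCatch({
        patch <- initial_patch(Q)
        if (model == "anchor") refine_anchor(patch, colMeans(Q), iterations)
        else refine_spline(patch, iterations)
      }, error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      meshes[[cl]] <- m
    }
    if (!ok) next
    geom <- merge_cluster_meshes(meshes, voxel_pitch = voxel_pitch)
    nuclei$k[i] <- k
    nuclei$surface[i] <- geom$surface
    nuclei$volume[i] <- geom$volume
    nuclei$sphericity[i] <- geom$sphericity
    nuclei$intersection_volume[i] <- geom$intersection_volume
    if (keep_meshes) nuclei$meshes[[i]] <- meshes
  }
  nuclei
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh an `envelope_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "envelope_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(t)
    sprintf("3 %d %d %d", t[1], t[2], t[3])), con)
  invisible(path)
}
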