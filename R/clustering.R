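#' k-means partition of a nucleus's detections
#'
#' Lloyd's algorithm with squared-Euclidean cost, 20 seeded random restarts
#' (best within-cluster sum of squares kept) plus, for k > 1, a deterministic
#' warm start derived from the best (k-1)-cluster solution — splitting off the
#' point farthest from its centroid — which makes the within-cluster sum of
#' squares non-increasing in k. Solutions with a cluster of fewer than
#' `min_size` members are rejected; if no restart yields a feasible solution
#' the requested k is declared infeasible. Results are bit-identical under a
#' fixed seed; cluster labels are ordered by centroid position.
#'
#' @param points matrix/tibble of detection positions (>= 4k rows).
#' @param k number of clusters, 1 to 3.
#' @param seed integer seed for the restart sequence.
#' @param n_init number of random restarts.
#' @param min_size minimum cluster membership (default 4, enough to anchor an
#'   envelope patch).
#' @return an object of class `npc_clusters`: `k`, `labels` (per point),
#'   `centroids` (tibble x, y, z, size), `within_ss` (total, um^2),
#'   `per_cluster_ss`.
#' @export
kmeans_cluster <- function(points, k, seed = 1, n_init = 20, min_size = 4) {
  P <- as_xyz_matrix(points)
  stopifnot(k >= 1, k <= 3, nrow(P) >= 4 * k)
  if (k == 1) {
    ctr <- colMeans(P)
    wss <- sum(sweep(P, 2, ctr)^2)
    return(structure(list(
      k = 1L, labels = rep(1L, nrow(P)),
      centroids = tibble::tibble(cluster = 1L, x = ctr[1], y = ctr[2],
                                 z = ctr[3], size = nrow(P)),
      within_ss = wss, per_cluster_ss = wss), class = "npc_clusters"))
  }

  run_lloyd <- function(centers) {
    km <- tryCatch(
      suppressWarnings(kmeans(P, centers = centers, iter.max = 100,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || any(km$size < min_size)) return(NULL)
    km
  }

  inits <- list()
  # warm start from the (k-1)-solution: guarantees monotone within_ss when valid
  prev <- tryCatch(kmeans_cluster(P, k - 1, seed = seed, n_init = n_init,
                                  min_size = min_size),
                   error = function(e) NULL)
  if (!is.null(prev)) {
    cent_prev <- as.matrix(prev$centroids[, c("x", "y", "z")])
    dists <- sqrt(rowSums((P - cent_prev[prev$labels, , drop = FALSE])^2))
    far <- which.max(dists)
    inits[[length(inits) + 1]] <- rbind(cent_prev, P[far, ])
  }
  seeds <- derive_seeds(seed, n_init)
  for (r in seq_len(n_init)) {
    set.seed(seeds[r])
    inits[[length(inits) + 1]] <- P[sample.int(nrow(P), k), , drop = FALSE]
  }

  best <- NULL
  for (init in inits) {
    if (anyDuplicated(init)) next
    km <- run_lloyd(init)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best))
    stop("infeasible k = ", k, ": no restart produced clusters of >= ",
         min_size, " members")

  ord <- order(best$centers[, 1], best$centers[, 2], best$centers[, 3])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[best$cluster]
  centers <- best$centers[ord, , drop = FALSE]
  sizes <- best$size[ord]
  structure(list(
    k = as.integer(k), labels = as.integer(labels),
    centroids = tibble::tibble(cluster = seq_len(k), x = centers[, 1],
                               y = centers[, 2], z = centers[, 3], size = sizes),
    within_ss = best$tot.withinss,
    per_cluster_ss = best$withinss[ord]), class = "npc_clusters")
}

#' @export
print.npc_clusters <- function(x, ...) {
  cat("<npc_clusters> k =", x$k, " within_ss =", signif(x$within_ss, 5), "um^2\n")
  print(x$centroids)
  invisible(x)
}

#' Choose the number of NPC clusters (1, 2 or 3)
#'
#' Interphase nuclei are fitted with a single cluster; mitotic dumbbells need
#' two and late-anaphase hourglass shapes three (lobes plus connecting tube).
#' Starting at k = 1, k+1 is accepted only if it reduces the within-cluster
#' sum of squares by more than the step's ratio threshold and its two nearest
#' centroids are more than `min_centroid_sep` apart. The 1 -> 2 ratio (2.0) is
#' calibrated so uniform spherical shells stay at k = 1 (splitting a shell in
#' half only reduces the sum of squares ~1.3-fold); the 2 -> 3 ratio (1.3) is
#' lower because isolating the thin anaphase tube removes fewer points — for
#' that step the centroid-separation guard carries the specificity, since
#' splitting a single lobe produces hemisphere centroids less than one lobe
#' radius apart.
#'
#' @param points matrix/tibble of >= 12 detection positions.
#' @param seed integer seed (shared with [kmeans_cluster()]).
#' @param ratio_threshold within_ss(k)/within_ss(k+1) needed to accept k+1;
#'   recycled to one value per step (k = 1 -> 2, 2 -> 3).
#' @param min_centroid_sep minimal distance between nearest centroids (um).
#' @return the chosen k as an integer.
#' @export
choose_k <- function(points, seed = 1, ratio_threshold = c(2.0, 1.3),
                     min_centroid_sep = 1.0) {
  P <- as_xyz_matrix(points)
  stopifnot(nrow(P) >= 12)
  ratio_threshold <- rep_len(ratio_threshold, 2)
  current <- kmeans_cluster(P, 1, seed = seed)
  for (k_next in 2:3) {
    if (nrow(P) < 4 * k_next) break
    cand <- tryCatch(kmeans_cluster(P, k_next, seed = seed),
                     error = function(e) NULL)
    if (is.null(cand)) break
    ratio <- if (cand$within_ss > 0) current$within_ss / cand$within_ss else Inf
    cen <- as.matrix(cand$centroids[, c("x", "y", "z")])
    min_sep <- min(dist(cen))
    if (ratio > ratio_threshold[k_next - 1] && min_sep > min_centroid_sep) {
      current <- cand
    } else break
  }
  current$k
}
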