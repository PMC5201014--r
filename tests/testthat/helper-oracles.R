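# small independent oracles shared across tests

# uniform unit-sphere directions, plain rejection-free Gaussian method
unit_sphere_points <- function(n) {
  g <- matrix(rnorm(3 * n), ncol = 3)
  g / sqrt(rowSums(g^2))
}

# brute-force 2D Gaussian KDE over an explicit point set (no reflection trick)
brute_kde <- function(s_eval, r_eval, pts_s, pts_r, h, w = NULL) {
  if (is.null(w)) w <- rep(1 / length(pts_s), length(pts_s))
  sum(w * dnorm(s_eval - pts_s, sd = h[1]) * dnorm(r_eval - pts_r, sd = h[2]))
}

# exhaustive best 2-partition of a tiny point set under the k-means cost
brute_best_2partition <- function(P) {
  n <- nrow(P)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (sum(lab) == 0 || sum(lab) == n) next
    cost <- 0
    for (g in 0:1) {
      Q <- P[lab == g, , drop = FALSE]
      cost <- cost + sum(sweep(Q, 2, colMeans(Q))^2)
    }
    best <- min(best, cost)
  }
  best
}

# normal-equations quadratic OLS (independent of lm)
quad_ols <- function(x, y) {
  X <- cbind(x^2, x, 1)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# nested nuclei tibble from a list of point sets with known centers
make_nuclei <- function(point_sets, centers, spb = NULL, nucleolus = NULL) {
  rows <- lapply(seq_along(point_sets), function(i) {
    det <- tibble::as_tibble(as.data.frame(point_sets[[i]]))
    names(det)[1:3] <- c("x", "y", "z")
    out <- tibble::tibble(
      nucleus_id = i, cell_id = sprintf("c%03d", i), timepoint = 0L,
      detections = list(det),
      center_x = centers[[i]][1], center_y = centers[[i]][2],
      center_z = centers[[i]][3])
    out$spb_x <- if (!is.null(spb)) spb[[i]][1] else NA_real_
    out$spb_y <- if (!is.null(spb)) spb[[i]][2] else NA_real_
    out$spb_z <- if (!is.null(spb)) spb[[i]][3] else NA_real_
    out$nucleolus_x <- if (!is.null(nucleolus)) nucleolus[[i]][1] else NA_real_
    out$nucleolus_y <- if (!is.null(nucleolus)) nucleolus[[i]][2] else NA_real_
    out$nucleolus_z <- if (!is.null(nucleolus)) nucleolus[[i]][3] else NA_real_
    out
  })
  dplyr::bind_rows(rows)
}
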