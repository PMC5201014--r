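#' Select round nuclei for aberration calibration
#'
#' The axial-aberration model must be fitted on nuclei that are truly
#' spherical, so that any apparent axial elongation is optical rather than
#' biological. Because the axial coordinate is biased before correction,
#' roundness is judged laterally only: the x-y covariance ellipse of a
#' nucleus's detections must have an axis ratio at most `eccentricity_max`,
#' and the detections must form a single k-means cluster (no dumbbells).
#'
#' The raw eigenvalue ratio of a sample covariance overestimates the true
#' axis ratio at the few dozen detections typical of one nucleus (the
#' orientation of the fitted ellipse adapts to the noise), so the estimate is
#' divided by a finite-sample calibration factor `1 + 2.6 n^(-0.67)` derived
#' from the Monte-Carlo null (points uniform on a sphere) before it is
#' compared with `eccentricity_max`.
#'
#' @param nuclei nested nuclei tibble.
#' @param eccentricity_max maximal lateral axis ratio (default 1.15).
#' @param seed seed forwarded to the cluster-number selection.
#' @return the subset of `nuclei` judged round.
#' @export
select_round_nuclei <- function(nuclei, eccentricity_max = 1.15, seed = 1) {
  seeds <- derive_seeds(seed, max(1, nrow(nuclei)))
  keep <- vapply(seq_len(nrow(nuclei)), function(i) {
    det <- nuclei$detections[[i]]
    P <- as_xyz_matrix(det)
    if (nrow(P) < 8) return(FALSE)
    ev <- eigen(stats::cov(P[, 1:2]), symmetric = TRUE, only.values = TRUE)$values
    ecc <- sqrt(ev[1] / max(ev[2], 1e-12)) / (1 + 2.6 * nrow(P)^(-0.67))
    if (ev[2] <= 0 || ecc > eccentricity_max) return(FALSE)
    if (nrow(P) >= 12 && choose_k(P, seed = seeds[i]) > 1) return(FALSE)
    TRUE
  }, logical(1))
  nuclei[keep, ]
}

#' Pool normalized radial samples from a set of nuclei
#'
#' For each nucleus, R is the mean center-to-detection distance; each
#' detection contributes a sample with normalized absolute axial coordinate
#' x = |z - z_center| / R and normalized radial distance d/R. Pooling these
#' over many round nuclei exposes the axial elongation as a trend of d/R
#' with x.
#'
#' @param nuclei nested nuclei tibble (pre-filtered to round nuclei for
#'   calibration fits).
#' @return tibble with `nucleus_id`, `x`, `d_over_R`.
#' @export
compute_samples <- function(nuclei) {
  rows <- purrr::map(seq_len(nrow(nuclei)), function(i) {
    P <- as_xyz_matrix(nuclei$detections[[i]])
    ctr <- c(nuclei$center_x[i], nuclei$center_y[i], nuclei$center_z[i])
    d <- sqrt(colSums((t(P) - ctr)^2))
    R <- mean(d)
    if (R <= 0) {
      warning("nucleus ", nuclei$nucleus_id[i], " has zero mean radius; skipped",
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(nucleus_id = nuclei$nucleus_id[i],
                   x = abs(P[, 3] - ctr[3]) / R,
                   d_over_R = d / R)
  })
  dplyr::bind_rows(rows)
}

#' Fit the axial-aberration polynomial
#'
#' Ordinary least squares of d/R on (x^2, x, 1): the normalized radial
#' distance of detections as a second-degree polynomial of the normalized
#' axial coordinate. On an unaberrated spherical population the curve is flat
#' at 1; refractive-index mismatch bends it upward with x.
#'
#' @param samples tibble from [compute_samples()] (columns `x`, `d_over_R`),
#'   or any data frame with those columns.
#' @return an object of class `aberration_model` with elements `a`, `b`, `c`
#'   (quadratic/linear/constant coefficients), `se` (their standard errors),
#'   `rmse`, `n_points`.
#' @export
fit_aberration <- function(samples) {
  stopifnot(all(c("x", "d_over_R") %in% names(samples)))
  if (diff(range(samples$x)) < 0.5)
    stop("x range too narrow (< 0.5): the polynomial fit is ill-conditioned")
  if (nrow(samples) < 100)
    warning("fewer than 100 samples; population fit is unreliable", call. = FALSE)
  fit <- lm(d_over_R ~ I(x^2) + x, data = samples)
  cf <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(a = unname(cf["I(x^2)"]), b = unname(cf["x"]),
                 c = unname(cf["(Intercept)"]),
                 se = c(a = unname(se["I(x^2)"]), b = unname(se["x"]),
                        c = unname(se["(Intercept)"])),
                 rmse = sqrt(mean(fit$residuals^2)),
                 n_points = nrow(samples)),
            class = "aberration_model")
}

#' @export
print.aberration_model <- function(x, ...) {
  cat(sprintf("<aberration_model> d/R = %.4g x^2 + %.4g x + %.4g  (rmse %.4g, n %d)\n",
              x$a, x$b, x$c, x$rmse, x$n_points))
  invisible(x)
}

#' @export
predict.aberration_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$a * x^2 + object$b * x + object$c
}

#' Serialize / load an aberration model as JSON
#'
#' @param model an `aberration_model`.
#' @param path output (input) file path.
#' @param instrument free-text tag identifying the optical configuration.
#' @return `write_aberration_model` returns `path` invisibly;
#'   `read_aberration_model` returns the model.
#' @export
write_aberration_model <- function(model, path, instrument = "unspecified") {
  jsonlite::write_json(
    list(a = model$a, b = model$b, c = model$c, rmse = model$rmse,
         n_points = model$n_points, instrument = instrument),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aberration_model
#' @export
read_aberration_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = j$a, b = j$b, c = j$c, se = c(a = NA, b = NA, c = NA),
                 rmse = j$rmse, n_points = j$n_points),
            class = "aberration_model")
}

#' Correct detections for axial aberration
#'
#' Applies d_corrected/R = d/R - (a x^2 + b x) to every NPC detection of every
#' nucleus: lateral (x, y) offsets are kept bit-identical and the axial offset
#' is rescaled so the center distance equals the corrected one. Where the
#' corrected distance falls below the lateral offset the axial offset is
#' clamped to 0 (counted); a non-positive corrected distance drops the
#' detection with a warning. Nuclear centers are recomputed afterwards. The
#' model is fitted on the round subpopulation but applies to every nucleus.
#'
#' @param nuclei nested nuclei tibble.
#' @param model an `aberration_model`.
#' @return corrected `nuclei` with recomputed centers and a
#'   `correction_report` attribute (`n_clamped`, `n_dropped`).
#' @export
correct_detections <- function(nuclei, model) {
  stopifnot(inherits(model, "aberration_model"))
  n_clamped <- 0L; n_dropped <- 0L
  for (i in seq_len(nrow(nuclei))) {
    det <- nuclei$detections[[i]]
    P <- as_xyz_matrix(det)
    ctr <- c(nuclei$center_x[i], nuclei$center_y[i], nuclei$center_z[i])
    off <- sweep(P, 2, ctr)
    d <- sqrt(rowSums(off^2))
    R <- mean(d)
    x <- abs(off[, 3]) / R
    d_corr <- d - (model$a * x^2 + model$b * x) * R
    drop <- d_corr <= 0
    if (any(drop)) {
      warning(sum(drop), " detection(s) dropped: corrected distance <= 0",
              call. = FALSE)
      n_dropped <- n_dropped + sum(drop)
    }
    lat2 <- off[, 1]^2 + off[, 2]^2
    clamp <- !drop & (d_corr^2 < lat2)
    n_clamped <- n_clamped + sum(clamp)
    dz_new <- sign(off[, 3]) * sqrt(pmax(d_corr^2 - lat2, 0))
    zcol <- if ("z_um" %in% names(det)) "z_um" else "z"
    det[[zcol]] <- ctr[3] + dz_new
    det <- det[!drop, ]
    nuclei$detections[[i]] <- det
    # the SPB spot sits in the same envelope and suffers the same aberration
    if (all(c("spb_x", "spb_y", "spb_z") %in% names(nuclei)) &&
        is.finite(nuclei$spb_z[i])) {
      so <- c(nuclei$spb_x[i], nuclei$spb_y[i], nuclei$spb_z[i]) - ctr
      sd_ <- vec3_norm(so)
      sx <- abs(so[3]) / R
      sdc <- sd_ - (model$a * sx^2 + model$b * sx) * R
      slat2 <- so[1]^2 + so[2]^2
      nuclei$spb_z[i] <- ctr[3] + sign(so[3]) * sqrt(max(sdc^2 - slat2, 0))
    }
    Pn <- as_xyz_matrix(det)
    nuclei$center_x[i] <- mean(Pn[, 1])
    nuclei$center_y[i] <- mean(Pn[, 2])
    nuclei$center_z[i] <- mean(Pn[, 3])
  }
  attr(nuclei, "correction_report") <- list(n_clamped = n_clamped,
                                            n_dropped = n_dropped)
  nuclei
}
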