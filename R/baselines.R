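#' SART configuration
#'
#' Defaults follow the benchmark settings: 40 iterations, relaxation 0.15.
#'
#' @param n_iterations Number of full SART sweeps (>= 1).
#' @param relaxation Relaxation parameter in (0, 2).
#' @return Object of class `sart_config`.
#' @export
sart_config <- function(n_iterations = 40L, relaxation = 0.15) {
  if (n_iterations < 1) stop_config("n_iterations must be >= 1")
  if (relaxation <= 0 || relaxation >= 2)
    stop_config("relaxation must be in (0, 2)")
  structure(list(n_iterations = as.integer(n_iterations),
                 relaxation = relaxation), class = "sart_config")
}

#' Simultaneous algebraic reconstruction (SART)
#'
#' Iterates the relaxed correction
#' \eqn{x \leftarrow x + \lambda \, C^{-1} A^T R^{-1} (y - A x)} where
#' \eqn{R = A\mathbf{1}} (ray weight sums) and \eqn{C = A^T\mathbf{1}}
#' (pixel weight sums), back-projecting the residual of *all* views
#' simultaneously, with a non-negativity clamp after every sweep. Starts
#' from a zero image. A warning is emitted if the projection residual norm
#' grows for five consecutive sweeps.
#'
#' @param sino Sinogram matrix.
#' @param geom A [projection_geometry()].
#' @param cfg A [sart_config()].
#' @return Reconstructed image matrix (non-negative).
#' @export
sart_reconstruct <- function(sino, geom, cfg = sart_config()) {
  check_sinogram(sino, geom)
  res <- cpp_sart(sino, geom$angles, geom$image_size, geom$detector_spacing,
                  cfg$n_iterations, cfg$relaxation)
  rn <- res$residual_norm
  if (length(rn) >= 6) {
    up <- diff(rn) > 0
    run <- rle(up)
    if (any(run$lengths[run$values] >= 5))
      warning("SART residual increased for 5 consecutive iterations; ",
              "possible divergence (relaxation too large?)")
  }
  res$image
}

#' Isotropic total variation of an image
#'
#' Sum over pixels of the Euclidean norm of the forward-difference gradient.
#'
#' @param image Numeric matrix.
#' @return Non-negative scalar.
#' @export
total_variation <- function(image) {
  gx <- rbind(diff(image), 0)
  gy <- cbind(t(diff(t(image))), 0)
  sum(sqrt(gx^2 + gy^2))
}

grad_xy <- function(u) {
  list(x = rbind(diff(u), 0), y = cbind(t(diff(t(u))), 0))
}

div_p <- function(px, py) {
  nr <- nrow(px); nc <- ncol(px)
  dx <- px - rbind(0, px[-nr, , drop = FALSE]); dx[nr, ] <- -px[nr - 1, ]
  dy <- py - cbind(0, py[, -nc, drop = FALSE]); dy[, nc] <- -py[, nc - 1]
  dx + dy
}

#' Total-variation denoising (Rudin-Osher-Fatemi)
#'
#' Solves \eqn{\arg\min_u \tfrac12\|u - f\|_2^2 + w \cdot TV(u)} with
#' Chambolle's dual projection algorithm (step 0.25, at most `max_iter`
#' iterations, stopping when the dual variable changes by less than `tol`
#' in max norm). The benchmark weight is 0.9 under this parameterization.
#'
#' @param image Input image matrix \eqn{f}.
#' @param weight TV weight \eqn{w \ge 0}; 0 returns the input unchanged.
#' @param max_iter Iteration cap (default 200).
#' @param tol Stopping tolerance on the dual update (default 1e-4).
#' @return Denoised image, same shape.
#' @export
tv_denoise <- function(image, weight = 0.9, max_iter = 200L, tol = 1e-4) {
  check_finite_matrix(image, "image")
  if (weight < 0) stop_invalid("weight must be >= 0")
  if (weight == 0) return(image)
  tau <- 0.25
  px <- matrix(0, nrow(image), ncol(image))
  py <- px
  f_w <- image / weight
  for (k in seq_len(max_iter)) {
    u <- div_p(px, py) - f_w
    g <- grad_xy(u)
    denom <- 1 + tau * sqrt(g$x^2 + g$y^2)
    px_new <- (px + tau * g$x) / denom
    py_new <- (py + tau * g$y) / denom
    delta <- max(abs(px_new - px), abs(py_new - py))
    px <- px_new; py <- py_new
    if (delta < tol) break
  }
  image - weight * div_p(px, py)
}

#' SART followed by TV denoising
#'
#' The classical regularized pipeline used as a baseline: a SART
#' reconstruction post-processed with [tv_denoise()].
#'
#' @inheritParams sart_reconstruct
#' @param tv_weight TV weight (default 0.9).
#' @return Reconstructed image matrix.
#' @export
sart_tv_reconstruct <- function(sino, geom, cfg = sart_config(),
                                tv_weight = 0.9) {
  tv_denoise(sart_reconstruct(sino, geom, cfg), tv_weight)
}
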