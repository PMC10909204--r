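#' Parallel-beam projection geometry
#'
#' Describes the discrete forward operator used throughout the package: a
#' parallel-beam Radon transform with `n_views` angles uniformly spaced over
#' the half-open interval \eqn{[0, \pi)} and `n_detectors` bins per view.
#' Angle 0 corresponds to rays parallel to the image columns; detectors are
#' centred on the image centre and spaced in units of the image pixel width.
#'
#' The default arguments reproduce the sparse-view acquisition used for the
#' benchmark experiments: 512x512 images, 64 views, 512 detector bins.
#'
#' @param image_size Pixels per side of the (square) image.
#' @param n_views Number of projection angles.
#' @param n_detectors Detector bins per view.
#' @param detector_spacing Detector pitch in units of image pixel width.
#' @return An object of class `projection_geometry` with fields
#'   `image_size`, `n_views`, `n_detectors`, `angles` (radians) and
#'   `detector_spacing`.
#' @examples
#' geom <- projection_geometry(128, n_views = 64, n_detectors = 128)
#' sino <- radon_forward(shepp_logan(128), geom)
#' @export
projection_geometry <- function(image_size = 512, n_views = 64,
                                n_detectors = 512, detector_spacing = 1.0) {
  if (image_size < 1 || n_views < 1 || n_detectors < 1)
    stop_invalid("image_size, n_views and n_detectors must all be >= 1")
  if (!is.finite(detector_spacing) || detector_spacing <= 0)
    stop_invalid("detector_spacing must be positive")
  angles <- seq(0, pi, length.out = n_views + 1L)[seq_len(n_views)]
  structure(list(image_size = as.integer(image_size),
                 n_views = as.integer(n_views),
                 n_detectors = as.integer(n_detectors),
                 angles = angles,
                 detector_spacing = detector_spacing),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("parallel-beam geometry: %d x %d image, %d views over [0, pi), %d detectors (pitch %g px)\n",
              x$image_size, x$image_size, x$n_views, x$n_detectors,
              x$detector_spacing))
  invisible(x)
}

check_image <- function(image, geom) {
  check_finite_matrix(image, "image")
  if (nrow(image) != geom$image_size || ncol(image) != geom$image_size)
    stop_invalid("image is ", nrow(image), "x", ncol(image),
                 " but geometry expects ", geom$image_size, "x", geom$image_size)
  invisible(image)
}

check_sinogram <- function(sino, geom) {
  check_finite_matrix(sino, "sinogram")
  if (nrow(sino) != geom$n_views || ncol(sino) != geom$n_detectors)
    stop_invalid("sinogram is ", nrow(sino), "x", ncol(sino),
                 " but geometry expects ", geom$n_views, "x", geom$n_detectors)
  invisible(sino)
}

#' Discrete Radon transform (forward projection)
#'
#' Computes line integrals of `image` along parallel rays for every
#' (angle, detector) pair of `geom`, using a pixel-driven splat with linear
#' detector interpolation. The operator is linear in the image, and
#' [back_project()] is its exact matrix transpose, which is what makes the
#' self-supervised projection loss differentiable: the gradient of any
#' sinogram-domain loss is pulled back to the image with `back_project()`.
#'
#' @param image Numeric matrix, `image_size` x `image_size`.
#' @param geom A [projection_geometry()].
#' @return Sinogram matrix, `n_views` x `n_detectors` (line-integral units,
#'   one image pixel width per step).
#' @export
radon_forward <- function(image, geom) {
  check_image(image, geom)
  cpp_radon(image, geom$angles, geom$n_detectors, geom$detector_spacing)
}

#' Backprojection (adjoint of the forward projector)
#'
#' Smears each view back across the image with the same interpolation
#' weights used by [radon_forward()], so that
#' \eqn{\langle A x, y \rangle = \langle x, A^T y \rangle} holds to floating
#' precision. No angular normalisation is applied; [fbp_reconstruct()] adds
#' the \eqn{\pi / n_{views}} quadrature factor.
#'
#' @param sino Sinogram matrix, `n_views` x `n_detectors`.
#' @param geom A [projection_geometry()].
#' @return Image matrix, `image_size` x `image_size`.
#' @export
back_project <- function(sino, geom) {
  check_sinogram(sino, geom)
  cpp_backproject(sino, geom$angles, geom$image_size, geom$detector_spacing)
}

# Band-limited ramp filter kernel (spatial domain), detector pitch d.
ramp_kernel_fft <- function(L, d) {
  off <- 0:(L - 1L)
  off[off > L / 2] <- off[off > L / 2] - L
  h <- numeric(L)
  h[off == 0] <- 1 / (4 * d^2)
  odd <- off %% 2L != 0L
  h[odd] <- -1 / (pi^2 * off[odd]^2 * d^2)
  Re(stats::fft(h))
}

#' Filtered back projection
#'
#' Ramp-filters each view along the detector axis (FFT convolution with the
#' band-limited ramp kernel) and backprojects with angular weight
#' \eqn{\pi / n_{views}}. Pixels beyond the field of view covered by the
#' detector array (outside the circle of radius
#' `n_detectors * detector_spacing / 2`) are unmeasured and set to zero,
#' following standard inverse-Radon practice for circle geometries. Output
#' values are not clipped; metric functions decide the data range.
#'
#' @param sino Sinogram matrix.
#' @param geom A [projection_geometry()].
#' @param filter_name Reconstruction filter; only `"ramp"` is available.
#' @return Reconstructed image matrix.
#' @export
fbp_reconstruct <- function(sino, geom, filter_name = "ramp") {
  check_sinogram(sino, geom)
  if (!identical(filter_name, "ramp"))
    stop_config("unknown FBP filter: '", filter_name, "' (available: 'ramp')")
  nd <- geom$n_detectors
  L <- 2L^ceiling(log2(max(2L * nd, 8L)))
  H <- ramp_kernel_fft(L, geom$detector_spacing)
  # columns of P are single views, zero-padded to L
  P <- matrix(0, L, geom$n_views)
  P[seq_len(nd), ] <- t(sino)
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / L
  filtered <- t(Q[seq_len(nd), , drop = FALSE]) * geom$detector_spacing
  img <- back_project(filtered, geom) * (pi / geom$n_views)
  img * fov_mask(geom)
}

# 1 inside the detector field of view, 0 outside (all-1 when the detector
# array covers the whole image).
fov_mask <- function(geom) {
  n <- geom$image_size
  r <- geom$n_detectors * geom$detector_spacing / 2
  if (r^2 >= 2 * ((n - 1) / 2)^2) return(matrix(1, n, n))
  c0 <- (n + 1) / 2
  d2 <- (row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2
  (d2 <= r^2) * 1
}
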