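#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(range^2 / MSE)} in dB; `Inf` when the images are
#' identical. Symmetric in its arguments.
#'
#' @param reference,test Numeric matrices of equal shape.
#' @param data_range Value range of the data (default 1 for images in
#'   \eqn{[0, 1]}).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = 1.0) {
  if (!all(dim(reference) == dim(test)))
    stop_invalid("reference and test must have the same shape")
  if (data_range <= 0) stop_invalid("data_range must be > 0")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Valid-region separable filtering: (H-size+1) x (W-size+1) output.
filter_valid <- function(x, k) {
  n <- length(k)
  H <- nrow(x); W <- ncol(x)
  Gh <- matrix(0, H - n + 1L, H)
  for (i in seq_len(nrow(Gh))) Gh[i, i:(i + n - 1L)] <- k
  Gw <- matrix(0, W - n + 1L, W)
  for (i in seq_len(nrow(Gw))) Gw[i, i:(i + n - 1L)] <- k
  Gh %*% x %*% t(Gw)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (\eqn{\sigma = 1.5}) and
#' the standard constants \eqn{K_1 = 0.01}, \eqn{K_2 = 0.03}; local
#' statistics are Gaussian-weighted population moments and the mean is taken
#' over the interior region where the window fits entirely.
#'
#' @param reference,test Numeric matrices of equal shape (at least 11x11).
#' @param data_range Value range of the data (default 1).
#' @return SSIM in \eqn{[-1, 1]}; exactly 1 for identical images.
#' @export
ssim <- function(reference, test, data_range = 1.0) {
  if (!all(dim(reference) == dim(test)))
    stop_invalid("reference and test must have the same shape")
  if (min(dim(reference)) < 11)
    stop_invalid("images must be at least 11x11 for the SSIM window")
  k <- gaussian_kernel_1d(11L, 1.5)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_x <- filter_valid(reference, k)
  mu_y <- filter_valid(test, k)
  sxx <- filter_valid(reference^2, k) - mu_x^2
  syy <- filter_valid(test^2, k) - mu_y^2
  sxy <- filter_valid(reference * test, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Extract a 1-D intensity profile
#'
#' Returns the exact pixel values along one row or column, as used for
#' profile plots comparing reconstructions against ground truth.
#'
#' @param image Numeric matrix.
#' @param axis `"row"` or `"col"`.
#' @param index 1-based line index.
#' @return Numeric vector.
#' @export
line_profile <- function(image, axis = c("row", "col"), index) {
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(image) else ncol(image)
  if (index < 1 || index > n)
    stop_invalid("index ", index, " out of range for axis '", axis,
                 "' of length ", n)
  if (axis == "row") image[index, ] else image[, index]
}

#' Evaluate reconstructions against references
#'
#' Computes per-image and summary PSNR/SSIM for a set of reconstructions.
#' Reconstructions are clipped to \eqn{[0, 1]} before metric computation
#' (recorded in the report); references are assumed already in range.
#'
#' @param references,reconstructions Lists of image matrices, same length.
#' @param method Method label recorded in the report.
#' @param noise_db Noise level label (dB) recorded in the report.
#' @param data_range Metric data range (default 1).
#' @param clip Clip reconstructions into \eqn{[0, 1]} first (default `TRUE`).
#' @return Object of class `evaluation_report`: `per_image` data frame and
#'   `summary` (mean and sd of each metric).
#' @export
evaluate_reconstructions <- function(references, reconstructions,
                                     method = "method", noise_db = NA_real_,
                                     data_range = 1.0, clip = TRUE) {
  if (length(references) != length(reconstructions))
    stop_invalid("references and reconstructions must have equal length")
  rows <- lapply(seq_along(references), function(i) {
    rec <- reconstructions[[i]]
    if (clip) rec <- pmin(pmax(rec, 0), data_range)
    data.frame(image = i,
               psnr = psnr(references[[i]], rec, data_range),
               ssim = ssim(references[[i]], rec, data_range))
  })
  per_image <- do.call(rbind, rows)
  structure(list(
    method = method, noise_db = noise_db, clip = clip,
    per_image = per_image,
    summary = data.frame(method = method, noise_db = noise_db,
                         n = nrow(per_image),
                         psnr_mean = mean(per_image$psnr),
                         psnr_sd = sd(per_image$psnr),
                         ssim_mean = mean(per_image$ssim),
                         ssim_sd = sd(per_image$ssim))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s (%s dB, n = %d): PSNR %.2f +/- %.2f dB, SSIM %.3f +/- %.3f\n",
              s$method, format(s$noise_db), s$n, s$psnr_mean, s$psnr_sd,
              s$ssim_mean, s$ssim_sd))
  invisible(x)
}
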