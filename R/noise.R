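#' Sinogram noise model
#'
#' Additive white Gaussian measurement noise at a target signal-to-noise
#' ratio defined on the whole sinogram: the noise variance is
#' \eqn{\sigma^2 = P_{signal} \cdot 10^{-SNR_{dB}/10}} where
#' \eqn{P_{signal}} is the mean squared sinogram value. `snr_db = Inf`
#' (configuration value "none") disables the noise.
#'
#' @param snr_db Target SNR in decibels (may be `Inf`).
#' @param seed Integer seed making the draw reproducible.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(snr_db = 33, seed = 1L) {
  if (is.character(snr_db) && identical(snr_db, "none")) snr_db <- Inf
  if (is.na(snr_db) || (!is.finite(snr_db) && snr_db < 0))
    stop_invalid("snr_db must be a finite number or Inf")
  structure(list(snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_model")
}

#' Contaminate a sinogram with white Gaussian noise at a target SNR
#'
#' @param sino Sinogram matrix with non-zero signal power.
#' @param model A [noise_model()].
#' @return Noisy sinogram of the same shape; identical to the input when
#'   `model$snr_db` is infinite.
#' @examples
#' geom <- projection_geometry(64, 32, 64)
#' y <- radon_forward(shepp_logan(64), geom)
#' yn <- add_noise_snr(y, noise_model(30, seed = 7))
#' @export
add_noise_snr <- function(sino, model) {
  check_finite_matrix(sino, "sinogram")
  if (!inherits(model, "noise_model")) stop_invalid("model must be a noise_model")
  if (is.infinite(model$snr_db)) return(sino)
  p_signal <- mean(sino^2)
  if (p_signal <= 0) stop_invalid("sinogram has zero signal power")
  sigma <- sqrt(p_signal * 10^(-model$snr_db / 10))
  noise <- with_seed(model$seed,
                     matrix(rnorm(length(sino), sd = sigma), nrow(sino)))
  sino + noise
}
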