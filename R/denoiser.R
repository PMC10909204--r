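#' Denoiser network configuration
#'
#' Describes the convolutional encoder-decoder \eqn{f_\theta} used to denoise
#' FBP reconstructions. The full-scale architecture is a five-scale U-shaped
#' network whose channel width doubles per scale (64, 128, 256, 512, 1024);
#' at desk scale much smaller presets are used. Each scale applies two 3x3
#' convolutions with ReLU; 2x max pooling between encoder scales; the decoder
#' mirrors the encoder with nearest-neighbour upsampling, a 3x3 "up"
#' convolution and concatenation skip connections; a final linear 1x1
#' convolution maps back to one channel. The degenerate `n_scales = 0`
#' configuration is a single 1x1 convolution (2 parameters).
#'
#' @param n_scales Number of scales (0 allowed as the degenerate case).
#' @param base_channels Channels at the first scale; doubles per scale.
#' @param seed Integer seed for deterministic weight initialization.
#' @param residual If `TRUE` the network output is input + correction
#'   (ablation flag; the default follows the direct-denoising formulation).
#' @param standardize If `TRUE` (default) the network operates on a
#'   per-image standardized input (zero mean, unit variance) and its output
#'   is restored with the same affine map. This keeps activations at the
#'   scale the He initialization assumes regardless of the brightness of the
#'   FBP input, and is transparent at the interface: `denoise()` still maps
#'   image to image.
#' @return Object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_scales = 5L, base_channels = 64L, seed = 1L,
                            residual = FALSE, standardize = TRUE) {
  if (n_scales < 0 || base_channels < 1)
    stop_config("n_scales must be >= 0 and base_channels >= 1")
  structure(list(n_scales = as.integer(n_scales),
                 base_channels = as.integer(base_channels),
                 in_channels = 1L, out_channels = 1L,
                 seed = as.integer(seed), residual = isTRUE(residual),
                 standardize = isTRUE(standardize)),
            class = "denoiser_config")
}

# per-image affine normalization used when config$standardize is TRUE;
# the scale is treated as a constant in backpropagation
input_stats <- function(d, image) {
  if (!isTRUE(d$config$standardize)) return(list(m = 0, s = 1))
  s <- stats::sd(image)
  list(m = mean(image), s = if (is.finite(s) && s > 1e-8) s else 1)
}

#' Desk-scale denoiser preset
#'
#' A reduced configuration (4 scales, 16 base channels) sized for CPU
#' experimentation on 128x128 images.
#'
#' @param seed Integer seed.
#' @inheritParams denoiser_config
#' @return A [denoiser_config()].
#' @export
denoiser_config_desk <- function(seed = 1L, n_scales = 4L, base_channels = 16L) {
  denoiser_config(n_scales = n_scales, base_channels = base_channels,
                  seed = seed)
}

# Named list of layer shapes: each entry c(kernel, cin, cout).
denoiser_layer_shapes <- function(cfg) {
  S <- cfg$n_scales
  shapes <- list()
  if (S == 0) {
    shapes[["final"]] <- c(1L, 1L, 1L)
    return(shapes)
  }
  ch <- cfg$base_channels * 2L^(seq_len(S) - 1L)
  for (s in seq_len(S)) {
    cin <- if (s == 1) cfg$in_channels else ch[s - 1]
    shapes[[sprintf("enc%d.conv1", s)]] <- c(3L, cin, ch[s])
    shapes[[sprintf("enc%d.conv2", s)]] <- c(3L, ch[s], ch[s])
  }
  for (s in rev(seq_len(S - 1))) {
    shapes[[sprintf("dec%d.up", s)]] <- c(3L, ch[s + 1], ch[s])
    shapes[[sprintf("dec%d.conv1", s)]] <- c(3L, 2L * ch[s], ch[s])
    shapes[[sprintf("dec%d.conv2", s)]] <- c(3L, ch[s], ch[s])
  }
  shapes[["final"]] <- c(1L, ch[1], cfg$out_channels)
  shapes
}

#' Build a denoiser with randomly initialized weights
#'
#' He-style initialization (`sd = sqrt(2 / fan_in)`, zero biases), fully
#' reproducible from `config$seed`.
#'
#' @param config A [denoiser_config()].
#' @return Object of class `denoiser` holding the configuration and the
#'   trainable parameters.
#' @export
build_denoiser <- function(config) {
  if (!inherits(config, "denoiser_config"))
    stop_config("config must be a denoiser_config")
  shapes <- denoiser_layer_shapes(config)
  params <- with_seed(config$seed, {
    out <- list()
    for (nm in names(shapes)) {
      k <- shapes[[nm]][1]; cin <- shapes[[nm]][2]; cout <- shapes[[nm]][3]
      fan_in <- k * k * cin
      out[[paste0(nm, ".W")]] <-
        matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
      out[[paste0(nm, ".b")]] <- numeric(cout)
    }
    out
  })
  structure(list(config = config, params = params), class = "denoiser")
}

#' Identity denoiser
#'
#' The degenerate 0-scale network with its single 1x1 convolution fixed to
#' weight 1 and bias 0, so `denoise()` returns its input unchanged. Useful
#' as an ablation and for testing the inference path.
#'
#' @return A `denoiser`.
#' @export
identity_denoiser <- function() {
  d <- build_denoiser(denoiser_config(n_scales = 0L, base_channels = 1L,
                                      standardize = FALSE))
  d$params[["final.W"]][] <- 1
  d$params[["final.b"]][] <- 0
  d
}

#' Number of trainable parameters
#'
#' @param d A `denoiser`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(d) {
  if (!inherits(d, "denoiser")) stop_invalid("d must be a denoiser")
  sum(vapply(d$params, length, integer(1)))
}

#' @export
print.denoiser <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("encoder-decoder denoiser: %d scales, base %d channels, %s parameters\n",
              cfg$n_scales, cfg$base_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

# Forward pass on a (H*W) x 1 plane matrix. Returns list(out, cache).
# The 3x3 convolutions run through fused C++ kernels with persistent
# per-layer workspaces (im2col buffers, ReLU masks); a backward pass must
# therefore directly follow its forward pass, with no other forward of the
# same layer in between — which the training loops guarantee.
net_forward <- function(den, x, H, W, want_cache = FALSE) {
  p <- den$params
  S <- den$config$n_scales
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  conv3 <- function(name, a, h, w, relu = TRUE) {
    cpp_conv3_fwd(name, a, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]],
                  h, w, relu, want_cache)
  }
  cur <- x; h <- H; w <- W
  if (S == 0) {
    z <- add_bias(cur %*% p[["final.W"]], p[["final.b"]])
    if (want_cache) cache[["final"]] <- list(cols = cur)
    return(list(out = z, cache = cache))
  }
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    cur <- conv3(sprintf("enc%d.conv1", s), cur, h, w)
    cur <- conv3(sprintf("enc%d.conv2", s), cur, h, w)
    if (s < S) {
      skips[[s]] <- cur
      pl <- cpp_maxpool2(cur, h, w)
      if (want_cache) cache[[sprintf("pool%d", s)]] <- list(index = pl$index,
                                                           h = h, w = w)
      cur <- pl$values
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  for (s in rev(seq_len(S - 1))) {
    up <- cpp_upsample2(cur, h, w)
    if (want_cache) cache[[sprintf("ups%d", s)]] <- list(h = h, w = w)
    h <- 2L * h; w <- 2L * w
    up <- conv3(sprintf("dec%d.up", s), up, h, w)
    cur <- cbind(skips[[s]], up)
    cur <- conv3(sprintf("dec%d.conv1", s), cur, h, w)
    cur <- conv3(sprintf("dec%d.conv2", s), cur, h, w)
  }
  z <- add_bias(cur %*% p[["final.W"]], p[["final.b"]])
  if (want_cache) cache[["final"]] <- list(cols = cur)
  list(out = z, cache = cache)
}

# Backward pass. dout: gradient w.r.t. the network output, (H*W) x 1.
# Returns a named list of parameter gradients (same names as den$params).
net_backward <- function(den, cache, dout, H, W) {
  p <- den$params
  S <- den$config$n_scales
  grads <- list()
  conv3_bwd <- function(name, d) {
    bw <- cpp_conv3_bwd(name, d, p[[paste0(name, ".W")]])
    grads[[paste0(name, ".W")]] <<- bw$dW
    grads[[paste0(name, ".b")]] <<- as.numeric(bw$db)
    bw$dx
  }
  if (S == 0) {
    cc <- cache[["final"]]
    grads[["final.W"]] <- crossprod(cc$cols, dout)
    grads[["final.b"]] <- colSums(dout)
    return(grads)
  }
  ch <- den$config$base_channels * 2L^(seq_len(S) - 1L)
  cc <- cache[["final"]]
  grads[["final.W"]] <- crossprod(cc$cols, dout)
  grads[["final.b"]] <- colSums(dout)
  d <- dout %*% t(p[["final.W"]])
  dskips <- vector("list", S)
  for (s in seq_len(S - 1)) {
    d <- conv3_bwd(sprintf("dec%d.conv2", s), d)
    d <- conv3_bwd(sprintf("dec%d.conv1", s), d)
    dskips[[s]] <- d[, seq_len(ch[s]), drop = FALSE]
    dup <- d[, ch[s] + seq_len(ch[s]), drop = FALSE]
    dup <- conv3_bwd(sprintf("dec%d.up", s), dup)
    uc <- cache[[sprintf("ups%d", s)]]
    d <- cpp_upsample2_backward(dup, uc$h, uc$w)
  }
  for (s in rev(seq_len(S))) {
    if (s < S) {
      pc <- cache[[sprintf("pool%d", s)]]
      d <- cpp_maxpool2_backward(d, pc$index, pc$h, pc$w)
      d <- d + dskips[[s]]
    }
    d <- conv3_bwd(sprintf("enc%d.conv2", s), d)
    d <- conv3_bwd(sprintf("enc%d.conv1", s), d)
  }
  grads
}

pad_multiple <- function(image, m) {
  H <- nrow(image); W <- ncol(image)
  Hp <- as.integer(ceiling(H / m) * m)
  Wp <- as.integer(ceiling(W / m) * m)
  if (Hp == H && Wp == W) return(list(image = image, H = H, W = W))
  # reflect-pad bottom/right
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  list(image = image[ri, ci, drop = FALSE], H = H, W = W)
}

#' Apply the denoiser to an image
#'
#' Runs the network image-to-image. Inputs whose sides are not divisible by
#' `2^(n_scales - 1)` are reflect-padded internally (and cropped back) when
#' `pad = TRUE`; otherwise an incompatible shape is an error.
#'
#' @param d A `denoiser`.
#' @param image Numeric matrix.
#' @param pad Pad internally to a compatible size (default `TRUE`).
#' @return Denoised image, same shape as the input.
#' @export
denoise <- function(d, image, pad = TRUE) {
  if (!inherits(d, "denoiser")) stop_invalid("d must be a denoiser")
  check_finite_matrix(image, "image")
  m <- 2L^max(d$config$n_scales - 1L, 0L)
  H0 <- nrow(image); W0 <- ncol(image)
  if ((H0 %% m != 0 || W0 %% m != 0)) {
    if (!pad)
      stop_invalid("image sides must be divisible by ", m,
                   " (or use pad = TRUE)")
    pm <- pad_multiple(image, m)
    image <- pm$image
  }
  st <- input_stats(d, image)
  x <- matrix((as.vector(image) - st$m) / st$s, ncol = 1)
  out <- net_forward(d, x, nrow(image), ncol(image))$out
  res <- matrix(out * st$s + st$m, nrow(image), ncol(image))
  if (d$config$residual) res <- res + image
  res[seq_len(H0), seq_len(W0), drop = FALSE]
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints are single-file RDS archives (format version 1) embedding the
#' configuration and all weights, so a checkpoint is self-describing.
#'
#' @param d A `denoiser`.
#' @param path File path.
#' @return `load_denoiser` returns the restored `denoiser`.
#' @export
save_denoiser <- function(d, path) {
  if (!inherits(d, "denoiser")) stop_invalid("d must be a denoiser")
  saveRDS(list(format = "proj2proj-checkpoint", version = 1L,
               config = d$config, params = d$params), path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "proj2proj-checkpoint"))
    stop_invalid(path, " is not a denoiser checkpoint")
  structure(list(config = obj$config, params = obj$params),
            class = "denoiser")
}
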