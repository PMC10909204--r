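#' Training configuration
#'
#' Bundles everything a training run needs. The published full-scale settings
#' are 200,000 iterations at learning rate 1e-4; the desk-scale defaults here
#' use a far shorter schedule and therefore a larger step size.
#'
#' @param geometry A [projection_geometry()] shared by all sinograms.
#' @param grid A [perturbation_grid()].
#' @param learning_rate Adam step size (> 0).
#' @param n_iterations Optimizer steps (>= 1).
#' @param batch_size Sinograms per step.
#' @param beta1,beta2,eps Adam moment parameters. The default `beta2 = 0.99`
#'   (faster second-moment adaptation than the textbook 0.999) suits the
#'   high-variance single-sample masked objective on short desk-scale
#'   schedules; see the methods vignette.
#' @param seed Integer seed (sampling order and any other randomness).
#' @param eval_every Validation period in iterations.
#' @param val_offset Fixed iteration offset used to perturb validation
#'   sinograms reproducibly.
#' @param perturbation `"cycling"` (the J-invariant scheme) or `"off"`, the
#'   ablation in which the network trains on the raw sinogram with the loss
#'   over all pixels — the configuration known to collapse towards the
#'   identity mapping.
#' @param checkpoint `"tail_average"` (default): return the uniform average
#'   of the weights over the last quarter of the schedule — single-sample
#'   masked losses make the trajectory noisy, and iterate averaging both
#'   damps that noise and sidesteps the weak correlation between the
#'   self-supervised validation loss and image fidelity near the optimum;
#'   or `"best_val"`: return the weights with the lowest validation
#'   self-supervised loss.
#' @return Object of class `train_config`.
#' @export
train_config <- function(geometry, grid = perturbation_grid(),
                         learning_rate = 2e-3, n_iterations = 2000L,
                         batch_size = 1L, beta1 = 0.9, beta2 = 0.99,
                         eps = 1e-8, seed = 1L, eval_every = 100L,
                         val_offset = 0L,
                         perturbation = c("cycling", "off"),
                         checkpoint = c("tail_average", "best_val")) {
  if (!inherits(geometry, "projection_geometry"))
    stop_config("geometry must be a projection_geometry")
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (n_iterations < 1) stop_config("n_iterations must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  perturbation <- match.arg(perturbation)
  checkpoint <- match.arg(checkpoint)
  structure(list(perturbation = perturbation, checkpoint = checkpoint,
                 geometry = geometry, grid = grid,
                 learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed),
                 eval_every = as.integer(eval_every),
                 val_offset = as.integer(val_offset)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  lr_t <- cfg$learning_rate *
    sqrt(1 - cfg$beta2^state$t) / (1 - cfg$beta1^state$t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + cfg$eps)
  }
  list(params = params, state = state)
}

check_sino_collection <- function(sinos, geom, what) {
  if (length(sinos) == 0) stop_invalid(what, " is empty")
  for (s in sinos) check_sinogram(s, geom)
  invisible(sinos)
}

# One forward/backward through FBP -> denoiser -> projector with a
# sinogram-domain loss gradient; returns loss and parameter gradients.
p2p_step_gradients <- function(den, x_in, target, mask, geom) {
  H <- nrow(x_in); W <- ncol(x_in)
  st <- input_stats(den, x_in)
  fw <- net_forward(den, matrix((as.vector(x_in) - st$m) / st$s, ncol = 1),
                    H, W, want_cache = TRUE)
  xhat <- matrix(fw$out * st$s + st$m, H, W)
  if (den$config$residual) xhat <- xhat + x_in
  if (!all(is.finite(xhat)))
    stop("training aborted: non-finite network output ",
         "(diverging optimization; reduce the learning rate)")
  yhat <- radon_forward(xhat, geom)
  nmask <- sum(mask)
  loss <- mean((yhat[mask] - target[mask])^2)
  dy <- matrix(0, nrow(yhat), ncol(yhat))
  dy[mask] <- 2 * (yhat[mask] - target[mask]) / nmask
  dx <- back_project(dy, geom)  # exact adjoint of radon_forward
  grads <- net_backward(den, fw$cache,
                        matrix(as.vector(dx) * st$s, ncol = 1), H, W)
  list(loss = loss, grads = grads, xhat = xhat)
}

accumulate_grads <- function(acc, g, scale) {
  if (is.null(acc)) return(lapply(g, function(x) x * scale))
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]] * scale
  acc
}

# Validation objective: the masked projection loss averaged over the val
# sinograms and over four fixed perturbation phases per sinogram (a single
# phase makes checkpoint selection hostage to one mask draw).
validation_p2p_loss <- function(den, val_sinos, cfg) {
  cell <- cfg$grid$cell_rows * cfg$grid$cell_cols
  phases <- floor(cell * (0:3) / 4)
  losses <- vapply(seq_along(val_sinos), function(i) {
    y <- val_sinos[[i]]
    if (cfg$perturbation == "off") {
      xhat <- denoise(den, fbp_reconstruct(y, cfg$geometry))
      return(mean((radon_forward(xhat, cfg$geometry) - y)^2))
    }
    mean(vapply(phases, function(ph) {
      pert <- perturb_sinogram(y, cfg$val_offset + i + ph, cfg$grid)
      x_in <- fbp_reconstruct(pert$sinogram, cfg$geometry)
      xhat <- denoise(den, x_in)
      yhat <- radon_forward(xhat, cfg$geometry)
      masked_projection_loss(yhat, y, pert$mask)
    }, numeric(1)))
  }, numeric(1))
  mean(losses)
}

finish_log <- function(iters, losses, val_iters, val_losses, best_iter,
                       pixel_index = NULL) {
  loss_df <- data.frame(iteration = iters, loss = losses)
  if (!is.null(pixel_index)) loss_df$pixel_index <- pixel_index
  structure(list(
    loss = loss_df,
    validation = data.frame(iteration = val_iters, loss = val_losses),
    best_iteration = best_iter), class = "training_log")
}

#' @export
print.training_log <- function(x, ...) {
  n <- nrow(x$loss)
  cat(sprintf("training_log: %d iterations, final loss %.4g, best checkpoint at iteration %s\n",
              n, x$loss$loss[n],
              if (is.na(x$best_iteration)) "end" else x$best_iteration))
  invisible(x)
}

#' Self-supervised training on low-dose projections only
#'
#' Trains the denoiser with the masked projection-domain objective. Per
#' iteration \eqn{t}: a low-dose sinogram \eqn{y_L} is sampled; a cycling
#' 1-per-cell subset of its pixels (in-cell index \eqn{t \bmod 16} for the
#' default 4x4 grid) is replaced by 4-neighbour means; the perturbed
#' sinogram is reconstructed with FBP and denoised; the denoised image is
#' re-projected; and the squared residual against the *unperturbed*
#' sinogram is minimized on the perturbed subset only. Gradients flow
#' through the projector via its exact adjoint. No ground-truth image or
#' normal-dose measurement is ever consumed.
#'
#' The returned denoiser carries the weights with the best validation
#' self-supervised loss (the only selection signal available without ground
#' truth).
#'
#' @param train_sinos,val_sinos Lists of sinogram matrices matching
#'   `cfg$geometry`.
#' @param denoiser Initial `denoiser`.
#' @param cfg A [train_config()].
#' @return List with elements `denoiser` (best checkpoint) and `log`
#'   (a `training_log`: per-iteration losses, periodic validation losses,
#'   best iteration).
#' @export
train_proj2proj <- function(train_sinos, val_sinos, denoiser, cfg) {
  check_sino_collection(train_sinos, cfg$geometry, "train_sinos")
  check_sino_collection(val_sinos, cfg$geometry, "val_sinos")
  state <- adam_init(denoiser$params)
  n <- length(train_sinos)
  losses <- numeric(cfg$n_iterations)
  val_iters <- integer(0); val_losses <- numeric(0)
  best <- list(loss = Inf, params = denoiser$params, iter = NA_integer_)
  tail_start <- ceiling(0.75 * cfg$n_iterations)
  tail_sum <- NULL; tail_n <- 0L
  order_draw <- with_seed(cfg$seed,
    sample.int(n, cfg$n_iterations * cfg$batch_size, replace = TRUE))
  # The perturbed input only depends on (sinogram, phase); with the default
  # 4x4 grid there are 16 phases, so the perturbed-FBP inputs repeat every
  # 16 iterations and are cached when that fits comfortably in memory.
  n_phase <- cfg$grid$cell_rows * cfg$grid$cell_cols
  use_cache <- cfg$perturbation == "cycling" &&
    n * n_phase * cfg$geometry$image_size^2 * 8 < 5e8
  fbp_cache <- if (use_cache) vector("list", n * n_phase)
  raw_fbp <- vector("list", n)
  mask_cache <- vector("list", n_phase)
  perturbed_input <- function(i, t) {
    phase <- select_pixel_index(t, cfg$grid)
    if (is.null(mask_cache[[phase + 1L]]))
      mask_cache[[phase + 1L]] <<-
        perturb_sinogram(train_sinos[[i]], phase, cfg$grid)$mask
    key <- (i - 1L) * n_phase + phase + 1L
    if (use_cache && !is.null(fbp_cache[[key]]))
      return(list(x_in = fbp_cache[[key]], mask = mask_cache[[phase + 1L]]))
    pert <- perturb_sinogram(train_sinos[[i]], phase, cfg$grid)
    x_in <- fbp_reconstruct(pert$sinogram, cfg$geometry)
    if (use_cache) fbp_cache[[key]] <<- x_in
    list(x_in = x_in, mask = pert$mask)
  }
  for (t in seq_len(cfg$n_iterations)) {
    acc <- NULL; loss_t <- 0
    for (b in seq_len(cfg$batch_size)) {
      i <- order_draw[(t - 1) * cfg$batch_size + b]
      y <- train_sinos[[i]]
      if (cfg$perturbation == "off") {
        if (is.null(raw_fbp[[i]]))
          raw_fbp[[i]] <- fbp_reconstruct(y, cfg$geometry)
        x_in <- raw_fbp[[i]]
        mask <- matrix(TRUE, nrow(y), ncol(y))
      } else {
        pin <- perturbed_input(i, t)
        x_in <- pin$x_in
        mask <- pin$mask
      }
      st <- p2p_step_gradients(denoiser, x_in, y, mask, cfg$geometry)
      loss_t <- loss_t + st$loss / cfg$batch_size
      acc <- accumulate_grads(acc, st$grads, 1 / cfg$batch_size)
    }
    if (!is.finite(loss_t))
      stop("training aborted: non-finite loss at iteration ", t,
           " (learning rate too high or degenerate input)")
    losses[t] <- loss_t
    upd <- adam_step(denoiser$params, acc, state, cfg)
    denoiser$params <- upd$params; state <- upd$state
    if (cfg$checkpoint == "tail_average" && t >= tail_start) {
      tail_sum <- accumulate_grads(tail_sum, denoiser$params, 1)
      tail_n <- tail_n + 1L
    }
    if (t %% cfg$eval_every == 0 || t == cfg$n_iterations) {
      vl <- validation_p2p_loss(denoiser, val_sinos, cfg)
      val_iters <- c(val_iters, t); val_losses <- c(val_losses, vl)
      if (vl < best$loss)
        best <- list(loss = vl, params = denoiser$params, iter = t)
    }
  }
  denoiser$params <- if (cfg$checkpoint == "tail_average")
    lapply(tail_sum, function(p) p / tail_n)
  else best$params
  list(denoiser = denoiser,
       log = finish_log(seq_len(cfg$n_iterations), losses,
                        val_iters, val_losses, best$iter,
                        pixel_index = vapply(seq_len(cfg$n_iterations),
                                             select_pixel_index,
                                             integer(1), grid = cfg$grid)))
}

#' Supervised baseline training (FBP + denoiser)
#'
#' Minimizes the image-domain mean squared error between the denoised FBP of
#' each low-dose sinogram and its paired reference image — the supervised
#' counterpart the self-supervised scheme is compared against.
#'
#' @param pairs List of `list(sinogram = , target = )` pairs; targets are
#'   reference images in \eqn{[0, 1]}.
#' @param denoiser Initial `denoiser`.
#' @param cfg A [train_config()].
#' @return List with elements `denoiser` (final weights) and `log`.
#' @export
train_supervised <- function(pairs, denoiser, cfg) {
  if (length(pairs) == 0) stop_invalid("pairs is empty")
  for (p in pairs) {
    check_sinogram(p$sinogram, cfg$geometry)
    check_image(p$target, cfg$geometry)
  }
  # FBP inputs are fixed; precompute once
  inputs <- lapply(pairs, function(p) fbp_reconstruct(p$sinogram, cfg$geometry))
  state <- adam_init(denoiser$params)
  n <- length(pairs)
  losses <- numeric(cfg$n_iterations)
  order_draw <- with_seed(cfg$seed,
    sample.int(n, cfg$n_iterations * cfg$batch_size, replace = TRUE))
  for (t in seq_len(cfg$n_iterations)) {
    acc <- NULL; loss_t <- 0
    for (b in seq_len(cfg$batch_size)) {
      i <- order_draw[(t - 1) * cfg$batch_size + b]
      x_in <- inputs[[i]]; target <- pairs[[i]]$target
      H <- nrow(x_in); W <- ncol(x_in)
      st <- input_stats(denoiser, x_in)
      fw <- net_forward(denoiser,
                        matrix((as.vector(x_in) - st$m) / st$s, ncol = 1),
                        H, W, want_cache = TRUE)
      xhat <- matrix(fw$out * st$s + st$m, H, W)
      if (denoiser$config$residual) xhat <- xhat + x_in
      resid <- xhat - target
      loss_t <- loss_t + mean(resid^2) / cfg$batch_size
      dx <- 2 * resid / length(resid)
      g <- net_backward(denoiser, fw$cache,
                        matrix(as.vector(dx) * st$s, ncol = 1), H, W)
      acc <- accumulate_grads(acc, g, 1 / cfg$batch_size)
    }
    if (!is.finite(loss_t))
      stop("training aborted: non-finite loss at iteration ", t)
    losses[t] <- loss_t
    upd <- adam_step(denoiser$params, acc, state, cfg)
    denoiser$params <- upd$params; state <- upd$state
  }
  list(denoiser = denoiser,
       log = finish_log(seq_len(cfg$n_iterations), losses,
                        integer(0), numeric(0), NA_integer_))
}

#' Reconstruct an image from a sinogram with a trained denoiser
#'
#' The inference path: filtered back projection of the *raw* (unperturbed)
#' sinogram followed by the denoiser. Deterministic given a checkpoint.
#'
#' @param sino Sinogram matrix.
#' @param denoiser A `denoiser`.
#' @param geom A [projection_geometry()].
#' @return Reconstructed image matrix.
#' @export
reconstruct <- function(sino, denoiser, geom) {
  check_sinogram(sino, geom)
  denoise(denoiser, fbp_reconstruct(sino, geom))
}
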