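tiny_setup <- function(n_imgs = 4, size = 64, snr = 33) {
  geom <- projection_geometry(size, 32, size)
  imgs <- lapply(seq_len(n_imgs), function(i)
    random_ellipses_image(size, rng_seed = 50 + i))
  sinos <- noisy_sinos(imgs, geom, snr, seed_offset = 300)
  list(geom = geom, imgs = imgs, sinos = sinos)
}

test_that("self-supervised training reduces the masked projection loss", {
  s <- tiny_setup()
  cfg <- train_config(s$geom, n_iterations = 150, batch_size = 1,
                      learning_rate = 1e-3, seed = 1, eval_every = 150)
  den <- build_denoiser(denoiser_config(2, 4, seed = 2))
  fit <- train_proj2proj(s$sinos[1:3], s$sinos[4], den, cfg)
  lo <- fit$log$loss$loss
  expect_true(all(is.finite(lo)))
  # averaged over windows, late loss is below early loss
  expect_lt(mean(tail(lo, 50)), mean(head(lo, 50)))
  # the perturbation phase cycles as iteration mod 16
  expect_identical(fit$log$loss$pixel_index,
                   vapply(1:150, function(t) t %% 16L, integer(1)))
})

test_that("training consumes only low-dose projections", {
  # the self-supervised path never receives images: its interface is
  # sinograms in, denoiser out, so ground truth cannot leak
  expect_named(formals(train_proj2proj),
               c("train_sinos", "val_sinos", "denoiser", "cfg"))
  s <- tiny_setup(2)
  cfg <- train_config(s$geom, n_iterations = 3, seed = 1, eval_every = 3)
  den <- build_denoiser(denoiser_config(1, 2, seed = 1))
  f1 <- train_proj2proj(s$sinos[1], s$sinos[2], den, cfg)
  f2 <- train_proj2proj(s$sinos[1], s$sinos[2], den, cfg)
  expect_identical(f1$denoiser$params, f2$denoiser$params)
})

test_that("supervised training overfits a single pair", {
  s <- tiny_setup(1, size = 32)
  s$geom <- projection_geometry(32, 32, 32)
  img <- random_ellipses_image(32, rng_seed = 77)
  sino <- add_noise_snr(radon_forward(img, s$geom), noise_model(33, 5))
  cfg <- train_config(s$geom, n_iterations = 500, batch_size = 1,
                      learning_rate = 1e-3, seed = 3)
  den <- build_denoiser(denoiser_config(2, 4, seed = 4))
  fit <- train_supervised(list(list(sinogram = sino, target = img)), den, cfg)
  lo <- fit$log$loss$loss
  expect_lt(lo[500], 0.1 * lo[1])
  expect_lt(mean(tail(lo, 20)), mean(lo[1:20]))
})

test_that("reconstruct is FBP + denoiser, deterministic, perturbation-free", {
  s <- tiny_setup(1)
  idd <- identity_denoiser()
  rec <- reconstruct(s$sinos[[1]], idd, s$geom)
  expect_identical(rec, fbp_reconstruct(s$sinos[[1]], s$geom))
  den <- build_denoiser(denoiser_config(2, 4, seed = 6))
  expect_identical(reconstruct(s$sinos[[1]], den, s$geom),
                   reconstruct(s$sinos[[1]], den, s$geom))
  bad_geom <- projection_geometry(64, 16, 64)
  expect_error(reconstruct(s$sinos[[1]], den, bad_geom),
               class = "proj2proj_invalid_input")
})

test_that("a diverging run aborts with a non-finite-loss diagnostic", {
  s <- tiny_setup(2)
  # an absurd step size overflows the activations within a few steps
  cfg <- train_config(s$geom, n_iterations = 50, batch_size = 1,
                      learning_rate = 1e40, seed = 1, eval_every = 50)
  den <- build_denoiser(denoiser_config(2, 4, seed = 2))
  expect_error(train_proj2proj(s$sinos[1], s$sinos[2], den, cfg),
               "non-finite")
})
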