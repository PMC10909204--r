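# Small shared fixtures, generated in code. The cache environment lets the
# expensive end-to-end runs be shared between acceptance criteria.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

centered_disk <- function(size, radius_px, value = 1) {
  rasterize_ellipses(size, data.frame(row = 0, col = 0,
                                      a = radius_px / (size / 2),
                                      b = radius_px / (size / 2),
                                      rotation = 0, intensity = value))
}

# noisy sparse-view sinograms for a list of images
noisy_sinos <- function(imgs, geom, snr_db, seed_offset = 0) {
  lapply(seq_along(imgs), function(i)
    add_noise_snr(radon_forward(imgs[[i]], geom),
                  noise_model(snr_db, seed = seed_offset + i)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

mean_psnr <- function(refs, recs) {
  mean(mapply(function(x, r) psnr(x, clip01(r)), refs, recs))
}
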