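test_that("initialization is deterministic and counts scale as expected", {
  cfg <- denoiser_config(3, 8, seed = 21)
  d1 <- build_denoiser(cfg)
  d2 <- build_denoiser(cfg)
  expect_identical(d1$params, d2$params)
  n8 <- count_parameters(build_denoiser(denoiser_config(3, 8)))
  n16 <- count_parameters(build_denoiser(denoiser_config(3, 16)))
  n32 <- count_parameters(build_denoiser(denoiser_config(3, 32)))
  expect_true(n8 < n16 && n16 < n32)
  # doubling the width roughly quadruples the parameter count
  expect_gt(n16 / n8, 3.5); expect_lt(n16 / n8, 4.5)
  expect_gt(n32 / n16, 3.5); expect_lt(n32 / n16, 4.5)
  # degenerate 0-scale config: a single 1x1 convolution
  expect_identical(count_parameters(build_denoiser(denoiser_config(0, 1))),
                   2L)
})

test_that("denoise preserves shape, handles padding, stays finite", {
  d <- build_denoiser(denoiser_config(3, 4, seed = 2))
  x <- matrix(runif(128 * 128), 128)
  out <- denoise(d, x)
  expect_identical(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  # side not divisible by 2^(n_scales-1): padded internally, error without
  x2 <- matrix(runif(90 * 90), 90)
  expect_identical(dim(denoise(d, x2)), c(90L, 90L))
  expect_error(denoise(d, x2, pad = FALSE),
               class = "proj2proj_invalid_input")
})

test_that("identity denoiser reproduces its input exactly", {
  d <- identity_denoiser()
  x <- matrix(runif(64 * 64), 64)
  expect_identical(denoise(d, x), x)
})

test_that("analytic gradients match finite differences", {
  den <- build_denoiser(denoiser_config(2, 2, seed = 3))
  set.seed(42)
  H <- 8; W <- 8
  x <- matrix(rnorm(H * W), ncol = 1)
  target <- matrix(rnorm(H * W), ncol = 1)
  lossf <- function(d) {
    out <- proj2proj:::net_forward(d, x, H, W)$out
    mean((out - target)^2)
  }
  fw <- proj2proj:::net_forward(den, x, H, W, want_cache = TRUE)
  dout <- 2 * (fw$out - target) / length(target)
  gr <- proj2proj:::net_backward(den, fw$cache, dout, H, W)
  for (nm in names(den$params)) {
    w <- den$params[[nm]]
    for (k in sample(length(w), min(4, length(w)))) {
      eps <- 1e-6
      d1 <- den; d1$params[[nm]][k] <- d1$params[[nm]][k] + eps
      d2 <- den; d2$params[[nm]][k] <- d2$params[[nm]][k] - eps
      num <- (lossf(d1) - lossf(d2)) / (2 * eps)
      ana <- gr[[nm]][k]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-3)
    }
  }
})

test_that("checkpoints round-trip through disk", {
  d <- build_denoiser(denoiser_config(2, 4, seed = 9))
  path <- tempfile(fileext = ".rds")
  save_denoiser(d, path)
  d2 <- load_denoiser(path)
  expect_identical(d2$params, d$params)
  expect_identical(d2$config, d$config)
  x <- matrix(runif(32 * 32), 32)
  expect_identical(denoise(d, x), denoise(d2, x))
  unlink(path)
  saveRDS(list(a = 1), path)
  expect_error(load_denoiser(path), class = "proj2proj_invalid_input")
})
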