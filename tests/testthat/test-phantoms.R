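test_that("shepp_logan respects the normalization contract", {
  ph <- cached("shepp256", shepp_logan(256))
  expect_equal(max(ph), 1.0)
  expect_equal(min(ph), 0.0)
  corners <- c(ph[1, 1], ph[1, 256], ph[256, 1], ph[256, 256])
  expect_true(all(corners == 0))
  expect_error(shepp_logan(8), class = "proj2proj_invalid_input")
})

test_that("rasterizer mirrors symmetric ellipse sets exactly", {
  # a left-right symmetric ellipse list rasterizes to an exactly
  # mirror-symmetric image (sampling grid is symmetric)
  spec <- data.frame(row = c(-0.2, 0.3, 0.3), col = c(0, -0.4, 0.4),
                     a = c(0.5, 0.2, 0.2), b = c(0.3, 0.1, 0.1),
                     rotation = c(0, 0.7, -0.7), intensity = c(1, 0.5, 0.5))
  img <- rasterize_ellipses(128, spec)
  expect_equal(img, img[, 128:1])
  # the standard head phantom is close to, but not exactly, symmetric
  ph <- cached("shepp256", shepp_logan(256))
  expect_lt(mean(abs(ph - ph[, 256:1])), 0.02)
  expect_gt(max(abs(ph - ph[, 256:1])), 0)
})

test_that("rasterization is consistent under grid refinement", {
  ph1 <- shepp_logan(128)
  ph2 <- shepp_logan(256)
  down <- 0.25 * (ph2[seq(1, 255, 2), seq(1, 255, 2)] +
                  ph2[seq(2, 256, 2), seq(1, 255, 2)] +
                  ph2[seq(1, 255, 2), seq(2, 256, 2)] +
                  ph2[seq(2, 256, 2), seq(2, 256, 2)])
  expect_lt(sqrt(mean((ph1 - down)^2)), 0.02)
})

test_that("random ellipse images are reproducible, in range, seed-sensitive", {
  a <- random_ellipses_image(64, rng_seed = 42)
  b <- random_ellipses_image(64, rng_seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_false(identical(a, random_ellipses_image(64, rng_seed = 43)))
  expect_equal(random_ellipses_image(64, c(0L, 0L), 1), matrix(0, 64, 64))
  expect_error(random_ellipses_image(64, c(5L, 2L), 1),
               class = "proj2proj_invalid_input")
})

test_that("generated images keep a stable foreground fraction", {
  # frozen regression value for seeds 1..1000 at size 128 (fraction of
  # pixels above 0.05); guards the generator's sampling distributions
  fr <- vapply(1:1000, function(s)
    mean(random_ellipses_image(128, rng_seed = s) > 0.05), numeric(1))
  expect_equal(mean(fr), 0.301820, tolerance = 0.005)
})

test_that("dataset splits are sized correctly and disjoint", {
  sp <- generate_dataset(10, c(0.6, 0.2, 0.2), size = 32, rng_seed = 1)
  expect_length(sp$train, 6)
  expect_length(sp$validation, 2)
  expect_length(sp$test, 2)
  hashes <- vapply(c(sp$train, sp$validation, sp$test),
                   function(m) paste(sum(m), sum(m^2)), character(1))
  expect_equal(anyDuplicated(hashes), 0L)
  # different master seeds give different content
  sp2 <- generate_dataset(10, c(0.6, 0.2, 0.2), size = 32, rng_seed = 2)
  h2 <- vapply(c(sp2$train, sp2$validation, sp2$test),
               function(m) paste(sum(m), sum(m^2)), character(1))
  expect_length(intersect(hashes, h2), 0)
  expect_error(generate_dataset(10, c(0.5, 0.2, 0.2), 32, 1),
               class = "proj2proj_config_error")
})

test_that("published corpus fractions reproduce the printed split sizes", {
  counts <- proj2proj:::split_counts(38400, c(32000, 3200, 3200) / 38400)
  expect_equal(unname(counts), c(32000, 3200, 3200))
})

test_that("image-folder reader round-trips generated slices", {
  dir <- withr::local_tempdir()
  img <- random_ellipses_image(32, rng_seed = 5)
  write_image_tiff(img, file.path(dir, "a.tif"))
  png::writePNG(img, file.path(dir, "b.png"))
  got <- read_image_folder(dir)
  expect_named(got, c("a.tif", "b.png"))
  expect_equal(got[["a.tif"]], img, tolerance = 1e-6)
  # PNG is 8-bit: agreement to the quantization step
  expect_lt(max(abs(got[["b.png"]] - img)), 1 / 255)
})
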