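#' Rasterize a set of ellipses onto a square grid
#'
#' Ellipses are described in normalized coordinates: centres `(row, col)` in
#' \eqn{[-1, 1]^2} (row increasing downwards), semi-axes in `(0, 1]`, rotation
#' in radians (about the centre, towards positive rows), additive intensity.
#' Edges are anti-aliased by area sampling (`supersample^2` subsamples per
#' pixel); overlapping ellipses add.
#'
#' @param size Pixels per side.
#' @param ellipses Data frame or matrix with columns
#'   `row`, `col`, `a`, `b`, `rotation`, `intensity`.
#' @param supersample Subsamples per pixel edge (default 4).
#' @return `size` x `size` numeric matrix.
#' @export
rasterize_ellipses <- function(size, ellipses, supersample = 4L) {
  if (size < 1) stop_invalid("size must be >= 1")
  m <- as.matrix(as.data.frame(ellipses)[, c("row", "col", "a", "b",
                                             "rotation", "intensity")])
  storage.mode(m) <- "double"
  if (any(m[, c("a", "b")] <= 0)) stop_invalid("semi-axes must be positive")
  cpp_rasterize_ellipses(as.integer(size), m, as.integer(supersample))
}

# Standard ("modified") Shepp-Logan ellipse set. Columns follow the usual
# convention (intensity, a, b, x0, y0, phi in degrees, y up); converted below
# to the row-down raster frame.
shepp_logan_ellipses <- function() {
  e <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6050,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  data.frame(row = -e[, 5], col = e[, 4], a = e[, 2], b = e[, 3],
             rotation = -e[, 6] * pi / 180, intensity = e[, 1])
}

#' Shepp-Logan head phantom
#'
#' The standard ten-ellipse head phantom with the usual low-contrast
#' ("modified") intensities, rasterized with anti-aliased edges and rescaled
#' so values span \eqn{[0, 1]} (background 0, skull 1).
#'
#' @param size Pixels per side (>= 16).
#' @return `size` x `size` matrix with values in \eqn{[0, 1]}.
#' @examples
#' ph <- shepp_logan(128)
#' range(ph)
#' @export
shepp_logan <- function(size) {
  if (size < 16) stop_invalid("size must be >= 16")
  img <- rasterize_ellipses(size, shepp_logan_ellipses())
  img <- pmax(img, 0)
  img / max(img)
}

# Draw one random ellipse set from the current RNG stream.
draw_ellipse_params <- function(n_ellipses_range,
                                intensity_range = c(0.1, 1.0),
                                center_range = c(-0.7, 0.7),
                                axis_range = c(0.05, 0.5)) {
  n <- if (n_ellipses_range[1] == n_ellipses_range[2]) n_ellipses_range[1]
       else sample(n_ellipses_range[1]:n_ellipses_range[2], 1L)
  if (n == 0)
    return(data.frame(row = numeric(0), col = numeric(0), a = numeric(0),
                      b = numeric(0), rotation = numeric(0),
                      intensity = numeric(0)))
  data.frame(row = runif(n, center_range[1], center_range[2]),
             col = runif(n, center_range[1], center_range[2]),
             a = runif(n, axis_range[1], axis_range[2]),
             b = runif(n, axis_range[1], axis_range[2]),
             rotation = runif(n, 0, pi),
             intensity = runif(n, intensity_range[1], intensity_range[2]))
}

raster_and_normalize <- function(size, params) {
  img <- rasterize_ellipses(size, params)
  img <- pmax(img, 0)
  m <- max(img)
  if (m > 1) img <- img / m
  img
}

#' Random-ellipse phantom
#'
#' Generates one synthetic attenuation image as the sum of uniformly sampled
#' ellipses, emulating an artificial ellipses training corpus: ellipse count
#' uniform over `n_ellipses_range`, intensities uniform in \eqn{[0.1, 1]},
#' centres uniform in \eqn{[-0.7, 0.7]^2}, semi-axes uniform in
#' \eqn{[0.05, 0.5]}, rotations uniform in \eqn{[0, \pi)}. Overlaps add and
#' the image is rescaled into \eqn{[0, 1]} when the sum exceeds 1.
#' Bit-reproducible for a fixed `rng_seed`.
#'
#' @param size Pixels per side (>= 16).
#' @param n_ellipses_range Integer pair `(min, max)` inclusive.
#' @param rng_seed Integer seed.
#' @return `size` x `size` matrix with values in \eqn{[0, 1]}.
#' @export
random_ellipses_image <- function(size, n_ellipses_range = c(3L, 10L),
                                  rng_seed = 1L) {
  if (size < 16) stop_invalid("size must be >= 16")
  if (length(n_ellipses_range) != 2 || any(n_ellipses_range < 0) ||
      n_ellipses_range[1] > n_ellipses_range[2])
    stop_invalid("n_ellipses_range must be a valid (min, max) pair")
  with_seed(rng_seed,
            raster_and_normalize(size, draw_ellipse_params(n_ellipses_range)))
}

split_counts <- function(n_total, fractions) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-6)
    stop_config("fractions must be three non-negative numbers summing to 1")
  n_train <- floor(n_total * fractions[1] + 0.5)
  n_val <- floor(n_total * fractions[2] + 0.5)
  c(train = n_train, validation = n_val, test = n_total - n_train - n_val)
}

#' Generate a split ellipse-phantom dataset
#'
#' Draws `n_total` random-ellipse images from one seeded stream and divides
#' them into disjoint train/validation/test collections.
#'
#' @param n_total Total number of images.
#' @param fractions Length-3 vector `(train, validation, test)` summing to 1.
#' @param size Pixels per side.
#' @param rng_seed Integer seed; the whole split is reproducible from it.
#' @param n_ellipses_range Passed to the per-image generator.
#' @return Object of class `dataset_split`: lists `train`, `validation`,
#'   `test` of image matrices, plus `seed` and `size`.
#' @export
generate_dataset <- function(n_total, fractions = c(0.6, 0.2, 0.2), size = 128,
                             rng_seed = 1L, n_ellipses_range = c(3L, 10L)) {
  counts <- split_counts(n_total, fractions)
  imgs <- with_seed(rng_seed, lapply(seq_len(n_total), function(i)
    raster_and_normalize(size, draw_ellipse_params(n_ellipses_range))))
  structure(list(train = imgs[seq_len(counts[1])],
                 validation = imgs[seq_len(counts[2]) + counts[1]],
                 test = imgs[seq_len(counts[3]) + counts[1] + counts[2]],
                 seed = as.integer(rng_seed), size = as.integer(size)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d validation / %d test images (%dx%d, seed %d)\n",
              length(x$train), length(x$validation), length(x$test),
              x$size, x$size, x$seed))
  invisible(x)
}

#' Read a folder of grayscale images
#'
#' Loads every TIFF/PNG file in `path` (sorted by name), averages colour
#' channels if present, and rescales each image into \eqn{[0, 1]} by its own
#' maximum when values exceed 1. Intended as the substitution point for real
#' CT slices in place of the synthetic generators.
#'
#' @param path Directory containing `.tif`, `.tiff` or `.png` files.
#' @return Named list of image matrices.
#' @export
read_image_folder <- function(path) {
  if (!dir.exists(path)) stop_invalid("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop_invalid("no TIFF/PNG files in ", path)
  out <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img <- pmax(img, 0)
    if (max(img) > 1) img <- img / max(img)
    img
  })
  names(out) <- basename(files)
  out
}
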