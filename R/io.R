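#' Write an image as 32-bit float TIFF
#'
#' @param image Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  check_finite_matrix(image, "image")
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a 32-bit float TIFF written by [write_image_tiff()]
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Save a CT dataset to a directory container
#'
#' Persists image and sinogram collections as 32-bit float TIFF slices under
#' `images/` and `sinograms/`, with a `metadata.json` sidecar carrying the
#' geometry, scale factors and any extra attributes (seed, noise level,
#' config hash). Sinograms are stored divided by a recorded per-dataset
#' scale so that line-integral values survive the unit-range TIFF encoding.
#'
#' @param path Directory to create (must not exist or be empty).
#' @param images Named or unnamed list of image matrices (may be empty).
#' @param sinograms List of sinogram matrices (may be empty).
#' @param geometry Optional [projection_geometry()] recorded in metadata.
#' @param metadata Named list of additional attributes.
#' @return `path`, invisibly.
#' @export
save_ct_dataset <- function(path, images = list(), sinograms = list(),
                            geometry = NULL, metadata = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sino_scale <- 1
  if (length(sinograms) > 0)
    sino_scale <- max(1e-12, max(vapply(sinograms, function(s) max(abs(s)),
                                        numeric(1))))
  if (length(images) > 0) {
    dir.create(file.path(path, "images"), showWarnings = FALSE)
    for (i in seq_along(images))
      write_image_tiff(pmin(pmax(images[[i]], 0), 1),
                       file.path(path, "images", sprintf("img_%05d.tif", i)))
  }
  if (length(sinograms) > 0) {
    dir.create(file.path(path, "sinograms"), showWarnings = FALSE)
    for (i in seq_along(sinograms))
      write_image_tiff((sinograms[[i]] / sino_scale + 1) / 2,
                       file.path(path, "sinograms", sprintf("sino_%05d.tif", i)))
  }
  meta <- c(list(format = "proj2proj-dataset", version = 1L,
                 n_images = length(images), n_sinograms = length(sinograms),
                 sinogram_scale = sino_scale), metadata)
  if (!is.null(geometry))
    meta$geometry <- list(image_size = geometry$image_size,
                          n_views = geometry$n_views,
                          n_detectors = geometry$n_detectors,
                          detector_spacing = geometry$detector_spacing)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CT dataset directory written by [save_ct_dataset()]
#'
#' @param path Dataset directory.
#' @return List with `images`, `sinograms`, `geometry` (or `NULL`) and
#'   `metadata`.
#' @export
load_ct_dataset <- function(path) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) stop_invalid(path, " is not a dataset directory")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  read_dir <- function(sub) {
    d <- file.path(path, sub)
    if (!dir.exists(d)) return(list())
    lapply(sort(list.files(d, full.names = TRUE)), read_image_tiff)
  }
  images <- read_dir("images")
  sinograms <- lapply(read_dir("sinograms"),
                      function(s) (s * 2 - 1) * meta$sinogram_scale)
  geometry <- NULL
  if (!is.null(meta$geometry))
    geometry <- projection_geometry(meta$geometry$image_size,
                                    meta$geometry$n_views,
                                    meta$geometry$n_detectors,
                                    meta$geometry$detector_spacing)
  list(images = images, sinograms = sinograms, geometry = geometry,
       metadata = meta)
}

# MD5 of a serialized R object (used to stamp outputs with the producing
# configuration).
config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(obj, NULL, version = 2), f)
  unname(tools::md5sum(f))
}
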