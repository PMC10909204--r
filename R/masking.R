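#' Perturbation grid for J-invariant masking
#'
#' The sinogram is tiled with `cell_rows` x `cell_cols` cells; every training
#' iteration perturbs one fixed position per cell, and the position cycles
#' deterministically through the cell so that over one full cycle each
#' sinogram pixel is perturbed exactly once.
#'
#' @param cell_rows,cell_cols Cell shape (default 4 x 4).
#' @return Object of class `perturbation_grid`.
#' @export
perturbation_grid <- function(cell_rows = 4L, cell_cols = 4L) {
  if (cell_rows < 1 || cell_cols < 1 || cell_rows * cell_cols < 2)
    stop_invalid("grid cells must contain at least 2 pixels")
  structure(list(cell_rows = as.integer(cell_rows),
                 cell_cols = as.integer(cell_cols)),
            class = "perturbation_grid")
}

#' Pixel index perturbed at a given iteration
#'
#' The perturbed in-cell position is the iteration number modulo the cell
#' size: with the default 4 x 4 grid, iteration 17 selects index
#' 17 mod 16 = 1. Indices enumerate the cell row-major, so index 1 is the
#' position (row 0, column 1) of each cell.
#'
#' @param iteration Non-negative iteration counter.
#' @param grid A [perturbation_grid()].
#' @return Integer in `[0, cell_rows * cell_cols)`.
#' @export
select_pixel_index <- function(iteration, grid = perturbation_grid()) {
  if (iteration < 0) stop_invalid("iteration must be >= 0")
  as.integer(iteration) %% (grid$cell_rows * grid$cell_cols)
}

# 4-neighbour mean of every pixel, border pixels averaging their available
# (2 or 3) neighbours; computed entirely from the unmodified input.
neighbor_mean <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  s <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  if (nr > 1) {
    s[-nr, ] <- s[-nr, ] + x[-1, ];  cnt[-nr, ] <- cnt[-nr, ] + 1  # below
    s[-1, ] <- s[-1, ] + x[-nr, ];   cnt[-1, ] <- cnt[-1, ] + 1    # above
  }
  if (nc > 1) {
    s[, -nc] <- s[, -nc] + x[, -1];  cnt[, -nc] <- cnt[, -nc] + 1  # right
    s[, -1] <- s[, -1] + x[, -nc];   cnt[, -1] <- cnt[, -1] + 1    # left
  }
  s / pmax(cnt, 1)
}

#' Perturb one pixel per grid cell by its neighbour mean
#'
#' Implements the J-invariant perturbation step: in every grid cell the pixel
#' at [select_pixel_index()] is replaced by the arithmetic mean of its
#' 4-connected neighbours in the *original* sinogram (the pixel itself
#' excluded; border pixels use their available neighbours); all other pixels
#' are returned bit-identical. Cells truncated by the sinogram edge are
#' perturbed only if the indexed position exists.
#'
#' @param sino Sinogram matrix, at least one full cell in size.
#' @param iteration Non-negative iteration counter (selects the in-cell index).
#' @param grid A [perturbation_grid()].
#' @return List with elements `sinogram` (perturbed copy), `mask` (logical
#'   matrix marking exactly the replaced pixels) and `pixel_index`.
#' @examples
#' y <- matrix(1:16, 4, 4, byrow = TRUE)
#' p <- perturb_sinogram(y, iteration = 5)
#' which(p$mask)
#' @export
perturb_sinogram <- function(sino, iteration, grid = perturbation_grid()) {
  check_finite_matrix(sino, "sinogram")
  if (nrow(sino) < grid$cell_rows || ncol(sino) < grid$cell_cols)
    stop_invalid("sinogram (", nrow(sino), "x", ncol(sino),
                 ") is smaller than one ", grid$cell_rows, "x",
                 grid$cell_cols, " grid cell")
  idx <- select_pixel_index(iteration, grid)
  r0 <- idx %/% grid$cell_cols  # 0-based within-cell position, row-major
  c0 <- idx %% grid$cell_cols
  rows <- seq.int(r0 + 1L, nrow(sino), by = grid$cell_rows)
  cols <- seq.int(c0 + 1L, ncol(sino), by = grid$cell_cols)
  mask <- matrix(FALSE, nrow(sino), ncol(sino))
  mask[rows, cols] <- TRUE
  out <- sino
  nm <- neighbor_mean(sino)
  out[mask] <- nm[mask]
  list(sinogram = out, mask = mask, pixel_index = idx)
}

#' Masked projection-domain loss
#'
#' Mean squared difference between predicted and target sinograms evaluated
#' only on the masked (perturbed) pixels — the self-supervised training
#' objective. Restricting the loss to the perturbed subset is what prevents
#' the denoiser from collapsing to the identity.
#'
#' @param pred_sino,target_sino Sinogram matrices of equal shape.
#' @param mask Logical matrix marking the pixels entering the loss.
#' @return Non-negative scalar; 0 iff the sinograms agree on the mask.
#' @export
masked_projection_loss <- function(pred_sino, target_sino, mask) {
  if (!all(dim(pred_sino) == dim(target_sino)) ||
      !all(dim(pred_sino) == dim(mask)))
    stop_invalid("pred_sino, target_sino and mask must share one shape")
  if (!any(mask)) stop_invalid("mask selects no pixels")
  mean((pred_sino[mask] - target_sino[mask])^2)
}
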