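test_that("pixel index cycles as iteration mod cell size", {
  grid <- perturbation_grid(4, 4)
  expect_identical(select_pixel_index(17, grid), 1L)
  expect_identical(select_pixel_index(0, grid), 0L)
  expect_identical(select_pixel_index(16, grid), 0L)
  expect_identical(select_pixel_index(5, perturbation_grid(2, 3)), 5L)
  expect_error(select_pixel_index(-1, grid),
               class = "proj2proj_invalid_input")
  expect_error(perturbation_grid(1, 1), class = "proj2proj_invalid_input")
})

test_that("perturbation replaces exactly the indexed pixel per cell", {
  y <- matrix(1:16, 4, 4, byrow = TRUE)
  # index 5 is in-cell position (row 1, col 1), the value 6
  p <- perturb_sinogram(y, iteration = 5)
  expect_identical(p$pixel_index, 5L)
  expect_equal(sum(p$mask), 1)
  expect_true(p$mask[2, 2])
  # the linear ramp makes the 4-neighbour mean reproduce the value itself
  expect_equal(p$sinogram[2, 2], mean(c(2, 5, 7, 10)))
  expect_equal(p$sinogram[2, 2], 6.0)
  # on a generic sinogram, changed pixels are exactly the masked ones
  set.seed(12)
  y2 <- matrix(rnorm(16), 4)
  p2 <- perturb_sinogram(y2, iteration = 5)
  expect_identical(which(p2$sinogram != y2), which(p2$mask))
})

test_that("border pixels average their available neighbours", {
  y <- matrix(1:16, 4, 4, byrow = TRUE)
  p0 <- perturb_sinogram(y, iteration = 0)  # corner (1,1), value 1
  expect_equal(p0$sinogram[1, 1], mean(c(2, 5)))
  p1 <- perturb_sinogram(y, iteration = 1)  # edge (1,2), value 2
  expect_equal(p1$sinogram[1, 2], mean(c(1, 3, 6)))
})

test_that("constant sinograms are fixed points with density 1/16", {
  y <- matrix(5, 16, 32)
  p <- perturb_sinogram(y, iteration = 7)
  expect_equal(p$sinogram, y)
  expect_equal(mean(p$mask), 1 / 16)
})

test_that("an 8x8 sinogram changes exactly one pixel per cell", {
  set.seed(2)
  y <- matrix(rnorm(64), 8)
  p <- perturb_sinogram(y, iteration = 11)
  expect_equal(sum(p$sinogram != y), 4)
})

test_that("16 consecutive iterations cover every pixel exactly once", {
  set.seed(3)
  y <- matrix(rnorm(16 * 32), 16)
  cover <- matrix(0L, 16, 32)
  for (t in 0:15) {
    p <- perturb_sinogram(y, t)
    cover <- cover + p$mask
  }
  expect_true(all(cover == 1L))
})

test_that("incomplete edge cells are perturbed only where the index exists", {
  y <- matrix(1, 6, 6)  # cells: one full, plus 2-row / 2-col remnants
  p_in <- perturb_sinogram(y, iteration = 5)   # position (1,1) exists in all
  expect_equal(sum(p_in$mask), 4)
  p_out <- perturb_sinogram(y, iteration = 15) # position (3,3) only in full
  expect_equal(sum(p_out$mask), 1)
  expect_error(perturb_sinogram(matrix(1, 3, 8), 0),
               class = "proj2proj_invalid_input")
})

test_that("masked loss sees only masked pixels", {
  set.seed(4)
  target <- matrix(rnorm(64), 8)
  p <- perturb_sinogram(target, iteration = 3)
  expect_equal(masked_projection_loss(target, target, p$mask), 0)
  expect_equal(masked_projection_loss(target + 1, target, p$mask), 1.0)
  # flipping an unmasked pixel is invisible
  pred <- target
  off <- which(!p$mask)[1]
  pred[off] <- pred[off] + 100
  expect_equal(masked_projection_loss(pred, target, p$mask), 0)
  # flipping a masked pixel is not
  pred2 <- target
  on <- which(p$mask)[1]
  pred2[on] <- pred2[on] + 1
  expect_gt(masked_projection_loss(pred2, target, p$mask), 0)
  expect_error(masked_projection_loss(target, target,
                                      matrix(FALSE, 8, 8)),
               class = "proj2proj_invalid_input")
})
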