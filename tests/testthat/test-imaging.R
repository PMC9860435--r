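test_that("gaussian blur preserves constants, degenerates to identity", {
  f <- new_frame(matrix(7, 16, 16))
  expect_true(all(gaussian_blur(f, 5) == 7))
  set.seed(1)
  g <- new_frame(matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_identical(unclass(gaussian_blur(g, 1)), unclass(g))
  expect_error(gaussian_blur(g, 4), "odd")
  expect_error(gaussian_blur(g, 0), "odd")
})

test_that("gaussian blur matches a brute-force 2-D convolution", {
  sigma <- 0.3 * ((5 - 1) / 2 - 1) + 0.8
  g1 <- exp(-(-2:2)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
    got <- unclass(gaussian_blur(new_frame(m), 5))
    want <- conv2_brute(m, g1)
    expect_lte(max(abs(got - want)), 1)  # rounding only
  }
})

test_that("blur is shift-equivariant away from borders", {
  set.seed(8)
  m <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  b <- unclass(gaussian_blur(new_frame(m), 5))
  m2 <- m[, c(2:40, 1)]                       # shift left by one column
  b2 <- unclass(gaussian_blur(new_frame(m2), 5))
  expect_identical(b[10:30, 10:30], b2[10:30, 9:29])
})

test_that("ROI crop converts bottom-left coordinates and checks bounds", {
  f <- new_frame(matrix(0, 240, 320))
  cr <- crop_roi(f, c(20, 20, 280, 200))
  expect_identical(dim(cr), c(200L, 280L))
  expect_identical(attr(cr, "offset"), c(left = 20, bottom = 20))

  expect_identical(px_of(crop_roi(f, c(0, 0, 320, 240))), px_of(f))
  expect_error(crop_roi(f, c(300, 0, 40, 40)), "bounds")
  expect_error(crop_roi(f, c(0, 0, 321, 240)), "bounds")

  # bottom-left origin: pixel 1 up / 1 right of the corner
  px <- matrix(0, 240, 320)
  px[239, 2] <- 200                     # row 239 = 1 above bottom
  g <- crop_roi(new_frame(px), c(1, 1, 10, 10))
  expect_identical(unclass(g)[10, 1], 200)
})

test_that("morphological closing merges gaps and fixes saturated masks", {
  # two 3x3 blobs with a 1-pixel vertical gap merge into one component
  m <- matrix(0, 9, 9)
  m[4:6, 2:4] <- 1
  m[4:6, 6:8] <- 1
  expect_identical(length(connected_components(m)$sizes), 2L)
  closed <- morph_close(new_mask(m), 3)
  expect_identical(length(connected_components(closed)$sizes), 1L)
  expect_true(all(unclass(closed)[4:6, 2:8] == 1))

  z <- new_mask(matrix(0, 6, 6))
  expect_identical(unclass(morph_close(z, 3)), unclass(z))
  o <- new_mask(matrix(1, 6, 6))
  expect_identical(unclass(morph_close(o, 3)), unclass(o))
})

test_that("closing is idempotent", {
  set.seed(11)
  for (i in 1:25) {
    m <- new_mask(matrix(rbinom(32 * 32, 1, 0.3), 32, 32))
    once <- morph_close(m, 3)
    expect_identical(unclass(morph_close(once, 3)), unclass(once))
  }
})

test_that("connected components match a flood-fill oracle", {
  expect_identical(length(connected_components(matrix(0, 8, 8))$sizes), 0L)

  m <- matrix(0, 30, 40); m[3:22, 5:29] <- 1   # 20 x 25 rectangle
  cc <- connected_components(new_mask(m))
  expect_identical(cc$sizes, 500L)
  expect_identical(cc$bboxes$row_min, 3L)
  expect_identical(cc$bboxes$col_max, 29L)

  set.seed(12)
  for (i in 1:200) {
    b <- matrix(rbinom(32 * 32, 1, runif(1, 0.15, 0.6)), 32, 32)
    got <- connected_components(b)
    want <- flood_cc(b)
    expect_identical(got$labels, want)               # same labelling order
    expect_identical(got$sizes, as.integer(tabulate(want[want > 0])))
    expect_identical(sum(got$sizes), sum(b))         # popcount invariant
  }
})

test_that("component structure is invariant under transposition", {
  set.seed(13)
  b <- matrix(rbinom(24 * 36, 1, 0.35), 24, 36)
  a <- connected_components(b)
  tr <- connected_components(t(b))
  expect_identical(sort(a$sizes), sort(tr$sizes))
  # the partitions agree: transposed label image maps 1:1 onto the original
  map <- table(a$labels[a$labels > 0], t(tr$labels)[a$labels > 0])
  expect_true(all(rowSums(map > 0) == 1) && all(colSums(map > 0) == 1))
})

test_that("CLAHE flattens nothing on constant frames and stays in range", {
  fc <- clahe(new_frame(matrix(100, 64, 64)))
  expect_identical(length(unique(as.vector(unclass(fc)))), 1L)
  set.seed(14)
  f <- new_frame(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  out <- clahe(f, clip_limit = 2, tiles = c(8, 8))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  expect_error(clahe(new_frame(matrix(1, 4, 4)), tiles = c(8, 8)), "tile")
  expect_error(clahe(f, clip_limit = 0), "clip_limit")
})

test_that("CLAHE widens low-contrast separation and tracks a reference", {
  set.seed(15)
  px <- matrix(100, 64, 64)
  px[, 33:64] <- 110
  out <- unclass(clahe(new_frame(px), clip_limit = 4, tiles = c(4, 4)))
  sep_in <- 10
  sep_out <- mean(out[, 49:64]) - mean(out[, 1:16])
  expect_gte(sep_out, sep_in)

  skip_if_not_installed("EBImage")
  # smooth gradient: both implementations should produce highly similar maps
  g <- outer(seq(60, 180, length.out = 64), rep(1, 64))
  mine <- unclass(clahe(new_frame(g), clip_limit = 2, tiles = c(8, 8)))
  ref <- EBImage::clahe(EBImage::Image(t(round(g)) / 255), nx = 8, ny = 8,
                        limit = 2)
  refm <- t(EBImage::imageData(ref)) * 255
  expect_gte(stats::cor(as.vector(mine), as.vector(refm)), 0.98)
})

test_that("frames round-trip through PNG and BMP encoders", {
  set.seed(16)
  f <- new_frame(matrix(sample(0:255, 48 * 60, TRUE), 48, 60))
  p1 <- withr::local_tempfile(fileext = ".png")
  write_frame(f, p1, type = "png")
  expect_identical(px_of(read_frame(p1)), px_of(f))
  p2 <- withr::local_tempfile(fileext = ".bmp")
  write_frame(f, p2, type = "bmp")
  expect_identical(px_of(read_frame(p2)), px_of(f))
  p3 <- withr::local_tempfile(fileext = ".jpg")
  write_frame(f, p3, type = "jpeg", quality = 95)
  expect_identical(dim(read_frame(p3)), dim(f))   # lossy: dims only
})
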