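test_that("binarize uses strict intensity > threshold on [0,1] images", {
  expect_true(all(binarize(matrix(0.5, 4, 4))))
  expect_false(any(binarize(matrix(0, 4, 4))))
  img <- matrix(0.05, 20, 20)
  img[5:10, 5:10] <- 0.2
  expect_identical(binarize(img), img > 0.1)
  # boundary semantics: exactly at the threshold is background
  expect_false(any(binarize(matrix(0.1, 3, 3))))
  expect_error(binarize(matrix(c(0.2, NaN, 0.3, 0.4), 2)), "non-finite")
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 1.2), "threshold")
})

test_that("clean_mask clears borders, fills holes, then drops small objects", {
  # interior blob at exactly the minimum area survives
  m <- matrix(FALSE, 260, 300)
  m[31:230, 26:275] <- TRUE  # 200 x 250 = 50000 px
  expect_identical(clean_mask(m), m)
  # one pixel below the minimum is erased
  m2 <- m
  m2[31, 26] <- FALSE  # 49999 px
  expect_false(any(clean_mask(m2)))
  # hole filling precedes the area test: 49990 solid px + 10 px hole passes
  # because the hole is filled before areas are measured
  m3 <- m
  m3[100:109, 100] <- FALSE    # 10 px interior hole
  expect_identical(clean_mask(m3), m)
  # border-touching blobs are removed no matter their size
  m4 <- matrix(FALSE, 260, 300)
  m4[1:220, 26:275] <- TRUE
  expect_false(any(clean_mask(m4)))
})

test_that("clean_mask is idempotent", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(60 * 60) > 0.4, 60, 60)
    once <- clean_mask(m, min_area = 15)
    expect_identical(clean_mask(once, min_area = 15), once)
  }
})

test_that("8-connected components are treated as one object", {
  # two blocks joined only diagonally form a single component
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  m[11:16, 11:16] <- TRUE
  expect_identical(clean_mask(m, min_area = 70), m)  # 72 px together
  o <- extract_outline(m)
  expect_equal(o$area, 72)
})

test_that("extract_outline returns the boundary and centre of gravity", {
  m <- matrix(FALSE, 22, 22)
  m[10:12, 10:12] <- TRUE
  o <- extract_outline(m)
  expect_equal(o$centroid, c(11, 11))
  expect_equal(nrow(o$boundary), 8)  # all perimeter pixels of a 3x3 square
  expect_true(all(o$boundary >= 10 & o$boundary <= 12))
  expect_false(any(o$boundary[, 1] == 11 & o$boundary[, 2] == 11))
  # boundary is a closed 8-connected cycle
  b <- o$boundary
  steps <- abs(b - b[c(2:nrow(b), 1), ])
  expect_true(all(steps <= 1))
})

test_that("extract_outline picks the largest component and rejects empty masks", {
  m <- matrix(FALSE, 60, 60)
  m[5:24, 5:24] <- TRUE    # 400 px
  m[40:49, 40:49] <- TRUE  # 100 px
  o <- extract_outline(m)
  expect_equal(o$area, 400)
  expect_true(all(o$boundary <= 24))
  expect_error(extract_outline(matrix(FALSE, 5, 5)), "no foreground")
})

test_that("a rasterised disk yields boundary radii within one pixel", {
  img <- raster_shape(function(th) rep(100, length(th)), 230, 230, 115, 115)
  mask <- clean_mask(binarize(img), min_area = 1000)
  o <- extract_outline(mask)
  r <- sqrt(rowSums(sweep(o$boundary, 2, o$centroid)^2))
  expect_true(all(abs(r - 100) <= 1))
})

test_that("radius signal starts near angle zero and is translation invariant", {
  img <- raster_shape(function(th) rep(50, length(th)), 160, 160, 80, 80)
  mask <- clean_mask(binarize(img), min_area = 1000)
  sig <- radius_signal(extract_outline(mask), "angle_sorted")
  expect_true(all(abs(sig$radii - 50) <= 1))
  expect_true(all(diff(sig$angles) >= 0))
  tra <- radius_signal(extract_outline(mask), "traversal")
  expect_lt(min(tra$angles[1], 2 * pi - tra$angles[1]), 0.1)
  # translate by (+17, -9): identical radii sequence
  m2 <- matrix(FALSE, 160, 160)
  m2[(row(m2) - 17 >= 1) & (row(m2) - 17 <= 160) &
       (col(m2) + 9 >= 1) & (col(m2) + 9 <= 160)] <- FALSE
  idx <- which(mask, arr.ind = TRUE)
  m2[cbind(idx[, 1] + 17, idx[, 2] - 9)] <- TRUE
  tra2 <- radius_signal(extract_outline(m2), "traversal")
  expect_identical(tra$radii, tra2$radii)
})

test_that("an axis-aligned ellipse matches its analytic polar radius", {
  a <- 120; b <- 60
  rfun <- function(th) a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  img <- raster_shape(rfun, 260, 300, 130, 150)
  sig <- image_to_signal(img, min_area = 1000)
  expect_true(all(abs(sig$radii - rfun(sig$angles)) < 1.5))
})

test_that("rotating a shape circularly shifts the radius sequence", {
  rho <- 0.7  # rotation angle in radians
  # mixed harmonics: no rotational symmetry, so the correlation peak is unique
  base <- function(th) 80 * (1 + 0.12 * cos(2 * th) + 0.08 * cos(3 * th))
  rot <- function(th) base(th - rho)
  grid <- seq(0, 2 * pi, length.out = 721)[-721]
  sig_of <- function(rf) {
    img <- raster_shape(rf, 260, 260, 130, 130)
    s <- image_to_signal(img, min_area = 1000, ordering = "angle_sorted")
    # resample onto a common uniform angle grid
    stats::approx(c(s$angles - 2 * pi, s$angles, s$angles + 2 * pi),
                  rep(s$radii, 3), xout = grid)$y
  }
  r1 <- sig_of(base)
  r2 <- sig_of(rot)
  n <- length(grid)
  xc <- vapply(0:(n - 1), function(k) {
    sum(r1 * r2[(seq_len(n) + k - 1) %% n + 1])
  }, numeric(1))
  best <- which.max(xc) - 1
  expected <- n * rho / (2 * pi)
  expect_lt(min(abs(best - expected), n - abs(best - expected)), 3)
})

test_that("doubling the shape radius doubles the radius signal", {
  rfun1 <- function(th) 60 * (1 + 0.1 * cos(2 * th))
  rfun2 <- function(th) 120 * (1 + 0.1 * cos(2 * th))
  s1 <- resample_fft(image_to_signal(
    raster_shape(rfun1, 160, 160, 80, 80), min_area = 1000), 500)
  s2 <- resample_fft(image_to_signal(
    raster_shape(rfun2, 300, 300, 150, 150), min_area = 1000), 500)
  expect_true(all(abs(s2 / (2 * s1) - 1) < 0.02))
})

test_that("degenerate shapes where the centroid meets the boundary error out", {
  m <- matrix(FALSE, 11, 11)
  m[6, 3:9] <- TRUE  # 1-px line: centroid lies on the boundary
  expect_error(radius_signal(extract_outline(m)), "degenerate")
})
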