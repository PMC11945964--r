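test_that("probe-centered crops have the calibrated side and copy pixels exactly", {
  set.seed(3)
  frame <- array(round(runif(600 * 600 * 3) * 255), c(600, 600, 3))
  cr <- slbic_crop(frame, c(300, 300), 50, crop_spec(3))
  expect_equal(dim(cr), c(100, 100, 3))
  # rows/cols [250, 350) in 0-based half-open convention
  expect_identical(cr, frame[251:350, 251:350, ])
  expect_equal(dim(slbic_crop(frame, c(300, 300), 50, 1))[1:2], c(200, 200))
  expect_error_class(slbic_crop(frame, c(30, 30), 50, 1), "ebusfusion_error_geometry")
  expect_error(slbic_crop(frame, c(30, 30), 50, 1), "px")
  expect_error_class(crop_spec(5), "ebusfusion_error_argument")
})

test_that("crop side equals round(side_cm * pixels_per_cm) over random calibrations", {
  set.seed(4)
  for (i in 1:25) {
    ppcm <- runif(1, 20, 70)
    t <- sample(1:4, 1)
    side <- round(crop_spec(t)$side_cm * ppcm)
    S <- as.integer(2 * side + 10)
    frame <- matrix(0, S, S)
    cr <- slbic_crop(frame, c(S %/% 2, S %/% 2), ppcm, t)
    expect_equal(nrow(cr), side)
    expect_equal(ncol(cr), side)
  }
})

test_that("nearest-neighbor polar transform matches the per-pixel oracle on all small grids", {
  set.seed(5)
  img <- matrix(round(runif(32 * 32) * 255), 32, 32)
  ctr <- c(15, 16)
  rmax <- ebusfusion:::center_edge_distance(ctr, c(32, 32))
  oracle <- function(nr, na) {
    out <- matrix(0, nr, na)
    for (i in 0:(nr - 1)) for (j in 0:(na - 1)) {
      r <- (i + 0.5) / nr * rmax
      th <- (j + 0.5) / na * 2 * pi
      rw <- min(max(ctr[1] - r * sin(th), 0), 31)
      cl <- min(max(ctr[2] + r * cos(th), 0), 31)
      out[i + 1, j + 1] <- img[min(max(floor(rw + 0.5), 0), 31) + 1,
                               min(max(floor(cl + 0.5), 0), 31) + 1]
    }
    out
  }
  for (nr in 1:16) for (na in c(1, 2, 3, 5, 8, 13, 16)) {
    sp <- polar_spec(nr, na, rmax, "nearest")
    expect_identical(polar_transform(img, ctr, sp), oracle(nr, na))
  }
})

test_that("polar transform preserves constants and honors its geometry precondition", {
  img <- matrix(77, 40, 40)
  sp <- polar_spec(12, 16, 15, "nearest")
  expect_true(all(polar_transform(img, c(20, 20), sp) == 77))
  spb <- polar_spec(12, 16, 15, "bilinear")
  expect_true(all(polar_transform(img, c(20, 20), spb) == 77))
  expect_error_class(polar_transform(img, c(2, 2), sp), "ebusfusion_error_geometry")
  # output dims follow the spec grid; defaults are 224 x 224
  expect_equal(dim(polar_transform(img, c(20, 20), polar_spec(7, 9, 10))), c(7, 9))
  def <- polar_spec(r_max_px = 10)
  expect_equal(c(def$n_radius, def$n_angle), c(224L, 224L))
})

test_that("a centered bright ring unwraps to a horizontal band", {
  S <- 64; ctr <- c(32, 32); r0 <- 20
  ring <- matrix(0, S, S)
  for (i in 0:(S - 1)) for (j in 0:(S - 1)) {
    if (abs(sqrt((i - ctr[1])^2 + (j - ctr[2])^2) - r0) < 1) ring[i + 1, j + 1] <- 255
  }
  pt <- polar_transform(ring, ctr, polar_spec(32, 32, 30, "nearest"))
  full_rows <- which(rowSums(pt > 0) >= 30)
  expect_true(all(abs(full_rows - 1 - floor(r0 / 30 * 32)) <= 1))
  # rows far from the ring radius stay dark
  expect_true(all(pt[1:10, ] == 0))
})

test_that("rotating the input by 90 degrees circularly shifts polar columns", {
  set.seed(6)
  n <- 33; ctr <- c(16, 16)
  img <- matrix(round(runif(n * n) * 255), n, n)
  sp <- polar_spec(16, 16, ebusfusion:::center_edge_distance(ctr, c(n, n)), "nearest")
  p0 <- polar_transform(img, ctr, sp)
  p_cw <- polar_transform(t(img[n:1, ]), ctr, sp)
  shift <- function(m, k) m[, ((seq_len(ncol(m)) - 1 + k) %% ncol(m)) + 1]
  expect_identical(p_cw, shift(p0, 4))
})

test_that("gray-scale conversion follows BT.601 luma with half-up rounding", {
  px <- function(r, g, b) array(rep(c(r, g, b), each = 1), c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(to_grayscale(px(255, 0, 0))), 76)
  expect_equal(as.vector(to_grayscale(px(0, 255, 0))), 150)
  set.seed(7)
  v <- round(runif(10) * 255)
  gray <- array(rep(v, 3), c(10, 1, 3))
  expect_equal(as.vector(to_grayscale(gray)), v)
  expect_error_class(to_grayscale(matrix(0, 4, 4)), "ebusfusion_error_shape")
})

test_that("resizing is identity at target size and averages as expected", {
  img <- matrix(round(runif(224 * 224) * 255), 224, 224)
  expect_identical(resize_to(img, c(224, 224)), img)
  expect_true(all(resize_to(matrix(9, 17, 13), c(5, 29)) == 9))
  checker <- matrix(c(0, 255, 255, 0), 2, 2)
  expect_equal(as.vector(resize_to(checker, c(1, 1))), 128)
  expect_error_class(resize_to(img, c(0, 5)), "ebusfusion_error_argument")
})

test_that("branch preprocessing produces correctly shaped images for all branch kinds", {
  sc <- small_cohort()
  m <- sc$manifest[1, ]
  frame <- read_frame(file.path(sc$dir, m$frame_path))
  for (ty in c("type4", "polar3", "MS 2-3-4", "PMS 1-2-3")) {
    img <- preprocess_frame(frame, c(m$probe_row, m$probe_col), m$pixels_per_cm,
                            ty, size = 64L)
    expect_equal(dim(img), c(64, 64, 3))
    expect_true(all(img >= 0 & img <= 255))
  }
})
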