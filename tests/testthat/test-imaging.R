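test_that("to_gray handles gray, RGB, and rejects other shapes", {
  g <- matrix(sample(0:255, 24, replace = TRUE), 4, 6)
  expect_identical(to_gray(g), matrix(as.integer(g), 4, 6))

  white <- array(255, dim = c(3, 3, 3))
  expect_true(all(to_gray(white) == 255L))

  px <- array(c(100, 200, 50), dim = c(1, 1, 3))
  expect_identical(to_gray(px)[1, 1], 153L)

  expect_error(to_gray(array(0, dim = c(2, 2, 2, 2))))
  expect_error(to_gray(array(0, dim = c(2, 2, 4))))
})

test_that("equalize matches the hand-computed cdf mapping", {
  expect_true(all(equalize(matrix(7L, 5, 5)) == 255L))

  m <- matrix(c(0L, 170L, 85L, 255L), 2, 2)
  expect_identical(equalize(m), matrix(c(64L, 191L, 128L, 255L), 2, 2))
})

test_that("equalize cdf is monotone and reaches 255", {
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    out <- equalize(img)
    # monotone: sorting by input intensity sorts output intensity
    ord <- order(as.vector(img))
    expect_true(all(diff(as.vector(out)[ord]) >= 0))
    expect_identical(max(out), 255L)
  }
})

test_that("otsu_threshold: two-delta plateau tie-break and constant error", {
  img <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
  expect_identical(otsu_threshold(img), 10L)
  expect_error(otsu_threshold(matrix(5L, 4, 4)), "separable")
})

test_that("otsu_threshold equals the exhaustive-search oracle", {
  set.seed(7)
  for (i in 1:100) {
    # bimodal-ish random images plus a few uniform-random ones
    n <- sample(30:120, 1)
    img <- if (i %% 4 == 0) {
      matrix(sample(0:255, n, replace = TRUE), 1)
    } else {
      v <- c(pmin(pmax(round(rnorm(n, 60, 18)), 0), 255),
             pmin(pmax(round(rnorm(n, 180, 25)), 0), 255))
      matrix(as.integer(v), 1)
    }
    if (length(unique(as.vector(img))) < 2L) next
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("segment_objects finds, filters and orders components", {
  img <- matrix(255L, 40, 40)
  img[5:14, 10:13] <- 0L
  s <- segment_objects(img, min_object_px = 20L)
  expect_length(s, 1)
  expect_identical(s[[1]]$pixel_count, 40L)
  expect_identical(dim(s[[1]]$mask), c(10L, 4L))
  expect_identical(s[[1]]$bbox_origin, c(row = 4L, col = 9L))
  expect_false(s[[1]]$touches_border)

  # three isolated 3x3 squares all below the size floor
  img2 <- matrix(255L, 40, 40)
  img2[2:4, 2:4] <- 0L; img2[10:12, 20:22] <- 0L; img2[30:32, 5:7] <- 0L
  expect_length(segment_objects(img2, min_object_px = 20L), 0)
  expect_length(segment_objects(img2, min_object_px = 9L), 3)

  # ids in raster order of bbox top-left corner
  s3 <- segment_objects(img2, min_object_px = 1L)
  origins <- t(vapply(s3, `[[`, c(row = 0L, col = 0L), "bbox_origin"))
  expect_identical(order(origins[, 1], origins[, 2]), seq_len(nrow(origins)))

  expect_error(segment_objects(matrix(7L, 5, 5)), "separable")
})

test_that("segmentation polarity picks the darker side as foreground", {
  img <- matrix(230L, 30, 30)
  img[10:19, 10:15] <- 20L             # dark object, light background
  s <- segment_objects(img, min_object_px = 20L)
  expect_length(s, 1)
  expect_identical(s[[1]]$pixel_count, 60L)
})

test_that("orient_vertical leaves vertical rectangles alone and turns
           horizontal ones", {
  v <- list(object_id = 1L, mask = matrix(1L, 40, 8))
  ov <- orient_vertical(v)
  expect_identical(ov$rotation_deg, 0)
  expect_identical(dim(ov$mask), c(40L, 8L))

  h <- list(object_id = 1L, mask = matrix(1L, 8, 40))
  oh <- orient_vertical(h)
  expect_identical(abs(oh$rotation_deg), 90)
  expect_identical(dim(oh$mask), c(40L, 8L))
  expect_lt(abs(oh$pixel_count - 320) / 320, 0.05)
})

test_that("orient_vertical recovers drawn angles within 2 degrees", {
  for (ang in c(-60, -30, 15, 30, 75)) {
    m <- draw_rect_mask(40, 8, ang)
    o <- orient_vertical(list(object_id = 1L, mask = m))
    target <- oracle_vertical_angle(m)
    # rotation applied should undo the drawn angle (mod 180)
    d <- (o$rotation_deg - target + 90) %% 180 - 90
    expect_lt(abs(d), 2)
  }
})

test_that("orient_vertical is a contraction toward vertical", {
  set.seed(11)
  for (i in 1:8) {
    m <- draw_rect_mask(runif(1, 25, 45), runif(1, 4, 9), runif(1, -85, 85))
    o1 <- orient_vertical(list(object_id = 1L, mask = m))
    o2 <- orient_vertical(o1)
    expect_lt(abs(o2$rotation_deg), 2)
  }
})

test_that("orient_vertical guards degenerate input", {
  expect_error(orient_vertical(list(object_id = 1L,
                                    mask = matrix(0L, 3, 3))), "empty")
  expect_error(orient_vertical(list(object_id = 1L,
                                    mask = matrix(c(1L, 0L, 0L, 0L), 2))))
  # symmetric square: no defined major axis, rotation 0
  sq <- orient_vertical(list(object_id = 1L, mask = matrix(1L, 7, 7)))
  expect_identical(sq$rotation_deg, 0)
})

test_that("image io round-trips PNG and reads PGM and BMP", {
  img <- matrix(sample(0:255, 48 * 32, replace = TRUE), 48, 32)
  f <- tempfile(fileext = ".png")
  write_gray_png(img, f)
  expect_identical(read_gray_image(f), to_gray(img))

  # ascii PGM written by hand
  f2 <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "# comment", "3 2", "255",
               "0 128 255", "10 20 30"), f2)
  expect_identical(read_gray_image(f2),
                   matrix(c(0L, 10L, 128L, 20L, 255L, 30L), 2, 3))

  # minimal 24-bit BMP assembled byte by byte (2x2, bottom-up rows)
  f3 <- tempfile(fileext = ".bmp")
  w <- 2L; h <- 2L; row_bytes <- 8L
  pix <- as.raw(c(0, 0, 255, 255, 255, 255, 0, 0,   # bottom row: red, white
                  0, 0, 0, 128, 128, 128, 0, 0))    # top row: black, gray
  hdr <- c(charToRaw("BM"),
           writeBin(54L + length(pix), raw(), size = 4, endian = "little"),
           raw(4),
           writeBin(54L, raw(), size = 4, endian = "little"),
           writeBin(40L, raw(), size = 4, endian = "little"),
           writeBin(w, raw(), size = 4, endian = "little"),
           writeBin(h, raw(), size = 4, endian = "little"),
           writeBin(1L, raw(), size = 2, endian = "little"),
           writeBin(24L, raw(), size = 2, endian = "little"),
           raw(24))
  writeBin(c(hdr, pix), f3)
  got <- read_gray_image(f3)
  expect_identical(dim(got), c(2L, 2L))
  expect_identical(got[1, 1], 0L)      # black
  expect_identical(got[1, 2], 128L)    # gray
  expect_identical(got[2, 1], 76L)     # pure red -> luminance 76
  expect_identical(got[2, 2], 255L)    # white

  expect_error(read_gray_image(tempfile(fileext = ".tiff")), "not found")
  f4 <- tempfile(fileext = ".tiff"); file.create(f4)
  expect_error(read_gray_image(f4), "TIFF")
})
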