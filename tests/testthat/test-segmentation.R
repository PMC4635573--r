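test_that("to_gray is the rounded channel mean and rejects non-RGB input", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(90, 90, 90)
  px[1, 2, ] <- c(0, 0, 255)
  px[2, 1, ] <- c(255, 255, 255)
  px[2, 2, ] <- c(10, 20, 30)
  g <- to_gray(rgb_image(px, dpi = 72))
  expect_identical(g[1, 1], 90)
  expect_identical(g[1, 2], 85)   # round(255/3) half-up
  expect_identical(g[2, 1], 255)
  expect_identical(g[2, 2], 20)
  expect_equal(img_dpi(g), 72)

  expect_error(to_gray(matrix(0, 3, 3)), "RGB")

  # half-up rounding across random channel triplets
  set.seed(1)
  px <- array(sample(0:255, 3 * 60, replace = TRUE), c(6, 10, 3))
  g <- to_gray(rgb_image(px))
  expect_equal(as.numeric(g),
               as.numeric(floor((px[, , 1] + px[, , 2] + px[, , 3]) / 3 + 0.5)))
})

test_that("otsu_threshold maximises between-class variance (exhaustive oracle)", {
  v <- c(0, 0, 0, 255, 255)
  expect_identical(otsu_threshold(gray_image(matrix(v, 1))), otsu_bruteforce(v))

  # two-valued image: any threshold in [50, 199] separates; smallest returned
  v <- c(rep(50, 7), rep(200, 3))
  t <- otsu_threshold(gray_image(matrix(v, 2)))
  expect_identical(t, 50L)
  expect_identical(t, otsu_bruteforce(v))

  expect_error(otsu_threshold(gray_image(matrix(7, 4, 4))), "degenerate")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    v <- sample(0:255, n, replace = TRUE)
    if (length(unique(v)) < 2) next
    expect_identical(otsu_threshold(gray_image(matrix(v, 1))),
                     otsu_bruteforce(v))
  }
})

test_that("binarize honours polarity and picks the minority class in auto mode", {
  g <- gray_image(matrix(c(0, 0, 255, 255, 255), 1))
  expect_equal(sum(binarize(g, 127, "auto")), 2)          # dark minority
  expect_true(all(binarize(gray_image(matrix(c(5, 100), 1)), 127,
                           "dark_foreground")))
  b <- binarize(gray_image(matrix(c(10, 240), 1)), 127, "light_foreground")
  expect_identical(as.logical(b), c(FALSE, TRUE))
})

test_that("opening removes thin structures, is idempotent and anti-extensive", {
  line <- matrix(FALSE, 9, 20)
  line[5, 3:18] <- TRUE
  expect_equal(sum(morphological_open(binary_mask(line), 1)), 0)

  # a solid square loses exactly its four corners to the diamond element
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE
  op <- morphological_open(binary_mask(sq), 1)
  expect_equal(sum(op), 100 - 4)
  expect_false(op[3, 3] || op[3, 12] || op[12, 3] || op[12, 12])
  # cross-check against the reference morphology implementation
  ref <- EBImage::opening(sq * 1, EBImage::makeBrush(3, "diamond"))
  expect_equal(as.logical(op), as.logical(as.matrix(ref) > 0.5))

  # a diamond-shaped blob is open with respect to the diamond element
  d <- outer(1:15, 1:15, function(r, c) abs(r - 8) + abs(c - 8) <= 5)
  expect_equal(as.logical(morphological_open(binary_mask(d), 1)),
               as.logical(d))

  for (seed in 1:8) {
    m <- random_blob_mask(seed)
    o1 <- morphological_open(binary_mask(m), 1)
    expect_true(all(o1 <= m))                          # anti-extensive
    expect_identical(as.logical(morphological_open(o1, 1)),
                     as.logical(o1))                   # idempotent
  }

  expect_error(morphological_open(binary_mask(line), 0), "radius")
})

test_that("fill_holes fills exactly the background not connected to the border", {
  ring <- matrix(FALSE, 10, 10)
  ring[3:8, 3:8] <- TRUE
  ring[4:7, 4:7] <- FALSE
  filled <- fill_holes(binary_mask(ring))
  solid <- matrix(FALSE, 10, 10)
  solid[3:8, 3:8] <- TRUE
  expect_identical(as.logical(filled), as.logical(solid))

  open_blob <- random_blob_mask(3)
  expect_identical(as.logical(fill_holes(binary_mask(open_blob))),
                   as.logical(fill_holes_floodfill(open_blob)))

  set.seed(11)
  for (seed in 1:8) {
    m <- random_blob_mask(seed)
    # punch interior holes
    holes <- matrix(runif(length(m)) < 0.08, nrow(m), ncol(m))
    m2 <- m & !holes
    got <- fill_holes(binary_mask(m2))
    expect_identical(as.logical(got), as.logical(fill_holes_floodfill(m2)))
    expect_true(all(got >= m2))                        # extensive
    expect_identical(as.logical(fill_holes(got)), as.logical(got)) # idempotent
  }
})

test_that("remove_small_objects applies a strict size cutoff", {
  m <- matrix(FALSE, 20, 40)
  m[2:12, 2:10] <- TRUE    # 11 x 9 = 99 px
  expect_equal(sum(m), 99)
  expect_equal(sum(remove_small_objects(binary_mask(m), 100)), 0)

  m2 <- matrix(FALSE, 20, 40)
  m2[2:11, 2:11] <- TRUE   # exactly 100 px: kept
  expect_equal(sum(remove_small_objects(binary_mask(m2), 100)), 100)

  m3 <- matrix(FALSE, 40, 40)
  m3[2:11, 2:6] <- TRUE    # 50 px
  m3[20:39, 15:39] <- TRUE # 500 px
  out <- remove_small_objects(binary_mask(m3), 100)
  expect_equal(sum(out), 500)
  expect_false(any(out[2:11, 2:6]))

  expect_error(remove_small_objects(binary_mask(m), 0), "min_pixels")
})

test_that("label_components uses 8-connectivity and raster-scan label order", {
  expect_equal(n_regions(label_components(binary_mask(matrix(FALSE, 5, 5)))), 0)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE
  diag2[2, 2] <- TRUE
  expect_equal(n_regions(label_components(binary_mask(diag2))), 1)

  # labels follow the raster order of each component's first pixel
  m <- matrix(FALSE, 10, 10)
  m[8:9, 1:2] <- TRUE  # later in raster order
  m[1:2, 7:8] <- TRUE  # first
  m[4:5, 3:4] <- TRUE
  lbl <- label_components(binary_mask(m))
  expect_equal(lbl[1, 7], 1L)
  expect_equal(lbl[4, 3], 2L)
  expect_equal(lbl[8, 1], 3L)

  set.seed(5)
  for (seed in 1:10) {
    m <- matrix(runif(30 * 35) < 0.35, 30, 35)
    lbl <- label_components(binary_mask(m))
    expect_equal(n_regions(lbl), count_components_bfs(m))
    # conservation: labelled pixels are exactly the foreground
    expect_equal(sum(lbl > 0), sum(m))
    expect_identical(as.logical(lbl > 0), as.logical(m))
  }
})

test_that("the pipeline stages are monotone in the documented directions", {
  gp <- generate_panicle(panicle_spec(seed = 5, n_branches = 4))
  g <- to_gray(gp$image)
  b <- binarize(g, otsu_threshold(g))
  op <- morphological_open(b, 1)
  fl <- fill_holes(op)
  cl <- remove_small_objects(fl, 100)
  expect_true(all(op <= b))
  expect_true(all(fl >= op))
  expect_true(all(cl <= fl))
  expect_equal(sum(label_components(cl) > 0), sum(cl))
})

test_that("extract_branch_regions recovers one region per branch and cleans dust", {
  gp <- generate_panicle(panicle_spec(seed = 21, n_branches = 7))
  lbl <- extract_branch_regions(gp$image)
  expect_equal(n_regions(lbl), gp$truth$n_branches)

  # blank scan: nothing to detect
  blank <- as_rgb_fixture(matrix(255, 60, 60))
  expect_error(extract_branch_regions(blank), "no panicle")

  # one branch plus sub-100-px dust specks -> exactly one region
  gp1 <- generate_panicle(panicle_spec(seed = 8, n_branches = 1, noise_sd = 0))
  px <- unclass(gp1$image)
  px[3:8, 3:8, ] <- 0            # 36-px speck
  px[12:14, 30:34, ] <- 0        # 15-px speck
  lbl1 <- extract_branch_regions(rgb_image(px, dpi = 72))
  expect_equal(n_regions(lbl1), 1)

  # debug stages carry the overlay b - b*(-f), the surviving part of b
  lbl_d <- extract_branch_regions(gp$image, debug = TRUE)
  st <- attr(lbl_d, "stages")
  expect_named(st, c("gray", "binary", "opened", "filled", "cleaned",
                     "threshold", "overlay"))
  f <- unclass(lbl_d) > 0
  expect_identical(as.logical(st$overlay), as.logical(st$binary & f))
})
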