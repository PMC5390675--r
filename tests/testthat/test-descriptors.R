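test_that("dense SIFT yields 128-dim descriptors on the expected grid", {
  set.seed(21)
  p <- matrix(rnorm(900, sd = 100), 30, 30)
  ds <- dense_sift(p, scales = 4, step = 4)
  expect_identical(nrow(ds$vectors), 128L)
  # brute-force count of valid grid sites: 4*4=16 px support, step 4
  sites <- 0L
  for (r in seq(1, 30, by = 4)) for (c in seq(1, 30, by = 4))
    if (r + 15 <= 30 && c + 15 <= 30) sites <- sites + 1L
  expect_identical(ncol(ds$vectors), sites)
  expect_identical(nrow(ds$keypoints), sites)
  # descriptors are unit-norm (or zero)
  nrm <- sqrt(colSums(ds$vectors^2))
  expect_true(all(abs(nrm - 1) < 1e-8 | nrm == 0))
  # constant patch: zero gradients, all-zero descriptors
  expect_true(all(dense_sift(matrix(5, 30, 30))$vectors == 0))
})

test_that("HOG at keypoints sees gradient orientation", {
  # vertical step edge (gradient along columns) concentrates one bin;
  # the 90-degree rotation moves it by two orientation bins
  stepv <- matrix(0, 30, 30); stepv[, 16:30] <- 100
  kp <- dense_sift(stepv)$keypoints
  hv <- hog_at_keypoints(stepv, kp)
  ev <- rowSums(matrix(rowSums(hv$vectors), 8))
  expect_identical(which.max(ev), 7L)
  expect_equal(sum(ev[-7]), 0)
  steph <- matrix(0, 30, 30); steph[16:30, ] <- 100
  eh <- rowSums(matrix(rowSums(hog_at_keypoints(steph, dense_sift(steph)$keypoints)$vectors), 8))
  expect_identical(which.max(eh), 5L)
  # constant patch: zero histograms
  expect_true(all(hog_at_keypoints(matrix(1, 30, 30), kp)$vectors == 0))
  # out-of-bounds keypoints are dropped with a message
  kp2 <- rbind(kp, data.frame(row = 2, col = 2, scale = 4))
  expect_message(h2 <- hog_at_keypoints(stepv, kp2), "dropped")
  expect_identical(ncol(h2$vectors), nrow(kp))
})

test_that("shape context counts all non-reference points in log-polar bins", {
  set.seed(22)
  pts <- cbind(sample.int(50, 10), sample.int(50, 10))
  h <- shape_context(pts, reference_idx = 1)
  expect_equal(sum(h), 9)
  # all points in one log-polar cell -> a single nonzero bin
  ref <- c(25, 25)
  clump <- rbind(ref, ref + c(10, 0), ref + c(11, 0), ref + c(10, 1))
  h2 <- shape_context(clump, 1)
  expect_identical(sum(h2 > 0), 1L)
  # uniform ring: concentrated in one radial band, spread over angles;
  # matches direct binning computed independently
  th <- seq(0, 2 * pi, length.out = 25)[1:24]
  ring <- rbind(c(0, 0), cbind(10 * cos(th), 10 * sin(th)))
  h3 <- shape_context(ring, 1, radial_bins = 5, angular_bins = 12)
  m3 <- matrix(h3, nrow = 12)
  radial_mass <- colSums(m3)
  expect_identical(sum(radial_mass > 0), 1L)
  expect_gte(sum(m3[, radial_mass > 0] > 0), 10L)
  # independent direct binning oracle
  dall <- c(stats::dist(ring))
  meand <- mean(dall)
  r <- sqrt(rowSums(ring[-1, ]^2)) / meand
  redges <- exp(seq(log(0.125), log(2), length.out = 6))
  rb <- findInterval(r, redges, all.inside = TRUE)
  ang <- atan2(ring[-1, 2], ring[-1, 1])
  ab <- floor((ang + pi) / (2 * pi / 12)) %% 12 + 1
  oracle <- tabulate((rb - 1) * 12 + ab, 60)
  expect_identical(as.integer(h3), oracle)
  # translation invariance
  h4 <- shape_context(ring + 100, 1, radial_bins = 5, angular_bins = 12)
  expect_identical(h4, h3)
  # scaling invariance through mean-distance normalization
  h5 <- shape_context(ring * 3.7, 1, radial_bins = 5, angular_bins = 12)
  expect_identical(h5, h3)
  expect_error(shape_context(matrix(1, 1, 2), 1), "2 points")
})

test_that("global context accumulates curvature mass around the keypoint", {
  expect_true(all(global_context(matrix(3, 41, 41), c(21, 21)) == 0))
  # a single bright dot far from the keypoint puts all mass in the dot's bin
  img <- matrix(0, 41, 41); img[31, 33] <- 50
  h <- global_context(img, c(21, 21))
  expect_identical(sum(h > 0), 1L)
  # conservation: total histogram mass equals summed curvature magnitude
  # within the support disc
  set.seed(23)
  img2 <- matrix(rnorm(41 * 41), 41, 41)
  h2 <- global_context(img2, c(21, 21), support = 20)
  curv <- lobdetect:::.max_curvature(img2)
  idx <- which(curv != 0, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 21)^2 + (idx[, 2] - 21)^2)
  expect_equal(sum(h2), sum(curv[idx][d > 0 & d <= 20]))
  expect_error(global_context(img2, c(100, 1)), "outside")
})

test_that("LIOP is dimensioned by ordinal bins x neighbor permutations", {
  set.seed(24)
  p <- matrix(sample.int(4096, 961, replace = TRUE), 31, 31)
  expect_length(liop(p, neighbors = 4, ordinal_bins = 6), 6 * factorial(4))
  expect_length(liop(p, neighbors = 3, ordinal_bins = 4), 4 * factorial(3))
  expect_error(liop(matrix(0, 30, 30)), "odd")
})

test_that("LIOP is exactly invariant to strictly monotone intensity maps", {
  set.seed(25)
  p <- matrix(sample.int(4096, 961, replace = TRUE), 31, 31)
  expect_identical(liop(p), liop(matrix(as.numeric(p)^3, 31, 31)))
  expect_identical(liop(p), liop(matrix(exp(p / 500), 31, 31)))
})

test_that("LIOP is invariant to quarter-turn rotation of a radial pattern", {
  cc <- 16
  g <- expand.grid(r = 1:31, c = 1:31)
  pat <- matrix(sin(sqrt((g$r - cc)^2 + (g$c - cc)^2)) * 100 + (g$r - cc) * 3, 31, 31)
  expect_equal(liop(pat), liop(rot90(pat)), tolerance = 1e-8)
})

test_that("LBP histogram conserves interior pixels and matches per-pixel codes", {
  set.seed(26)
  p <- matrix(rnorm(31 * 31), 31, 31)
  h <- lbp(p)
  expect_length(h, 59L)
  expect_equal(sum(h), 29 * 29)
  # constant patch: every pixel gets the all-neighbors-equal (all-ones) code
  hc <- lbp(matrix(2, 31, 31))
  expect_identical(sum(hc > 0), 1L)
  expect_equal(sum(hc), 29 * 29)
  # checkerboard against a per-pixel brute-force oracle
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 * 10)
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  codes <- c()
  for (r in 2:9) for (c in 2:9) {
    code <- 0L
    for (j in seq_along(offs))
      if (chk[r + offs[[j]][1], c + offs[[j]][2]] >= chk[r, c])
        code <- code + 2L^(j - 1L)
    codes <- c(codes, code)
  }
  is_uniform <- function(code) {
    bits <- as.integer(intToBits(code)[1:8])
    sum(bits != c(bits[-1], bits[1])) <= 2
  }
  oracle_uniform_total <- sum(vapply(codes, is_uniform, logical(1)))
  h2 <- lbp(chk)
  expect_equal(sum(h2[1:58]), oracle_uniform_total)
  expect_equal(sum(h2), length(codes))
})

test_that("fuse concatenates matching descriptor sets", {
  a <- descriptor_set(matrix(1, 128, 3), data.frame(row = 1:3, col = 1:3, scale = 4), "PHOW")
  b <- descriptor_set(matrix(2, 36, 3), data.frame(row = 1:3, col = 1:3, scale = 4), "HOG")
  f <- fuse(a, b)
  expect_identical(dim(f$vectors), c(164L, 3L))
  expect_true(all(f$vectors[1:128, ] == 1) && all(f$vectors[129:164, ] == 2))
  # empty second argument is the identity
  e <- descriptor_set(matrix(0, 0, 0), NULL, "EMPTY")
  expect_identical(fuse(a, e)$vectors, a$vectors)
  # order matters but both stackings are valid
  g <- fuse(b, a)
  expect_identical(dim(g$vectors), c(164L, 3L))
  expect_false(isTRUE(all.equal(f$vectors, g$vectors)))
  bad <- descriptor_set(matrix(2, 36, 3), data.frame(row = 4:6, col = 1:3, scale = 4), "HOG")
  expect_error(fuse(a, bad), "keypoint")
})

test_that("extract_descriptors dispatches every detector kind", {
  set.seed(27)
  p30 <- matrix(rnorm(900, sd = 50), 30, 30)
  p31 <- matrix(rnorm(961, sd = 50), 31, 31)
  dims <- c(PHOW = 128L, PHOW_HOG = 200L, PHOW_SC = 188L, PHOW_GC = 188L)
  for (k in names(dims)) {
    d <- extract_descriptors(p30, k)
    expect_identical(nrow(d$vectors), dims[[k]])
    expect_gt(ncol(d$vectors), 0L)
  }
  expect_identical(dim(extract_descriptors(p31, "LIOP")$vectors), c(144L, 1L))
  expect_identical(dim(extract_descriptors(p31, "LIOP_LBP")$vectors), c(203L, 1L))
})
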