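test_that("k-means codebook recovers separated clusters and is seeded", {
  set.seed(31)
  X <- t(rbind(matrix(rnorm(100, 0, 0.2), 50, 2), matrix(rnorm(100, 5, 0.2), 50, 2)))
  cb <- build_codebook(X, k = 2, kind = "kmeans", seed = 3)
  cents <- cb$centroids[order(cb$centroids[, 1]), ]
  expect_equal(cents[1, ], c(0, 0), tolerance = 0.15, ignore_attr = TRUE)
  expect_equal(cents[2, ], c(5, 5), tolerance = 0.15, ignore_attr = TRUE)
  # determinism and the distinct-vector precondition
  expect_identical(cb$centroids, build_codebook(X, 2, "kmeans", seed = 3)$centroids)
  expect_error(build_codebook(matrix(1, 2, 10), k = 4, kind = "kmeans"), "distinct")
})

test_that("GMM codebook carries weights and diagonal variances", {
  set.seed(32)
  X <- t(rbind(matrix(rnorm(225, 0, 0.5), 75, 3), matrix(rnorm(225, 4, 0.5), 75, 3)))
  cb <- build_codebook(X, k = 2, kind = "gmm", seed = 5)
  expect_equal(sum(cb$weights), 1)
  expect_identical(dim(cb$variances), dim(cb$centroids))
  expect_true(all(cb$variances > 0))
  cents <- cb$centroids[order(cb$centroids[, 1]), ]
  expect_equal(cents[2, ] - cents[1, ], c(4, 4, 4), tolerance = 0.4,
               ignore_attr = TRUE)
})

test_that("BOF is the nearest-centroid histogram on the probability simplex", {
  set.seed(33)
  cb <- build_codebook(matrix(rnorm(20 * 40), 20, 40), k = 5, kind = "kmeans", seed = 1)
  X <- matrix(rnorm(20 * 30), 20, 30)
  b <- encode_bof(X, cb)
  expect_length(b, 5L)
  expect_equal(sum(b), 1)
  expect_true(all(b >= 0))
  # exhaustive nearest-neighbor oracle
  nn <- apply(X, 2, function(x) which.min(colSums((t(cb$centroids) - x)^2)))
  expect_equal(as.numeric(b), tabulate(nn, 5) / 30)
  # single descriptor is one-hot
  one <- encode_bof(X[, 1, drop = FALSE], cb)
  expect_equal(sort(as.numeric(one), decreasing = TRUE)[1], 1)
  # empty set encodes to the zero vector
  expect_equal(as.numeric(encode_bof(matrix(0, 20, 0), cb)), numeric(5))
})

test_that("VLAD equals brute-force residual accumulation", {
  set.seed(34)
  cb <- build_codebook(matrix(rnorm(8 * 40), 8, 40), k = 4, kind = "kmeans", seed = 2)
  X <- matrix(rnorm(8 * 25), 8, 25)
  v <- encode_vlad(X, cb)
  expect_length(v, 32L)
  expect_equal(sum(v^2), 1)
  nn <- apply(X, 2, function(x) which.min(colSums((t(cb$centroids) - x)^2)))
  acc <- matrix(0, 4, 8)
  for (i in 1:25) acc[nn[i], ] <- acc[nn[i], ] + X[, i] - cb$centroids[nn[i], ]
  ref <- as.numeric(t(acc)); ref <- ref / sqrt(sum(ref^2))
  expect_equal(as.numeric(v), ref)
  # descriptors exactly at centroids: zero residuals, normalization skipped
  atc <- t(cb$centroids)[, c(1, 2, 2, 3)]
  expect_equal(as.numeric(encode_vlad(atc, cb)), numeric(32))
  # one descriptor near c1: only block 1 is nonzero and it is unit-norm
  x1 <- cb$centroids[1, ] + c(0.01, numeric(7))
  v1 <- matrix(as.numeric(encode_vlad(matrix(x1), cb)), nrow = 8)
  expect_equal(sum(v1[, 2:4]^2), 0)
  expect_equal(as.numeric(v1[, 1]), c(1, numeric(7)))
})

test_that("Fisher vector matches the closed-form single-Gaussian gradient", {
  # k = 1, dim = 1 toy with hand-derived gradients of the log-likelihood:
  # dL/dmu ~ mean(z)/sigma, dL/dsigma ~ mean(z^2 - 1), z = (x - mu)/sigma
  cb <- codebook(matrix(2), "gmm", weights = 1, variances = matrix(4))
  xs <- matrix(c(1, 3, 5), 1, 3)
  z <- (c(1, 3, 5) - 2) / 2
  ref <- c(mean(z), mean(z^2 - 1) / sqrt(2))
  ref <- sign(ref) * sqrt(abs(ref))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(as.numeric(encode_fv(xs, cb)), ref)
  # descriptors at the mean with unit responsibility: zero mean-gradient
  at_mu <- matrix(2, 1, 5)
  fv0 <- as.numeric(encode_fv(at_mu, cb))
  expect_equal(fv0[1], 0)
  # dimension 2*k*dim and determinism
  set.seed(35)
  cb2 <- build_codebook(matrix(rnorm(6 * 60), 6, 60), k = 3, kind = "gmm", seed = 4)
  X <- matrix(rnorm(6 * 20), 6, 20)
  expect_length(encode_fv(X, cb2), 2 * 3 * 6)
  expect_equal(as.numeric(encode_fv(X, cb2)), as.numeric(encode_fv(X, cb2)))
  expect_error(encode_fv(X, build_codebook(matrix(rnorm(6 * 60), 6, 60), 3,
                                           "kmeans", 1)), "GMM")
})

test_that("encodings are permutation-invariant in the descriptors", {
  set.seed(36)
  cb <- build_codebook(matrix(rnorm(10 * 50), 10, 50), k = 4, kind = "kmeans", seed = 1)
  cbg <- build_codebook(matrix(rnorm(10 * 50), 10, 50), k = 3, kind = "gmm", seed = 1)
  X <- matrix(rnorm(10 * 15), 10, 15)
  perm <- sample(15)
  expect_equal(as.numeric(encode_bof(X, cb)), as.numeric(encode_bof(X[, perm], cb)))
  expect_equal(as.numeric(encode_vlad(X, cb)), as.numeric(encode_vlad(X[, perm], cb)))
  expect_equal(as.numeric(encode_fv(X, cbg)), as.numeric(encode_fv(X[, perm], cbg)))
})

test_that("positive-sample augmentation produces the jittered box family", {
  set.seed(37)
  boxes <- data.frame(row = sample.int(300, 25) + 50, col = sample.int(300, 25) + 50,
                      height = 30, width = 30)
  aug <- augment_positives(boxes, per_box = 4, jitter_px = 2, seed = 5)
  expect_identical(nrow(aug), 100L)
  expect_identical(sum(!aug$jittered), 25L)
  expect_true(all(abs(aug$row - rep(boxes$row, each = 4)) <= 2))
  # zero jitter: identical copies
  a0 <- augment_positives(boxes, per_box = 3, jitter_px = 0, seed = 1)
  expect_identical(a0$row, rep(boxes$row, each = 3))
  # seeded reproducibility
  expect_identical(aug, augment_positives(boxes, 4, 2, seed = 5))
  # clamping against image bounds is reported
  edge <- data.frame(row = 1, col = 1, height = 30, width = 30)
  expect_message(ae <- augment_positives(edge, per_box = 10, jitter_px = 3, seed = 2,
                                         image_size = c(40, 40)), "clamped")
  expect_true(all(ae$row >= 1 & ae$col >= 1))
})

test_that("training separates phantom lobulated from smooth patches", {
  set.seed(38)
  mkpatch <- function(lob, seed) {
    nd <- nodule_spec(c(30, 30), runif(1, 10, 13), if (lob) runif(1, 0.15, 0.2) else 0,
                      if (lob) sample(4:6, 1) else 0)
    cfg <- phantom_config(c(59, 59), noise_sigma = 10, vessels = 0,
                          nodules = list(nd), lung_radius = 29, seed = seed)
    generate_phantom(cfg)$hu$values[15:45, 15:45]
  }
  pos <- lapply(1:12, function(i) mkpatch(TRUE, i))
  neg <- lapply(1:24, function(i) mkpatch(FALSE, 100 + i))
  model <- train_detector(pos[1:8], neg[1:16], "LIOP_LBP", "BOF", k = 8, seed = 1)
  # in-sample separation on a linearly separable-ish encoding
  enc <- function(p) as.numeric(encode(extract_descriptors(p, "LIOP_LBP"),
                                       model$codebook, "BOF"))
  Xte <- t(vapply(c(pos[9:12], neg[17:24]), enc, numeric(8)))
  pr <- predict(model$svm, Xte)
  acc <- mean(pr == rep(c("pos", "neg"), c(4, 8)))
  expect_gt(acc, 0.66)
  # persisted model reloads identically
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  expect_equal(load_model(f), model)
  unlink(f)
  expect_error(train_detector(list(), neg, "LIOP_LBP", "BOF"), "nonempty")
})

test_that("detect enforces the odd LIOP window and stays deterministic", {
  set.seed(39)
  nd <- nodule_spec(c(64, 64), 12, 0.18, 5)
  cfg <- phantom_config(c(128, 128), nodules = list(nd), vessels = 1,
                        lung_radius = 60, seed = 7)
  ph <- generate_phantom(cfg)
  mask <- segment_parenchyma(ph$hu, 60)
  pos <- lapply(1:6, function(i) {
    ph$hu$values[(49 + i):(79 + i), (49 + i):(79 + i)]
  })
  neg <- lapply(seq(1, 60, by = 8), function(o)
    ph$hu$values[o:(o + 30), 1:31])
  model <- train_detector(pos, neg, "LIOP_LBP", "BOF", k = 4, seed = 2)
  expect_error(detect(ph$hu, mask, model, window_spec(30, 8)), "incompatible")
  d1 <- detect(ph$hu, mask, model, window_spec(31, 8))
  d2 <- detect(ph$hu, mask, model, window_spec(31, 8))
  expect_identical(d1, d2)
  # doubling the step never increases the number of evaluated windows
  n8 <- nrow(window_positions(ph$hu, mask, window_spec(31, 8)))
  n16 <- nrow(window_positions(ph$hu, mask, window_spec(31, 16)))
  expect_lte(n16, n8)
})

test_that("the A2-A9 table maps ids to descriptor/encoding pairs", {
  tab <- algorithm_table()
  expect_identical(tab$id, paste0("A", 2:9))
  expect_identical(tab$encoding[tab$id == "A3"], "FV")
  expect_identical(tab$encoding[tab$id == "A4"], "VLAD")
  expect_identical(tab$descriptor[tab$id == "A8"], "LIOP")
  expect_identical(tab$descriptor[tab$id == "A9"], "LIOP_LBP")
  expect_true(all(tab$window_px[tab$descriptor %in% c("LIOP", "LIOP_LBP")] == 31L))
  expect_true(all(tab$window_px[!tab$descriptor %in% c("LIOP", "LIOP_LBP")] == 30L))
})
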