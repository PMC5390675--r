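test_that("Otsu threshold maximizes between-class variance", {
  # two-level patch: threshold strictly between the levels
  p <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  th <- otsu_threshold(p)
  expect_gt(th, 10); expect_lt(th, 200)
  fg <- otsu_binarize(p)
  expect_identical(fg, p > th)
  expect_identical(sum(fg), 50L)
  # constant patch: empty foreground, with a message
  expect_message(fc <- otsu_binarize(matrix(7, 5, 5)), "constant")
  expect_false(any(fc))
  # exhaustive search oracle over the same 256-level quantization
  set.seed(41)
  p2 <- matrix(rnorm(400, 100, 40), 20, 20)
  th2 <- otsu_threshold(p2, levels = 256)
  rng <- range(p2)
  q <- floor((p2 - rng[1]) / diff(rng) * 255)
  bcv <- function(t) {
    w0 <- mean(q <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(q[q <= t]) - mean(q[q > t]))^2
  }
  scores <- vapply(0:254, bcv, numeric(1))
  best_bin <- which.max(scores) - 1
  th2_bin <- floor((th2 - rng[1]) / diff(rng) * 255)
  expect_lte(abs(th2_bin - best_bin), 1)
})

test_that("extract_contour traces the dominant closed boundary", {
  # filled axis-aligned square: perimeter close to 4s
  b <- matrix(FALSE, 40, 40); b[11:30, 11:30] <- TRUE
  ct <- extract_contour(b)
  expect_equal(ct$P, 80, tolerance = 0.05)
  expect_identical(ct$M, 256L)
  # two components: the larger is selected
  b2 <- b; b2[2:5, 2:5] <- TRUE
  ct2 <- extract_contour(b2)
  expect_equal(ct2$P, ct$P, tolerance = 0.02)
  # filled digital disc r = 12: perimeter within 2% of 2*pi*r
  g <- expand.grid(r = 1:40, c = 1:40)
  disc <- matrix((g$r - 20)^2 + (g$c - 20)^2 <= 144, 40, 40)
  expect_equal(extract_contour(disc)$P, 2 * pi * 12, tolerance = 0.02)
  expect_error(extract_contour(matrix(FALSE, 10, 10)), "foreground")
  # foreground running off every border leaves no closed loop
  stripe <- matrix(FALSE, 20, 20); stripe[9:12, ] <- TRUE
  expect_error(extract_contour(stripe), "closed")
})

test_that("curvature matches closed forms on analytic contours", {
  t <- seq(0, 2 * pi, length.out = 4097)[1:4096]
  # circle: constant curvature 1/r
  cc <- contour_from_points(10 * cos(t), 10 * sin(t), 256)
  expect_equal(contour_curvature(cc), rep(0.1, 256), tolerance = 1e-4)
  # ellipse: k(t) = ab / (a^2 sin^2 t + b^2 cos^2 t)^(3/2), within 1%
  a <- 20; b <- 12
  ce <- contour_from_points(a * cos(t), b * sin(t), 256)
  kap <- contour_curvature(ce, harmonics = 48)
  tt <- atan2(ce$y / b, ce$x / a)
  kref <- a * b / ((a^2 * sin(tt)^2 + b^2 * cos(tt)^2)^1.5)
  expect_lt(max(abs(kap - kref) / kref), 0.01)
  # rounded-rectangle straight run: near-zero curvature away from corners
  th2 <- seq(0, 2 * pi, length.out = 1025)[1:1024]
  rr <- cbind(24 * cos(th2), 10 * sin(th2))  # elongated oval as stand-in
  cr <- contour_from_points(rr[, 1], rr[, 2], 256)
  kap2 <- contour_curvature(cr, harmonics = 48)
  expect_lt(min(abs(kap2)), 0.03)
  expect_error(contour_curvature(structure(list(M = 4), class = "lob_contour")),
               "at least 8")
})

test_that("Fourier and finite-difference curvature agree on analytic contours", {
  t <- seq(0, 2 * pi, length.out = 4097)[1:4096]
  for (ab in list(c(10, 10), c(20, 12))) {
    ct <- contour_from_points(ab[1] * cos(t), ab[2] * sin(t), 256)
    kf <- contour_curvature(ct, harmonics = 48)
    kd <- contour_curvature(ct, method = "diff")
    expect_lt(max(abs(kf - kd) / abs(kd)), 0.01)
  }
})

test_that("bending energy obeys the circle closed form and 1/s^2 scaling", {
  t <- seq(0, 2 * pi, length.out = 2049)[1:2048]
  # circle radius 10: E = 1/r^2 = 0.01
  c10 <- contour_from_points(10 * cos(t), 10 * sin(t), 256)
  expect_equal(bending_energy(c10), 0.01, tolerance = 1e-6)
  # lobulated contour scaled by s: E scales by 1/s^2 exactly
  r <- 12 * (1 + 0.15 * sin(5 * t))
  E1 <- bending_energy(contour_from_points(r * cos(t), r * sin(t), 256))
  for (s in c(0.5, 2, 4)) {
    Es <- bending_energy(contour_from_points(s * r * cos(t), s * r * sin(t), 256))
    expect_equal(Es * s^2, E1, tolerance = 1e-6)
  }
  # rotation/translation invariance
  xr <- r * cos(t + 1.1) + 40; yr <- r * sin(t + 1.1) - 17
  expect_equal(bending_energy(contour_from_points(xr, yr, 256)), E1, tolerance = 1e-6)
})

test_that("rasterized phantom margins reproduce the quadrature energy", {
  # digitized circle r = 10 (partial-volume rendering, Otsu-level trace)
  p <- render_disc(10)
  E <- bending_energy(extract_contour(p))
  expect_equal(E, 0.01, tolerance = 0.05)
  # sin-perturbed margin against dense quadrature of the analytic curvature
  nd <- nodule_spec(c(1, 1), 12, 0.15, 5)
  E_ref <- nodule_reference_energy(nd)
  pl <- render_disc(12, 0.15, 5)
  El <- bending_energy(extract_contour(pl))
  expect_equal(El, E_ref, tolerance = 0.05)
  expect_gt(E_ref, 1 / 144)
})

test_that("filter_candidates keeps undulating margins and drops smooth ones", {
  # one smooth (r = 12 -> E ~ 0.007 < theta1) and one lobulated nodule
  nds <- list(nodule_spec(c(70, 70), 12, 0, 0),
              nodule_spec(c(180, 180), 12, 0.18, 5))
  cfg <- phantom_config(c(256, 256), nodules = nds, vessels = 0,
                        lung_radius = 120, seed = 3)
  ph <- generate_phantom(cfg)
  boxes <- data.frame(source_id = "phantom", row = c(55, 165), col = c(55, 165),
                      height = 31, width = 31, score = c(1, 2),
                      algorithm = "A9", stringsAsFactors = FALSE)
  kept <- filter_candidates(boxes, ph$hu)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$row, 165)
  diag <- attr(kept, "diagnostics")
  expect_lt(diag$E[1], 0.0124)
  expect_gt(diag$E[2], 0.0124)
  # empty input passes through
  expect_identical(nrow(filter_candidates(boxes[0, ], ph$hu)), 0L)
  # the theta2 guard rejects windows dominated by foreground
  tight <- bending_filter_params(theta2 = 0.05)
  expect_identical(nrow(filter_candidates(boxes, ph$hu, tight)), 0L)
})
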