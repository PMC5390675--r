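# Bending-energy false-positive filter.
#
# Candidate windows are binarized by Otsu's threshold, the boundary of the
# dominant foreground component is traced as a closed sub-pixel isocontour,
# its curvature is computed from a truncated Fourier series of the
# arc-length parameterization (x(p), y(p)), and the average bending energy
# per unit length E = (1/P) * integral k(p)^2 dp decides whether a window
# is kept. A circle of radius r has E = 1/r^2, so a smooth nodule margin
# scores low while an undulating (lobulated) one scores high.

#' Bending-filter parameters
#'
#' The energy threshold `theta1 = 0.0124` and the guard `theta2 = 0.8`
#' (maximum foreground-area fraction of the window) are the operating
#' points of the filter; `resample_points` is the number of equal
#' arc-length samples of the contour.
#'
#' @param theta1 Minimum bending energy for a window to be kept (> 0).
#' @param theta2 Maximum foreground-area fraction (in `(0, 1]`).
#' @param resample_points Contour samples `M` (>= 8, even).
#' @return An object of class `bending_filter_params`.
#' @export
bending_filter_params <- function(theta1 = 0.0124, theta2 = 0.8,
                                  resample_points = 256) {
  .assert(theta1 > 0, "theta1 must be > 0")
  .assert(theta2 > 0 && theta2 <= 1, "theta2 must be in (0, 1]")
  .assert(resample_points >= 8 && resample_points %% 2 == 0,
          "resample_points must be even and >= 8")
  structure(list(theta1 = theta1, theta2 = theta2,
                 resample_points = as.integer(resample_points)),
            class = "bending_filter_params")
}

#' Otsu threshold and binarization of a patch
#'
#' The threshold maximizes the between-class variance of the 256-level
#' patch histogram; foreground is the above-threshold class. A constant
#' patch has no threshold and binarizes to all-background.
#'
#' @param patch A patch object or numeric matrix.
#' @param levels Histogram resolution.
#' @return `otsu_threshold`: the threshold on the patch intensity scale
#'   (`NA` for a constant patch). `otsu_binarize`: a logical foreground
#'   matrix.
#' @export
otsu_threshold <- function(patch, levels = 256) {
  m <- .as_pixels(patch)
  rng <- range(m)
  if (diff(rng) == 0) return(NA_real_)
  z <- (m - rng[1L]) / diff(rng)
  th <- EBImage::otsu(z, range = c(0, 1), levels = levels)
  rng[1L] + th * diff(rng)
}

#' @rdname otsu_threshold
#' @export
otsu_binarize <- function(patch, levels = 256) {
  m <- .as_pixels(patch)
  th <- otsu_threshold(m, levels)
  if (is.na(th)) {
    message("otsu_binarize: constant patch, returning empty foreground")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  m > th
}

#' Extract the closed boundary contour of the dominant foreground object
#'
#' Traces the level-set isocontour of the raster with marching squares
#' (sub-pixel positions), picks the closed loop enclosing the largest area,
#' and resamples it to `M` points equally spaced in arc length. Binary
#' input is smoothed with a 1 px Gaussian first, recovering a sub-pixel
#' boundary from the pixelated mask; grayscale input (e.g. an HU patch with
#' the Otsu threshold as `level`) is smoothed only lightly (0.3 px), since
#' its partial-volume transitions already carry sub-pixel information.
#'
#' @param x Logical or numeric matrix (or patch object).
#' @param level Iso-level to trace; default 0.5 for logical input, the
#'   Otsu threshold for numeric input.
#' @param smooth_sigma Gaussian pre-smoothing in px; default 1 for logical
#'   input, 0.5 for numeric.
#' @param M Number of equal arc-length samples (even, >= 8).
#' @param select Optional `(row, col)` point: return the closed loop
#'   containing it (or with the nearest centroid) instead of the largest.
#' @return An object of class `lob_contour`: `x`, `y` (sub-pixel row/col
#'   coordinates), perimeter `P`, `M`, `closed`.
#' @export
extract_contour <- function(x, level = NULL, smooth_sigma = NULL, M = 256,
                            select = NULL) {
  .assert(M >= 8 && M %% 2 == 0, "M must be even and >= 8")
  binary <- is.logical(x) || (is.matrix(x) && all(x %in% c(0, 1)))
  m <- .as_pixels(if (is.logical(x)) x * 1 else x)
  storage.mode(m) <- "double"
  if (binary) .assert(any(m > 0), "empty foreground")
  if (is.null(smooth_sigma)) smooth_sigma <- if (binary) 1 else 0.3
  if (is.null(level)) {
    level <- if (binary) 0.5 else otsu_threshold(m)
    .assert(!is.na(level), "constant raster has no contour")
  }
  ms <- .gauss_smooth(m, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = ms, levels = level)
  closed <- Filter(function(u) {
    length(u$x) >= 4 && u$x[1] == u$x[length(u$x)] && u$y[1] == u$y[length(u$y)]
  }, cl)
  .assert(length(closed) > 0, "no closed contour")
  area <- vapply(closed, function(u) {
    n <- length(u$x)
    abs(sum(u$x[-n] * u$y[-1] - u$x[-1] * u$y[-n])) / 2
  }, numeric(1))
  pick <- which.max(area)
  if (!is.null(select)) {
    inside <- vapply(closed, function(u)
      .point_in_poly(select[1L], select[2L], u$x, u$y), logical(1))
    if (any(inside)) {
      pick <- which(inside)[which.max(area[inside])]
    } else {
      cdist <- vapply(closed, function(u)
        sqrt((mean(u$x) - select[1L])^2 + (mean(u$y) - select[2L])^2), numeric(1))
      pick <- which.min(cdist)
    }
  }
  best <- closed[[pick]]
  px <- best$x[-length(best$x)]; py <- best$y[-length(best$y)]
  .resample_contour(px, py, M)
}

# Ray-casting point-in-polygon test.
.point_in_poly <- function(pr, pc, px, py) {
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((py[i] > pc) != (py[j] > pc)) &&
        (pr < (px[j] - px[i]) * (pc - py[i]) / (py[j] - py[i]) + px[i]))
      inside <- !inside
    j <- i
  }
  inside
}

# Equal arc-length resampling of a closed polygon.
.resample_contour <- function(px, py, M) {
  d <- sqrt(diff(c(px, px[1L]))^2 + diff(c(py, py[1L]))^2)
  s <- c(0, cumsum(d))
  P <- s[length(s)]
  .assert(P > 0, "degenerate contour")
  t <- seq(0, P, length.out = M + 1L)[seq_len(M)]
  structure(list(x = stats::approx(s, c(px, px[1L]), xout = t)$y,
                 y = stats::approx(s, c(py, py[1L]), xout = t)$y,
                 P = P, M = as.integer(M), closed = TRUE),
            class = "lob_contour")
}

#' Create a contour from explicit points
#'
#' Resamples a closed polygon (e.g. analytic curve samples) to `M` equal
#' arc-length points.
#'
#' @param x,y Coordinates of a closed curve (last point should not repeat
#'   the first).
#' @param M Number of resampled points.
#' @return A `lob_contour`.
#' @export
contour_from_points <- function(x, y, M = 256) {
  .assert(length(x) == length(y) && length(x) >= 4, "need >= 4 points")
  .resample_contour(x, y, M)
}

#' @export
print.lob_contour <- function(x, ...) {
  cat(sprintf("<lob_contour: M=%d, P=%.2f px>\n", x$M, x$P))
  invisible(x)
}

# Fourier representation of the contour with a harmonic-selection rule:
# keep |k| <= 1 always, plus any harmonic whose amplitude is at least
# `rel_amp` times the fundamental's. Pixel-level digitization noise sits
# well below that fraction of the object size, while genuine margin
# undulations sit well above it, so the rule adapts the cutoff to the
# shape and keeps the selection invariant under uniform scaling.
.contour_fourier <- function(contour, harmonics = "auto", rel_amp = 0.0025) {
  M <- contour$M
  X <- stats::fft(contour$x); Y <- stats::fft(contour$y)
  k <- c(0:(M / 2), -((M / 2 - 1):1))
  if (identical(harmonics, "auto")) {
    A <- sqrt(Mod(X / M)^2 + Mod(Y / M)^2)
    amp_of <- function(j) sqrt(sum(A[abs(k) == j]^2))
    A1 <- amp_of(1L)
    keep_j <- vapply(seq_len(M / 2), function(j) amp_of(j) >= rel_amp * A1, logical(1))
    keep <- abs(k) <= 1 | (abs(k) >= 1 & keep_j[pmax(abs(k), 1L)])
    keep <- keep & abs(k) <= M / 4
  } else {
    .assert(.is_scalar_number(harmonics) && harmonics >= 1, "harmonics must be >= 1 or 'auto'")
    keep <- abs(k) <= harmonics
  }
  X[!keep] <- 0; Y[!keep] <- 0
  list(X = X, Y = Y, k = k)
}

#' Curvature along a closed contour
#'
#' The default estimator differentiates the truncated Fourier series of
#' `(x(p), y(p))`; harmonic selection is automatic (amplitude-based, see
#' Details in the package vignette) or an explicit cutoff. The
#' finite-difference estimator (`method = "diff"`) is a three-point
#' circular stencil retained as an independent cross-check.
#'
#' @param contour A `lob_contour` (M >= 8).
#' @param harmonics `"auto"` or a harmonic cutoff for the Fourier method.
#' @param method `"fourier"` or `"diff"`.
#' @return Numeric vector of signed curvatures (1/px) at the M samples.
#' @export
contour_curvature <- function(contour, harmonics = "auto",
                              method = c("fourier", "diff")) {
  .assert(inherits(contour, "lob_contour"), "contour must be a lob_contour")
  .assert(contour$M >= 8, "contour must have at least 8 samples")
  method <- match.arg(method)
  if (method == "diff") {
    x <- contour$x; y <- contour$y; M <- contour$M
    ip <- c(2:M, 1L); im <- c(M, 1:(M - 1L))
    x1 <- (x[ip] - x[im]) / 2; y1 <- (y[ip] - y[im]) / 2
    x2 <- x[ip] - 2 * x + x[im]; y2 <- y[ip] - 2 * y + y[im]
    return((x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5)
  }
  f <- .contour_fourier(contour, harmonics)
  M <- contour$M
  ik <- 2i * pi * f$k / M
  x1 <- Re(stats::fft(f$X * ik, inverse = TRUE)) / M
  y1 <- Re(stats::fft(f$Y * ik, inverse = TRUE)) / M
  x2 <- Re(stats::fft(f$X * ik^2, inverse = TRUE)) / M
  y2 <- Re(stats::fft(f$Y * ik^2, inverse = TRUE)) / M
  (x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
}

#' Average bending energy per unit length of a closed contour
#'
#' `E = (1/P) * integral k(p)^2 dp`, evaluated on the (Fourier-smoothed)
#' contour; `P` is the smoothed perimeter for the Fourier method and the
#' polygon perimeter for the finite-difference method. A circle of radius
#' `r` has `E = 1/r^2`; scaling a contour by `s` scales `E` by `1/s^2`.
#'
#' @inheritParams contour_curvature
#' @return Nonnegative scalar energy (1/px^2).
#' @export
bending_energy <- function(contour, harmonics = "auto",
                           method = c("fourier", "diff")) {
  method <- match.arg(method)
  if (method == "diff") {
    kap <- contour_curvature(contour, method = "diff")
    return(mean(kap^2))
  }
  f <- .contour_fourier(contour, harmonics)
  M <- contour$M
  ik <- 2i * pi * f$k / M
  x1 <- Re(stats::fft(f$X * ik, inverse = TRUE)) / M
  y1 <- Re(stats::fft(f$Y * ik, inverse = TRUE)) / M
  x2 <- Re(stats::fft(f$X * ik^2, inverse = TRUE)) / M
  y2 <- Re(stats::fft(f$Y * ik^2, inverse = TRUE)) / M
  sp <- sqrt(x1^2 + y1^2)
  kap <- (x1 * y2 - y1 * x2) / sp^3
  sum(kap^2 * sp) / sum(sp)
}

#' Bending-energy filtering of candidate detections
#'
#' The lesion a candidate window points at usually extends beyond the
#' window, so each box is analyzed on a context crop grown by half the box
#' size on every side. The crop is binarized by Otsu's method, the closed
#' threshold-level contour containing the window center is traced, and the
#' box is kept iff its bending energy is at least `theta1` and the
#' foreground-area fraction *of the window itself* is at most `theta2`.
#' Windows whose object yields no closed contour (clipped at the image
#' border, or constant intensity) are rejected. The output is a subset of
#' the input in the original order, with per-box diagnostics (`E`,
#' `area_frac`) attached as attribute `"diagnostics"`.
#'
#' @param boxes Detection data frame (from [detect()] or [match_top_n()]).
#' @param hu The [hu_image()] the boxes refer to.
#' @param params A [bending_filter_params()].
#' @param context_pad Crop margin around the box in px; default half the
#'   box size.
#' @return Filtered detection data frame.
#' @export
filter_candidates <- function(boxes, hu, params = bending_filter_params(),
                              context_pad = NULL) {
  v <- .as_pixels(hu)
  n <- nrow(boxes)
  E <- rep(NA_real_, n); af <- rep(NA_real_, n); keep <- logical(n)
  for (i in seq_len(n)) {
    h <- boxes$height[i]; w <- boxes$width[i]
    pad <- if (is.null(context_pad)) ceiling(max(h, w) / 2) else context_pad
    r0 <- max(1L, boxes$row[i] - pad); c0 <- max(1L, boxes$col[i] - pad)
    r1 <- min(nrow(v), boxes$row[i] + h - 1L + pad)
    c1 <- min(ncol(v), boxes$col[i] + w - 1L + pad)
    p <- v[r0:r1, c0:c1, drop = FALSE]
    th <- otsu_threshold(p)
    if (is.na(th)) next
    wr <- max(1L, boxes$row[i]):min(nrow(v), boxes$row[i] + h - 1L)
    wc <- max(1L, boxes$col[i]):min(ncol(v), boxes$col[i] + w - 1L)
    af[i] <- mean(v[wr, wc] > th)
    ctr <- c(boxes$row[i] + floor(h / 2) - r0 + 1L,
             boxes$col[i] + floor(w / 2) - c0 + 1L)
    ct <- tryCatch(extract_contour(p, level = th, M = params$resample_points,
                                   select = ctr),
                   error = function(e) NULL)
    if (is.null(ct)) next
    E[i] <- bending_energy(ct)
    keep[i] <- E[i] >= params$theta1 && af[i] <= params$theta2
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- data.frame(row = boxes$row, col = boxes$col,
                                         E = E, area_frac = af, kept = keep)
  out
}
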