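# Local descriptors extracted from sliding-window patches.
#
# All keypoint-based descriptors share the dense-SIFT grid keypoints, so
# SIFT/HOG/shape-context/global-context columns can be concatenated
# column-wise. LIOP and LBP are whole-patch descriptors (one column).

#' Descriptor set container
#'
#' @param vectors Numeric matrix, one descriptor per column (`dim x N`).
#' @param keypoints Data frame with columns `row`, `col`, `scale` (one row
#'   per descriptor), or `NULL` for whole-patch descriptors.
#' @param kind Descriptor kind label.
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(vectors, keypoints = NULL, kind = "PHOW") {
  .assert(is.matrix(vectors), "vectors must be a dim x N matrix")
  if (!is.null(keypoints))
    .assert(nrow(keypoints) == ncol(vectors), "one keypoint per descriptor required")
  structure(list(vectors = vectors, keypoints = keypoints, kind = kind),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set %s: %d x %d>\n", x$kind, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

# Central-difference gradients with zero borders.
.gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  if (nr > 2) gr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nc > 2) gc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  list(gr = gr, gc = gc)
}

# Per-orientation gradient-magnitude maps (hard assignment into `bins`
# equal sectors of [-pi, pi)), returned as integral images.
.orientation_integrals <- function(m, bins = 8L) {
  g <- .gradients(m)
  mag <- sqrt(g$gr^2 + g$gc^2)
  ang <- atan2(g$gc, g$gr)
  b <- (floor((ang + pi) / (2 * pi / bins))) %% bins + 1L
  lapply(seq_len(bins), function(k) .integral_image(mag * (b == k)))
}

#' Dense SIFT (PHOW) descriptors on a regular grid
#'
#' Simple dense SIFT: at each grid site a 4x4 array of `bin_px`-sized cells
#' accumulates gradient magnitude into 8 orientation bins, giving the usual
#' 128-dimensional descriptor, which is L2-normalized, clipped at 0.2 and
#' renormalized. Applied at several cell sizes (`scales`) to mimic the
#' multi-resolution dense SIFT of PHOW. A constant patch has zero gradients
#' and yields all-zero descriptors.
#'
#' @param patch A patch object or numeric matrix (at least 16x16).
#' @param scales Cell sizes in pixels; each descriptor covers `4 * scale`.
#' @param step Grid step between keypoints in pixels.
#' @return A [descriptor_set()] of kind `"PHOW"` (128 x N).
#' @export
dense_sift <- function(patch, scales = c(4, 6, 8, 10), step = 3) {
  m <- .as_pixels(patch)
  .assert(min(dim(m)) >= 16, "patch must be at least 16x16")
  oi <- .orientation_integrals(m, 8L)
  vecs <- list(); kps <- list()
  for (b in scales) {
    side <- 4L * b
    if (side > min(dim(m))) next
    tr <- seq.int(1L, nrow(m) - side + 1L, by = step)
    tc <- seq.int(1L, ncol(m) - side + 1L, by = step)
    if (!length(tr) || !length(tc)) next
    grid <- cbind(rep(tr, each = length(tc)), rep(tc, times = length(tr)))
    nkp <- nrow(grid)
    d <- matrix(0, 128L, nkp)
    row1 <- 0L
    for (u in 0:3) for (v in 0:3) {
      rs <- grid[, 1L] + u * b
      cs <- grid[, 2L] + v * b
      for (o in 1:8) {
        d[row1 + o, ] <- .block_sum(oi[[o]], rs, cs, b, b)
      }
      row1 <- row1 + 8L
    }
    d <- apply(d, 2L, function(v) {
      v <- .l2_normalize(v)
      v <- pmin(v, 0.2)
      .l2_normalize(v)
    })
    if (is.null(dim(d))) d <- matrix(d, 128L)
    vecs[[length(vecs) + 1L]] <- d
    kps[[length(kps) + 1L]] <- data.frame(row = grid[, 1L] + 2L * b,
                                          col = grid[, 2L] + 2L * b, scale = b)
  }
  if (!length(vecs))
    return(descriptor_set(matrix(0, 128L, 0L),
                          data.frame(row = integer(), col = integer(), scale = numeric()),
                          "PHOW"))
  descriptor_set(do.call(cbind, vecs), do.call(rbind, kps), "PHOW")
}

#' HOG descriptors at given keypoints
#'
#' A 3x3 block of `cell_px`-sized cells centered on each keypoint, 8
#' orientation bins per cell (72 dimensions), block-L2-normalized. Keypoints
#' whose block leaves the patch are dropped with a message.
#'
#' @param patch A patch object or numeric matrix.
#' @param keypoints Data frame with `row`, `col` columns (e.g. from
#'   [dense_sift()]).
#' @param cell_px Cell side length in pixels.
#' @return A [descriptor_set()] of kind `"HOG"`.
#' @export
hog_at_keypoints <- function(patch, keypoints, cell_px = 4) {
  m <- .as_pixels(patch)
  side <- 3L * cell_px
  half <- floor(side / 2)
  tl_r <- keypoints$row - half
  tl_c <- keypoints$col - half
  ok <- tl_r >= 1 & tl_c >= 1 & tl_r + side - 1 <= nrow(m) & tl_c + side - 1 <= ncol(m)
  if (any(!ok)) message(sprintf("hog_at_keypoints: dropped %d out-of-bounds keypoint(s)",
                                sum(!ok)))
  kp <- keypoints[ok, , drop = FALSE]
  oi <- .orientation_integrals(m, 8L)
  d <- matrix(0, 72L, nrow(kp))
  if (nrow(kp)) {
    row1 <- 0L
    for (u in 0:2) for (v in 0:2) {
      rs <- kp$row - half + u * cell_px
      cs <- kp$col - half + v * cell_px
      for (o in 1:8) d[row1 + o, ] <- .block_sum(oi[[o]], rs, cs, cell_px, cell_px)
      row1 <- row1 + 8L
    }
    d <- apply(d, 2L, .l2_normalize)
    if (is.null(dim(d))) d <- matrix(d, 72L)
  }
  out <- descriptor_set(d, kp, "HOG")
  attr(out, "kept") <- ok
  out
}

#' Canny edge detection
#'
#' Central-difference gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding. Thresholds
#' are fractions of the patch intensity range.
#'
#' @param patch A patch object or numeric matrix.
#' @param low,high Hysteresis thresholds as fractions of the intensity range.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(patch, low = 0.1, high = 0.2) {
  m <- .as_pixels(patch)
  rng <- diff(range(m))
  if (rng == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  g <- .gradients(m)
  mag <- sqrt(g$gr^2 + g$gc^2)
  ang <- atan2(g$gc, g$gr)
  # quantize direction into 4 sectors: 0=row, 1=diag, 2=col, 3=anti-diag
  sector <- (round(ang / (pi / 4)) %% 4 + 4) %% 4
  nr <- nrow(m); nc <- ncol(m)
  nms <- matrix(FALSE, nr, nc)
  ir <- 2:(nr - 1); ic <- 2:(nc - 1)
  off <- list(`0` = c(1L, 0L), `1` = c(1L, 1L), `2` = c(0L, 1L), `3` = c(-1L, 1L))
  core <- mag[ir, ic]
  for (s in 0:3) {
    o <- off[[as.character(s)]]
    sel <- sector[ir, ic] == s
    n1 <- mag[ir + o[1L], ic + o[2L]]
    n2 <- mag[ir - o[1L], ic - o[2L]]
    nms[ir, ic] <- nms[ir, ic] | (sel & core >= n1 & core >= n2)
  }
  strong <- nms & mag >= high * rng
  weak <- nms & mag >= low * rng
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nr, nc) & weak
}

# Log-polar binning shared by shape and global context. Returns bin indices
# (1..radial*angular) for relative offsets (dr, dc); radii are clamped into
# the end bins so no sample is lost.
.logpolar_bins <- function(dr, dc, radial_bins, angular_bins, r_min, r_max) {
  r <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  redges <- exp(seq(log(r_min), log(r_max), length.out = radial_bins + 1L))
  rb <- findInterval(r, redges, all.inside = TRUE)
  ab <- (floor((theta + pi) / (2 * pi / angular_bins))) %% angular_bins + 1L
  (rb - 1L) * angular_bins + ab
}

#' Shape context of a point set
#'
#' Log-polar histogram of the positions of all other points relative to a
#' reference point. Radii are normalized by the mean pairwise distance of
#' the point set, making the histogram invariant to translation and uniform
#' scaling; out-of-range radii are clamped into the end bins so the
#' histogram total is always `nrow(points) - 1`.
#'
#' @param points Numeric matrix of `(row, col)` positions (>= 2 points),
#'   e.g. edge pixels from [canny_edges()].
#' @param reference_idx Index of the reference point.
#' @param radial_bins,angular_bins Log-polar resolution.
#' @param r_min,r_max Radial range in units of the mean pairwise distance.
#' @return Numeric histogram of length `radial_bins * angular_bins`.
#' @export
shape_context <- function(points, reference_idx, radial_bins = 5, angular_bins = 12,
                          r_min = 0.125, r_max = 2) {
  .assert(is.matrix(points) && nrow(points) >= 2, "need at least 2 points")
  ref <- points[reference_idx, ]
  rest <- points[-reference_idx, , drop = FALSE]
  meand <- mean(stats::dist(points))
  if (meand == 0) meand <- 1
  bins <- .logpolar_bins((rest[, 1L] - ref[1L]) / meand, (rest[, 2L] - ref[2L]) / meand,
                         radial_bins, angular_bins, r_min, r_max)
  tabulate(bins, nbins = radial_bins * angular_bins)
}

# Shape-context descriptors at dense-SIFT keypoints: histogram of Canny
# edge pixels relative to each keypoint, L1-normalized.
.sc_at_keypoints <- function(patch, keypoints, radial_bins = 5, angular_bins = 12,
                             canny_low = 0.1, canny_high = 0.2) {
  m <- .as_pixels(patch)
  ed <- which(canny_edges(m, canny_low, canny_high), arr.ind = TRUE)
  nb <- radial_bins * angular_bins
  d <- matrix(0, nb, nrow(keypoints))
  if (nrow(ed) >= 2) {
    meand <- mean(stats::dist(ed))
    if (meand == 0) meand <- 1
    for (i in seq_len(nrow(keypoints))) {
      dr <- (ed[, 1L] - keypoints$row[i]) / meand
      dc <- (ed[, 2L] - keypoints$col[i]) / meand
      sel <- dr != 0 | dc != 0
      h <- tabulate(.logpolar_bins(dr[sel], dc[sel], radial_bins, angular_bins,
                                   0.125, 2), nbins = nb)
      s <- sum(h)
      d[, i] <- if (s > 0) h / s else h
    }
  }
  descriptor_set(d, keypoints, "SC")
}

# Maximum-curvature raster: largest-magnitude eigenvalue of the local
# Hessian at each pixel (zero on the one-pixel border).
.max_curvature <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  .assert(nr >= 3 && nc >= 3, "image must be at least 3x3")
  hrr <- matrix(0, nr, nc); hcc <- matrix(0, nr, nc); hrc <- matrix(0, nr, nc)
  hrr[2:(nr - 1), ] <- m[3:nr, ] - 2 * m[2:(nr - 1), ] + m[1:(nr - 2), ]
  hcc[, 2:(nc - 1)] <- m[, 3:nc] - 2 * m[, 2:(nc - 1)] + m[, 1:(nc - 2)]
  g <- .gradients(m)
  grc <- .gradients(g$gr)$gc
  hrc <- grc
  tr2 <- (hrr + hcc) / 2
  disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
  pmax(abs(tr2 + disc), abs(tr2 - disc))
}

#' Global curvature context around a keypoint
#'
#' Computes a per-pixel maximum-curvature raster (largest-magnitude
#' eigenvalue of the local Hessian) and accumulates its mass into a
#' log-polar histogram centered on the keypoint, over a support region
#' covering a large portion of the image (default radius `min(dim) / 2`).
#' A constant image has zero curvature and yields a zero histogram; the
#' histogram total equals the summed curvature magnitude inside the support.
#'
#' @param image An [hu_image()], patch or matrix (at least 3x3).
#' @param keypoint Numeric `(row, col)` position inside the image.
#' @param radial_bins,angular_bins Log-polar resolution.
#' @param support Support radius in pixels; `NULL` for `min(dim) / 2`.
#' @return Numeric histogram of length `radial_bins * angular_bins`.
#' @export
global_context <- function(image, keypoint, radial_bins = 5, angular_bins = 12,
                           support = NULL) {
  m <- .as_pixels(image)
  .assert(keypoint[1L] >= 1 && keypoint[1L] <= nrow(m) &&
            keypoint[2L] >= 1 && keypoint[2L] <= ncol(m), "keypoint outside image")
  if (is.null(support)) support <- min(dim(m)) / 2
  curv <- .max_curvature(m)
  idx <- which(curv != 0, arr.ind = TRUE)
  nb <- radial_bins * angular_bins
  if (!nrow(idx)) return(numeric(nb))
  dr <- idx[, 1L] - keypoint[1L]; dc <- idx[, 2L] - keypoint[2L]
  d <- sqrt(dr^2 + dc^2)
  sel <- d > 0 & d <= support
  if (!any(sel)) return(numeric(nb))
  bins <- .logpolar_bins(dr[sel] / support, dc[sel] / support,
                         radial_bins, angular_bins, 2^(-radial_bins), 1)
  w <- curv[idx][sel]
  as.numeric(tapply(w, factor(bins, levels = seq_len(nb)), sum, default = 0))
}

.gc_at_keypoints <- function(patch, keypoints, radial_bins = 5, angular_bins = 12) {
  m <- .as_pixels(patch)
  d <- vapply(seq_len(nrow(keypoints)), function(i) {
    h <- global_context(m, c(keypoints$row[i], keypoints$col[i]),
                        radial_bins, angular_bins)
    s <- sum(h)
    if (s > 0) h / s else h
  }, numeric(radial_bins * angular_bins))
  if (is.null(dim(d))) d <- matrix(d, radial_bins * angular_bins)
  descriptor_set(d, keypoints, "GC")
}

# --- LIOP -------------------------------------------------------------------

.liop_cache <- new.env(parent = emptyenv())

# Precompute, for a given odd patch size, the linear indices of the region
# pixels and of their rotationally aligned neighbor samples (nearest-pixel,
# so intensity comparisons are exact under monotone maps).
.liop_geometry <- function(size, neighbors, nbr_radius) {
  key <- paste(size, neighbors, nbr_radius, sep = "_")
  if (!is.null(.liop_cache[[key]])) return(.liop_cache[[key]])
  cc <- (size + 1) / 2
  g <- expand.grid(row = seq_len(size), col = seq_len(size))
  dr <- g$row - cc; dc <- g$col - cc
  dist <- sqrt(dr^2 + dc^2)
  rmax <- (size - 1) / 2 - nbr_radius - 1
  sel <- dist <= rmax & dist > 0
  rows <- g$row[sel]; cols <- g$col[sel]
  alpha <- atan2(dc[sel], dr[sel])
  nbr_idx <- matrix(0L, sum(sel), neighbors)
  for (j in seq_len(neighbors)) {
    phi <- alpha + 2 * pi * (j - 1) / neighbors
    nr <- pmin(pmax(round(rows + nbr_radius * cos(phi)), 1L), size)
    nc <- pmin(pmax(round(cols + nbr_radius * sin(phi)), 1L), size)
    nbr_idx[, j] <- (nc - 1L) * size + nr
  }
  perms <- .permutations(neighbors)
  pkey <- perms %*% (neighbors + 1)^(seq_len(neighbors) - 1)
  geom <- list(pix_idx = (cols - 1L) * size + rows, nbr_idx = nbr_idx,
               perm_keys = as.numeric(pkey))
  .liop_cache[[key]] <- geom
  geom
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

#' Local intensity order pattern (LIOP) descriptor
#'
#' The circular patch region is partitioned into `ordinal_bins` subregions
#' by the global rank of each pixel's intensity. For every pixel,
#' `neighbors` sample points on a circle of radius `nbr_radius` around it
#' (rotationally aligned with the pixel's angular position, sampled at the
#' nearest pixel so only intensity *comparisons* enter) are ranked, and the
#' resulting permutation is accumulated one-hot into the pixel's ordinal
#' bin. Concatenating the bins gives a descriptor of dimension
#' `ordinal_bins * factorial(neighbors)` (144 by default), L2-normalized.
#' Because both the partition and the patterns depend only on intensity
#' order, the descriptor is exactly invariant to strictly monotone
#' intensity transformations and approximately invariant to rotation.
#'
#' @param patch A patch object or numeric matrix with odd side length
#'   (31 in the detection pipeline).
#' @param neighbors Number of circular sample points per pixel.
#' @param ordinal_bins Number of intensity-rank subregions.
#' @param nbr_radius Sampling circle radius in pixels.
#' @return Numeric descriptor of length `ordinal_bins * factorial(neighbors)`.
#' @export
liop <- function(patch, neighbors = 4, ordinal_bins = 6, nbr_radius = 3) {
  m <- .as_pixels(patch)
  .assert(nrow(m) == ncol(m) && nrow(m) %% 2 == 1,
          "LIOP requires a square patch with odd side length")
  geom <- .liop_geometry(nrow(m), neighbors, nbr_radius)
  npix <- length(geom$pix_idx)
  center_vals <- m[geom$pix_idx]
  rk <- rank(center_vals, ties.method = "first")
  bin <- ceiling(rk * ordinal_bins / npix)
  v <- matrix(m[geom$nbr_idx], npix, neighbors)
  nrk <- matrix(1L, npix, neighbors)
  for (j in seq_len(neighbors)) for (l in seq_len(neighbors)) {
    if (l == j) next
    nrk[, j] <- nrk[, j] + ((v[, l] < v[, j]) | (v[, l] == v[, j] & l < j))
  }
  keys <- as.numeric(nrk %*% (neighbors + 1)^(seq_len(neighbors) - 1))
  pattern <- match(keys, geom$perm_keys)
  nf <- factorial(neighbors)
  h <- tabulate((bin - 1L) * nf + pattern, nbins = ordinal_bins * nf)
  .l2_normalize(h)
}

# --- LBP --------------------------------------------------------------------

.lbp_uniform_map <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    m <- integer(256)
    nxt <- 1L
    for (code in 0:255) {
      bits <- as.integer(intToBits(code)[1:8])
      trans <- sum(bits != c(bits[-1], bits[1]))
      if (trans <= 2) { m[code + 1] <- nxt; nxt <- nxt + 1L } else m[code + 1] <- 59L
    }
    map <<- m
    map
  }
})

#' Local binary pattern (LBP) histogram
#'
#' Classic 8-neighbor LBP at radius 1 with the uniform-pattern mapping:
#' the 58 uniform codes get individual bins and all non-uniform codes share
#' one bin (59 bins). The histogram counts interior pixels, so it sums to
#' the number of interior pixels. A constant patch maps every pixel to the
#' all-ones (all neighbors >= center) uniform code.
#'
#' @param patch A patch object or numeric matrix.
#' @param points Number of neighbors (only 8 supported).
#' @param radius Neighborhood radius (only 1 supported).
#' @return Numeric histogram of length 59 (raw counts).
#' @export
lbp <- function(patch, points = 8, radius = 1) {
  .assert(points == 8 && radius == 1, "only the 8-point, radius-1 LBP is implemented")
  m <- .as_pixels(patch)
  .assert(min(dim(m)) > 2 * radius + 1, "patch too small for LBP radius")
  nr <- nrow(m); nc <- ncol(m)
  ir <- 2:(nr - 1); ic <- 2:(nc - 1)
  ctr <- m[ir, ic]
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  code <- matrix(0L, length(ir), length(ic))
  for (j in seq_along(offs)) {
    o <- offs[[j]]
    code <- code + as.integer(m[ir + o[1L], ic + o[2L]] >= ctr) * 2L^(j - 1L)
  }
  umap <- .lbp_uniform_map()
  tabulate(umap[code + 1L], nbins = 59L)
}

#' Fuse two descriptor sets by column-wise concatenation
#'
#' Both sets must describe the same keypoints (or both be whole-patch
#' histograms). The first argument's rows come first; an empty second set
#' returns the first unchanged.
#'
#' @param a,b [descriptor_set()] objects.
#' @return A [descriptor_set()] with `dim = dim_a + dim_b`.
#' @export
fuse <- function(a, b) {
  .assert(inherits(a, "descriptor_set") && inherits(b, "descriptor_set"),
          "fuse expects descriptor_set objects")
  if (nrow(b$vectors) == 0L) return(a)
  if (nrow(a$vectors) == 0L) return(b)
  .assert(ncol(a$vectors) == ncol(b$vectors), "descriptor counts differ")
  if (!is.null(a$keypoints) && !is.null(b$keypoints))
    .assert(all(a$keypoints$row == b$keypoints$row) &&
              all(a$keypoints$col == b$keypoints$col), "keypoint mismatch")
  descriptor_set(rbind(a$vectors, b$vectors), a$keypoints,
                 paste(a$kind, b$kind, sep = "_"))
}

#' Default descriptor parameters
#'
#' @return Named list of the tunable descriptor settings.
#' @export
descriptor_defaults <- function() {
  list(sift_scales = c(4, 6, 8, 10), sift_step = 3, hog_cell_px = 4,
       sc_radial_bins = 5, sc_angular_bins = 12,
       gc_radial_bins = 5, gc_angular_bins = 12,
       canny_low = 0.1, canny_high = 0.2,
       liop_neighbors = 4, liop_bins = 6, liop_radius = 3,
       lbp_points = 8, lbp_radius = 1)
}

#' Extract descriptors of a given kind from a patch
#'
#' Dispatches to the descriptor implementations; the fused kinds use the
#' dense-SIFT keypoints for their second component, as in the detection
#' pipeline. `LIOP` and `LIOP_LBP` yield a single whole-patch column and
#' require an odd patch size.
#'
#' @param patch A patch object or numeric matrix.
#' @param kind One of `"PHOW"`, `"PHOW_HOG"`, `"PHOW_SC"`, `"PHOW_GC"`,
#'   `"LIOP"`, `"LIOP_LBP"`.
#' @param params Parameter list; see [descriptor_defaults()].
#' @return A [descriptor_set()].
#' @export
extract_descriptors <- function(patch, kind, params = descriptor_defaults()) {
  p <- utils::modifyList(descriptor_defaults(), params)
  m <- .as_pixels(patch)
  kind <- match.arg(kind, c("PHOW", "PHOW_HOG", "PHOW_SC", "PHOW_GC", "LIOP", "LIOP_LBP"))
  if (kind %in% c("LIOP", "LIOP_LBP")) {
    lv <- liop(m, p$liop_neighbors, p$liop_bins, p$liop_radius)
    if (kind == "LIOP") return(descriptor_set(matrix(lv), NULL, "LIOP"))
    hb <- lbp(m, p$lbp_points, p$lbp_radius)
    s <- sum(hb)
    if (s > 0) hb <- hb / s
    return(descriptor_set(matrix(c(lv, hb)), NULL, "LIOP_LBP"))
  }
  ds <- dense_sift(m, p$sift_scales, p$sift_step)
  if (kind == "PHOW" || ncol(ds$vectors) == 0L) {
    if (kind != "PHOW") return(descriptor_set(matrix(0, 0, 0), NULL, kind))
    return(ds)
  }
  other <- switch(kind,
    PHOW_HOG = hog_at_keypoints(m, ds$keypoints, p$hog_cell_px),
    PHOW_SC = .sc_at_keypoints(m, ds$keypoints, p$sc_radial_bins, p$sc_angular_bins,
                               p$canny_low, p$canny_high),
    PHOW_GC = .gc_at_keypoints(m, ds$keypoints, p$gc_radial_bins, p$gc_angular_bins))
  if (kind == "PHOW_HOG" && !is.null(attr(other, "kept")) &&
      !all(attr(other, "kept"))) {
    keep <- attr(other, "kept")
    ds <- descriptor_set(ds$vectors[, keep, drop = FALSE],
                         ds$keypoints[keep, , drop = FALSE], ds$kind)
  }
  out <- fuse(ds, other)
  out$kind <- kind
  out
}
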