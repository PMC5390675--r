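# Internal numerical helpers shared across modules.

# Separable Gaussian smoothing with replicate padding. sigma = 0 is a no-op.
.gauss_smooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  nr <- nrow(z); nc <- ncol(z)
  zp <- z[c(rep(1L, r), seq_len(nr), rep(nr, r)), c(rep(1L, r), seq_len(nc), rep(nc, r))]
  # stats::filter leaves NA at the ends of the padded signal; the interior is exact
  zc <- apply(zp, 2L, function(v) stats::filter(v, k)[(r + 1L):(r + nr)])
  zc <- t(apply(zc, 1L, function(v) stats::filter(v, k)[(r + 1L):(r + nc)]))
  zc
}

# Summed-area table padded with a leading zero row/column, so that
# .block_sum(ii, r, c, h, w) is O(1) for any block.
.integral_image <- function(m) {
  cs <- apply(m, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  cs <- t(apply(cs, 1L, cumsum))
  if (is.null(dim(cs)) || nrow(cs) != nrow(m)) cs <- matrix(cs, nrow = nrow(m))
  ii <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  ii[-1L, -1L] <- cs
  ii
}

# Sum of m[r..r+h-1, c..c+w-1] for vectors of top-left corners r, c.
.block_sum <- function(ii, r, c, h, w) {
  ii[cbind(r + h, c + w)] - ii[cbind(r, c + w)] - ii[cbind(r + h, c)] + ii[cbind(r, c)]
}

# L2 normalization that maps an (almost) zero vector to exact zeros.
.l2_normalize <- function(v, eps = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < eps) return(v * 0)
  v / n
}

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Pixel raster of a 2D object or plain matrix.
.as_pixels <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "lob_patch")) return(x$pixels)
  if (inherits(x, "hu_image")) return(x$values)
  if (inherits(x, "lob_template")) return(x$pixels)
  stop("cannot interpret input as a pixel raster", call. = FALSE)
}
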