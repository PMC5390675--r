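# Template bank construction and NCC-based matching.
#
# Eight base regions of interest, one per ~45-degree lobulation orientation,
# are each expanded into 9 variants: 6 length-width ratios (1:0.8 ... 1:1.3,
# the 1:1 identity counted once) plus 3 isotropic scalings (1.1, 1.2, 1.3),
# giving the 72-template bank. Matching uses zero-mean, unit-variance
# normalized cross-correlation computed in the frequency domain.

.TEMPLATE_RATIOS <- c(0.8, 0.9, 1.0, 1.1, 1.2, 1.3)
.TEMPLATE_SCALES <- c(1.1, 1.2, 1.3)

#' Build the 72-template bank from 8 base ROIs
#'
#' @param base_rois List of exactly 8 numeric matrices (at least 8x8 each,
#'   non-constant), one per orientation.
#' @return An object of class `template_bank`: a list with `templates`
#'   (list of `lob_template`, each carrying `pixels`, `orientation_idx`,
#'   `ratio`, `scale`, `label`) and `base_count`.
#' @export
build_template_bank <- function(base_rois) {
  .assert(is.list(base_rois) && length(base_rois) == 8L,
          "exactly 8 base ROIs are required (one per orientation)")
  templates <- list()
  for (i in seq_along(base_rois)) {
    b <- .as_pixels(base_rois[[i]])
    .assert(min(dim(b)) >= 8L, sprintf("base ROI %d smaller than 8x8", i))
    .assert(stats::sd(b) > 0, sprintf("base ROI %d is constant", i))
    j <- 0L
    for (ratio in .TEMPLATE_RATIOS) {
      j <- j + 1L
      px <- if (ratio == 1) b else .resize_bilinear(b, nrow(b), round(ncol(b) * ratio))
      templates[[length(templates) + 1L]] <- structure(
        list(pixels = px, orientation_idx = i, ratio = ratio, scale = 1.0,
             label = sprintf("T%d-%d", i, j)), class = "lob_template")
    }
    for (scale in .TEMPLATE_SCALES) {
      j <- j + 1L
      px <- .resize_bilinear(b, round(nrow(b) * scale), round(ncol(b) * scale))
      templates[[length(templates) + 1L]] <- structure(
        list(pixels = px, orientation_idx = i, ratio = 1.0, scale = scale,
             label = sprintf("T%d-%d", i, j)), class = "lob_template")
    }
  }
  structure(list(templates = templates, base_count = 8L), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank: %d templates from %d bases>\n",
              length(x$templates), x$base_count))
  invisible(x)
}

.resize_bilinear <- function(m, nr, nc) {
  out <- EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
  matrix(out, nrow = nr, ncol = nc)
}

#' Normalized cross-correlation of two equally sized rasters
#'
#' Zero-mean, unit-variance ("standard") NCC: the score is the cosine of
#' the angle between the mean-subtracted rasters, in `[-1, 1]`, invariant
#' to positive-gain affine intensity changes of either argument. A constant
#' (zero-variance) raster carries no texture evidence and scores 0.
#'
#' @param f,g Numeric matrices of identical shape.
#' @return A scalar in `[-1, 1]`.
#' @export
ncc <- function(f, g) {
  f <- .as_pixels(f); g <- .as_pixels(g)
  .assert(all(dim(f) == dim(g)), "ncc: shape mismatch")
  f0 <- f - mean(f); g0 <- g - mean(g)
  den <- sqrt(sum(f0^2) * sum(g0^2))
  if (den < 1e-12) return(0)
  max(-1, min(1, sum(f0 * g0) / den))
}

# Full cross-correlation of image with kernel via FFT; returns the "valid"
# part: out[r, c] = sum(img[r..r+kh-1, c..c+kw-1] * kern).
.xcorr_fft_valid <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img); kh <- nrow(kern); kw <- ncol(kern)
  pr <- nr + kh - 1L; pc <- nc + kw - 1L
  ip <- matrix(0, pr, pc); ip[1:nr, 1:nc] <- img
  kp <- matrix(0, pr, pc); kp[1:kh, 1:kw] <- kern
  out <- Re(stats::fft(stats::fft(ip) * Conj(stats::fft(kp)), inverse = TRUE)) / (pr * pc)
  out[1:(nr - kh + 1L), 1:(nc - kw + 1L), drop = FALSE]
}

#' Step-dependent NCC matrix of a template over an image
#'
#' The dense per-position NCC map is computed in the frequency domain (the
#' numerator by FFT cross-correlation with the mean-subtracted template, the
#' local image variance by summed-area tables), then subsampled on the
#' stride grid anchored at the image origin. Window centers outside the
#' parenchyma mask are flagged invalid.
#'
#' @param hu An [hu_image()] or matrix.
#' @param template A template (or plain matrix) that fits inside the image.
#' @param step_px Stride of the subsampling grid (1 = dense).
#' @param mask Optional [parenchyma_mask()].
#' @return An object of class `ncc_matrix`: `values` (score matrix over the
#'   step grid), `rows`/`cols` (top-left coordinates of each grid entry),
#'   `valid` (logical matrix), `step_px`, `template_dim`.
#' @export
ncc_matrix <- function(hu, template, step_px = 1, mask = NULL) {
  img <- .as_pixels(hu)
  tpl <- .as_pixels(template)
  kh <- nrow(tpl); kw <- ncol(tpl)
  .assert(kh <= nrow(img) && kw <= ncol(img), "template larger than image")
  t0 <- tpl - mean(tpl)
  t_ss <- sum(t0^2)
  num <- .xcorr_fft_valid(img, t0)
  ii1 <- .integral_image(img)
  ii2 <- .integral_image(img^2)
  nrv <- nrow(img) - kh + 1L; ncv <- ncol(img) - kw + 1L
  rr <- rep(seq_len(nrv), times = ncv); cc <- rep(seq_len(ncv), each = nrv)
  s1 <- matrix(.block_sum(ii1, rr, cc, kh, kw), nrv, ncv)
  s2 <- matrix(.block_sum(ii2, rr, cc, kh, kw), nrv, ncv)
  varp <- pmax(s2 - s1^2 / (kh * kw), 0)
  den <- sqrt(varp * t_ss)
  dense <- ifelse(den < 1e-8, 0, num / den)
  dense <- pmin(pmax(dense, -1), 1)
  ri <- seq.int(1L, nrv, by = step_px)
  ci <- seq.int(1L, ncv, by = step_px)
  vals <- dense[ri, ci, drop = FALSE]
  valid <- matrix(TRUE, length(ri), length(ci))
  if (!is.null(mask)) {
    offr <- floor(kh / 2); offc <- floor(kw / 2)
    valid <- matrix(mask$mask[cbind(rep(ri + offr, times = length(ci)),
                                    rep(ci + offc, each = length(ri)))],
                    length(ri), length(ci))
  }
  structure(list(values = vals, rows = ri, cols = ci, valid = valid,
                 step_px = as.integer(step_px), template_dim = c(kh, kw)),
            class = "ncc_matrix")
}

#' Template-matching detection: pooled top-N over the bank
#'
#' For each template the single best-scoring valid position is recorded;
#' the 72 per-template candidates are pooled, sorted by score (ties broken
#' by row-major position, then template label) and the top `n` returned.
#'
#' @param hu An [hu_image()].
#' @param mask A [parenchyma_mask()] or `NULL`.
#' @param bank A [build_template_bank()] result.
#' @param step_px Sliding step for the correlation grid.
#' @param n Number of detections to return.
#' @return Detection data frame with columns `source_id`, `row`, `col`,
#'   `height`, `width`, `score`, `algorithm`, `template_label`.
#' @export
match_top_n <- function(hu, mask, bank, step_px = 4, n = 10) {
  .assert(inherits(bank, "template_bank") && length(bank$templates) > 0, "empty bank")
  .assert(n >= 1, "n must be >= 1")
  sid <- if (inherits(hu, "hu_image")) hu$source_id else "image"
  cand <- lapply(bank$templates, function(tpl) {
    nm <- ncc_matrix(hu, tpl, step_px = step_px, mask = mask)
    v <- nm$values
    v[!nm$valid] <- -Inf
    if (!any(is.finite(v))) return(NULL)
    mx <- max(v)  # row-major tie-break below (which.max alone is column-major)
    hits <- which(v == mx, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    r <- nm$rows[hits[1L, 1L]]; c <- nm$cols[hits[1L, 2L]]
    data.frame(source_id = sid, row = as.integer(r), col = as.integer(c),
               height = as.integer(nm$template_dim[1L]),
               width = as.integer(nm$template_dim[2L]),
               score = mx, algorithm = "A1", template_label = tpl$label,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L)
    return(empty_detections(template_label = TRUE))
  ord <- order(-cand$score, cand$row, cand$col, cand$template_label)
  out <- cand[ord, , drop = FALSE][seq_len(min(n, nrow(cand))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared empty-detection schema.
empty_detections <- function(template_label = FALSE) {
  d <- data.frame(source_id = character(), row = integer(), col = integer(),
                  height = integer(), width = integer(), score = numeric(),
                  algorithm = character(), stringsAsFactors = FALSE)
  if (template_label) d$template_label <- character()
  d
}
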