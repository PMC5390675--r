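# Sliding-window enumeration over the masked parenchyma.

#' Sliding-window specification
#'
#' The window size is the mean radiologist bounding-box size, 30 px; the
#' LIOP-based detectors need an odd size and use 31 px. The step is swept
#' over 4, 6, ..., 20 in the step-size experiments.
#'
#' @param size_px Window side length in pixels (>= 3).
#' @param step_px Stride between adjacent window top-left corners (>= 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size_px = 30, step_px = 4) {
  .assert(.is_scalar_number(size_px) && size_px >= 3, "size_px must be >= 3")
  .assert(.is_scalar_number(step_px) && step_px >= 1, "step_px must be >= 1")
  structure(list(size_px = as.integer(size_px), step_px = as.integer(step_px)),
            class = "window_spec")
}

#' Enumerate valid window positions
#'
#' Positions lie on the stride grid anchored at the image origin (so they
#' are reproducible across masks and match the step-dependent template
#' correlation grid). Only fully in-bounds windows are emitted, in row-major
#' order, and only those whose center pixel lies inside the parenchyma mask.
#'
#' @param hu An [hu_image()] or matrix.
#' @param mask A [parenchyma_mask()], or `NULL` to keep every window.
#' @param spec A [window_spec()].
#' @return Integer matrix with columns `row`, `col` (top-left, 1-based) and
#'   attribute `size_px`.
#' @export
window_positions <- function(hu, mask, spec) {
  v <- .as_pixels(hu)
  s <- spec$size_px
  .assert(s <= min(dim(v)), "window larger than image")
  rs <- seq.int(1L, nrow(v) - s + 1L, by = spec$step_px)
  cs <- seq.int(1L, ncol(v) - s + 1L, by = spec$step_px)
  pos <- cbind(row = rep(rs, each = length(cs)), col = rep(cs, times = length(rs)))
  off <- floor(s / 2)
  if (!is.null(mask)) {
    keep <- mask$mask[cbind(pos[, 1L] + off, pos[, 2L] + off)]
    pos <- pos[keep, , drop = FALSE]
  }
  attr(pos, "size_px") <- s
  pos
}

#' Extract the patch at one window position
#'
#' @param hu An [hu_image()] or matrix.
#' @param row,col Top-left corner (1-based).
#' @param size_px Window side length.
#' @return An object of class `lob_patch` with fields `pixels`, `top_left`
#'   and `center`.
#' @export
patch_at <- function(hu, row, col, size_px) {
  v <- .as_pixels(hu)
  .assert(row >= 1 && col >= 1 && row + size_px - 1 <= nrow(v) &&
            col + size_px - 1 <= ncol(v), "window out of image bounds")
  off <- floor(size_px / 2)
  structure(list(pixels = v[row:(row + size_px - 1L), col:(col + size_px - 1L)],
                 top_left = c(row, col), center = c(row + off, col + off)),
            class = "lob_patch")
}

#' Generate the ordered sliding-window patch stream
#'
#' Deterministic: re-running on identical inputs yields the identical
#' sequence. Windows overlapping the mask boundary are kept as long as their
#' center is inside; partial windows at the right/bottom edge are dropped.
#'
#' @inheritParams window_positions
#' @return List of [patch_at()] objects in row-major order.
#' @export
generate_patches <- function(hu, mask, spec) {
  pos <- window_positions(hu, mask, spec)
  lapply(seq_len(nrow(pos)), function(i)
    patch_at(hu, pos[i, 1L], pos[i, 2L], spec$size_px))
}
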