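# Shared fixtures, all generated in code at test time.

# Partial-volume rendering of a (possibly lobulated) disc on a quiet
# background; mirrors how CT digitizes a sharp margin.
render_disc <- function(r0, a = 0, m = 0, phase = 0, pad = 8,
                        bg = -800, fg = 30) {
  n <- 2L * ceiling(r0 * (1 + a)) + 2L * pad + 1L
  cc <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  th <- atan2(g$col - cc, g$row - cc)
  d <- sqrt((g$row - cc)^2 + (g$col - cc)^2)
  cov <- pmin(pmax(0.5 + r0 * (1 + a * sin(m * th + phase)) - d, 0), 1)
  matrix(cov * fg + (1 - cov) * bg, n, n)
}

# Rotate a matrix by 90 degrees (counter-clockwise in (row, col) terms).
rot90 <- function(m) t(m)[, nrow(m):1]

# Minimal single-frame explicit-VR little-endian DICOM writer, used only to
# exercise the reader; supports unsigned 16-bit pixels.
write_test_dicom <- function(path, pixels, slope = 1, intercept = -1024,
                             spacing = c(0.7, 0.7)) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_str <- function(group, elem, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(group); u16(elem); writeChar(vr, con, eos = NULL); u16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  elem_us <- function(group, elem, val) {
    u16(group); u16(elem); writeChar("US", con, eos = NULL); u16(2); u16(val)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group (always explicit VR)
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  # image module
  elem_us(0x0028, 0x0002, 1)
  elem_str(0x0028, 0x0004, "CS", "MONOCHROME2")
  elem_us(0x0028, 0x0010, nrow(pixels))
  elem_us(0x0028, 0x0011, ncol(pixels))
  elem_str(0x0028, 0x0030, "DS", paste(spacing, collapse = "\\"))
  elem_us(0x0028, 0x0100, 16)
  elem_us(0x0028, 0x0101, 16)
  elem_us(0x0028, 0x0102, 15)
  elem_us(0x0028, 0x0103, 0)
  elem_str(0x0028, 0x1052, "DS", format(intercept))
  elem_str(0x0028, 0x1053, "DS", format(slope))
  npx <- length(pixels)
  u16(0x7fe0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  u32(npx * 2)
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

# One small seeded benchmark shared by the pipeline and acceptance tests;
# built once per test session.
shared_benchmark_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.json"))) {
      dir <<- file.path(tempdir(), "lobdetect_bench")
      phantom_benchmark(dir, n_images = 20, mix = 0.5, seed = 42)
    }
    dir
  }
})
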