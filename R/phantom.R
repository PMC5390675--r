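# Synthetic lung-CT phantom generator.
#
# A phantom slice is a body-tissue background with a low-HU lung disc
# (radius 180 px, matching the circular parenchyma model), vessel-like
# bright chords, and nodules whose margin follows the radial model
# r(phi) = r0 * (1 + a * sin(m * phi)): a = 0 gives a smooth (circular)
# margin, a > 0 an undulating, lobulated one. The margin has a closed-form
# curvature, so every nodule carries an analytic reference contour and a
# dense-quadrature reference bending energy -- the oracle for the bending
# filter. Margins are rendered with linear partial-volume antialiasing
# (one-pixel transition), emulating the partial-volume effect of CT.

#' Nodule specification
#'
#' @param center `(row, col)` center in pixels.
#' @param r0 Base radius in pixels (> 0).
#' @param a Lobulation amplitude in `[0, 0.5]`; 0 = smooth.
#' @param m Number of lobes (>= 2 when `a > 0`).
#' @param hu Nodule attenuation in HU.
#' @param phase Angular phase of the lobulation pattern.
#' @return An object of class `nodule_spec` with a `label` of `"smooth"`
#'   or `"lobulated"`.
#' @export
nodule_spec <- function(center, r0, a = 0, m = 0, hu = 30, phase = 0) {
  .assert(r0 > 0, "r0 must be > 0")
  .assert(a >= 0 && a <= 0.5, "a must be in [0, 0.5]")
  if (a > 0) .assert(m >= 2, "lobulated nodules need m >= 2")
  structure(list(center = center, r0 = r0, a = a, m = m, hu = hu, phase = phase,
                 label = if (a > 0) "lobulated" else "smooth"),
            class = "nodule_spec")
}

#' Phantom configuration
#'
#' Defaults emulate a thorax CT slice: lung parenchyma at -800 HU, body
#' tissue at +40 HU, vessels at -100 HU, additive Gaussian noise of 10 HU.
#'
#' @param image_size `(rows, cols)`; must contain the 180 px lung disc.
#' @param lung_hu,tissue_hu,vessel_hu Attenuation levels in HU.
#' @param noise_sigma Gaussian noise standard deviation in HU (>= 0).
#' @param nodules List of [nodule_spec()] objects.
#' @param vessels Number of vessel-like chords.
#' @param lung_radius Lung disc radius in px.
#' @param seed Integer seed controlling noise and vessel placement.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(448, 448), lung_hu = -800, tissue_hu = 40,
                           vessel_hu = -100, noise_sigma = 10, nodules = list(),
                           vessels = 4, lung_radius = 180, seed = 1) {
  .assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  .assert(min(image_size) >= 2 * lung_radius, "image must contain the lung disc")
  ctr <- floor(image_size / 2) + 1
  for (nd in nodules) {
    .assert(inherits(nd, "nodule_spec"), "nodules must be nodule_spec objects")
    .assert(sqrt(sum((nd$center - ctr)^2)) + nd$r0 * (1 + nd$a) <= lung_radius,
            "nodule extends outside the lung disc")
  }
  structure(list(image_size = as.integer(image_size), lung_hu = lung_hu,
                 tissue_hu = tissue_hu, vessel_hu = vessel_hu,
                 noise_sigma = noise_sigma, nodules = nodules,
                 vessels = vessels, lung_radius = lung_radius, seed = seed),
            class = "phantom_config")
}

# Analytic margin, its dense contour in image coordinates, and the
# quadrature reference bending energy.
.nodule_reference <- function(nd, n = 4096) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  r <- nd$r0 * (1 + nd$a * sin(nd$m * t + nd$phase))
  r1 <- nd$r0 * nd$a * nd$m * cos(nd$m * t + nd$phase)
  r2 <- -nd$r0 * nd$a * nd$m^2 * sin(nd$m * t + nd$phase)
  sp <- sqrt(r^2 + r1^2)
  kap <- (r^2 + 2 * r1^2 - r * r2) / sp^3
  list(x = nd$center[1L] + r * cos(t), y = nd$center[2L] + r * sin(t),
       E_ref = sum(kap^2 * sp) / sum(sp), P_ref = sum(sp) * 2 * pi / n)
}

#' Reference bending energy of a nodule margin
#'
#' Dense quadrature of the analytic curvature of
#' `r(phi) = r0 (1 + a sin(m phi))`; for `a = 0` this is exactly `1/r0^2`.
#'
#' @param nd A [nodule_spec()].
#' @return Scalar energy in 1/px^2.
#' @export
nodule_reference_energy <- function(nd) .nodule_reference(nd)$E_ref

#' Generate a phantom slice
#'
#' Fully deterministic given `config$seed`. Ground-truth boxes are the
#' tight bounding boxes of the *lobulated* nodules (the detection target);
#' smooth nodules, vessels and noise act as distractors. Reference
#' (analytic) contours are returned for every nodule for oracle use.
#'
#' @param config A [phantom_config()].
#' @param source_id Identifier for the slice.
#' @return List with elements `slice` (a [ct_slice()], slope 1 / intercept
#'   -1024), `hu` (the clean + noisy [hu_image()]), `gt` (ground-truth box
#'   data frame), `contours` (list of per-nodule references with `E_ref`),
#'   `vessels` (segment endpoints of the rendered vessels).
#' @export
generate_phantom <- function(config, source_id = "phantom") {
  nr <- config$image_size[1L]; nc <- config$image_size[2L]
  ctr <- floor(config$image_size / 2) + 1
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dlung <- sqrt((rowg - ctr[1L])^2 + (colg - ctr[2L])^2)
  img <- matrix(config$tissue_hu, nr, nc)
  cov_lung <- pmin(pmax(0.5 + config$lung_radius - dlung, 0), 1)
  img <- cov_lung * config$lung_hu + (1 - cov_lung) * img
  vessel_log <- NULL
  img <- withr::with_seed(config$seed, {
    if (config$vessels > 0) {
      # keep vessels clear of nodule margins: a vessel crossing a margin
      # would invalidate the nodule's analytic reference contour
      clear <- matrix(1, nr, nc)
      for (nd in config$nodules) {
        dnod <- sqrt((rowg - nd$center[1L])^2 + (colg - nd$center[2L])^2)
        clear <- clear * pmin(pmax(dnod - (nd$r0 * (1 + nd$a) + 3), 0), 1)
      }
      for (v in seq_len(config$vessels)) {
        ang0 <- stats::runif(1, 0, 2 * pi)
        rad0 <- stats::runif(1, 0, config$lung_radius * 0.7)
        p0 <- ctr + rad0 * c(cos(ang0), sin(ang0))
        dirang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 50, 140)
        p1 <- p0 + len * c(cos(dirang), sin(dirang))
        w <- stats::runif(1, 1, 2)
        vessel_log <- rbind(vessel_log,
                             data.frame(p0_row = p0[1L], p0_col = p0[2L],
                                        p1_row = p1[1L], p1_col = p1[2L], width = w))
        dseg <- .dist_to_segment(rowg, colg, p0, p1)
        cov <- pmin(pmax(0.5 + w / 2 - dseg, 0), 1) *
          (dlung <= config$lung_radius - 1) * clear
        img <- cov * config$vessel_hu + (1 - cov) * img
      }
    }
    for (nd in config$nodules) {
      dr <- rowg - nd$center[1L]; dc <- colg - nd$center[2L]
      phi <- atan2(dc, dr)
      rphi <- nd$r0 * (1 + nd$a * sin(nd$m * phi + nd$phase))
      cov <- pmin(pmax(0.5 + rphi - sqrt(dr^2 + dc^2), 0), 1)
      img <- cov * nd$hu + (1 - cov) * img
    }
    if (config$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sigma), nr, nc)
    img
  })
  raw <- pmin(pmax(round(img) + 1024, 0), 65535)
  slice <- ct_slice(raw, slope = 1, intercept = -1024, source_id = source_id)
  contours <- lapply(config$nodules, function(nd) {
    ref <- .nodule_reference(nd)
    c(ref, list(label = nd$label, center = nd$center, r0 = nd$r0, a = nd$a, m = nd$m))
  })
  gt <- do.call(rbind, lapply(contours, function(cf) {
    if (cf$label != "lobulated") return(NULL)
    data.frame(source_id = source_id,
               row = floor(min(cf$x)), col = floor(min(cf$y)),
               height = ceiling(max(cf$x)) - floor(min(cf$x)) + 1L,
               width = ceiling(max(cf$y)) - floor(min(cf$y)) + 1L,
               label = "lobulation", stringsAsFactors = FALSE)
  }))
  if (is.null(gt))
    gt <- data.frame(source_id = character(), row = integer(), col = integer(),
                     height = integer(), width = integer(), label = character(),
                     stringsAsFactors = FALSE)
  if (is.null(vessel_log))
    vessel_log <- data.frame(p0_row = numeric(), p0_col = numeric(),
                             p1_row = numeric(), p1_col = numeric(),
                             width = numeric())
  list(slice = slice, hu = to_hounsfield(slice), gt = gt, contours = contours,
       vessels = vessel_log)
}

.dist_to_segment <- function(rowg, colg, p0, p1) {
  vr <- p1[1L] - p0[1L]; vc <- p1[2L] - p0[2L]
  L2 <- vr^2 + vc^2
  t <- ((rowg - p0[1L]) * vr + (colg - p0[2L]) * vc) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((rowg - (p0[1L] + t * vr))^2 + (colg - (p0[2L] + t * vc))^2)
}

#' Randomly place nodules inside the lung disc
#'
#' Rejection-samples non-overlapping nodule centers with the whole margin
#' inside the parenchyma circle. Lobulated nodules draw
#' `a ~ U(0.15, 0.22)`, `m in {4, 5, 6}`; radii are `U(10, 14)` px.
#'
#' @param n_lobulated,n_smooth Nodule counts.
#' @param image_size,lung_radius Geometry (see [phantom_config()]).
#' @param seed Integer seed.
#' @return List of [nodule_spec()].
#' @export
sample_nodules <- function(n_lobulated, n_smooth, image_size = c(448, 448),
                           lung_radius = 180, seed = 1) {
  ctr <- floor(image_size / 2) + 1
  withr::with_seed(seed, {
    specs <- list()
    placed <- NULL
    total <- n_lobulated + n_smooth
    for (i in seq_len(total)) {
      lob <- i <= n_lobulated
      for (try in 1:200) {
        r0 <- stats::runif(1, 10, 14)
        a <- if (lob) stats::runif(1, 0.15, 0.22) else 0
        m <- if (lob) sample(4:6, 1) else 0
        rmax <- r0 * (1 + a)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * (lung_radius - rmax - 6)
        cen <- round(ctr + rad * c(cos(ang), sin(ang)))
        ok <- TRUE
        if (!is.null(placed))
          ok <- all(sqrt((placed[, 1L] - cen[1L])^2 + (placed[, 2L] - cen[2L])^2) >
                      placed[, 3L] + rmax + 8)
        if (ok) {
          placed <- rbind(placed, c(cen, rmax))
          specs[[length(specs) + 1L]] <-
            nodule_spec(cen, r0, a, m, hu = 30,
                        phase = stats::runif(1, 0, 2 * pi))
          break
        }
      }
    }
    specs
  })
}

#' Write a seeded multi-image phantom benchmark to disk
#'
#' Produces `n_images` phantom slices as 16-bit TIFFs with HU sidecars,
#' a pooled ground-truth CSV, a per-nodule reference-contour CSV (analytic
#' bending energies), and a JSON manifest with a train/test split.
#' Regenerating with the same seed reproduces identical files.
#'
#' @param dir Output directory (created if needed).
#' @param n_images Number of slices (>= 1).
#' @param mix Fraction of nodules that are lobulated, in `[0, 1]`.
#' @param nodules_per_image Nodules per slice.
#' @param train_frac Fraction of images assigned to the training split.
#' @param seed Integer seed.
#' @param image_size Slice dimensions.
#' @return The manifest, invisibly (list with `images`, `train`, `test`).
#' @export
phantom_benchmark <- function(dir, n_images = 20, mix = 0.5, nodules_per_image = 3,
                              train_frac = 0.5, seed = 1, image_size = c(448, 448)) {
  .assert(n_images >= 1, "n_images must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_all <- list(); ref_all <- list(); ves_all <- list(); images <- list()
  counts <- withr::with_seed(seed, stats::rbinom(n_images, nodules_per_image, mix))
  for (i in seq_len(n_images)) {
    sid <- sprintf("phantom_%03d", i)
    n_lob <- counts[i]
    nd <- sample_nodules(n_lob, nodules_per_image - n_lob,
                         image_size = image_size, seed = seed + 1000L + i)
    cfg <- phantom_config(image_size = image_size, nodules = nd, seed = seed + i)
    ph <- generate_phantom(cfg, source_id = sid)
    f <- file.path(dir, paste0(sid, ".tif"))
    tiff::writeTIFF(ph$slice$pixels / 65535, f, bits.per.sample = 16,
                    compression = "none")
    write_sidecar(f, slope = 1, intercept = -1024)
    gt_all[[i]] <- ph$gt
    ref_all[[i]] <- do.call(rbind, lapply(seq_along(ph$contours), function(j) {
      cf <- ph$contours[[j]]
      data.frame(source_id = sid, nodule = j, label = cf$label,
                 center_row = cf$center[1L], center_col = cf$center[2L],
                 r0 = cf$r0, a = cf$a, m = cf$m, E_ref = cf$E_ref,
                 stringsAsFactors = FALSE)
    }))
    ves_all[[i]] <- if (nrow(ph$vessels)) cbind(source_id = sid, ph$vessels) else NULL
    images[[i]] <- list(source_id = sid, file = basename(f),
                        meta = paste0(basename(f), ".meta"),
                        n_lobulated = n_lob,
                        n_smooth = nodules_per_image - n_lob)
  }
  gt <- do.call(rbind, gt_all)
  if (is.null(gt)) gt <- data.frame()
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, ref_all), file.path(dir, "reference_contours.csv"),
                   row.names = FALSE)
  ves <- do.call(rbind, ves_all)
  if (is.null(ves))
    ves <- data.frame(source_id = character(), p0_row = numeric(), p0_col = numeric(),
                      p1_row = numeric(), p1_col = numeric(), width = numeric())
  utils::write.csv(ves, file.path(dir, "vessels.csv"), row.names = FALSE)
  ntrain <- ceiling(train_frac * n_images)
  manifest <- list(seed = seed, n_images = n_images, mix = mix,
                   nodules_per_image = nodules_per_image,
                   images = images,
                   train = vapply(images[seq_len(ntrain)], `[[`, "", "source_id"),
                   test = vapply(images[setdiff(seq_len(n_images), seq_len(ntrain))],
                                 `[[`, "", "source_id"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Template bases cut from noise-free phantoms
#'
#' Renders one lobulated margin at 8 orientations (45-degree phase steps of
#' the same radial pattern) and crops a window around the margin, giving
#' the 8 base ROIs for [build_template_bank()] without any external data.
#'
#' @param size_px Base ROI side length.
#' @param r0,a,m Margin parameters of the rendered nodule.
#' @return List of 8 numeric matrices.
#' @export
phantom_template_bases <- function(size_px = 30, r0 = 10, a = 0.18, m = 5) {
  lapply(0:7, function(o) {
    nd <- nodule_spec(c(64, 64), r0, a, m, hu = 30, phase = o * pi / 4)
    cfg <- phantom_config(image_size = c(128, 128), noise_sigma = 0, vessels = 0,
                          nodules = list(nd), lung_radius = 60, seed = 1)
    ph <- generate_phantom(cfg, source_id = sprintf("base_%d", o + 1))
    half <- floor(size_px / 2)
    ph$hu$values[(64 - half + 1):(64 - half + size_px),
                 (64 - half + 1):(64 - half + size_px)]
  })
}

#' Crop training patches centered on ground-truth boxes
#'
#' @param hu An [hu_image()].
#' @param boxes Box data frame (`row`, `col`, `height`, `width`).
#' @param size_px Patch side length.
#' @return List of patch matrices (boxes too close to the border are
#'   skipped).
#' @export
crop_box_patches <- function(hu, boxes, size_px) {
  v <- .as_pixels(hu)
  half <- floor(size_px / 2)
  out <- list()
  for (i in seq_len(nrow(boxes))) {
    cr <- boxes$row[i] + floor(boxes$height[i] / 2)
    cc <- boxes$col[i] + floor(boxes$width[i] / 2)
    r0 <- cr - half; c0 <- cc - half
    if (r0 < 1 || c0 < 1 || r0 + size_px - 1 > nrow(v) || c0 + size_px - 1 > ncol(v))
      next
    out[[length(out) + 1L]] <- v[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)]
  }
  out
}

#' Sample negative training patches away from ground truth
#'
#' Draws window positions whose center lies in the parenchyma mask and
#' whose box does not overlap any ground-truth box.
#'
#' @param hu An [hu_image()].
#' @param mask A [parenchyma_mask()].
#' @param gts Ground-truth boxes to avoid.
#' @param n Number of patches.
#' @param size_px Patch side length.
#' @param seed Integer seed.
#' @return List of patch matrices.
#' @export
sample_negative_patches <- function(hu, mask, gts, n, size_px, seed = 1) {
  v <- .as_pixels(hu)
  half <- floor(size_px / 2)
  withr::with_seed(seed, {
    out <- list()
    guard <- 0L
    while (length(out) < n && guard < 50L * n) {
      guard <- guard + 1L
      r0 <- sample.int(nrow(v) - size_px + 1L, 1L)
      c0 <- sample.int(ncol(v) - size_px + 1L, 1L)
      if (!mask$mask[r0 + half, c0 + half]) next
      box <- list(row = r0, col = c0, height = size_px, width = size_px)
      overlaps <- FALSE
      for (j in seq_len(nrow(gts)))
        if (box_iou(box, gts[j, ]) > 0) { overlaps <- TRUE; break }
      if (overlaps) next
      out[[length(out) + 1L]] <- v[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)]
    }
    out
  })
}
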