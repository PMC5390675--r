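# Benchmark-level plumbing: loading a phantom benchmark directory,
# assembling training sets, running detectors over a split, and the
# step-size sweep.

#' Load a phantom benchmark directory
#'
#' Reads the manifest, every slice (converted to HU), the pooled
#' ground-truth boxes and the per-nodule reference table written by
#' [phantom_benchmark()].
#'
#' @param dir Benchmark directory.
#' @return An object of class `lob_benchmark`: `images` (named list of
#'   [hu_image()]), `gt`, `refs`, `manifest`.
#' @export
load_benchmark <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"), stringsAsFactors = FALSE)
  refs <- utils::read.csv(file.path(dir, "reference_contours.csv"),
                          stringsAsFactors = FALSE)
  vfile <- file.path(dir, "vessels.csv")
  vessels <- if (file.exists(vfile)) utils::read.csv(vfile, stringsAsFactors = FALSE)
             else NULL
  files <- mf$images$file
  ids <- mf$images$source_id
  images <- stats::setNames(lapply(files, function(f)
    to_hounsfield(read_slice(file.path(dir, f)))), ids)
  structure(list(images = images, gt = gt, refs = refs, vessels = vessels,
                 manifest = mf),
            class = "lob_benchmark")
}

#' @export
print.lob_benchmark <- function(x, ...) {
  cat(sprintf("<lob_benchmark: %d images (%d train / %d test), %d ground-truth boxes>\n",
              length(x$images), length(x$manifest$train), length(x$manifest$test),
              nrow(x$gt)))
  invisible(x)
}

#' Assemble a training set and fit a detector from a benchmark
#'
#' Positive patches are windows centered on the lobulated ground-truth
#' boxes of the training split, augmented by small jitters
#' ([augment_positives()]). Negative patches combine (i) windows centered
#' on the smooth (non-target) nodules, (ii) windows sampled along the
#' vessel segments, and (iii) windows centered on parenchyma / lung-wall
#' regions sampled uniformly away from ground truth. The detector is then
#' trained with [train_detector()].
#'
#' @param bench A [load_benchmark()] result (or a directory path).
#' @param algorithm Detector id from [algorithm_table()] (A2-A9).
#' @param seed Integer seed for augmentation, sampling and training.
#' @param k Codebook size.
#' @param per_box Positive samples per ground-truth box.
#' @param jitter_px Augmentation jitter.
#' @param neg_per_image Random negative patches per training image.
#' @param params Descriptor parameters.
#' @return A `lob_model`.
#' @export
train_from_benchmark <- function(bench, algorithm = "A9", seed = 1, k = 64,
                                 per_box = 4, jitter_px = 2, neg_per_image = 40,
                                 params = descriptor_defaults()) {
  if (is.character(bench)) bench <- load_benchmark(bench)
  tab <- algorithm_table()
  .assert(algorithm %in% tab$id, sprintf("unknown algorithm id '%s'", algorithm))
  cfgrow <- tab[tab$id == algorithm, ]
  size_px <- cfgrow$window_px
  train_ids <- bench$manifest$train
  pos <- list(); neg <- list()
  for (sid in train_ids) {
    hu <- bench$images[[sid]]
    mask <- segment_parenchyma(hu)
    g <- bench$gt[bench$gt$source_id == sid, , drop = FALSE]
    if (nrow(g)) {
      aug <- augment_positives(g, per_box = per_box, jitter_px = jitter_px,
                               seed = seed + match(sid, train_ids),
                               image_size = dim(hu$values))
      pos <- c(pos, crop_box_patches(hu, aug, size_px))
    }
    smooth <- bench$refs[bench$refs$source_id == sid &
                           bench$refs$label == "smooth", , drop = FALSE]
    if (nrow(smooth)) {
      sb <- data.frame(row = smooth$center_row - floor(size_px / 2),
                       col = smooth$center_col - floor(size_px / 2),
                       height = size_px, width = size_px)
      sb <- augment_positives(sb, per_box = 2, jitter_px = jitter_px,
                              seed = seed + 500L + match(sid, train_ids),
                              image_size = dim(hu$values))
      neg <- c(neg, crop_box_patches(hu, sb, size_px))
    }
    ves <- bench$vessels[bench$vessels$source_id == sid, , drop = FALSE]
    if (!is.null(ves) && nrow(ves)) {
      half <- floor(size_px / 2)
      for (j in seq_len(nrow(ves))) for (t in c(0.2, 0.5, 0.8)) {
        cen <- round(c(ves$p0_row[j] + t * (ves$p1_row[j] - ves$p0_row[j]),
                       ves$p0_col[j] + t * (ves$p1_col[j] - ves$p0_col[j])))
        r0 <- cen[1L] - half; c0 <- cen[2L] - half
        if (r0 < 1 || c0 < 1 || r0 + size_px - 1 > nrow(hu$values) ||
            c0 + size_px - 1 > ncol(hu$values)) next
        if (!mask$mask[cen[1L], cen[2L]]) next
        box <- list(row = r0, col = c0, height = size_px, width = size_px)
        if (nrow(g) && any(vapply(seq_len(nrow(g)), function(q)
          box_iou(box, g[q, ]) > 0, logical(1)))) next
        neg <- c(neg, list(hu$values[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)]))
      }
    }
    neg <- c(neg, sample_negative_patches(hu, mask, g, neg_per_image, size_px,
                                          seed = seed + 900L + match(sid, train_ids)))
  }
  .assert(length(pos) > 0, "training split contains no lobulated nodules")
  train_detector(pos, neg, descriptor_kind = cfgrow$descriptor,
                 encoding = cfgrow$encoding, k = k, seed = seed, params = params)
}

#' Run a detector over one split of a benchmark
#'
#' @param bench A [load_benchmark()] result.
#' @param model A `lob_model`.
#' @param step_px Sliding step.
#' @param split `"test"`, `"train"` or `"all"`.
#' @param bend Optional [bending_filter_params()]; when given, the bending
#'   filter is applied per image and the filtered detections are returned.
#' @return Detection data frame pooled over the split.
#' @export
detect_benchmark <- function(bench, model, step_px = 12, split = "test",
                             bend = NULL) {
  ids <- switch(split, test = bench$manifest$test, train = bench$manifest$train,
                all = names(bench$images))
  spec <- window_spec(model$window_px, step_px)
  out <- lapply(ids, function(sid) {
    hu <- bench$images[[sid]]
    mask <- segment_parenchyma(hu)
    d <- detect(hu, mask, model, spec)
    if (!is.null(bend) && nrow(d)) d <- filter_candidates(d, hu, bend)
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty_detections()
  rownames(out) <- NULL
  out
}

#' Step-size sweep
#'
#' Re-runs detection and evaluation for each sliding step and tabulates
#' SNTP, APPI, recall, precision and F1 per step, mirroring the step-size
#' experiments.
#'
#' @param bench A [load_benchmark()] result.
#' @param model A `lob_model`.
#' @param steps Step sizes to sweep.
#' @param split Benchmark split to evaluate.
#' @param iou_min Matching threshold for [compute_metrics()].
#' @param bend Optional [bending_filter_params()] applied before scoring.
#' @return Data frame with one row per step.
#' @export
sweep_steps <- function(bench, model, steps = seq(4, 20, by = 2), split = "test",
                        iou_min = 0.25, bend = NULL) {
  ids <- switch(split, test = bench$manifest$test, train = bench$manifest$train,
                all = names(bench$images))
  gt <- bench$gt[bench$gt$source_id %in% ids, , drop = FALSE]
  do.call(rbind, lapply(steps, function(s) {
    dets <- detect_benchmark(bench, model, step_px = s, split = split, bend = bend)
    rep <- compute_metrics(dets, gt, iou_min = iou_min, image_ids = ids)
    data.frame(step = s, SNTP = rep$SNTP, APPI = rep$APPI, recall = rep$recall,
               precision = rep$precision, f1 = rep$f1)
  }))
}
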