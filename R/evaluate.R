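# Matching detections to ground truth and the detection metrics:
# APPI (average positive detections per image), SNTP (average true
# positives per image), recall, precision, and F1.

#' Intersection-over-union of two boxes
#'
#' Boxes are `(row, col, height, width)` with 1-based inclusive corners.
#'
#' @param a,b Lists/rows with `row`, `col`, `height`, `width`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  r0 <- max(a$row, b$row); c0 <- max(a$col, b$col)
  r1 <- min(a$row + a$height, b$row + b$height) - 1
  c1 <- min(a$col + a$width, b$col + b$width) - 1
  inter <- max(0, r1 - r0 + 1) * max(0, c1 - c0 + 1)
  inter / (a$height * a$width + b$height * b$width - inter)
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Detections are visited in order of descending score; each is a true
#' positive iff its IoU with a still-unmatched ground-truth box of the same
#' image reaches `iou_min`. Remaining detections are false positives and
#' unmatched ground truth false negatives.
#'
#' @param dets Detection data frame (`source_id`, `row`, `col`, `height`,
#'   `width`, `score`).
#' @param gts Ground-truth data frame (same box columns).
#' @param iou_min Minimum IoU for a match.
#' @return List with data frames `tp`, `fp`, `fn`; `tp` gains a
#'   `matched_gt` index into `gts`.
#' @export
match_detections <- function(dets, gts, iou_min = 0.25) {
  if (nrow(dets)) dets <- dets[order(-dets$score), , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  is_tp <- logical(nrow(dets))
  matched <- rep(NA_integer_, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!used & gts$source_id == dets$source_id[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) box_iou(dets[i, ], gts[j, ]), numeric(1))
    jbest <- cand[which.max(ious)]
    if (max(ious) >= iou_min) {
      used[jbest] <- TRUE
      is_tp[i] <- TRUE
      matched[i] <- jbest
    }
  }
  tp <- dets[is_tp, , drop = FALSE]
  if (nrow(tp)) tp$matched_gt <- matched[is_tp]
  list(tp = tp, fp = dets[!is_tp, , drop = FALSE],
       fn = gts[!used, , drop = FALSE])
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both are 0. Accepts either
#' fractions or percentages (values > 1 are divided by 100).
#'
#' @param precision,recall Precision and recall.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (precision > 1) precision <- precision / 100
  if (recall > 1) recall <- recall / 100
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Detection metrics over a test set
#'
#' Precision, recall and F1 are pooled (micro-averaged) over all images;
#' APPI and SNTP are per-image means. With zero detections precision is
#' reported as 0 and flagged.
#'
#' @param dets Detections over all images.
#' @param gts Ground truth over all images.
#' @param iou_min Minimum IoU for a true positive.
#' @param image_ids Test-set image identifiers; defaults to the union of
#'   ids seen in `dets` and `gts`. Images with no detections still count in
#'   the per-image averages.
#' @return An object of class `eval_report`: counts, `APPI`, `SNTP`,
#'   `recall`, `precision`, `f1`, `per_image`, `match_criterion`.
#' @export
compute_metrics <- function(dets, gts, iou_min = 0.25, image_ids = NULL) {
  if (is.null(image_ids))
    image_ids <- sort(unique(c(dets$source_id, gts$source_id)))
  .assert(length(image_ids) >= 1, "need at least one image")
  per <- lapply(image_ids, function(id) {
    m <- match_detections(dets[dets$source_id == id, , drop = FALSE],
                          gts[gts$source_id == id, , drop = FALSE], iou_min)
    data.frame(source_id = id, tp = nrow(m$tp), fp = nrow(m$fp), fn = nrow(m$fn))
  })
  per <- do.call(rbind, per)
  TP <- sum(per$tp); FP <- sum(per$fp); FN <- sum(per$fn)
  no_dets <- (TP + FP) == 0
  precision <- if (no_dets) 0 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  structure(list(per_image = per, TP = TP, FP = FP, FN = FN,
                 APPI = mean(per$tp + per$fp), SNTP = mean(per$tp),
                 recall = recall, precision = precision,
                 f1 = f1_score(precision, recall),
                 precision_undefined = no_dets,
                 match_criterion = sprintf("greedy one-to-one, IoU >= %g", iou_min)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detection metrics over %d image(s) [%s]\n", nrow(x$per_image),
              x$match_criterion))
  cat(sprintf("  SNTP %.2f | APPI %.2f | recall %.2f%% | precision %.2f%%%s | F1 %.4f\n",
              x$SNTP, x$APPI, 100 * x$recall, 100 * x$precision,
              if (x$precision_undefined) " (no detections)" else "", x$f1))
  invisible(x)
}

#' Write / read detection boxes as CSV
#'
#' Shared schema used by the template, classifier and filter stages:
#' `source_id,row,col,height,width,score,algorithm` (plus any extra
#' columns present).
#'
#' @param boxes Detection (or ground-truth) data frame.
#' @param path CSV path.
#' @return `write_boxes` returns `path` invisibly; `read_boxes` the frame.
#' @export
write_boxes <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes
#' @export
read_boxes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tabulate an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    SNTP = report$SNTP, APPI = report$APPI, recall = report$recall,
    precision = report$precision, f1 = report$f1, TP = report$TP,
    FP = report$FP, FN = report$FN, match_criterion = report$match_criterion,
    per_image = report$per_image), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
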