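# Codebooks, descriptor-set encodings (BOF / VLAD / FV), training-set
# augmentation, SVM training, and the sliding-window detectors A2-A9.

#' Codebook container
#'
#' @param centroids `k x dim` matrix of visual words (GMM means for FV).
#' @param kind `"kmeans"` or `"gmm"`.
#' @param weights Mixture weights (GMM only).
#' @param variances `k x dim` diagonal variances (GMM only).
#' @param seed Seed used for training, for provenance.
#' @return An object of class `codebook`.
#' @export
codebook <- function(centroids, kind = c("kmeans", "gmm"), weights = NULL,
                     variances = NULL, seed = NA_integer_) {
  kind <- match.arg(kind)
  .assert(is.matrix(centroids) && nrow(centroids) >= 1, "centroids must be a k x dim matrix")
  if (kind == "gmm") {
    .assert(!is.null(weights) && !is.null(variances), "GMM codebook needs weights and variances")
    .assert(length(weights) == nrow(centroids), "one weight per component")
    .assert(all(dim(variances) == dim(centroids)), "variances must match centroids")
  }
  structure(list(centroids = centroids, kind = kind, weights = weights,
                 variances = variances, k = nrow(centroids), seed = seed),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook %s: k=%d, dim=%d>\n", x$kind, x$k, ncol(x$centroids)))
  invisible(x)
}

#' Build a codebook from training descriptors
#'
#' k-means (multiple fixed restarts) for BOF/VLAD, or a diagonal-covariance
#' Gaussian mixture for Fisher vectors (EM started from the k-means
#' partition). Deterministic given `seed`.
#'
#' @param descriptors `dim x N` matrix of training descriptors (columns), or
#'   a [descriptor_set()].
#' @param k Number of visual words (>= 2).
#' @param kind `"kmeans"` or `"gmm"`.
#' @param seed Integer seed.
#' @return A [codebook()].
#' @export
build_codebook <- function(descriptors, k, kind = c("kmeans", "gmm"), seed = 1) {
  kind <- match.arg(kind)
  X <- if (inherits(descriptors, "descriptor_set")) t(descriptors$vectors) else t(descriptors)
  .assert(k >= 2, "k must be >= 2")
  ndistinct <- nrow(unique(X))
  .assert(ndistinct >= k, sprintf("need at least k=%d distinct descriptors, have %d", k, ndistinct))
  withr::with_seed(seed, {
    km <- stats::kmeans(X, centers = k, nstart = 5, iter.max = 100)
    if (kind == "kmeans")
      return(codebook(km$centers, "kmeans", seed = seed))
    z <- mclust::unmap(km$cluster, groups = seq_len(k))
    fit <- if (ncol(X) == 1L) mclust::meV(data = X[, 1L], z = z)
           else mclust::meVVI(data = X, z = z)
    if (ncol(X) == 1L) {
      mu <- matrix(fit$parameters$mean, ncol = 1L)
      vr <- matrix(fit$parameters$variance$sigmasq, ncol = 1L)
      if (nrow(vr) == 1L) vr <- matrix(rep(vr[1L], k), ncol = 1L)
    } else {
      mu <- t(fit$parameters$mean)
      vr <- t(apply(fit$parameters$variance$sigma, 3L, diag))
    }
    codebook(mu, "gmm", weights = fit$parameters$pro, variances = pmax(vr, 1e-8),
             seed = seed)
  })
}

.desc_matrix <- function(d) {
  if (inherits(d, "descriptor_set")) d$vectors else as.matrix(d)
}

# Squared Euclidean distances between descriptor columns and centroid rows.
.sqdist_to_centroids <- function(X, C) {
  # X: dim x N, C: k x dim -> N x k
  outer(colSums(X^2), rep(1, nrow(C))) - 2 * t(X) %*% t(C) +
    outer(rep(1, ncol(X)), rowSums(C^2))
}

#' Bag-of-features encoding
#'
#' Hard-assigns each descriptor to its nearest centroid and returns the
#' L1-normalized assignment histogram (length k, on the probability
#' simplex; the zero vector for an empty descriptor set).
#'
#' @param d A [descriptor_set()] or `dim x N` matrix.
#' @param cb A k-means [codebook()].
#' @return An `encoded_vector` (numeric with attributes `encoding`, `norm`).
#' @export
encode_bof <- function(d, cb) {
  .assert(cb$kind == "kmeans", "BOF requires a k-means codebook")
  X <- .desc_matrix(d)
  .assert(nrow(X) == 0L || nrow(X) == ncol(cb$centroids), "descriptor dimension mismatch")
  if (ncol(X) == 0L) return(.encoded(numeric(cb$k), "BOF", "L1"))
  nn <- max.col(-.sqdist_to_centroids(X, cb$centroids), ties.method = "first")
  h <- tabulate(nn, nbins = cb$k)
  .encoded(h / sum(h), "BOF", "L1")
}

#' VLAD encoding
#'
#' Accumulates, for each visual word, the residuals `x - c_i` of the
#' descriptors assigned to it; the concatenated `k * dim` vector is
#' L2-normalized (exactly zero when every residual is zero).
#'
#' @inheritParams encode_bof
#' @return An `encoded_vector` of length `k * dim`.
#' @export
encode_vlad <- function(d, cb) {
  .assert(cb$kind == "kmeans", "VLAD requires a k-means codebook")
  X <- .desc_matrix(d)
  dim_ <- ncol(cb$centroids)
  .assert(nrow(X) == 0L || nrow(X) == dim_, "descriptor dimension mismatch")
  out <- matrix(0, cb$k, dim_)
  if (ncol(X) > 0L) {
    nn <- max.col(-.sqdist_to_centroids(X, cb$centroids), ties.method = "first")
    for (i in seq_len(cb$k)) {
      sel <- nn == i
      if (any(sel))
        out[i, ] <- rowSums(X[, sel, drop = FALSE]) - sum(sel) * cb$centroids[i, ]
    }
  }
  .encoded(.l2_normalize(as.numeric(t(out))), "VLAD", "L2")
}

#' Fisher-vector encoding
#'
#' Gradient of the mean per-descriptor log-likelihood of a diagonal GMM
#' with respect to the component means and standard deviations, normalized
#' by the Fisher information approximation, then power-normalized
#' (`sign(z) * sqrt(|z|)`) and L2-normalized. Length `2 * k * dim`.
#'
#' @param d A [descriptor_set()] or `dim x N` matrix.
#' @param cb A GMM [codebook()].
#' @return An `encoded_vector` of length `2 * k * dim`.
#' @export
encode_fv <- function(d, cb) {
  .assert(cb$kind == "gmm", "FV requires a GMM codebook")
  X <- .desc_matrix(d)
  k <- cb$k; dim_ <- ncol(cb$centroids)
  .assert(nrow(X) == 0L || nrow(X) == dim_, "descriptor dimension mismatch")
  if (ncol(X) == 0L) return(.encoded(numeric(2 * k * dim_), "FV", "power+L2"))
  N <- ncol(X)
  sd_ <- sqrt(cb$variances)
  # log responsibilities
  logp <- sapply(seq_len(k), function(i) {
    z <- (X - cb$centroids[i, ]) / sd_[i, ]
    log(cb$weights[i]) - 0.5 * colSums(z^2) - sum(log(sd_[i, ])) - dim_ / 2 * log(2 * pi)
  })
  if (is.null(dim(logp))) logp <- matrix(logp, nrow = N)
  mx <- apply(logp, 1L, max)
  gam <- exp(logp - mx)
  gam <- gam / rowSums(gam)
  Gmu <- matrix(0, k, dim_); Gsd <- matrix(0, k, dim_)
  for (i in seq_len(k)) {
    z <- (X - cb$centroids[i, ]) / sd_[i, ]
    g <- gam[, i]
    Gmu[i, ] <- (z %*% g) / (N * sqrt(cb$weights[i]))
    Gsd[i, ] <- ((z^2 - 1) %*% g) / (N * sqrt(2 * cb$weights[i]))
  }
  v <- c(as.numeric(t(Gmu)), as.numeric(t(Gsd)))
  v <- sign(v) * sqrt(abs(v))
  .encoded(.l2_normalize(v), "FV", "power+L2")
}

.encoded <- function(v, encoding, norm) {
  structure(v, encoding = encoding, norm = norm, class = c("encoded_vector", "numeric"))
}

#' Encode a descriptor set with a named encoding
#'
#' @param d A [descriptor_set()] or matrix.
#' @param cb A [codebook()] of the matching kind.
#' @param encoding `"BOF"`, `"VLAD"` or `"FV"`.
#' @return An `encoded_vector`.
#' @export
encode <- function(d, cb, encoding = c("BOF", "VLAD", "FV")) {
  switch(match.arg(encoding),
         BOF = encode_bof(d, cb), VLAD = encode_vlad(d, cb), FV = encode_fv(d, cb))
}

#' Jitter ground-truth boxes into additional positive samples
#'
#' Each input box yields `per_box` samples: the original plus
#' `per_box - 1` copies offset by uniform integer jitters in
#' `[-jitter_px, jitter_px]` on each coordinate (so 25 boxes with
#' `per_box = 4` give 100 positives). Jittered boxes pushed outside the
#' image are clamped back in, with a message.
#'
#' @param boxes Data frame with `row`, `col`, `height`, `width` columns.
#' @param per_box Samples produced per input box (>= 1).
#' @param jitter_px Maximum absolute offset in pixels.
#' @param seed Integer seed.
#' @param image_size Optional `(rows, cols)` used for clamping.
#' @return Data frame of `nrow(boxes) * per_box` boxes; a `jittered` column
#'   marks the non-originals.
#' @export
augment_positives <- function(boxes, per_box = 4, jitter_px = 2, seed = 1,
                              image_size = NULL) {
  .assert(per_box >= 1, "per_box must be >= 1")
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, , drop = FALSE]
      reps <- b[rep(1L, per_box), , drop = FALSE]
      if (per_box > 1) {
        dr <- sample(-jitter_px:jitter_px, per_box - 1, replace = TRUE)
        dc <- sample(-jitter_px:jitter_px, per_box - 1, replace = TRUE)
        reps$row[-1L] <- reps$row[-1L] + dr
        reps$col[-1L] <- reps$col[-1L] + dc
      }
      reps$jittered <- c(FALSE, rep(TRUE, per_box - 1))
      reps
    })
    out <- do.call(rbind, out)
    if (!is.null(image_size)) {
      r2 <- pmin(pmax(out$row, 1L), image_size[1L] - out$height + 1L)
      c2 <- pmin(pmax(out$col, 1L), image_size[2L] - out$width + 1L)
      nclamp <- sum(r2 != out$row | c2 != out$col)
      if (nclamp > 0) message(sprintf("augment_positives: clamped %d box(es) to image bounds", nclamp))
      out$row <- r2; out$col <- c2
    }
    rownames(out) <- NULL
    out
  })
}

#' The descriptor/encoding configuration of detectors A2-A9
#'
#' The eight local-feature detectors differ only in their descriptor kind
#' and encoding; the mapping is data shared by training, detection and the
#' command-line interface.
#'
#' @return Data frame with columns `id`, `descriptor`, `encoding`,
#'   `window_px`.
#' @export
algorithm_table <- function() {
  data.frame(
    id = paste0("A", 2:9),
    descriptor = c("PHOW", "PHOW", "PHOW", "PHOW_HOG", "PHOW_SC", "PHOW_GC",
                   "LIOP", "LIOP_LBP"),
    encoding = c("BOF", "FV", "VLAD", "BOF", "BOF", "BOF", "BOF", "BOF"),
    window_px = c(30L, 30L, 30L, 30L, 30L, 30L, 31L, 31L),
    stringsAsFactors = FALSE)
}

#' Train a lobulation detector
#'
#' Extracts descriptors of the requested kind from the positive and
#' negative training patches, builds the codebook on the pooled training
#' descriptors only, encodes every patch, and fits a polynomial-kernel
#' (degree 3) SVM with class weights balancing the positive/negative
#' imbalance. All stochastic steps are governed by `seed`.
#'
#' @param pos_patches,neg_patches Lists of patches (matrices or patch
#'   objects); both classes must be nonempty.
#' @param descriptor_kind One of the kinds in [algorithm_table()].
#' @param encoding `"BOF"`, `"VLAD"` or `"FV"`.
#' @param k Codebook size.
#' @param svm_cost SVM regularization constant.
#' @param seed Integer seed.
#' @param params Descriptor parameters, see [descriptor_defaults()].
#' @return An object of class `lob_model` holding the codebook, the SVM,
#'   and the full configuration.
#' @export
train_detector <- function(pos_patches, neg_patches, descriptor_kind = "LIOP_LBP",
                           encoding = "BOF", k = 64, svm_cost = 1, seed = 1,
                           params = descriptor_defaults()) {
  .assert(length(pos_patches) > 0 && length(neg_patches) > 0,
          "both classes must be nonempty")
  all_patches <- c(pos_patches, neg_patches)
  dsets <- lapply(all_patches, extract_descriptors, kind = descriptor_kind, params = params)
  pooled <- do.call(cbind, lapply(dsets, function(d) d$vectors))
  cb_kind <- if (encoding == "FV") "gmm" else "kmeans"
  cb <- build_codebook(pooled, k = k, kind = cb_kind, seed = seed)
  X <- t(vapply(dsets, function(d) as.numeric(encode(d, cb, encoding)),
                numeric(.encoding_length(encoding, cb))))
  y <- factor(rep(c("pos", "neg"), c(length(pos_patches), length(neg_patches))),
              levels = c("neg", "pos"))
  wts <- c(neg = 1, pos = length(neg_patches) / length(pos_patches))
  sv <- withr::with_seed(seed,
    e1071::svm(X, y, kernel = "polynomial", degree = 3, coef0 = 1, cost = svm_cost,
               class.weights = wts, scale = FALSE))
  structure(list(codebook = cb, svm = sv, descriptor_kind = descriptor_kind,
                 encoding = encoding, params = params, svm_cost = svm_cost,
                 seed = seed, window_px = if (descriptor_kind %in% c("LIOP", "LIOP_LBP")) 31L else 30L),
            class = "lob_model")
}

.encoding_length <- function(encoding, cb) {
  switch(encoding, BOF = cb$k, VLAD = cb$k * ncol(cb$centroids),
         FV = 2L * cb$k * ncol(cb$centroids))
}

#' @export
print.lob_model <- function(x, ...) {
  cat(sprintf("<lob_model %s + %s, k=%d, window=%d px, seed=%d>\n",
              x$descriptor_kind, x$encoding, x$codebook$k, x$window_px, x$seed))
  invisible(x)
}

#' Save / load a trained detector
#'
#' @param model A `lob_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Run a trained detector over an image
#'
#' Slides the model's window over the masked parenchyma, encodes each
#' patch, and reports one detection per positively classified window with
#' the (oriented) SVM decision value as score. Deterministic.
#'
#' @param hu An [hu_image()].
#' @param mask A [parenchyma_mask()] or `NULL`.
#' @param model A [train_detector()] result.
#' @param spec A [window_spec()]; its size must match the model's window
#'   (odd, 31, for LIOP kinds).
#' @param algorithm_id Label stored in the `algorithm` column.
#' @return Detection data frame (possibly 0 rows).
#' @export
detect <- function(hu, mask, model, spec, algorithm_id = NULL) {
  .assert(inherits(model, "lob_model"), "model must be a lob_model")
  .assert(spec$size_px == model$window_px,
          sprintf("window size %d incompatible with %s model (needs %d)",
                  spec$size_px, model$descriptor_kind, model$window_px))
  if (is.null(algorithm_id)) {
    tab <- algorithm_table()
    hit <- tab$descriptor == model$descriptor_kind & tab$encoding == model$encoding
    algorithm_id <- if (any(hit)) tab$id[which(hit)[1L]] else "custom"
  }
  pos <- window_positions(hu, mask, spec)
  if (!nrow(pos)) return(empty_detections())
  v <- .as_pixels(hu)
  enc_len <- .encoding_length(model$encoding, model$codebook)
  X <- matrix(0, nrow(pos), enc_len)
  for (i in seq_len(nrow(pos))) {
    p <- v[pos[i, 1L]:(pos[i, 1L] + spec$size_px - 1L),
           pos[i, 2L]:(pos[i, 2L] + spec$size_px - 1L)]
    d <- extract_descriptors(p, model$descriptor_kind, model$params)
    X[i, ] <- as.numeric(encode(d, model$codebook, model$encoding))
  }
  pr <- stats::predict(model$svm, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- if (grepl("^pos", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
  keep <- pr == "pos"
  if (!any(keep)) return(empty_detections())
  sid <- if (inherits(hu, "hu_image")) hu$source_id else "image"
  out <- data.frame(source_id = sid, row = pos[keep, 1L], col = pos[keep, 2L],
                    height = spec$size_px, width = spec$size_px,
                    score = score[keep], algorithm = algorithm_id,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$score, out$row, out$col), , drop = FALSE]
}
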