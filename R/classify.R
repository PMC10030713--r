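# Classification and evaluation: confusion counts, the five derived scores,
# stratified k-fold splitting, and light image-classifier backends.

# Accepts character/factor "acceptable"/"unacceptable", logical (TRUE =
# acceptable) or 0/1 (1 = acceptable); returns a logical "is positive".
normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(labels == 1)
  }
  lv <- as.character(labels)
  bad <- setdiff(unique(lv), c("acceptable", "unacceptable"))
  if (length(bad))
    stopf("labels must be binary acceptable/unacceptable; got '%s'", bad[1L])
  lv == "acceptable"
}

#' Confusion matrix for quality labels
#'
#' Positive class is `"acceptable"`: TP counts acceptable signals predicted
#' acceptable, TN unacceptable predicted unacceptable, FP unacceptable
#' predicted acceptable, FN acceptable predicted unacceptable.
#'
#' @param labels,predictions equal-length binary label vectors
#'   (`"acceptable"`/`"unacceptable"`, logical, or 0/1).
#' @return a `confusion_matrix`: list with TP, TN, FP, FN.
#' @export
confusion_matrix <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stopf("labels (%d) and predictions (%d) differ in length",
          length(labels), length(predictions))
  y <- normalize_labels(labels)
  p <- normalize_labels(predictions)
  structure(list(TP = sum(y & p), TN = sum(!y & !p),
                 FP = sum(!y & p), FN = sum(y & !p)),
            class = "confusion_matrix")
}

#' Classification scores from a confusion matrix
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' `F1 = TP/(TP + 0.5(FP+FN))`, accuracy `Acc = (TP+TN)/total` and the
#' balanced accuracy `mAcc = (Se+Sp)/2`, all as percentages. A score whose
#' denominator is zero is reported as `NaN` (undefined).
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report`: named numeric vector
#'   `c(Se, Sp, F1, Acc, mAcc)` in percent.
#' @examples
#' compute_metrics(confusion_matrix(c(1,1,1,1,0,0,0,0), c(1,1,1,0,1,1,0,0)))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0) stopf("empty confusion matrix")
  div <- function(num, den) if (den == 0) NaN else num / den
  se <- 100 * div(cm$TP, cm$TP + cm$FN)
  sp <- 100 * div(cm$TN, cm$TN + cm$FP)
  structure(c(Se = se, Sp = sp,
              F1 = 100 * div(cm$TP, cm$TP + 0.5 * (cm$FP + cm$FN)),
              Acc = 100 * (cm$TP + cm$TN) / total,
              mAcc = (se + sp) / 2),
            class = c("metrics_report", "numeric"))
}

#' Deterministic k-fold split
#'
#' Partitions `1..n` into `k` folds whose sizes differ by at most one.
#' With `stratified = TRUE` (and labels supplied) each fold preserves the
#' class ratio to within one record per class. Deterministic under `seed`.
#'
#' @param n number of records.
#' @param k number of folds, `2 <= k <= n`.
#' @param labels optional labels for stratification.
#' @param stratified stratify on `labels`?
#' @param seed integer seed.
#' @return list of `k` integer index vectors (disjoint, covering `1..n`).
#' @export
kfold_split <- function(n, k = 10L, labels = NULL,
                        stratified = !is.null(labels), seed = 1L) {
  if (k < 2L || k > n) stopf("need 2 <= k <= n (got k = %d, n = %d)", k, n)
  if (stratified && is.null(labels)) stopf("stratified split needs labels")
  if (!is.null(labels) && length(labels) != n)
    stopf("labels length %d != n = %d", length(labels), n)
  ordered_idx <- with_seed(seed, {
    if (stratified) {
      y <- normalize_labels(labels)
      unlist(lapply(unique(y), function(cl) sample(which(y == cl))),
             use.names = FALSE)
    } else sample.int(n)
  })
  fold_of <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(f) sort(ordered_idx[fold_of == f]))
}

# Ridge-penalized logistic regression via IRLS; switches to the dual
# (Woodbury) update when features outnumber observations. The intercept is
# carried as a feature and shares the (small) ridge penalty.
ridge_logistic_fit <- function(X, y, lambda = 1e-2, maxit = 50L,
                               tol = 1e-9) {
  X <- cbind(1, X)
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  dual <- p > n
  G <- if (dual) tcrossprod(X)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- if (dual) {
      sw <- sqrt(w)
      M <- G * outer(sw, sw)
      diag(M) <- diag(M) + lambda
      drop(crossprod(X, sw * solve(M, sw * z)))
    } else {
      A <- crossprod(X, X * w)
      diag(A) <- diag(A) + lambda
      drop(solve(A, crossprod(X, w * z)))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  beta
}

ridge_logistic_prob <- function(beta, X) stats::plogis(drop(cbind(1, X) %*% beta))

# 5x5x3 patch index template for stride-2 convolution over a square image.
conv_patch_index <- function(side, ksize = 5L, stride = 2L) {
  npos <- (side - ksize) %/% stride + 1L
  offs <- as.vector(outer(0:(ksize - 1L), 0:(ksize - 1L) * side, `+`))
  offs <- as.vector(outer(offs, (0:2) * side * side, `+`))  # 3 channels
  starts <- as.vector(outer(seq(1L, by = stride, length.out = npos),
                            (seq(1L, by = stride, length.out = npos) - 1L) *
                              side, `+`))
  list(idx = outer(offs, starts, `+`), npos = npos)
}

# Random-filter convolution features: conv (8 filters, 5x5x3, stride 2) ->
# ReLU -> 5x5 mean pool (stride 5). Filters are fixed given the seed; only
# the logistic head is trained.
cnn_features <- function(image, filters, template) {
  a <- downsample_image(image, side = 64L)
  patches <- matrix(a[template$idx], nrow = nrow(filters))
  act <- pmax(crossprod(patches, filters), 0)  # npos^2 x nfilt
  npos <- template$npos
  pool <- 5L
  npool <- npos %/% pool
  g <- rep(seq_len(npool), each = pool)
  keep <- seq_len(npool * pool)
  out <- numeric(0)
  for (f in seq_len(ncol(act))) {
    m <- matrix(act[, f], npos, npos)[keep, keep]
    m <- rowsum(m, g) / pool
    m <- t(rowsum(t(m), g) / pool)
    out <- c(out, as.vector(m))
  }
  out
}

linear_features <- function(image) as.vector(downsample_image(image, 64L))

extract_features <- function(images, backend, filters = NULL,
                             template = NULL) {
  if (backend == "linear_pixels") {
    t(vapply(images, linear_features,
             numeric(length(linear_features(images[[1L]])))))
  } else {
    f1 <- cnn_features(images[[1L]], filters, template)
    t(vapply(images, cnn_features, numeric(length(f1)), filters = filters,
             template = template))
  }
}

#' Train an image quality classifier
#'
#' Backends share one predict contract. `"baseline_cnn"` (default) is a
#' small convolutional network: one convolution layer of eight fixed,
#' seed-determined random 5x5x3 filters with ReLU and mean pooling, followed
#' by a trained ridge-logistic head -- deterministic and CPU-trainable in
#' seconds. `"linear_pixels"` fits the ridge-logistic head directly on
#' 64x64 downsampled pixels. `"googlenet_transfer"` is a placeholder
#' adapter that requires externally supplied pretrained weights and is not
#' available in this build.
#'
#' @param images list of `raster_image` arrays (equal dimensions, RGB).
#' @param labels binary quality labels, both classes present.
#' @param backend one of `"baseline_cnn"`, `"linear_pixels"`,
#'   `"googlenet_transfer"`.
#' @param seed integer seed (drives the random filters).
#' @param lambda ridge penalty of the logistic head.
#' @return an `ecg_classifier` model handle.
#' @export
train_classifier <- function(images, labels,
                             backend = c("baseline_cnn", "linear_pixels",
                                         "googlenet_transfer"),
                             seed = 1L, lambda = 1e-2) {
  backend <- match.arg(backend)
  if (backend == "googlenet_transfer")
    stopf(paste("the googlenet_transfer backend needs pretrained Inception",
                "weights and a deep-learning runtime; use baseline_cnn"))
  if (length(images) != length(labels))
    stopf("images (%d) and labels (%d) differ in length",
          length(images), length(labels))
  dims <- vapply(images, function(im) dim(unclass(im)), integer(3L))
  if (length(unique(dims[1L, ])) != 1L || any(dims[3L, ] != 3L))
    stopf("all images must share one height x width x 3 shape")
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stopf("training needs both classes present")
  filters <- template <- NULL
  if (backend == "baseline_cnn") {
    template <- conv_patch_index(64L)
    filters <- with_seed(derive_seed(seed, 7L),
                         matrix(rnorm(75L * 8L) / sqrt(75), 75L, 8L))
  }
  X <- extract_features(images, backend, filters, template)
  beta <- ridge_logistic_fit(X, as.numeric(y), lambda = lambda)
  structure(list(backend = backend, beta = beta, filters = filters,
                 template = template, lambda = lambda, seed = seed),
            class = "ecg_classifier")
}

#' @rdname train_classifier
#' @param object an `ecg_classifier`.
#' @param type `"class"` for labels, `"prob"` for P(acceptable).
#' @param ... ignored.
#' @export
predict.ecg_classifier <- function(object, images, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  X <- extract_features(images, object$backend, object$filters,
                        object$template)
  pr <- ridge_logistic_prob(object$beta, X)
  if (type == "prob") return(pr)
  ifelse(pr >= 0.5, "acceptable", "unacceptable")
}

#' k-fold cross-validated evaluation
#'
#' Stratified folds (class ratio preserved within one record per fold);
#' each fold is held out once while the backend trains on the rest; the five
#' scores of [compute_metrics()] are reported per fold with their mean and
#' standard deviation. Deterministic under `seed`.
#'
#' @inheritParams train_classifier
#' @param k number of folds, default 10.
#' @param stratified stratify folds on the labels?
#' @return a `cv_result`: list with `per_fold` (k x 5 data.frame), `mean`,
#'   `sd`, `folds`, `k`, `backend`.
#' @export
cross_validate <- function(images, labels, k = 10L,
                           backend = c("baseline_cnn", "linear_pixels",
                                       "googlenet_transfer"),
                           seed = 1L, lambda = 1e-2, stratified = TRUE) {
  backend <- match.arg(backend)
  folds <- kfold_split(length(images), k, labels = labels,
                       stratified = stratified,
                       seed = derive_seed(seed, 3L))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    model <- train_classifier(images[-test], labels[-test], backend,
                              seed = derive_seed(seed, 10L + f),
                              lambda = lambda)
    pred <- predict(model, images[test])
    per_fold[[f]] <- as.numeric(compute_metrics(
      confusion_matrix(labels[test], pred)))
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  names(per_fold) <- c("Se", "Sp", "F1", "Acc", "mAcc")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, sd),
                 folds = folds, k = k, backend = backend, seed = seed),
            class = "cv_result")
}

#' @rdname cross_validate
#' @param x a `cv_result`.
#' @param ... ignored.
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d-fold, backend %s>\n", x$k, x$backend))
  for (m in names(x$mean))
    cat(sprintf("  %-4s %6.2f +/- %.2f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}
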