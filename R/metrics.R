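## The five standard semantic-segmentation performance measures over
## pairs of label rasters: global/mean accuracy, mean/weighted IoU, and
## the mean boundary F-score.

#' Confusion matrix between two label rasters
#'
#' @param reference,predicted [label_raster()]s of equal dimensions.
#' @return 3x3 integer matrix of pixel counts, rows = reference class,
#'   columns = predicted class, in the order artery, vein, background.
#' @export
confusion <- function(reference, predicted) {
  check_same_dim(reference, predicted)
  cls <- c(AV_ARTERY, AV_VEIN, AV_BACKGROUND)
  cm <- table(factor(as.integer(reference), levels = cls),
              factor(as.integer(predicted), levels = cls))
  cm <- matrix(as.integer(cm), 3L, 3L,
               dimnames = list(reference = c("artery", "vein", "background"),
                               predicted = c("artery", "vein", "background")))
  cm
}

check_nonempty_cm <- function(cm) {
  if (sum(cm) == 0L) av_error("EmptyComparison", "confusion matrix is empty")
}

#' Global accuracy
#'
#' Fraction of all compared pixels classified correctly:
#' `(TP + TN) / (TP + FP + FN + TN)`, i.e. the trace of the confusion
#' matrix over its total.
#'
#' @param cm confusion matrix from [confusion()].
#' @return Scalar in `[0, 1]`.
#' @export
global_accuracy <- function(cm) {
  check_nonempty_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Mean accuracy
#'
#' Per-class recall (correctly classified pixels over reference pixels of
#' the class), averaged over the classes present in the reference.
#'
#' @inheritParams global_accuracy
#' @return Scalar in `[0, 1]`.
#' @export
mean_accuracy <- function(cm) {
  check_nonempty_cm(cm)
  present <- rowSums(cm) > 0
  mean(diag(cm)[present] / rowSums(cm)[present])
}

#' Mean intersection over union
#'
#' Per-class IoU `TP_c / (TP_c + FP_c + FN_c)`, averaged over classes
#' present in the reference or the prediction (classes absent from both
#' are excluded to avoid 0/0).
#'
#' @inheritParams global_accuracy
#' @return Scalar in `[0, 1]`.
#' @export
mean_iou <- function(cm) {
  check_nonempty_cm(cm)
  iou <- class_iou(cm)
  mean(iou[!is.na(iou)])
}

class_iou <- function(cm) {
  tp <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - tp
  ifelse(union > 0, tp / union, NA_real_)
}

#' Weighted intersection over union
#'
#' Per-class IoU weighted by the class's share of reference pixels.
#'
#' @inheritParams global_accuracy
#' @return Scalar in `[0, 1]`.
#' @export
weighted_iou <- function(cm) {
  check_nonempty_cm(cm)
  iou <- class_iou(cm)
  wt <- rowSums(cm) / sum(cm)
  sum(ifelse(wt > 0, wt * iou, 0))
}

## boundary pixels of one class: class pixels 8-adjacent to any
## different-class pixel
class_boundary <- function(labels, cls) {
  M <- unclass(labels) == cls
  h <- nrow(M); w <- ncol(M)
  P <- matrix(TRUE, h + 2L, w + 2L)        # frame counts as same-class:
  P[2:(h + 1), 2:(w + 1)] <- M             # image border alone is no boundary
  nb <- neighbor_views(P, h, w)
  any_diff <- !nb$p2 | !nb$p3 | !nb$p4 | !nb$p5 | !nb$p6 | !nb$p7 | !nb$p8 | !nb$p9
  M & any_diff
}

## for every pixel, Euclidean distance to the nearest TRUE pixel of b
dist_to_set <- function(b) {
  if (!any(b)) return(matrix(Inf, nrow(b), ncol(b)))
  d <- EBImage::distmap(!b)
  matrix(as.numeric(d), nrow(b), ncol(b))
}

#' Mean boundary F-score
#'
#' For each class, boundary precision is the fraction of predicted
#' boundary pixels within `tolerance` (Euclidean) of a reference boundary
#' pixel, recall the symmetric quantity, and `BF_c = 2PR / (P + R)` (zero
#' when both are zero). The mean is over classes with any boundary in
#' either raster. A class's boundary pixels are its pixels 8-adjacent to
#' a different class.
#'
#' @param reference,predicted [label_raster()]s of equal dimensions.
#' @param tolerance matching distance in pixels; default 0.75% of the
#'   image diagonal (the de-facto convention for this measure).
#' @return Scalar in `[0, 1]`; 1 for identical rasters.
#' @export
mean_bf_score <- function(reference, predicted, tolerance = NULL) {
  check_same_dim(reference, predicted)
  if (is.null(tolerance))
    tolerance <- 0.0075 * sqrt(nrow(reference)^2 + ncol(reference)^2)
  if (tolerance <= 0) av_error("ToleranceError", "tolerance must be positive")
  scores <- c()
  for (cls in c(AV_ARTERY, AV_VEIN, AV_BACKGROUND)) {
    rb <- class_boundary(reference, cls)
    pb <- class_boundary(predicted, cls)
    if (!any(rb) && !any(pb)) next
    prec <- if (any(pb)) mean(dist_to_set(rb)[pb] <= tolerance) else 0
    rec <- if (any(rb)) mean(dist_to_set(pb)[rb] <= tolerance) else 0
    bf <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    scores <- c(scores, bf)
  }
  if (length(scores) == 0L)                # no boundaries anywhere
    return(as.numeric(all(unclass(reference) == unclass(predicted))))
  mean(scores)
}

#' All five performance measures at once
#'
#' @param reference,predicted [label_raster()]s.
#' @param bf_tolerance boundary-matching tolerance, see
#'   [mean_bf_score()].
#' @param classes `"all"` (default) scores artery, vein and background;
#'   `"vessel"` restricts the confusion matrix to pixels that are vessel
#'   in the reference, scoring only the artery/vein discrimination.
#' @return A `metrics_report`: list with `global_accuracy`,
#'   `mean_accuracy`, `mean_iou`, `weighted_iou`, `mean_bf_score`, and a
#'   `per_class` data.frame of recall and IoU.
#' @export
metrics_report <- function(reference, predicted, bf_tolerance = NULL,
                           classes = c("all", "vessel")) {
  classes <- match.arg(classes)
  cm <- confusion(reference, predicted)
  if (classes == "vessel") cm <- cm[1:2, , drop = FALSE]
  ga <- sum(diag(cm)) / sum(cm)
  present <- rowSums(cm) > 0
  ma <- mean((diag(cm) / rowSums(cm))[present])
  if (classes == "vessel") {
    tp <- diag(cm)
    union <- rowSums(cm) + colSums(cm)[1:2] - tp
    iou <- ifelse(union > 0, tp / union, NA_real_)
    mi <- mean(iou, na.rm = TRUE)
    wi <- sum(ifelse(present, rowSums(cm) / sum(cm) * iou, 0))
    recall <- diag(cm) / rowSums(cm)
    cls_names <- c("artery", "vein")
  } else {
    mi <- mean_iou(cm)
    wi <- weighted_iou(cm)
    iou <- class_iou(cm)
    recall <- diag(cm) / rowSums(cm)
    cls_names <- c("artery", "vein", "background")
  }
  structure(list(
    global_accuracy = ga, mean_accuracy = ma, mean_iou = mi,
    weighted_iou = wi,
    mean_bf_score = mean_bf_score(reference, predicted, bf_tolerance),
    per_class = data.frame(class = cls_names, recall = recall, iou = iou,
                           row.names = NULL)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Semantic segmentation metrics\n")
  for (m in c("global_accuracy", "mean_accuracy", "mean_iou",
              "weighted_iou", "mean_bf_score"))
    cat(sprintf("  %-16s %.4f\n", m, x[[m]]))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  out <- report[c("global_accuracy", "mean_accuracy", "mean_iou",
                  "weighted_iou", "mean_bf_score")]
  out$per_class <- report$per_class
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
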