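#' Mean intersection-over-union of two binary masks
#'
#' Per-class IoU averaged over the background and tissue classes.  A class
#' absent from both the prediction and the truth contributes an IoU of 1
#' for that class (vacuous agreement).
#'
#' @param pred,truth Binary (0/1) matrices of equal shape.
#' @return A fraction in `[0, 1]`.
#' @examples
#' p <- matrix(c(1, 1, 0, 0), 1)
#' t <- matrix(c(1, 0, 0, 0), 1)
#' mean_iou(p, t)  # (1/2 + 2/3) / 2 = 7/12
#' @export
mean_iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", truth is ", paste(dim(truth), collapse = "x"))
  }
  ious <- vapply(c(0L, 1L), function(cls) {
    p <- pred == cls
    t <- truth == cls
    u <- sum(p | t)
    if (u == 0) 1 else sum(p & t) / u
  }, numeric(1))
  mean(ious)
}

#' Pixel accuracy of a binary prediction
#'
#' Fraction of pixels classified correctly.
#'
#' @inheritParams mean_iou
#' @return A fraction in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", truth is ", paste(dim(truth), collapse = "x"))
  }
  mean(pred == truth)
}

#' Evaluate a trained model on the held-out datasets
#'
#' Computes per-scan mean IoU and pixel accuracy on the healthy test set and
#' the distribution-shifted ("unhealthy") test set, averages per dataset,
#' and reports an overall column as the unweighted mean of the two dataset
#' scores.  Probability maps are binarised at 0.5.
#'
#' @param object A fitted [pseudoseg()] model, or anything accepted by
#'   `predict_fun`.
#' @param split A dataset split with `test` and/or `shifted_test` lists of
#'   `(scan, mask)` pairs (see [phantom_dataset()]).
#' @param predict_fun Optional function `(object, scan) -> probability
#'   matrix`; defaults to the native network forward pass.  Supplying a
#'   different backend (e.g. [onnx_predict()]) evaluates the exported model
#'   under the identical protocol.
#' @return A list of class `pseudoseg_metrics` with per-dataset and overall
#'   mean IoU / pixel accuracy, plus per-scan values.
#' @export
evaluate_model <- function(object, split, predict_fun = NULL) {
  if (is.null(predict_fun)) {
    predict_fun <- function(object, scan) predict(object, scan, type = "prob")
  }
  eval_set <- function(pairs) {
    if (length(pairs) == 0) return(NULL)
    iou <- numeric(length(pairs))
    pa <- numeric(length(pairs))
    for (i in seq_along(pairs)) {
      prob <- predict_fun(object, pairs[[i]]$scan)
      pred <- matrix(as.integer(prob >= 0.5), nrow(prob), ncol(prob))
      iou[i] <- mean_iou(pred, pairs[[i]]$mask)
      pa[i] <- pixel_accuracy(pred, pairs[[i]]$mask)
    }
    list(mean_iou = mean(iou), pixel_accuracy = mean(pa),
         per_scan_iou = iou, per_scan_pa = pa, n = length(pairs))
  }
  healthy <- eval_set(split$test)
  shifted <- eval_set(split$shifted_test)
  if (is.null(healthy) && is.null(shifted)) {
    stop("no test data: both `test` and `shifted_test` are empty")
  }
  both <- !is.null(healthy) && !is.null(shifted)
  overall <- list(
    mean_iou = mean(c(healthy$mean_iou, shifted$mean_iou)),
    pixel_accuracy = mean(c(healthy$pixel_accuracy, shifted$pixel_accuracy))
  )
  structure(
    list(healthy = healthy, shifted = shifted, overall = overall,
         aggregation = "per-scan mean, classes averaged per scan",
         datasets_present = c(healthy = !is.null(healthy),
                              shifted = !is.null(shifted)),
         both = both),
    class = "pseudoseg_metrics"
  )
}

#' @export
print.pseudoseg_metrics <- function(x, ...) {
  cat("Segmentation metrics (prediction binarised at 0.5)\n")
  fmt <- function(s) {
    if (is.null(s)) "     -      -" else
      sprintf("%6.2f %6.2f", 100 * s$mean_iou, 100 * s$pixel_accuracy)
  }
  cat("                 IoU(%)  PA(%)\n")
  cat("  healthy test ", fmt(x$healthy), "\n")
  cat("  shifted test ", fmt(x$shifted), "\n")
  cat("  overall      ", fmt(x$overall), "\n")
  if (!x$both) {
    cat("  (one dataset absent; overall equals the present dataset)\n")
  }
  invisible(x)
}

#' Serialise a metrics report
#'
#' Writes the dataset-level metrics as CSV or JSON, mirroring the usual
#' method-comparison table layout (dataset, mean IoU, pixel accuracy).
#'
#' @param report An [evaluate_model()] result.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "pseudoseg_metrics"))
  rows <- do.call(rbind, lapply(c("healthy", "shifted", "overall"), function(d) {
    s <- report[[d]]
    if (is.null(s)) return(NULL)
    data.frame(dataset = d, mean_iou = s$mean_iou,
               pixel_accuracy = s$pixel_accuracy,
               n_scans = if (d == "overall") NA_integer_ else s$n)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
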