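# S3 methods for the fitted model object.

#' @export
print.pseudoseg <- function(x, ...) {
  cat("Semi-supervised boundary segmentation fit\n")
  cat(sprintf("  method: %s  (%d labelled, %d unlabelled scans)\n",
              x$method, x$n_labelled, x$n_unlabelled))
  cat(sprintf("  U-Net depth %d, base channels %d; %d parameters\n",
              x$model$depth, x$model$base_channels,
              sum(vapply(x$params, length, numeric(1)))))
  cat(sprintf("  best validation IoU %.4f at epoch %d of %d (%s)\n",
              x$val_iou, x$best_epoch, nrow(x$record),
              if (x$stopped_early) "stopped early" else "ran to epoch cap"))
  invisible(x)
}

#' @export
summary.pseudoseg <- function(object, ...) {
  structure(list(fit = object), class = "summary.pseudoseg")
}

#' @export
print.summary.pseudoseg <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPre-training:", nrow(f$pretrain_record), "epoch(s), final val IoU",
      sprintf("%.4f\n", utils::tail(f$pretrain_record$val_iou, 1)))
  cat("\nJoint-training record (last 5 epochs):\n")
  print(utils::tail(f$record[, c("epoch", "val_iou", "loss_sl", "loss_pl",
                                 "alpha_mean", "n_ignored_mean")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Predict tissue probabilities or a binary mask for a scan
#'
#' @param object A fitted [pseudoseg()] model.
#' @param scan Numeric matrix in `[0, 1]` with both dimensions divisible by
#'   `2^depth`, or a list of such matrices.
#' @param type `"prob"` for the per-pixel tissue probability map,
#'   `"mask"` for the 0/1 segmentation binarised at `threshold`.
#' @param threshold Binarisation threshold for `type = "mask"`.
#' @param ... Unused.
#' @return A matrix (or list of matrices) matching the input shape.
#' @export
predict.pseudoseg <- function(object, scan, type = c("prob", "mask"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(s) {
    prob <- unet_predict(object$params, s, object$model)
    if (type == "prob") prob
    else matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  }
  if (is.list(scan)) lapply(scan, one) else one(scan)
}

#' Network weights as a named numeric vector
#'
#' @param object A fitted [pseudoseg()] model.
#' @param ... Unused.
#' @return Named numeric vector; names identify layer and element index.
#' @export
coef.pseudoseg <- function(object, ...) {
  unlist(lapply(object$params, as.numeric))
}

#' Plot the training history
#'
#' Validation IoU per epoch across pre-training and joint training, with
#' the best (restored) epoch marked; for pseudo-label methods a second
#' panel traces the mean ignored-pixel fraction, which typically shrinks
#' as the pseudo-labels firm up.
#'
#' @param x A fitted [pseudoseg()] model.
#' @param ... Passed to [plot.default()].
#' @export
plot.pseudoseg <- function(x, ...) {
  has_pl <- !all(is.na(x$record$n_ignored_mean))
  op <- graphics::par(mfrow = c(if (has_pl) 2 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$record$epoch, x$record$val_iou, type = "b", pch = 16,
       xlab = "joint-training epoch", ylab = "validation mean IoU",
       main = paste("method:", x$method), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  if (has_pl) {
    plot(x$record$epoch, x$record$n_ignored_mean, type = "b", pch = 16,
         xlab = "joint-training epoch", ylab = "mean ignored pixels/scan")
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Stores weights, optimiser state, architecture and training metadata in a
#' single file.
#'
#' @param object A [pseudoseg()] or [pseudoseg_pretrain()] result.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("pseudoseg", "pseudoseg_pretrain")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("pseudoseg", "pseudoseg_pretrain"))) {
    stop("file does not contain a model checkpoint")
  }
  obj
}
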