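#' Confidence-thresholded trinary pseudo-labels
#'
#' Converts a predicted per-pixel tissue probability map into a trinary
#' pseudo-label: pixels with probability above `threshold` become tissue (1),
#' pixels below `1 - threshold` become background (0), and everything in
#' between — the low-confidence band, including values exactly on either
#' cut-off — is marked ignored and excluded from the pseudo-label loss.
#'
#' @param probs Numeric matrix of predicted tissue probabilities in `[0, 1]`.
#' @param threshold Confidence cut-off in `(0.5, 1)`; the default 0.9
#'   trusts a pixel only when the model is at least 90% confident in
#'   either class.
#' @return An object of class `pseudo_label`: a list with `labels` (integer
#'   matrix over `{0, 1, NA}`, `NA` marking ignored pixels), `n_ignored`,
#'   and `n_total`.
#' @examples
#' p <- matrix(c(0.95, 0.05, 0.50), 1, 3)
#' pl <- make_pseudo_label(p, 0.9)
#' pl$labels      # 1, 0, NA
#' pl$n_ignored   # 1
#' @seealso [compute_alpha()], [masked_bce()]
#' @export
make_pseudo_label <- function(probs, threshold = 0.9) {
  stopifnot(is.numeric(probs), is.matrix(probs))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0.5 || threshold >= 1) {
    stop("`threshold` must be a single value in (0.5, 1), got ", threshold)
  }
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("`probs` must be finite and within [0, 1]")
  }
  labels <- matrix(NA_integer_, nrow(probs), ncol(probs))
  labels[probs > threshold] <- 1L
  labels[probs < 1 - threshold] <- 0L
  structure(
    list(labels = labels,
         n_ignored = sum(is.na(labels)),
         n_total = length(labels)),
    class = "pseudo_label"
  )
}

#' Adaptive pseudo-label loss weight
#'
#' The weight multiplying the pseudo-label loss is set to half the total
#' number of pixels in the scan divided by the number of ignored pixels,
#' so that a cleaner pseudo-label (fewer ignored pixels) contributes more
#' to the combined loss.  When no pixel is ignored the formula diverges;
#' the weight is then capped at `alpha_cap`.
#'
#' @param pseudo A [make_pseudo_label()] result.
#' @param alpha_cap Upper bound on the weight (default 10).
#' @return A single nonnegative number.
#' @examples
#' pl <- list(labels = NULL, n_ignored = 500, n_total = 1000)
#' class(pl) <- "pseudo_label"
#' compute_alpha(pl)  # 0.5 * 1000 / 500 = 1
#' @export
compute_alpha <- function(pseudo, alpha_cap = 10) {
  stopifnot(inherits(pseudo, "pseudo_label"), alpha_cap >= 0)
  if (pseudo$n_ignored == 0) return(alpha_cap)
  min(0.5 * pseudo$n_total / pseudo$n_ignored, alpha_cap)
}

# probability clamp used inside logs
.bce_eps <- 1e-7

#' Binary cross-entropy over a full mask
#'
#' Mean over all pixels of
#' \eqn{-[y \log p + (1 - y) \log(1 - p)]}, with probabilities clamped to
#' `[1e-7, 1 - 1e-7]` for finiteness.
#'
#' @param probs Numeric matrix of predicted probabilities.
#' @param target Binary matrix (0/1) of the same shape.
#' @return Nonnegative scalar loss.
#' @examples
#' bce(matrix(0.8), matrix(1))      # -log(0.8) ~ 0.22314
#' bce(matrix(0.5, 2, 2), matrix(c(0, 1, 0, 1), 2, 2))  # log(2)
#' @export
bce <- function(probs, target) {
  if (!all(dim(probs) == dim(target))) {
    stop("shape mismatch: probs is ", paste(dim(probs), collapse = "x"),
         ", target is ", paste(dim(target), collapse = "x"))
  }
  p <- pmin(pmax(probs, .bce_eps), 1 - .bce_eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Masked binary cross-entropy over a trinary pseudo-label
#'
#' Binary cross-entropy averaged over the non-ignored pixels only; ignored
#' pixels contribute nothing (their gradient is exactly zero).  Returns 0
#' when every pixel is ignored.
#'
#' @param probs Numeric matrix of predicted probabilities.
#' @param pseudo A [make_pseudo_label()] result of the same shape.
#' @return Nonnegative scalar loss.
#' @export
masked_bce <- function(probs, pseudo) {
  stopifnot(inherits(pseudo, "pseudo_label"))
  y <- pseudo$labels
  if (!all(dim(probs) == dim(y))) {
    stop("shape mismatch: probs is ", paste(dim(probs), collapse = "x"),
         ", pseudo-label is ", paste(dim(y), collapse = "x"))
  }
  keep <- !is.na(y)
  if (!any(keep)) return(0)
  p <- pmin(pmax(probs[keep], .bce_eps), 1 - .bce_eps)
  yk <- y[keep]
  mean(-(yk * log(p) + (1 - yk) * log(1 - p)))
}

#' Combine supervised and pseudo-label losses
#'
#' Total loss for one optimisation step:
#' \eqn{L = L_{SL} + \alpha L_{PL}}.
#'
#' @param loss_sl Supervised loss on labelled data.
#' @param loss_pl Pseudo-label loss on unlabelled data.
#' @param alpha Adaptive pseudo-label weight, see [compute_alpha()].
#' @return A list of class `loss_bundle` with components `loss_sl`,
#'   `loss_pl`, `alpha` and `total`.
#' @export
combine_losses <- function(loss_sl, loss_pl, alpha) {
  stopifnot(loss_sl >= 0, loss_pl >= 0, alpha >= 0)
  structure(
    list(loss_sl = loss_sl, loss_pl = loss_pl, alpha = alpha,
         total = loss_sl + alpha * loss_pl),
    class = "loss_bundle"
  )
}

#' @export
print.pseudo_label <- function(x, ...) {
  cat("Trinary pseudo-label:", nrow(x$labels), "x", ncol(x$labels),
      sprintf("(%d / %d pixels ignored, %.1f%%)\n",
              x$n_ignored, x$n_total, 100 * x$n_ignored / x$n_total))
  invisible(x)
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("L = L_SL + alpha * L_PL = %.5f + %.3f * %.5f = %.5f\n",
              x$loss_sl, x$alpha, x$loss_pl, x$total))
  invisible(x)
}
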