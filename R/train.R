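# Training pipeline: supervised pre-training until a validation-IoU gate,
# then joint training on labelled + pseudo-labelled scans with the
# pseudo-labels regenerated from the current weights at the start of every
# epoch, early stopping on validation IoU, and best-weights restore.
# Comparison variants: fully supervised continuation (fsl), hard
# pseudo-labels with an epoch-ramped weight (pseudo_lee), and hard
# pseudo-labels with a fixed weight of 1 (pseudo_notrust).

#' Training configuration
#'
#' Defaults follow the full-scale training protocol: Adam with learning
#' rate 1e-5, batch size 1, at most 40 joint-training epochs with early
#' stopping at patience 10, pre-training until validation mean IoU exceeds
#' 0.70, confidence threshold 0.90, and rotation/brightness augmentation of
#' the labelled scans.  Desk-scale experiments on small phantoms typically
#' raise the learning rate (see the package vignette).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Number of labelled/pseudo-labelled pairs accumulated
#'   per optimiser step (protocol default 1).
#' @param max_epochs_pl Maximum joint-training epochs.
#' @param patience Early-stopping patience: training stops once validation
#'   IoU has failed to exceed the running maximum for this many consecutive
#'   epochs.
#' @param pretrain_iou_gate Validation mean-IoU gate ending pre-training.
#' @param pretrain_max_epochs Hard cap on pre-training epochs; reaching it
#'   without passing the gate is reported as an explicit failure.
#' @param confidence_threshold Pseudo-label confidence cut-off in (0.5, 1).
#' @param alpha_cap Cap on the adaptive pseudo-label weight.
#' @param lee_ramp_epochs Ramp length (epochs) of the linear 0 to 1
#'   pseudo-label weight schedule used by the `pseudo_lee` variant.
#' @param augment Apply rotation/brightness augmentation to labelled scans.
#' @param augment_pseudo Also augment pseudo-labelled scans (off by
#'   default: pseudo-labels are generated on, and compared against, the
#'   un-augmented scan).
#' @param angle_range,brightness_range Augmentation ranges, see
#'   [augment_pair()].
#' @param val_threshold Binarisation threshold for validation/test IoU.
#' @param on_epoch,on_epoch_end Optional callbacks for instrumenting the
#'   joint loop; `on_epoch(info)` fires after the pseudo-label refresh with
#'   `info$epoch`, `info$params_start` and `info$pseudo`; `on_epoch_end`
#'   fires after the epoch with `info$params` and `info$val_iou`.
#' @return A list of class `pseudoseg_control`.
#' @export
pseudoseg_control <- function(learning_rate = 1e-5, batch_size = 1,
                              max_epochs_pl = 40, patience = 10,
                              pretrain_iou_gate = 0.70,
                              pretrain_max_epochs = 200,
                              confidence_threshold = 0.90, alpha_cap = 10,
                              lee_ramp_epochs = 10,
                              augment = TRUE, augment_pseudo = FALSE,
                              angle_range = c(10, 20),
                              brightness_range = c(1, 2),
                              val_threshold = 0.5,
                              on_epoch = NULL, on_epoch_end = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1,
            max_epochs_pl >= 1, patience >= 1, patience <= max_epochs_pl,
            pretrain_iou_gate >= 0, pretrain_iou_gate <= 1,
            pretrain_max_epochs >= 1,
            confidence_threshold > 0.5, confidence_threshold < 1,
            alpha_cap >= 0, lee_ramp_epochs >= 1,
            val_threshold > 0, val_threshold < 1)
  structure(as.list(environment()), class = "pseudoseg_control")
}

# mean validation IoU at the binarisation threshold
val_mean_iou <- function(params, cfg, val_pairs, threshold = 0.5) {
  mean(vapply(val_pairs, function(p) {
    prob <- unet_predict(params, p$scan, cfg)
    mean_iou(matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob)),
             p$mask)
  }, numeric(1)))
}

# gradient of the mean BCE w.r.t. the logits, plus the loss value
supervised_grad <- function(params, cfg, scan, mask) {
  fw <- unet_forward(params, scan, cfg, keep_cache = TRUE)
  gz <- (fw$prob - mask) / length(mask)
  list(grads = unet_backward(params, cfg, fw$cache, gz),
       loss = bce(fw$prob, mask))
}

# gradient of alpha * masked BCE w.r.t. the logits; ignored pixels get an
# exactly-zero gradient.  Returns NULL grads when the contribution vanishes
# (all ignored, or alpha == 0) so the optimiser step is bit-identical to a
# purely supervised one.
pseudo_grad <- function(params, cfg, scan, pl, alpha) {
  fw <- unet_forward(params, scan, cfg,
                     keep_cache = alpha > 0 && pl$n_ignored < pl$n_total)
  loss_pl <- masked_bce(fw$prob, pl)
  if (alpha == 0 || pl$n_ignored == pl$n_total) {
    return(list(grads = NULL, loss = loss_pl))
  }
  keep <- !is.na(pl$labels)
  y0 <- pl$labels
  y0[!keep] <- 0L
  gz <- alpha * (fw$prob - y0) * keep / sum(keep)
  list(grads = unet_backward(params, cfg, fw$cache, gz), loss = loss_pl)
}

# ---- early stopping state machine ---------------------------------------

es_init <- function(patience) {
  list(patience = patience, best = -Inf, best_epoch = 0L, wait = 0L,
       stop = FALSE)
}

es_update <- function(state, metric, epoch) {
  if (metric > state$best) {
    state$best <- metric
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
  }
  state$stop <- state$wait >= state$patience
  state
}

# replay an injected validation-metric sequence through the state machine;
# used to pin down the stopping semantics independently of any training
es_trace <- function(metrics, patience) {
  st <- es_init(patience)
  stopped_at <- length(metrics)
  for (e in seq_along(metrics)) {
    st <- es_update(st, metrics[e], e)
    if (st$stop) { stopped_at <- e; break }
  }
  list(stop_epoch = stopped_at, best_epoch = st$best_epoch,
       stopped_early = st$stop)
}

#' Supervised pre-training to the validation-IoU gate
#'
#' Trains the network on the labelled scans only, with binary cross-entropy,
#' stopping at the end of the first epoch whose validation mean IoU exceeds
#' `control$pretrain_iou_gate`.  If the gate is not reached within
#' `control$pretrain_max_epochs` the returned record flags the failure
#' explicitly (`gate_reached = FALSE`).
#'
#' @param split An `oct_split` with `train_labelled` and `val` components
#'   (see [label_split()]); a raw `train` pool is used as fully labelled.
#' @param model A [unet_config()].
#' @param control A [pseudoseg_control()].
#' @param seed Integer seed covering weight init, data order and
#'   augmentation.
#' @return An object of class `pseudoseg_pretrain`: weights, optimiser
#'   state, per-epoch record and `gate_reached` flag.
#' @export
pseudoseg_pretrain <- function(split, model = unet_config(),
                               control = pseudoseg_control(), seed = 1) {
  labelled <- split$train_labelled %||% split$train
  stopifnot(length(labelled) >= 1, length(split$val) >= 1)
  with_seed(seed, {
    params <- unet_init(model)
    opt <- adam_init(params)
    rows <- list()
    gate_reached <- FALSE
    for (epoch in seq_len(control$pretrain_max_epochs)) {
      step <- run_supervised_epoch(params, opt, labelled, control, model)
      params <- step$params; opt <- step$opt
      viou <- val_mean_iou(params, model, split$val, control$val_threshold)
      rows[[epoch]] <- data.frame(epoch = epoch, val_iou = viou,
                                  loss_sl = step$mean_loss)
      if (viou > control$pretrain_iou_gate) { gate_reached <- TRUE; break }
    }
    structure(list(params = params, opt = opt,
                   record = do.call(rbind, rows),
                   gate_reached = gate_reached,
                   model = model, control = control, seed = seed),
              class = "pseudoseg_pretrain")
  })
}

#' @export
print.pseudoseg_pretrain <- function(x, ...) {
  n <- nrow(x$record)
  cat(sprintf("Pre-trained U-Net: %d epoch(s), final val IoU %.3f (gate %s)\n",
              n, x$record$val_iou[n],
              if (x$gate_reached) "reached" else "NOT reached"))
  invisible(x)
}

# one supervised epoch over the labelled pairs (shared by pre-training and
# the fsl continuation); consumes RNG for shuffling and augmentation only
run_supervised_epoch <- function(params, opt, labelled, control, model) {
  ord <- sample(length(labelled))
  acc <- NULL; nacc <- 0L
  losses <- numeric(length(labelled))
  for (k in seq_along(labelled)) {
    pair <- labelled[[ord[k]]]
    if (control$augment) {
      pair <- augment_pair(pair$scan, pair$mask,
                           angle_range = control$angle_range,
                           brightness_range = control$brightness_range)
    }
    sg <- supervised_grad(params, model, pair$scan, pair$mask)
    losses[k] <- sg$loss
    acc <- add_grads(acc, sg$grads); nacc <- nacc + 1L
    if (nacc == control$batch_size || k == length(labelled)) {
      st <- adam_step(params, scale_grads(acc, 1 / nacc), opt,
                      control$learning_rate)
      params <- st$params; opt <- st$opt
      acc <- NULL; nacc <- 0L
    }
  }
  list(params = params, opt = opt, mean_loss = mean(losses))
}

# pseudo-label refresh for one epoch: predictions with the current weights,
# then the method's labelling rule and weight
refresh_pseudo <- function(params, model, unlabelled, method, control, epoch) {
  pls <- lapply(unlabelled, function(u) {
    prob <- unet_predict(params, u$scan, model)
    if (method == "pseudosegrt") {
      make_pseudo_label(prob, control$confidence_threshold)
    } else {
      make_hard_label(prob)
    }
  })
  alphas <- switch(method,
    pseudosegrt = vapply(pls, compute_alpha, numeric(1),
                         alpha_cap = control$alpha_cap),
    pseudo_notrust = rep(1, length(pls)),
    pseudo_lee = rep(min(1, (epoch - 1) / control$lee_ramp_epochs),
                     length(pls)))
  list(pls = pls, alphas = alphas)
}

#' Hard (thresholdless) pseudo-labels
#'
#' The `pseudo_notrust` and `pseudo_lee` labelling rule: every pixel takes
#' the argmax class (probability >= 0.5 maps to tissue), no pixel is
#' ignored.
#'
#' @param probs Numeric probability matrix.
#' @return A `pseudo_label` with `n_ignored = 0`.
#' @export
make_hard_label <- function(probs) {
  labels <- matrix(as.integer(probs >= 0.5), nrow(probs), ncol(probs))
  structure(list(labels = labels, n_ignored = 0L, n_total = length(labels)),
            class = "pseudo_label")
}

#' Fit a boundary-segmentation network with pseudo-labelling
#'
#' The main fitting function.  Starting from a supervised pre-trained
#' network (run internally unless `pretrained` is supplied), continues
#' training according to `method`:
#' \describe{
#'   \item{`pseudosegrt`}{joint training on labelled and pseudo-labelled
#'     scans; trinary confidence-thresholded pseudo-labels regenerated from
#'     the current weights every epoch; combined loss
#'     \eqn{L = L_{SL} + \alpha L_{PL}} with the adaptive weight of
#'     [compute_alpha()].}
#'   \item{`fsl`}{fully supervised continuation on the labelled scans only.}
#'   \item{`pseudo_lee`}{hard pseudo-labels with a linear 0 to 1 epoch ramp
#'     on the pseudo-label weight.}
#'   \item{`pseudo_notrust`}{hard pseudo-labels, weight fixed at 1.}
#' }
#' Labelled and pseudo-labelled scans alternate 1:1 within an epoch and the
#' two loss terms are optimised in a single combined step per pair.  Early
#' stopping monitors validation mean IoU; the weights attaining the maximum
#' are restored.
#'
#' @param split An `oct_split` carrying `train_labelled`,
#'   `train_unlabelled`, `val` and test sets (see [label_split()]).
#' @param method One of `"pseudosegrt"`, `"fsl"`, `"pseudo_lee"`,
#'   `"pseudo_notrust"`.
#' @param model A [unet_config()].
#' @param control A [pseudoseg_control()].
#' @param seed Integer seed; pre-training uses `seed`, the continuation
#'   phase `seed + 50000`, so method variants sharing one `pretrained`
#'   state see identical data order and augmentation draws.
#' @param pretrained Optional [pseudoseg_pretrain()] result to continue
#'   from (shared across methods for paired comparisons).
#' @return An object of class `pseudoseg` with `params` (weights), the
#'   per-epoch `record`, `best_epoch`, `val_iou`, and the configuration.
#' @examples
#' \donttest{
#' split <- label_split(phantom_dataset(n_train = 8, n_val = 2, n_test = 2,
#'                                      n_shifted_test = 2, seed = 1),
#'                      n_labelled = 4, n_unlabelled = 4, seed = 1)
#' ctrl <- pseudoseg_control(learning_rate = 1e-3, max_epochs_pl = 3,
#'                           patience = 3, pretrain_max_epochs = 10)
#' fit <- pseudoseg(split, "pseudosegrt", unet_config(depth = 2, base_channels = 4),
#'                  ctrl, seed = 1)
#' evaluate_model(fit, split)
#' }
#' @export
pseudoseg <- function(split,
                      method = c("pseudosegrt", "fsl", "pseudo_lee",
                                 "pseudo_notrust"),
                      model = unet_config(), control = pseudoseg_control(),
                      seed = 1, pretrained = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "unet_config"),
            inherits(control, "pseudoseg_control"))
  if (is.null(pretrained)) {
    pretrained <- pseudoseg_pretrain(split, model, control, seed)
  }
  if (!pretrained$gate_reached) {
    stop("pre-training failed to reach the validation IoU gate (",
         control$pretrain_iou_gate, ") within ",
         control$pretrain_max_epochs, " epochs; final val IoU ",
         signif(utils::tail(pretrained$record$val_iou, 1), 3))
  }
  labelled <- split$train_labelled %||% split$train
  unlabelled <- split$train_unlabelled
  status <- "ok"
  if (method != "fsl" && length(unlabelled) == 0) {
    warning("no unlabelled scans available; falling back to supervised ",
            "continuation")
    method_run <- "fsl"
    status <- "no_unlabelled_fallback"
  } else {
    method_run <- method
  }

  res <- with_seed(seed + 50000L, {
    params <- pretrained$params
    opt <- pretrained$opt
    es <- es_init(control$patience)
    best_params <- params
    rows <- list()
    pseudo_stats <- function(pls, alphas) {
      ni <- vapply(pls, function(p) p$n_ignored, numeric(1))
      data.frame(alpha_mean = mean(alphas), alpha_min = min(alphas),
                 alpha_max = max(alphas), n_ignored_mean = mean(ni),
                 n_ignored_min = min(ni), n_ignored_max = max(ni))
    }
    n_lab <- length(labelled)
    for (epoch in seq_len(control$max_epochs_pl)) {
      if (method_run != "fsl") {
        rp <- refresh_pseudo(params, model, unlabelled, method_run, control,
                             epoch)
        if (!is.null(control$on_epoch)) {
          control$on_epoch(list(epoch = epoch, params_start = params,
                                pseudo = rp$pls, alphas = rp$alphas))
        }
        n_unl <- length(unlabelled)
        acc <- NULL; nacc <- 0L
        ord <- sample(n_lab)
        loss_sl <- numeric(n_lab); loss_pl <- numeric(n_lab)
        for (k in seq_len(n_lab)) {
          pair <- labelled[[ord[k]]]
          if (control$augment) {
            pair <- augment_pair(pair$scan, pair$mask,
                                 angle_range = control$angle_range,
                                 brightness_range = control$brightness_range)
          }
          sg <- supervised_grad(params, model, pair$scan, pair$mask)
          loss_sl[k] <- sg$loss
          ui <- ((k - 1L) %% n_unl) + 1L
          uscan <- unlabelled[[ui]]$scan
          upl <- rp$pls[[ui]]
          if (control$augment_pseudo) {
            ap <- augment_trinary(uscan, upl, control)
            uscan <- ap$scan; upl <- ap$pseudo
          }
          pg <- pseudo_grad(params, model, uscan, upl, rp$alphas[ui])
          loss_pl[k] <- pg$loss
          g <- add_grads(sg$grads, pg$grads)
          acc <- add_grads(acc, g); nacc <- nacc + 1L
          if (nacc == control$batch_size || k == n_lab) {
            st <- adam_step(params, scale_grads(acc, 1 / nacc), opt,
                            control$learning_rate)
            params <- st$params; opt <- st$opt
            acc <- NULL; nacc <- 0L
          }
        }
        row <- cbind(data.frame(epoch = epoch, val_iou = NA_real_,
                                loss_sl = mean(loss_sl),
                                loss_pl = mean(loss_pl)),
                     pseudo_stats(rp$pls, rp$alphas))
      } else {
        step <- run_supervised_epoch(params, opt, labelled, control, model)
        params <- step$params; opt <- step$opt
        row <- data.frame(epoch = epoch, val_iou = NA_real_,
                          loss_sl = step$mean_loss, loss_pl = NA_real_,
                          alpha_mean = NA_real_, alpha_min = NA_real_,
                          alpha_max = NA_real_, n_ignored_mean = NA_real_,
                          n_ignored_min = NA_real_, n_ignored_max = NA_real_)
      }
      viou <- val_mean_iou(params, model, split$val, control$val_threshold)
      row$val_iou <- viou
      rows[[epoch]] <- row
      if (!is.null(control$on_epoch_end)) {
        control$on_epoch_end(list(epoch = epoch, params = params,
                                  val_iou = viou))
      }
      es <- es_update(es, viou, epoch)
      if (es$best_epoch == epoch) best_params <- params
      if (es$stop) break
    }
    list(params = best_params, final_params = params, opt = opt,
         record = do.call(rbind, rows), best_epoch = es$best_epoch,
         val_iou = es$best, stopped_early = es$stop)
  })

  structure(
    list(params = res$params, opt = res$opt, model = model,
         control = control, method = method, method_run = method_run,
         status = status, seed = seed,
         pretrain_record = pretrained$record, record = res$record,
         best_epoch = res$best_epoch, val_iou = res$val_iou,
         stopped_early = res$stopped_early,
         n_labelled = length(labelled), n_unlabelled = length(unlabelled)),
    class = "pseudoseg"
  )
}

# rotate/brighten a pseudo-labelled scan consistently with its trinary
# label (ignored pixels stay ignored; pixels rotated in from outside the
# canvas are ignored too)
augment_trinary <- function(scan, pl, control) {
  angle <- sample(c(-1, 1), 1) *
    stats::runif(1, control$angle_range[1], control$angle_range[2])
  bright <- stats::runif(1, control$brightness_range[1],
                         control$brightness_range[2])
  lab <- pl$labels
  lab[is.na(lab)] <- -1L
  if (angle != 0) {
    si <- as_ebimage(scan)
    scan <- from_ebimage(EBImage::rotate(si, angle, filter = "bilinear",
                                         output.dim = dim(si), bg.col = 0))
    li <- as_ebimage(lab)
    lab <- from_ebimage(EBImage::rotate(li, angle, filter = "none",
                                        output.dim = dim(li), bg.col = -1))
  }
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  lab[lab < 0L] <- NA_integer_
  scan <- pmin(pmax(scan * bright, 0), 1)
  list(scan = scan,
       pseudo = structure(list(labels = lab, n_ignored = sum(is.na(lab)),
                               n_total = length(lab)),
                          class = "pseudo_label"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
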