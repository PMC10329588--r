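#' Scaled-down distribution-shift generalisation experiment
#'
#' Runs the central method comparison on synthetic phantoms at desk scale:
#' for each seed, a healthy train pool is generated and carved into
#' labelled and unlabelled subsets, the network is pre-trained once to the
#' validation-IoU gate, and each requested method continues from that same
#' pre-trained state (a paired design).  Every fit is evaluated on a
#' healthy test set and on a distribution-shifted ("unhealthy") test set
#' never seen in training.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_labelled,n_unlabelled Labelled / unlabelled training scans
#'   (protocol default 25 each).
#' @param n_val Validation scans.
#' @param n_test,n_shifted_test Healthy / shifted test scans.
#' @param methods Methods to compare (see [pseudoseg()]).
#' @param model A [unet_config()].
#' @param control A [pseudoseg_control()]; the default raises the learning
#'   rate to 1e-3 and shortens the epoch budget, matching the phantom desk
#'   scale (see the package vignette).
#' @param params_healthy,params_shifted Phantom parameter sets.
#' @return A data.frame of class `pseudoseg_experiment` with one row per
#'   (seed, method): IoU and pixel accuracy on the healthy and shifted
#'   test sets plus the overall (unweighted dataset mean) columns.
#' @export
generalisation_experiment <- function(seeds = 1:5,
                                      n_labelled = 25, n_unlabelled = 25,
                                      n_val = 8, n_test = 50,
                                      n_shifted_test = 50,
                                      methods = c("pseudosegrt", "fsl",
                                                  "pseudo_notrust"),
                                      model = unet_config(depth = 2,
                                                          base_channels = 8),
                                      control = pseudoseg_control(
                                        learning_rate = 1e-3,
                                        max_epochs_pl = 15, patience = 5,
                                        pretrain_max_epochs = 60),
                                      params_healthy = phantom_params(),
                                      params_shifted = phantom_params(
                                        shift_severity = 1)) {
  rows <- list()
  for (sd in seeds) {
    ds <- phantom_dataset(params_healthy, params_shifted,
                          n_train = n_labelled + n_unlabelled,
                          n_val = n_val, n_test = n_test,
                          n_shifted_test = n_shifted_test, seed = sd)
    split <- label_split(ds, n_labelled, n_unlabelled, seed = sd)
    pre <- pseudoseg_pretrain(split, model, control, seed = sd)
    for (m in methods) {
      fit <- pseudoseg(split, m, model, control, seed = sd, pretrained = pre)
      mt <- evaluate_model(fit, split)
      rows[[length(rows) + 1]] <- data.frame(
        seed = sd, method = m,
        pretrain_val_iou = utils::tail(pre$record$val_iou, 1),
        iou_healthy = mt$healthy$mean_iou,
        iou_shifted = mt$shifted$mean_iou,
        iou_overall = mt$overall$mean_iou,
        pa_healthy = mt$healthy$pixel_accuracy,
        pa_shifted = mt$shifted$pixel_accuracy,
        pa_overall = mt$overall$pixel_accuracy,
        best_epoch = fit$best_epoch,
        stopped_early = fit$stopped_early)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pseudoseg_experiment", "data.frame")
  out
}

#' @export
print.pseudoseg_experiment <- function(x, ...) {
  cat("Paired generalisation experiment (", length(unique(x$seed)),
      " seeds)\n", sep = "")
  agg <- stats::aggregate(
    x[, c("iou_healthy", "iou_shifted", "iou_overall",
          "pa_healthy", "pa_shifted", "pa_overall")],
    by = list(method = x$method), FUN = mean)
  num <- vapply(agg, is.numeric, logical(1))
  agg[num] <- lapply(agg[num], function(v) round(100 * v, 2))
  names(agg) <- c("method", "IoU HD", "IoU UD", "IoU overall",
                  "PA HD", "PA UD", "PA overall")
  print(agg, row.names = FALSE)
  invisible(x)
}
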