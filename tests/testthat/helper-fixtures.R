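# Small desk-scale fixtures, generated in code.  Heavier fits are memoised
# so several test files can share one training run.

quick_params <- function(...) phantom_params(height = 32, width = 64, ...)

quick_split <- function(n_lab = 8, n_unl = 4, n_val = 2, n_test = 3,
                        n_shift = 3, seed = 11) {
  ds <- phantom_dataset(quick_params(), quick_params(shift_severity = 1),
                        n_train = n_lab + n_unl, n_val = n_val,
                        n_test = n_test, n_shifted_test = n_shift,
                        seed = seed)
  label_split(ds, n_lab, n_unl, seed = seed)
}

quick_ctrl <- function(...) {
  defaults <- list(learning_rate = 1e-3, max_epochs_pl = 4, patience = 4,
                   pretrain_max_epochs = 60)
  do.call(pseudoseg_control, utils::modifyList(defaults, list(...)))
}

.fixtures <- new.env()

small_pretrain <- function() {
  if (is.null(.fixtures$pre)) {
    .fixtures$split <- quick_split()
    .fixtures$pre <- pseudoseg_pretrain(.fixtures$split, unet_config(2, 4),
                                        quick_ctrl(), seed = 11)
  }
  list(split = .fixtures$split, pre = .fixtures$pre)
}

small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    sp <- small_pretrain()
    .fixtures$fit <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4),
                               quick_ctrl(), seed = 11, pretrained = sp$pre)
  }
  list(split = .fixtures$split, fit = .fixtures$fit)
}

# brute-force set-counting oracles, deliberately loop-based
iou_oracle <- function(pred, truth) {
  total <- 0
  for (cls in c(0L, 1L)) {
    inter <- 0; uni <- 0
    for (i in seq_along(pred)) {
      p <- pred[i] == cls
      t <- truth[i] == cls
      if (p && t) inter <- inter + 1
      if (p || t) uni <- uni + 1
    }
    total <- total + if (uni == 0) 1 else inter / uni
  }
  total / 2
}

pa_oracle <- function(pred, truth) {
  n_eq <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) n_eq <- n_eq + 1
  n_eq / length(pred)
}

pseudo_label_oracle <- function(probs, threshold) {
  out <- matrix(NA_integer_, nrow(probs), ncol(probs))
  n_ign <- 0
  for (i in seq_along(probs)) {
    if (probs[i] > threshold) out[i] <- 1L
    else if (probs[i] < 1 - threshold) out[i] <- 0L
    else n_ign <- n_ign + 1
  }
  list(labels = out, n_ignored = n_ign)
}
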