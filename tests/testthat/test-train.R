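# Training-loop semantics: early stopping, the pre-training gate,
# pseudo-label refresh provenance, supervised-equivalence limits, and the
# comparison-method variants.

ns <- asNamespace("pseudosegrt")

test_that("early stopping fires exactly `patience` epochs after the peak", {
  # injected validation sequence peaking at epoch 5 then plateauing
  metrics <- c(0.1, 0.2, 0.3, 0.4, 0.9, rep(0.85, 20))
  tr <- ns$es_trace(metrics, patience = 10)
  expect_identical(tr$stop_epoch, 15L)
  expect_identical(tr$best_epoch, 5L)
  expect_true(tr$stopped_early)
  # strictly improving sequence never stops
  tr2 <- ns$es_trace(seq(0.1, 0.9, length.out = 12), patience = 10)
  expect_false(tr2$stopped_early)
  expect_identical(tr2$best_epoch, 12L)
  # ties do not count as improvement
  tr3 <- ns$es_trace(c(0.5, rep(0.5, 3)), patience = 3)
  expect_identical(tr3$stop_epoch, 4L)
  expect_identical(tr3$best_epoch, 1L)
})

test_that("a vacuous pre-training gate terminates after one epoch", {
  sp <- quick_split(n_lab = 3, n_unl = 0)
  pre <- pseudoseg_pretrain(sp, unet_config(2, 2),
                            quick_ctrl(pretrain_iou_gate = 0), seed = 1)
  expect_identical(nrow(pre$record), 1L)
  expect_true(pre$gate_reached)
})

test_that("an unreachable gate is reported as an explicit failure", {
  sp <- quick_split(n_lab = 2, n_unl = 0)
  ctrl <- quick_ctrl(pretrain_iou_gate = 0.999999, pretrain_max_epochs = 2)
  pre <- pseudoseg_pretrain(sp, unet_config(2, 2), ctrl, seed = 1)
  expect_false(pre$gate_reached)
  expect_error(pseudoseg(sp, "fsl", unet_config(2, 2), ctrl, seed = 1,
                         pretrained = pre),
               "failed to reach the validation IoU gate")
})

test_that("pre-training reaches the 0.70 gate on phantoms, deterministically", {
  sp <- small_pretrain()
  expect_true(sp$pre$gate_reached)
  expect_gt(utils::tail(sp$pre$record$val_iou, 1), 0.70)
  pre2 <- pseudoseg_pretrain(sp$split, unet_config(2, 4), quick_ctrl(),
                             seed = 11)
  expect_identical(sp$pre$record, pre2$record)
  expect_identical(sp$pre$params, pre2$params)
})

test_that("restored weights reproduce the recorded best validation IoU", {
  sf <- small_fit()
  fit <- sf$fit
  expect_equal(fit$val_iou, max(fit$record$val_iou))
  expect_equal(fit$record$val_iou[fit$best_epoch], fit$val_iou)
  recomputed <- ns$val_mean_iou(fit$params, fit$model, sf$split$val,
                                fit$control$val_threshold)
  expect_identical(recomputed, fit$val_iou)
  expect_lte(nrow(fit$record), fit$control$max_epochs_pl)
})

test_that("pseudo-labels at epoch e+1 derive from the epoch-e weights", {
  sp <- small_pretrain()
  starts <- list(); ends <- list(); pseudos <- list()
  ctrl <- quick_ctrl(max_epochs_pl = 3, patience = 3,
                     on_epoch = function(info) {
                       starts[[info$epoch]] <<- info$params_start
                       pseudos[[info$epoch]] <<- info$pseudo
                     },
                     on_epoch_end = function(info) {
                       ends[[info$epoch]] <<- info$params
                     })
  fit <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4), ctrl,
                   seed = 11, pretrained = sp$pre)
  expect_length(pseudos, 3)
  for (e in 1:2) {
    # the refresh at epoch e+1 uses exactly the weights after epoch e
    expect_identical(starts[[e + 1]], ends[[e]])
    # and the labels equal the thresholding rule applied to those weights
    u1 <- sp$split$train_unlabelled[[1]]$scan
    prob <- ns$unet_predict(ends[[e]], u1, fit$model)
    expect_identical(pseudos[[e + 1]][[1]]$labels,
                     make_pseudo_label(prob, ctrl$confidence_threshold)$labels)
  }
  # weights change across epochs, so the refresh is not vacuous
  expect_false(identical(starts[[1]], starts[[2]]))
})

test_that("joint training with no pseudo contribution equals supervised", {
  sp <- small_pretrain()
  ctrl <- quick_ctrl(max_epochs_pl = 3, patience = 3)
  fsl <- pseudoseg(sp$split, "fsl", unet_config(2, 4), ctrl, seed = 11,
                   pretrained = sp$pre)
  # alpha forced to 0 through the cap: step-for-step identical trajectory
  ctrl0 <- quick_ctrl(max_epochs_pl = 3, patience = 3, alpha_cap = 0)
  a0 <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4), ctrl0,
                  seed = 11, pretrained = sp$pre)
  expect_identical(coef(a0), coef(fsl))
  expect_identical(a0$record$val_iou, fsl$record$val_iou)
  # empty unlabelled pool: supervised fallback with a warning
  sp_empty <- sp$split; sp_empty$train_unlabelled <- list()
  expect_warning(
    nf <- pseudoseg(sp_empty, "pseudosegrt", unet_config(2, 4), ctrl,
                    seed = 11, pretrained = sp$pre),
    "no unlabelled")
  expect_identical(nf$status, "no_unlabelled_fallback")
  expect_identical(coef(nf), coef(fsl))
})

test_that("fits are reproducible for a fixed seed", {
  sp <- small_pretrain()
  ctrl <- quick_ctrl(max_epochs_pl = 2, patience = 2)
  f1 <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4), ctrl,
                  seed = 11, pretrained = sp$pre)
  f2 <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4), ctrl,
                  seed = 11, pretrained = sp$pre)
  expect_identical(f1$record, f2$record)
  expect_identical(coef(f1), coef(f2))
})

test_that("variant labelling rules and weights follow their definitions", {
  probs <- matrix(c(0.95, 0.05, 0.5), 1, 3)
  hard <- make_hard_label(probs)
  expect_identical(as.vector(hard$labels), c(1L, 0L, 1L))  # >= 0.5 rule
  expect_identical(hard$n_ignored, 0L)
  # pseudo_lee's weight ramp: 0 at the start, 1 from the ramp end onwards
  sp <- small_pretrain()
  ctrl <- quick_ctrl(lee_ramp_epochs = 10)
  r1 <- ns$refresh_pseudo(sp$pre$params, unet_config(2, 4),
                          sp$split$train_unlabelled, "pseudo_lee", ctrl, 1)
  r11 <- ns$refresh_pseudo(sp$pre$params, unet_config(2, 4),
                           sp$split$train_unlabelled, "pseudo_lee", ctrl, 11)
  r6 <- ns$refresh_pseudo(sp$pre$params, unet_config(2, 4),
                          sp$split$train_unlabelled, "pseudo_lee", ctrl, 6)
  expect_identical(unique(r1$alphas), 0)
  expect_identical(unique(r11$alphas), 1)
  expect_equal(unique(r6$alphas), 0.5)
  # pseudo_notrust: weight fixed at 1, nothing ignored
  rn <- ns$refresh_pseudo(sp$pre$params, unet_config(2, 4),
                          sp$split$train_unlabelled, "pseudo_notrust", ctrl, 1)
  expect_identical(unique(rn$alphas), 1)
  expect_true(all(vapply(rn$pls, function(p) p$n_ignored == 0L, logical(1))))
  expect_error(pseudoseg(sp$split, "nonsense"), "arg")
})

test_that("fully-ignored pseudo-labels reduce the step to supervised only", {
  sp <- small_pretrain()
  cfg <- unet_config(2, 4)
  scan <- sp$split$train_unlabelled[[1]]$scan
  pl <- make_pseudo_label(matrix(0.5, nrow(scan), ncol(scan)), 0.9)
  pg <- ns$pseudo_grad(sp$pre$params, cfg, scan, pl, alpha = 2)
  expect_null(pg$grads)
  expect_identical(pg$loss, 0)
})

test_that("the ignored-pixel count trends downwards as training proceeds", {
  sp <- small_pretrain()
  ctrl <- quick_ctrl(max_epochs_pl = 6, patience = 6)
  fit <- pseudoseg(sp$split, "pseudosegrt", unet_config(2, 4), ctrl,
                   seed = 11, pretrained = sp$pre)
  ni <- fit$record$n_ignored_mean
  # trend check tolerating single-epoch violations
  expect_lte(mean(utils::tail(ni, 2)), mean(utils::head(ni, 2)))
})
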