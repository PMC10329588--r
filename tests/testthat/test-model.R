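# The U-Net: shapes, ranges, determinism, analytic gradients, and a
# single-pair overfitting smoke property of the training machinery.

ns <- asNamespace("pseudosegrt")

test_that("output shape and range invariants hold across depths", {
  set.seed(21)
  for (depth in 1:3) {
    cfg <- unet_config(depth = depth, base_channels = 2)
    params <- ns$unet_init(cfg)
    x <- matrix(runif(16 * 24), 16, 24)
    prob <- ns$unet_predict(params, x, cfg)
    expect_identical(dim(prob), dim(x))
    expect_true(all(prob > 0 & prob < 1))
    expect_true(all(is.finite(prob)))
    # deterministic in evaluation for fixed weights
    expect_identical(prob, ns$unet_predict(params, x, cfg))
  }
})

test_that("zero weights at the output head give probability one half", {
  set.seed(22)
  cfg <- unet_config(2, 2)
  params <- ns$unet_init(cfg)
  params[["head.w"]][] <- 0
  params[["head.b"]][] <- 0
  prob <- ns$unet_predict(params, matrix(runif(64), 8, 8), cfg)
  expect_true(all(prob == 0.5))
})

test_that("incompatible input shapes are rejected with the divisibility rule", {
  cfg <- unet_config(2, 2)
  params <- ns$unet_init(cfg)
  expect_error(ns$unet_predict(params, matrix(0, 15, 16), cfg),
               "divisible by 2\\^depth = 4")
})

test_that("backprop matches finite differences through the whole network", {
  set.seed(42)
  cfg <- unet_config(2, 2)
  params <- ns$unet_init(cfg)
  x <- matrix(runif(16 * 16), 16, 16)
  y <- matrix(rbinom(16 * 16, 1, 0.5), 16, 16)
  fw <- ns$unet_forward(params, x, cfg, keep_cache = TRUE)
  gz <- (fw$prob - y) / length(y)
  grads <- ns$unet_backward(params, cfg, fw$cache, gz)
  lossf <- function(p) bce(ns$unet_forward(p, x, cfg)$prob, y)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossf(p1) - lossf(p2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("a small U-Net overfits one phantom pair to IoU > 0.99", {
  pair <- phantom_scan(quick_params(), 3)
  cfg <- unet_config(2, 4)
  set.seed(1)
  params <- ns$unet_init(cfg)
  opt <- ns$adam_init(params)
  for (step in 1:120) {
    sg <- ns$supervised_grad(params, cfg, pair$scan, pair$mask)
    st <- ns$adam_step(params, sg$grads, opt, 1e-2)
    params <- st$params; opt <- st$opt
  }
  prob <- ns$unet_predict(params, pair$scan, cfg)
  pred <- matrix(as.integer(prob >= 0.5), nrow(prob), ncol(prob))
  expect_gt(mean_iou(pred, pair$mask), 0.99)
})

test_that("checkpoints round-trip weights, config and metadata", {
  sf <- small_fit()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(sf$fit, path)
  back <- load_checkpoint(path)
  expect_s3_class(back, "pseudoseg")
  scan <- sf$split$test[[1]]$scan
  expect_identical(predict(back, scan), predict(sf$fit, scan))
  expect_identical(back$model, sf$fit$model)
  expect_identical(back$record, sf$fit$record)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
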