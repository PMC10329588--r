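# The synthetic OCT phantom generator.

test_that("noiseless generation reproduces the mask exactly", {
  p <- phantom_params(speckle_strength = 0, tissue_intensity_mean = 1,
                      background_intensity_mean = 0)
  s <- phantom_scan(p, 7)
  expect_true(all(s$scan == s$mask))
})

test_that("generation is deterministic for a fixed (params, seed)", {
  p <- phantom_params()
  a <- phantom_scan(p, 123)
  b <- phantom_scan(p, 123)
  expect_identical(a, b)
  expect_false(identical(a$scan, phantom_scan(p, 124)$scan))
})

test_that("scans are in range and masks are a single contiguous band", {
  p <- quick_params()
  for (seed in 1:25) {
    s <- phantom_scan(p, seed)
    expect_true(all(is.finite(s$scan)), info = seed)
    expect_true(all(s$scan >= 0 & s$scan <= 1))
    expect_true(all(s$mask %in% c(0L, 1L)))
    # per-column tissue run is contiguous
    for (j in seq_len(ncol(s$mask))) {
      runs <- rle(s$mask[, j])
      expect_identical(sum(runs$values == 1L), 1L)
    }
  }
})

test_that("default healthy tissue fraction is calibrated to ~42-44%", {
  p <- phantom_params()
  fr <- vapply(1:50, function(i) mean(phantom_scan(p, i)$mask), numeric(1))
  expect_gte(mean(fr), 0.40)
  expect_lte(mean(fr), 0.46)
})

test_that("the shifted distribution is thinner and rougher than healthy", {
  ph <- phantom_params()
  ps <- phantom_params(shift_severity = 1)
  th_h <- vapply(1:50, function(i) phantom_scan(ph, i)$meta$mean_thickness,
                 numeric(1))
  th_s <- vapply(1:50, function(i) phantom_scan(ps, 500 + i)$meta$mean_thickness,
                 numeric(1))
  expect_lt(mean(th_s), mean(th_h))
  # boundary roughness: variability of the top-boundary row across columns
  rough <- function(pp, seed) {
    m <- phantom_scan(pp, seed)$mask
    top <- apply(m, 2, function(col) which(col == 1L)[1])
    mean(abs(diff(top)))
  }
  r_h <- mean(vapply(1:30, function(i) rough(ph, i), numeric(1)))
  r_s <- mean(vapply(1:30, function(i) rough(ps, 500 + i), numeric(1)))
  expect_gt(r_s, r_h)
})

test_that("parameterisations whose band exits the image are rejected", {
  bad <- phantom_params(ilm_baseline = 0.6, band_thickness_mean = 40)
  expect_error(phantom_scan(bad, 1), "exits the image")
})

test_that("dataset splits have the requested sizes and disjoint content", {
  ds <- phantom_dataset(n_train = 14, n_val = 3, n_test = 3,
                        n_shifted_test = 3, seed = 5)
  expect_length(ds$train, 14)
  expect_length(ds$val, 3)
  expect_length(ds$test, 3)
  expect_length(ds$shifted_test, 3)
  # per-split seed fan-out: no scan appears in two splits
  seeds <- c(vapply(ds$train, function(p) p$meta$seed, numeric(1)),
             vapply(ds$val, function(p) p$meta$seed, numeric(1)),
             vapply(ds$test, function(p) p$meta$seed, numeric(1)),
             vapply(ds$shifted_test, function(p) p$meta$seed, numeric(1)))
  expect_identical(anyDuplicated(seeds), 0L)
  # determinism at the dataset level
  expect_identical(ds$train[[1]],
                   phantom_dataset(n_train = 14, n_val = 3, n_test = 3,
                                   n_shifted_test = 3, seed = 5)$train[[1]])
  # empty shifted test leaves healthy splits unaffected
  ds0 <- phantom_dataset(n_train = 14, n_val = 3, n_test = 3,
                         n_shifted_test = 0, seed = 5)
  expect_length(ds0$shifted_test, 0)
  expect_identical(ds0$test, ds$test)
})

test_that("labelled subset keeps pattern coverage and withholds masks", {
  ds <- phantom_dataset(n_train = 20, n_val = 2, n_test = 2,
                        n_shifted_test = 2, seed = 3)
  any_onh <- any(vapply(ds$train, function(p) isTRUE(p$meta$onh), logical(1)))
  sp <- label_split(ds, n_labelled = 5, n_unlabelled = 10, seed = 3)
  expect_length(sp$train_labelled, 5)
  expect_length(sp$train_unlabelled, 10)
  expect_null(sp$train)
  if (any_onh) {
    expect_true(any(vapply(sp$train_labelled,
                           function(p) isTRUE(p$meta$onh), logical(1))))
  }
  expect_true(all(vapply(sp$train_unlabelled,
                         function(p) is.null(p$mask), logical(1))))
  # labelled and unlabelled are disjoint
  ls <- vapply(sp$train_labelled, function(p) p$meta$seed, numeric(1))
  us <- vapply(sp$train_unlabelled, function(p) p$meta$seed, numeric(1))
  expect_length(intersect(ls, us), 0)
})
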