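# The pseudo-labelling core math: trinary labels, adaptive weight, masked
# binary cross-entropy, loss combination.

test_that("trinary pseudo-labels follow the confidence rule, ties ignored", {
  p <- matrix(c(0.95, 0.05, 0.50), 1, 3)
  pl <- make_pseudo_label(p, 0.9)
  expect_identical(as.vector(pl$labels), c(1L, 0L, NA))
  expect_identical(pl$n_ignored, 1L)
  expect_identical(pl$n_total, 3L)

  # values exactly on either cut-off are ignored (strict inequalities)
  ties <- matrix(c(0.9, 0.1, 0.9000001, 0.0999999), 1, 4)
  plt <- make_pseudo_label(ties, 0.9)
  expect_identical(as.vector(plt$labels), c(NA, NA, 1L, 0L))

  # maximal uncertainty: everything ignored
  pu <- matrix(0.5, 5, 5)
  plu <- make_pseudo_label(pu, 0.9)
  expect_true(all(is.na(plu$labels)))
  expect_identical(plu$n_ignored, plu$n_total)

  expect_error(make_pseudo_label(p, 0.5), "0.5")
  expect_error(make_pseudo_label(p, 1), "0.5")
})

test_that("pseudo-labels match a per-pixel brute-force loop on random maps", {
  set.seed(101)
  probs <- matrix(runif(1e4), 100, 100)
  for (th in c(0.7, 0.8, 0.9)) {
    pl <- make_pseudo_label(probs, th)
    oracle <- pseudo_label_oracle(probs, th)
    expect_identical(pl$labels, oracle$labels)
    expect_identical(pl$n_ignored, as.integer(oracle$n_ignored))
    # conservation: every pixel in exactly one of {0, 1, ignored}
    expect_identical(sum(pl$labels == 1L, na.rm = TRUE) +
                       sum(pl$labels == 0L, na.rm = TRUE) + pl$n_ignored,
                     pl$n_total)
  }
})

test_that("raising the threshold never decreases the ignored count", {
  set.seed(202)
  for (rep in 1:20) {
    probs <- matrix(runif(400), 20, 20)
    ths <- sort(runif(2, 0.7, 0.95))
    n1 <- make_pseudo_label(probs, ths[1])$n_ignored
    n2 <- make_pseudo_label(probs, ths[2])$n_ignored
    expect_gte(n2, n1)
  }
})

test_that("adaptive weight equals half-total over ignored, capped", {
  mk <- function(n_ign, n_tot) {
    structure(list(labels = NULL, n_ignored = n_ign, n_total = n_tot),
              class = "pseudo_label")
  }
  expect_equal(compute_alpha(mk(500, 1000)), 1.0)
  expect_equal(compute_alpha(mk(1000, 1000)), 0.5)
  expect_equal(compute_alpha(mk(0, 1000), alpha_cap = 10), 10)
  expect_equal(compute_alpha(mk(10, 1000), alpha_cap = 10), 10)  # capped
  expect_equal(compute_alpha(mk(100, 1000), alpha_cap = 10), 5)
  # non-increasing in the ignored count (cleaner labels weigh more)
  a <- vapply(seq(10, 1000, by = 10),
              function(ni) compute_alpha(mk(ni, 1000)), numeric(1))
  expect_true(all(diff(a) <= 0))
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce(matrix(0.8), matrix(1)), -log(0.8), tolerance = 1e-12)
  expect_equal(bce(matrix(0.8), matrix(1)), 0.22314, tolerance = 1e-4)
  set.seed(3)
  tgt <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_equal(bce(matrix(0.5, 10, 10), tgt), log(2), tolerance = 1e-12)
  # perfect prediction: only the clamp keeps the loss nonzero
  expect_lte(bce(matrix(c(0, 1), 1, 2), matrix(c(0, 1), 1, 2)), 1e-6)
  expect_error(bce(matrix(0.5, 2, 2), matrix(1, 2, 3)), "mismatch")
})

test_that("masked BCE averages over retained pixels only", {
  set.seed(4)
  probs <- matrix(runif(64), 8, 8)
  # no pixel ignored: masking is the identity
  hard <- make_hard_label(probs)
  expect_equal(masked_bce(probs, hard), bce(probs, hard$labels))
  # everything ignored: empty-support convention
  allig <- make_pseudo_label(matrix(0.5, 8, 8), 0.9)
  expect_identical(masked_bce(probs, allig), 0)
  # half ignored: brute-force mean over retained pixels
  labels <- matrix(NA_integer_, 8, 8)
  labels[1:4, ] <- matrix(rbinom(32, 1, 0.5), 4, 8)
  pl <- structure(list(labels = labels, n_ignored = sum(is.na(labels)),
                       n_total = 64L), class = "pseudo_label")
  acc <- 0; n <- 0
  for (i in 1:8) for (j in 1:8) {
    if (!is.na(labels[i, j])) {
      p <- min(max(probs[i, j], 1e-7), 1 - 1e-7)
      acc <- acc + -(labels[i, j] * log(p) + (1 - labels[i, j]) * log(1 - p))
      n <- n + 1
    }
  }
  expect_equal(masked_bce(probs, pl), acc / n, tolerance = 1e-12)
})

test_that("masked BCE has exactly zero gradient at ignored pixels", {
  set.seed(5)
  probs <- matrix(runif(16, 0.2, 0.8), 4, 4)
  labels <- matrix(c(1L, NA, 0L, NA), 4, 4)
  pl <- structure(list(labels = labels, n_ignored = sum(is.na(labels)),
                       n_total = 16L), class = "pseudo_label")
  eps <- 1e-5
  fd <- function(i) {
    p1 <- probs; p1[i] <- p1[i] + eps
    p2 <- probs; p2[i] <- p2[i] - eps
    (masked_bce(p1, pl) - masked_bce(p2, pl)) / (2 * eps)
  }
  ignored <- which(is.na(labels))
  retained <- which(!is.na(labels))
  for (i in ignored) expect_identical(fd(i), 0)
  expect_true(all(abs(vapply(retained, fd, numeric(1))) > 1e-3))
})

test_that("loss combination is the weighted sum", {
  b <- combine_losses(0.5, 0.2, 1.0)
  expect_equal(b$total, 0.7)
  expect_equal(combine_losses(0.3, 0.4, 0.5)$total, 0.5)
  expect_equal(combine_losses(0.3, 0.4, 0)$total, 0.3)
  expect_equal(b$total, b$loss_sl + b$alpha * b$loss_pl)
  expect_s3_class(b, "loss_bundle")
  expect_error(combine_losses(-1, 0, 0))
})
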