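# Synthetic OCT B-scan phantoms: a single connected tissue band bounded by a
# smooth upper (ILM-like) and lower (BM-like) curve, rendered with
# multiplicative speckle.  A shift_severity > 0 variant emulates a damaged
# retina: thinner band, rougher boundaries, local pockets of thinning.

#' Parameters of the OCT phantom generator
#'
#' Defaults describe the "healthy" distribution at desk scale (64 x 128):
#' an ILM-like upper boundary around 22% of the image height, a tissue band
#' of mean thickness 43% of the height (so the tissue class occupies about
#' 43% of pixels, mirroring the roughly 42-44% tissue balance of retinal
#' boundary-segmentation data), smooth curvature, an optic-nerve-head-like
#' dip inserted with probability 0.3, and multiplicative speckle with
#' standard deviation 0.6 about the class mean intensity.
#'
#' @param height,width Image size in pixels.
#' @param ilm_baseline Fractional row position of the upper boundary, in (0,1).
#' @param band_thickness_mean Mean tissue-band thickness in pixels.
#' @param band_thickness_jitter Amplitude (pixels) of the smooth thickness
#'   variation along the scan.
#' @param curvature_amplitude Amplitude (pixels) of the smooth boundary
#'   curvature.
#' @param onh_probability Probability of inserting an optic-nerve-head-like
#'   localised dip in both boundaries.
#' @param speckle_strength Standard deviation of the multiplicative speckle
#'   factor (mean 1); 0 disables noise.
#' @param tissue_intensity_mean,background_intensity_mean Class mean
#'   intensities in `[0, 1]`.
#' @param shift_severity 0 for the healthy distribution; > 0 produces the
#'   distribution-shifted "unhealthy" variant (band thinning proportional to
#'   severity, rough boundaries, localised disruptions).
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(height = 64, width = 128,
                           ilm_baseline = 0.22,
                           band_thickness_mean = 0.43 * height,
                           band_thickness_jitter = 0.05 * height,
                           curvature_amplitude = 0.08 * height,
                           onh_probability = 0.3,
                           speckle_strength = 0.6,
                           tissue_intensity_mean = 0.65,
                           background_intensity_mean = 0.15,
                           shift_severity = 0) {
  p <- list(height = as.integer(height), width = as.integer(width),
            ilm_baseline = ilm_baseline,
            band_thickness_mean = band_thickness_mean,
            band_thickness_jitter = band_thickness_jitter,
            curvature_amplitude = curvature_amplitude,
            onh_probability = onh_probability,
            speckle_strength = speckle_strength,
            tissue_intensity_mean = tissue_intensity_mean,
            background_intensity_mean = background_intensity_mean,
            shift_severity = shift_severity)
  with(p, {
    stopifnot(height >= 8, width >= 8,
              ilm_baseline > 0, ilm_baseline < 1,
              band_thickness_mean > 0,
              band_thickness_jitter >= 0,
              curvature_amplitude >= 0,
              onh_probability >= 0, onh_probability <= 1,
              speckle_strength >= 0,
              tissue_intensity_mean > 0, tissue_intensity_mean <= 1,
              background_intensity_mean >= 0, background_intensity_mean < 1,
              shift_severity >= 0)
  })
  structure(p, class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf(paste0(
    "OCT phantom parameters: %d x %d px, ILM baseline %.2f, band %.1f +/- %.1f px,\n",
    "  curvature %.1f px, ONH prob %.2f, speckle sd %.2f, ",
    "intensities %.2f/%.2f, shift severity %.2f\n"),
    x$height, x$width, x$ilm_baseline, x$band_thickness_mean,
    x$band_thickness_jitter, x$curvature_amplitude, x$onh_probability,
    x$speckle_strength, x$tissue_intensity_mean,
    x$background_intensity_mean, x$shift_severity))
  invisible(x)
}

# run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth zero-mean curve along the scan width, rescaled to a fixed peak
# amplitude; built from a low-order spline through random knots
smooth_curve <- function(width, amplitude, n_knots = 4) {
  if (amplitude == 0) return(rep(0, width))
  kx <- seq(1, width, length.out = n_knots + 2)
  ky <- stats::rnorm(n_knots + 2)
  cv <- stats::spline(kx, ky, xout = seq_len(width))$y
  cv <- cv - mean(cv)
  m <- max(abs(cv))
  if (m < 1e-12) return(rep(0, width))
  cv * amplitude / m
}

#' Generate one phantom B-scan with its ground-truth mask
#'
#' Deterministic for a fixed `(params, seed)` pair.  The mask is the exact
#' noiseless band geometry; the scan renders the two classes at their mean
#' intensities and applies multiplicative speckle (gamma-distributed factor
#' with mean 1 and standard deviation `speckle_strength`), clipped to
#' `[0, 1]`.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed for this scan.
#' @return A list with `scan` (numeric matrix in `[0, 1]`, row 1 = top of
#'   the B-scan), `mask` (integer 0/1 matrix) and `meta` (list: `onh` flag,
#'   realised mean thickness, seed).
#' @export
phantom_scan <- function(params, seed) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    H <- params$height; W <- params$width
    s <- params$shift_severity

    curvature <- smooth_curve(W, params$curvature_amplitude)
    thickness <- params$band_thickness_mean +
      smooth_curve(W, params$band_thickness_jitter)

    onh <- stats::runif(1) < params$onh_probability
    dip <- rep(0, W)
    if (onh) {
      centre <- stats::runif(1, 0.25 * W, 0.75 * W)
      sigma <- stats::runif(1, 0.06 * W, 0.10 * W)
      depth <- stats::runif(1, 0.08 * H, 0.14 * H)
      dip <- depth * exp(-0.5 * ((seq_len(W) - centre) / sigma)^2)
    }

    rough <- rep(0, W)
    if (s > 0) {
      # damaged variant: global thinning, boundary roughness, local pockets
      thickness <- thickness * (1 - 0.3 * min(s, 2))
      rough <- s * 1.2 * stats::filter(stats::rnorm(W + 4), rep(1 / 3, 3),
                                       sides = 2)[3:(W + 2)]
      n_pockets <- stats::rpois(1, 3 * s)
      for (k in seq_len(n_pockets)) {
        centre <- stats::runif(1, 1, W)
        sigma <- stats::runif(1, 0.03 * W, 0.10 * W)
        frac <- stats::runif(1, 0.4, 0.75)
        bump <- exp(-0.5 * ((seq_len(W) - centre) / sigma)^2)
        thickness <- thickness - frac * thickness * bump
      }
      thickness <- pmax(thickness, 2)
    }

    ilm <- params$ilm_baseline * H + curvature + dip + rough
    r0 <- round(ilm)
    nt <- round(pmax(thickness, 1))
    r1 <- r0 + nt - 1
    if (any(r0 < 1) || any(r1 > H)) {
      stop("phantom band exits the image vertically (rows ",
           min(r0), "..", max(r1), " for height ", H,
           "); reduce baseline/curvature/thickness parameters")
    }

    mask <- matrix(0L, H, W)
    for (j in seq_len(W)) mask[r0[j]:r1[j], j] <- 1L

    base <- ifelse(mask == 1L, params$tissue_intensity_mean,
                   params$background_intensity_mean)
    if (params$speckle_strength > 0) {
      shape <- 1 / params$speckle_strength^2
      fac <- matrix(stats::rgamma(H * W, shape = shape, rate = shape), H, W)
      scan <- pmin(pmax(base * fac, 0), 1)
    } else {
      scan <- base
    }

    list(scan = scan, mask = mask,
         meta = list(onh = onh, mean_thickness = mean(r1 - r0 + 1),
                     seed = seed))
  })
}

# fixed per-split seed offsets keep each split reproducible independently
# of the other splits' sizes
.split_offsets <- c(train = 100000L, val = 200000L, test = 300000L,
                    shifted_test = 400000L)

#' Generate a phantom dataset with healthy and distribution-shifted splits
#'
#' The train/val/test splits are drawn from the healthy parameter set only;
#' the shifted test split from the shifted parameter set only (the damaged
#' distribution is never seen in training).  One master seed fans out to
#' per-image seeds through fixed per-split offsets plus a within-split
#' counter, so every subset is reproducible independently of split sizes.
#'
#' @param params_healthy,params_shifted [phantom_params()] objects for the
#'   two distributions.
#' @param n_train,n_val,n_test,n_shifted_test Split sizes (shifted may be 0).
#' @param seed Master integer seed.
#' @return An object of class `oct_split` with lists `train`, `val`, `test`,
#'   `shifted_test` of `(scan, mask, meta)` pairs.  Use [label_split()] to
#'   carve the train pool into labelled and unlabelled subsets.
#' @export
phantom_dataset <- function(params_healthy = phantom_params(),
                            params_shifted = phantom_params(shift_severity = 1),
                            n_train = 14, n_val = 3, n_test = 3,
                            n_shifted_test = 3, seed = 1) {
  stopifnot(n_train > 0, n_val > 0, n_test > 0, n_shifted_test >= 0)
  gen <- function(params, n, offset) {
    lapply(seq_len(n), function(i) phantom_scan(params, seed + offset + i))
  }
  structure(
    list(train = gen(params_healthy, n_train, .split_offsets[["train"]]),
         val = gen(params_healthy, n_val, .split_offsets[["val"]]),
         test = gen(params_healthy, n_test, .split_offsets[["test"]]),
         shifted_test = gen(params_shifted, n_shifted_test,
                            .split_offsets[["shifted_test"]]),
         params_healthy = params_healthy, params_shifted = params_shifted,
         seed = seed),
    class = "oct_split"
  )
}

#' Carve a train pool into labelled and unlabelled subsets
#'
#' The labelled subset is chosen to capture the scan-pattern variability:
#' if any training scan contains an optic-nerve-head-like dip, at least one
#' such scan is guaranteed among the labelled examples.  The unlabelled
#' subset is drawn at random from the remainder and its masks are dropped.
#'
#' @param split An [phantom_dataset()] result (or any `oct_split` whose
#'   `train` pairs carry masks).
#' @param n_labelled,n_unlabelled Subset sizes;
#'   `n_labelled + n_unlabelled` must not exceed the train pool.
#' @param seed Integer seed for the subset draw.
#' @return The split with `train_labelled` (pairs) and `train_unlabelled`
#'   (scans only) added; the raw `train` pool is removed.
#' @export
label_split <- function(split, n_labelled, n_unlabelled, seed = 1) {
  stopifnot(inherits(split, "oct_split"), n_labelled >= 1, n_unlabelled >= 0,
            n_labelled + n_unlabelled <= length(split$train))
  with_seed(seed, {
    n <- length(split$train)
    lab <- sample(n, n_labelled)
    has_onh <- vapply(split$train, function(p) isTRUE(p$meta$onh), logical(1))
    if (any(has_onh) && !any(has_onh[lab])) {
      lab[1] <- which(has_onh)[1]  # ensure pattern coverage in the labels
      lab <- unique(lab)
      while (length(lab) < n_labelled) {
        cand <- setdiff(seq_len(n), lab)
        lab <- c(lab, cand[1])
      }
    }
    rest <- setdiff(seq_len(n), lab)
    unl <- if (n_unlabelled > 0) sample(rest, n_unlabelled) else integer(0)
    split$train_labelled <- split$train[lab]
    split$train_unlabelled <- lapply(split$train[unl], function(p) {
      list(scan = p$scan, meta = p$meta)  # masks withheld
    })
    split$train <- NULL
    split
  })
}

#' @export
print.oct_split <- function(x, ...) {
  n <- function(s) if (is.null(x[[s]])) 0L else length(x[[s]])
  cat("OCT phantom dataset split:\n")
  if (!is.null(x$train)) cat("  train pool      ", n("train"), "\n")
  if (!is.null(x$train_labelled)) {
    cat("  train labelled  ", n("train_labelled"), "\n")
    cat("  train unlabelled", n("train_unlabelled"), "(masks withheld)\n")
  }
  cat("  validation      ", n("val"), "\n")
  cat("  healthy test    ", n("test"), "\n")
  cat("  shifted test    ", n("shifted_test"), "\n")
  invisible(x)
}
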