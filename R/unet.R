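# A compact 1-in / 1-out U-Net: per level two 3x3 convolutions + ReLU and
# 2x2 max pooling on the way down, 2x2 transposed convolution + skip
# concatenation + two 3x3 convolutions on the way up, a 1x1 head and a
# sigmoid.  Forward/backward are written against the C++ kernels in
# src/layers.cpp; parameters live in a flat named list so the optimiser,
# checkpointing and ONNX export can treat them uniformly.

#' U-Net architecture configuration
#'
#' @param depth Number of down/up-sampling levels (>= 1).  Input height and
#'   width must be divisible by `2^depth`.
#' @param base_channels Channel count at the first level; doubled per level.
#' @param input_channels,output_channels Fixed at 1 for grayscale in /
#'   single-probability out.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(depth = 2, base_channels = 8,
                        input_channels = 1, output_channels = 1) {
  stopifnot(depth >= 1, base_channels >= 1,
            input_channels == 1, output_channels == 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_channels = 1L, output_channels = 1L),
            class = "unet_config")
}

#' @export
print.unet_config <- function(x, ...) {
  cat(sprintf("U-Net: depth %d, base channels %d (1 channel in, 1 out)\n",
              x$depth, x$base_channels))
  invisible(x)
}

# channel widths per encoder level
enc_channels <- function(cfg, i) {
  cin <- if (i == 1) 1L else cfg$base_channels * 2L^(i - 2)
  c(cin = cin, cout = cfg$base_channels * 2L^(i - 1))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# flat named parameter list; draws from the current RNG stream
unet_init <- function(cfg) {
  b <- cfg$base_channels; d <- cfg$depth
  p <- list()
  conv <- function(cin, cout, k = 3) {
    list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
  }
  add <- function(name, l) {
    p[[paste0(name, ".w")]] <<- l$w
    p[[paste0(name, ".b")]] <<- l$b
  }
  for (i in seq_len(d)) {
    ch <- enc_channels(cfg, i)
    add(paste0("enc", i, ".c1"), conv(ch[["cin"]], ch[["cout"]]))
    add(paste0("enc", i, ".c2"), conv(ch[["cout"]], ch[["cout"]]))
  }
  add("bot.c1", conv(b * 2L^(d - 1), b * 2L^d))
  add("bot.c2", conv(b * 2L^d, b * 2L^d))
  for (i in rev(seq_len(d))) {
    cu <- b * 2L^(i - 1)                   # channels after up-conv
    add(paste0("dec", i, ".up"),
        list(w = he_init(c(2, 2, 2 * cu, cu), 4 * 2 * cu), b = numeric(cu)))
    add(paste0("dec", i, ".c1"), conv(2 * cu, cu))
    add(paste0("dec", i, ".c2"), conv(cu, cu))
  }
  add("head", conv(b, 1, k = 1))
  p
}

# 4D weight array -> (k*k*cin, cout) matrix expected by the C++ kernels
wmat <- function(w) {
  d <- dim(w)
  matrix(w, prod(d[1:3]), d[4])
}

check_unet_input <- function(x, cfg) {
  div <- 2^cfg$depth
  if (nrow(x) %% div != 0 || ncol(x) %% div != 0) {
    stop("input is ", nrow(x), "x", ncol(x),
         " but both dimensions must be divisible by 2^depth = ", div)
  }
}

cat_channels <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# forward pass; returns probabilities, logits and (optionally) the
# activation cache needed by unet_backward
unet_forward <- function(params, x, cfg, keep_cache = FALSE) {
  check_unet_input(x, cfg)
  d <- cfg$depth
  cache <- if (keep_cache) list() else NULL
  keep <- function(name, val) if (keep_cache) cache[[name]] <<- val
  cr <- function(a, name) {   # conv3x3 + relu
    h <- conv_fw(a, wmat(params[[paste0(name, ".w")]]),
                 params[[paste0(name, ".b")]], 3L, 1L)
    h <- pmax(h, 0)
    keep(paste0(name, ".x"), a)
    keep(paste0(name, ".h"), h)
    h
  }
  a <- array(x, c(nrow(x), ncol(x), 1))
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    a <- cr(a, paste0("enc", i, ".c1"))
    a <- cr(a, paste0("enc", i, ".c2"))
    skips[[i]] <- a
    mp <- maxpool2_fw(a)
    keep(paste0("pool", i, ".idx"), mp$idx)
    a <- mp$y
  }
  a <- cr(a, "bot.c1")
  a <- cr(a, "bot.c2")
  for (i in rev(seq_len(d))) {
    keep(paste0("dec", i, ".up.x"), a)
    u <- convt2_fw(a, wmat(params[[paste0("dec", i, ".up.w")]]),
                   params[[paste0("dec", i, ".up.b")]])
    a <- cat_channels(u, skips[[i]])
    a <- cr(a, paste0("dec", i, ".c1"))
    a <- cr(a, paste0("dec", i, ".c2"))
  }
  keep("head.x", a)
  z <- conv_fw(a, wmat(params[["head.w"]]), params[["head.b"]], 1L, 0L)
  z <- matrix(z, nrow(x), ncol(x))
  list(prob = stats::plogis(z), z = z, cache = cache)
}

# backward pass from d(loss)/d(logits); returns flat named gradient list
unet_backward <- function(params, cfg, cache, gz) {
  d <- cfg$depth
  grads <- list()
  # conv3x3+relu backward: g is grad at post-relu output
  cr_bw <- function(g, name) {
    g <- g * (cache[[paste0(name, ".h")]] > 0)
    bw <- conv_bw(cache[[paste0(name, ".x")]],
                  wmat(params[[paste0(name, ".w")]]), g, 3L, 1L)
    grads[[paste0(name, ".w")]] <<- as.numeric(bw$gw)
    grads[[paste0(name, ".b")]] <<- as.numeric(bw$gb)
    bw$gx
  }
  hb <- conv_bw(cache[["head.x"]], wmat(params[["head.w"]]),
                array(gz, c(nrow(gz), ncol(gz), 1)), 1L, 0L)
  grads[["head.w"]] <- as.numeric(hb$gw)
  grads[["head.b"]] <- as.numeric(hb$gb)
  g <- hb$gx
  gskip <- vector("list", d)
  for (i in seq_len(d)) {           # decoder ran d..1; unwind 1..d
    g <- cr_bw(g, paste0("dec", i, ".c2"))
    g <- cr_bw(g, paste0("dec", i, ".c1"))
    cu <- ncol(wmat(params[[paste0("dec", i, ".up.w")]]))  # up-conv channels
    gu <- g[, , seq_len(cu), drop = FALSE]
    gskip[[i]] <- g[, , cu + seq_len(dim(g)[3] - cu), drop = FALSE]
    ub <- convt2_bw(cache[[paste0("dec", i, ".up.x")]],
                    wmat(params[[paste0("dec", i, ".up.w")]]), gu)
    grads[[paste0("dec", i, ".up.w")]] <- as.numeric(ub$gw)
    grads[[paste0("dec", i, ".up.b")]] <- as.numeric(ub$gb)
    g <- ub$gx
  }
  g <- cr_bw(g, "bot.c2")
  g <- cr_bw(g, "bot.c1")
  for (i in rev(seq_len(d))) {
    g <- maxpool2_bw(g, cache[[paste0("pool", i, ".idx")]]) + gskip[[i]]
    g <- cr_bw(g, paste0("enc", i, ".c2"))
    g <- cr_bw(g, paste0("enc", i, ".c1"))
  }
  grads
}

unet_predict <- function(params, x, cfg) {
  unet_forward(params, x, cfg, keep_cache = FALSE)$prob
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) numeric(length(p))),
       v = lapply(params, function(p) numeric(length(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (n in names(params)) {
    g <- grads[[n]]
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * g
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * g * g
    params[[n]] <- params[[n]] -
      lr * (opt$m[[n]] / bc1) / (sqrt(opt$v[[n]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# elementwise sum of two flat gradient lists
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (n in names(b)) a[[n]] <- a[[n]] + b[[n]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
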