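# Minimal ONNX reader and reference executor.  Parses the protobuf wire
# format back into a graph and evaluates it with plain-R implementations of
# the ops the exported U-Net uses (Conv, Relu, MaxPool, ConvTranspose,
# Concat, Sigmoid), written against the ONNX operator semantics and kept
# independent of the native C++ forward pass — so the parity check
# exercises a genuinely separate numerical route over the serialised
# weights.

pb_parse <- function(r) {
  pos <- 1L
  n <- length(r)
  read_varint <- function() {
    val <- 0
    shift <- 1
    repeat {
      b <- as.integer(r[pos]); pos <<- pos + 1L
      val <- val + (b %% 128) * shift
      if (b < 128) break
      shift <- shift * 128
    }
    val
  }
  fields <- list()
  while (pos <= n) {
    key <- read_varint()
    field <- key %/% 8
    wt <- key %% 8
    val <- switch(as.character(wt),
      "0" = read_varint(),
      "1" = { v <- r[pos:(pos + 7L)]; pos <- pos + 8L; v },
      "2" = {
        len <- read_varint()
        v <- if (len > 0) r[pos:(pos + len - 1L)] else raw(0)
        pos <- pos + len
        v
      },
      "5" = { v <- r[pos:(pos + 3L)]; pos <- pos + 4L; v },
      stop("unsupported protobuf wire type ", wt))
    fields[[length(fields) + 1L]] <- list(field = field, wt = wt, val = val)
  }
  fields
}

pb_field <- function(fields, id) {
  out <- Filter(function(f) f$field == id, fields)
  lapply(out, function(f) f$val)
}
pb_field1 <- function(fields, id) {
  v <- pb_field(fields, id)
  if (length(v) == 0) NULL else v[[1]]
}
pb_unpack_varints <- function(payload) {
  if (length(payload) == 0) return(numeric(0))
  vals <- numeric(0)
  pos <- 1L
  while (pos <= length(payload)) {
    val <- 0; shift <- 1
    repeat {
      b <- as.integer(payload[pos]); pos <- pos + 1L
      val <- val + (b %% 128) * shift
      if (b < 128) break
      shift <- shift * 128
    }
    vals <- c(vals, val)
  }
  vals
}

parse_tensorproto <- function(r) {
  f <- pb_parse(r)
  dims_raw <- pb_field(f, 1)
  dims <- if (length(dims_raw) == 1 && is.raw(dims_raw[[1]])) {
    pb_unpack_varints(dims_raw[[1]])          # packed
  } else {
    as.numeric(unlist(dims_raw))              # repeated varint
  }
  dtype <- pb_field1(f, 2)
  name <- rawToChar(pb_field1(f, 8))
  raw_data <- pb_field1(f, 9)
  if (is.null(dtype) || dtype != 1) stop("tensor '", name, "' is not float32")
  vals <- readBin(raw_data, numeric(), n = length(raw_data) / 4, size = 4,
                  endian = "little")
  arr <- if (length(dims) > 1) {
    aperm(array(vals, rev(dims)), rev(seq_along(dims)))  # row- to col-major
  } else {
    vals
  }
  list(name = name, dims = dims, data = arr)
}

parse_attr <- function(r) {
  f <- pb_parse(r)
  name <- rawToChar(pb_field1(f, 1))
  type <- pb_field1(f, 20)
  val <- switch(as.character(type),
    "2" = pb_field1(f, 3),                        # int
    "7" = {                                       # ints (packed or not)
      iv <- pb_field(f, 8)
      if (length(iv) == 1 && is.raw(iv[[1]])) pb_unpack_varints(iv[[1]])
      else as.numeric(unlist(iv))
    },
    "3" = rawToChar(pb_field1(f, 4)),             # string
    "1" = readBin(pb_field1(f, 2), numeric(), 1, size = 4,
                  endian = "little"),             # float
    stop("unsupported attribute type ", type, " for '", name, "'"))
  list(name = name, value = val)
}

parse_node <- function(r) {
  f <- pb_parse(r)
  attrs <- lapply(pb_field(f, 5), parse_attr)
  names(attrs) <- vapply(attrs, function(a) a$name, character(1))
  list(inputs = vapply(pb_field(f, 1), rawToChar, character(1)),
       output = rawToChar(pb_field1(f, 2)),
       op_type = rawToChar(pb_field1(f, 4)),
       attrs = lapply(attrs, function(a) a$value))
}

parse_value_info <- function(r) {
  f <- pb_parse(r)
  name <- rawToChar(pb_field1(f, 1))
  dims <- numeric(0)
  type_raw <- pb_field1(f, 2)
  if (!is.null(type_raw)) {
    tt <- pb_field1(pb_parse(type_raw), 1)
    if (!is.null(tt)) {
      shape_raw <- pb_field1(pb_parse(tt), 2)
      if (!is.null(shape_raw)) {
        dims <- vapply(pb_field(pb_parse(shape_raw), 1), function(dr) {
          v <- pb_field1(pb_parse(dr), 1)
          if (is.null(v)) NA_real_ else as.numeric(v)
        }, numeric(1))
      }
    }
  }
  list(name = name, dims = dims)
}

#' Load an ONNX model file
#'
#' Parses the protobuf container into nodes, initializers and declared
#' inputs/outputs, ready for [onnx_predict()].
#'
#' @param path Path to a `.onnx` file.
#' @return A list of class `onnx_model`.
#' @export
onnx_load <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  f <- pb_parse(r)
  graph_raw <- pb_field1(f, 7)
  if (is.null(graph_raw)) stop("not an ONNX model: no graph found")
  g <- pb_parse(graph_raw)
  inits <- lapply(pb_field(g, 5), parse_tensorproto)
  names(inits) <- vapply(inits, function(t) t$name, character(1))
  opset <- lapply(pb_field(f, 8), function(o) pb_field1(pb_parse(o), 2))
  structure(
    list(ir_version = pb_field1(f, 1),
         opset = if (length(opset)) opset[[1]] else NA,
         nodes = lapply(pb_field(g, 1), parse_node),
         initializers = inits,
         inputs = lapply(pb_field(g, 11), parse_value_info),
         outputs = lapply(pb_field(g, 12), parse_value_info)),
    class = "onnx_model"
  )
}

#' @export
print.onnx_model <- function(x, ...) {
  cat("ONNX model: ir_version", x$ir_version, "opset", x$opset, "\n")
  cat(" ", length(x$nodes), "nodes,", length(x$initializers),
      "initializers\n")
  ins <- vapply(x$inputs, function(v) {
    paste0(v$name, " [", paste(v$dims, collapse = "x"), "]")
  }, character(1))
  outs <- vapply(x$outputs, function(v) v$name, character(1))
  cat("  inputs:", paste(ins, collapse = ", "),
      " outputs:", paste(outs, collapse = ", "), "\n")
  invisible(x)
}

#' Structural validation of an ONNX file
#'
#' Checks that the file parses, declares an IR version and opset, has named
#' graph inputs and outputs, that every node input is either a graph input,
#' an initializer, or the output of an earlier node (single static
#' assignment), and that every declared graph output is produced.
#'
#' @param path Path to a `.onnx` file.
#' @return `TRUE` (invisibly) if valid; otherwise an error describing the
#'   first violation.
#' @export
onnx_validate <- function(path) {
  m <- onnx_load(path)
  if (is.null(m$ir_version)) stop("missing ir_version")
  if (is.na(m$opset)) stop("missing opset import")
  if (length(m$inputs) == 0) stop("graph declares no inputs")
  if (length(m$outputs) == 0) stop("graph declares no outputs")
  known <- c(vapply(m$inputs, function(v) v$name, character(1)),
             names(m$initializers))
  for (nd in m$nodes) {
    missing <- setdiff(nd$inputs, known)
    if (length(missing)) {
      stop("node '", nd$output, "' (", nd$op_type,
           ") consumes undefined tensor(s): ",
           paste(missing, collapse = ", "))
    }
    if (nd$output %in% known) stop("tensor '", nd$output, "' defined twice")
    known <- c(known, nd$output)
  }
  produced <- vapply(m$outputs, function(v) v$name, character(1))
  if (!all(produced %in% known)) {
    stop("graph output(s) never produced: ",
         paste(setdiff(produced, known), collapse = ", "))
  }
  invisible(TRUE)
}

# ---- reference op implementations (NCHW, batch 1) ------------------------

ref_conv <- function(x, w, b, pads, kernel) {
  k <- kernel[1]
  pad <- pads[1]
  Ci <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Co <- dim(w)[1]
  Ho <- H + 2 * pad - k + 1
  Wo <- W + 2 * pad - k + 1
  xp <- array(0, c(Ci, H + 2 * pad, W + 2 * pad))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x[1, , , ]
  col <- matrix(0, k * k * Ci, Ho * Wo)
  row <- 0L
  for (ci in seq_len(Ci)) for (dh in seq_len(k)) for (dw in seq_len(k)) {
    row <- row + 1L
    col[row, ] <- as.vector(xp[ci, dh:(dh + Ho - 1), dw:(dw + Wo - 1)])
  }
  wr <- aperm(w, c(4, 3, 2, 1))            # (kw, kh, Ci, Co)
  wm <- matrix(wr, k * k * Ci, Co)
  y <- t(wm) %*% col + b                   # (Co, Ho*Wo)
  out <- array(0, c(1, Co, Ho, Wo))
  for (co in seq_len(Co)) out[1, co, , ] <- matrix(y[co, ], Ho, Wo)
  out
}

ref_convtranspose <- function(x, w, b) {   # kernel 2, stride 2
  Ci <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Co <- dim(w)[2]
  out <- array(0, c(1, Co, 2 * H, 2 * W))
  for (co in seq_len(Co)) out[1, co, , ] <- b[co]
  # each channel flattened column-major (H fastest)
  xm <- t(vapply(seq_len(Ci), function(ci) as.vector(x[1, ci, , ]),
                 numeric(H * W)))
  dim(xm) <- c(Ci, H * W)
  for (di in 1:2) for (dj in 1:2) {
    wm <- matrix(w[, , di, dj], Ci, Co)
    y <- t(wm) %*% xm                      # (Co, H*W)
    for (co in seq_len(Co)) {
      out[1, co, seq(di, 2 * H, 2), seq(dj, 2 * W, 2)] <-
        out[1, co, seq(di, 2 * H, 2), seq(dj, 2 * W, 2)] + matrix(y[co, ], H, W)
    }
  }
  out
}

ref_maxpool2 <- function(x) {
  H <- dim(x)[3]; W <- dim(x)[4]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2)
  j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  pmax(x[, , i1, j1, drop = FALSE], x[, , i2, j1, drop = FALSE],
       x[, , i1, j2, drop = FALSE], x[, , i2, j2, drop = FALSE])
}

ref_concat <- function(a, b) {
  out <- array(0, c(1, dim(a)[2] + dim(b)[2], dim(a)[3], dim(a)[4]))
  out[, seq_len(dim(a)[2]), , ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), , ] <- b
  out
}

#' Run inference through a loaded ONNX model
#'
#' Executes the graph node by node with the package's reference op
#' implementations.
#'
#' @param model An [onnx_load()] result.
#' @param scan Numeric matrix (the B-scan); wrapped to `1 x 1 x H x W`.
#' @return The probability map as a matrix of the input shape.
#' @export
onnx_predict <- function(model, scan) {
  stopifnot(inherits(model, "onnx_model"))
  env <- new.env(parent = emptyenv())
  for (nm in names(model$initializers)) {
    assign(nm, model$initializers[[nm]]$data, envir = env)
  }
  x <- array(0, c(1, 1, nrow(scan), ncol(scan)))
  x[1, 1, , ] <- scan
  assign(model$inputs[[1]]$name, x, envir = env)
  get_t <- function(nm) get(nm, envir = env)
  for (nd in model$nodes) {
    out <- switch(nd$op_type,
      Conv = ref_conv(get_t(nd$inputs[1]), get_t(nd$inputs[2]),
                      get_t(nd$inputs[3]), nd$attrs$pads,
                      nd$attrs$kernel_shape),
      Relu = pmax(get_t(nd$inputs[1]), 0),
      MaxPool = ref_maxpool2(get_t(nd$inputs[1])),
      ConvTranspose = ref_convtranspose(get_t(nd$inputs[1]),
                                        get_t(nd$inputs[2]),
                                        get_t(nd$inputs[3])),
      Concat = ref_concat(get_t(nd$inputs[1]), get_t(nd$inputs[2])),
      Sigmoid = stats::plogis(get_t(nd$inputs[1])),
      stop("unsupported op in executor: ", nd$op_type))
    assign(nd$output, out, envir = env)
  }
  y <- get_t(model$outputs[[1]]$name)
  matrix(y[1, 1, , ], nrow(scan), ncol(scan))
}

#' Numerical parity between native and exported inference
#'
#' Exports the model (unless `path` points to an existing export), runs
#' `n_inputs` random phantom scans through both the native forward pass and
#' the ONNX reference executor, and reports the probability differences.
#'
#' @param object A fitted [pseudoseg()] model.
#' @param path Optional path for the `.onnx` file (temporary by default).
#' @param n_inputs Number of random inputs to check (default 20).
#' @param tolerance Pass threshold on the max absolute difference
#'   (default 1e-4, appropriate for float32 serialisation).
#' @param params Phantom parameters used to draw the check inputs.
#' @param seed Seed for the check inputs.
#' @return A list of class `onnx_parity_report`: `max_abs_diff`,
#'   `mean_abs_diff`, `n_inputs_checked`, `tolerance`, `passed`.
#' @export
onnx_parity <- function(object, path = tempfile(fileext = ".onnx"),
                        n_inputs = 20, tolerance = 1e-4,
                        params = phantom_params(), seed = 1) {
  if (!file.exists(path)) {
    export_onnx(object, path, input_h = params$height,
                input_w = params$width)
  }
  m <- onnx_load(path)
  diffs <- vapply(seq_len(n_inputs), function(i) {
    scan <- phantom_scan(params, seed + i)$scan
    native <- unet_predict(object$params, scan, object$model)
    exported <- onnx_predict(m, scan)
    max(abs(native - exported))
  }, numeric(1))
  structure(
    list(max_abs_diff = max(diffs), mean_abs_diff = mean(diffs),
         n_inputs_checked = n_inputs, tolerance = tolerance,
         passed = max(diffs) <= tolerance),
    class = "onnx_parity_report"
  )
}

#' @export
print.onnx_parity_report <- function(x, ...) {
  cat(sprintf(paste0("ONNX parity over %d inputs: max |diff| = %.3g, ",
                     "mean |diff| = %.3g (tolerance %.1g): %s\n"),
              x$n_inputs_checked, x$max_abs_diff, x$mean_abs_diff,
              x$tolerance, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}
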