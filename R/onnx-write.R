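# ONNX export.  The ONNX interchange format is protobuf-encoded; emitting
# protobuf is a small, well-defined job (varints + length-delimited
# fields), done directly here.  Field numbers follow the onnx.proto3
# schema; opset 13, weights stored as float32 raw_data in row-major order.

pb_varint <- function(x) {
  x <- as.numeric(x)
  stopifnot(x >= 0)
  out <- raw(0)
  repeat {
    b <- x %% 128
    x <- (x - b) %/% 128
    if (x > 0) {
      out <- c(out, as.raw(b + 128))
    } else {
      out <- c(out, as.raw(b))
      break
    }
  }
  out
}

pb_key <- function(field, wiretype) pb_varint(field * 8 + wiretype)
pb_bytes <- function(field, payload) {
  c(pb_key(field, 2), pb_varint(length(payload)), payload)
}
pb_string <- function(field, s) pb_bytes(field, charToRaw(s))
pb_int <- function(field, v) c(pb_key(field, 0), pb_varint(v))
pb_packed_ints <- function(field, vs) {
  pb_bytes(field, do.call(c, lapply(vs, pb_varint)))
}
pb_float <- function(field, v) {
  c(pb_key(field, 5), writeBin(as.numeric(v), raw(), size = 4,
                               endian = "little"))
}

# R (column-major) array -> row-major float32 bytes
row_major_f32 <- function(arr) {
  d <- dim(arr)
  flat <- if (is.null(d) || length(d) == 1) as.numeric(arr)
          else as.numeric(aperm(arr, rev(seq_along(d))))
  writeBin(flat, raw(), size = 4, endian = "little")
}

# TensorProto: dims=1, data_type=2 (1 = float32), name=8, raw_data=9
onnx_tensorproto <- function(name, arr) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  c(pb_packed_ints(1, d), pb_int(2, 1), pb_string(8, name),
    pb_bytes(9, row_major_f32(arr)))
}

# AttributeProto: name=1, f=2, i=3, s=4, ints=8, type=20
onnx_attr_ints <- function(name, vs) {
  c(pb_string(1, name), pb_packed_ints(8, vs), pb_int(20, 7))
}
onnx_attr_int <- function(name, v) {
  c(pb_string(1, name), pb_int(3, v), pb_int(20, 2))
}
onnx_attr_string <- function(name, s) {
  c(pb_string(1, name), pb_bytes(4, charToRaw(s)), pb_int(20, 3))
}

# NodeProto: input=1, output=2, name=3, op_type=4, attribute=5
onnx_node <- function(op_type, inputs, output, name = output, attrs = list()) {
  body <- raw(0)
  for (i in inputs) body <- c(body, pb_string(1, i))
  body <- c(body, pb_string(2, output), pb_string(3, name),
            pb_string(4, op_type))
  for (a in attrs) body <- c(body, pb_bytes(5, a))
  body
}

# ValueInfoProto with a float tensor type and concrete dims
onnx_value_info <- function(name, dims) {
  dim_msgs <- do.call(c, lapply(dims, function(d) pb_bytes(1, pb_int(1, d))))
  shape <- dim_msgs
  tensor <- c(pb_int(1, 1), pb_bytes(2, shape))
  type <- pb_bytes(1, tensor)
  c(pb_string(1, name), pb_bytes(2, type))
}

# assemble the U-Net graph in NCHW layout
onnx_build_graph <- function(params, cfg, input_h, input_w) {
  nodes <- list()
  inits <- list()
  conv_attrs3 <- list(onnx_attr_ints("kernel_shape", c(3, 3)),
                      onnx_attr_ints("pads", c(1, 1, 1, 1)),
                      onnx_attr_ints("strides", c(1, 1)))
  add_conv <- function(x, pname, out, k = 3) {
    w <- params[[paste0(pname, ".w")]]
    b <- params[[paste0(pname, ".b")]]
    wn <- paste0(pname, ".w"); bn <- paste0(pname, ".b")
    inits[[wn]] <<- onnx_tensorproto(wn, aperm(w, c(4, 3, 1, 2)))
    inits[[bn]] <<- onnx_tensorproto(bn, b)
    attrs <- if (k == 3) conv_attrs3 else
      list(onnx_attr_ints("kernel_shape", c(1, 1)),
           onnx_attr_ints("pads", c(0, 0, 0, 0)),
           onnx_attr_ints("strides", c(1, 1)))
    nodes[[length(nodes) + 1]] <<- onnx_node("Conv", c(x, wn, bn), out,
                                             attrs = attrs)
    out
  }
  add_relu <- function(x, out) {
    nodes[[length(nodes) + 1]] <<- onnx_node("Relu", x, out)
    out
  }
  d <- cfg$depth
  x <- "input"
  skips <- character(d)
  for (i in seq_len(d)) {
    x <- add_relu(add_conv(x, paste0("enc", i, ".c1"),
                           paste0("enc", i, "_c1")),
                  paste0("enc", i, "_c1r"))
    x <- add_relu(add_conv(x, paste0("enc", i, ".c2"),
                           paste0("enc", i, "_c2")),
                  paste0("enc", i, "_c2r"))
    skips[i] <- x
    out <- paste0("pool", i)
    nodes[[length(nodes) + 1]] <- onnx_node(
      "MaxPool", x, out,
      attrs = list(onnx_attr_ints("kernel_shape", c(2, 2)),
                   onnx_attr_ints("strides", c(2, 2))))
    x <- out
  }
  x <- add_relu(add_conv(x, "bot.c1", "bot_c1"), "bot_c1r")
  x <- add_relu(add_conv(x, "bot.c2", "bot_c2"), "bot_c2r")
  for (i in rev(seq_len(d))) {
    wn <- paste0("dec", i, ".up.w"); bn <- paste0("dec", i, ".up.b")
    w <- params[[wn]]
    inits[[wn]] <- onnx_tensorproto(wn, aperm(w, c(3, 4, 1, 2)))
    inits[[bn]] <- onnx_tensorproto(bn, params[[bn]])
    up <- paste0("up", i)
    nodes[[length(nodes) + 1]] <- onnx_node(
      "ConvTranspose", c(x, wn, bn), up,
      attrs = list(onnx_attr_ints("kernel_shape", c(2, 2)),
                   onnx_attr_ints("strides", c(2, 2))))
    cat_out <- paste0("cat", i)
    nodes[[length(nodes) + 1]] <- onnx_node(
      "Concat", c(up, skips[i]), cat_out,
      attrs = list(onnx_attr_int("axis", 1)))
    x <- add_relu(add_conv(cat_out, paste0("dec", i, ".c1"),
                           paste0("dec", i, "_c1")),
                  paste0("dec", i, "_c1r"))
    x <- add_relu(add_conv(x, paste0("dec", i, ".c2"),
                           paste0("dec", i, "_c2")),
                  paste0("dec", i, "_c2r"))
  }
  x <- add_conv(x, "head", "logits", k = 1)
  nodes[[length(nodes) + 1]] <- onnx_node("Sigmoid", x, "prob")

  body <- raw(0)
  for (n in nodes) body <- c(body, pb_bytes(1, n))
  body <- c(body, pb_string(2, "unet_boundary_segmentation"))
  for (t in inits) body <- c(body, pb_bytes(5, t))
  body <- c(body,
            pb_bytes(11, onnx_value_info("input", c(1, 1, input_h, input_w))),
            pb_bytes(12, onnx_value_info("prob", c(1, 1, input_h, input_w))))
  body
}

#' Export a trained network to ONNX
#'
#' Serialises the U-Net (weights as float32, NCHW layout, opset 13) to a
#' standalone `.onnx` file with a declared `1 x 1 x H x W` input and a
#' sigmoid probability output.  The file can be consumed by any ONNX
#' runtime (and, downstream, compiled to a TensorRT engine — that
#' hardware-specific step is outside this package); [onnx_parity()] checks
#' numerical agreement against the native forward pass using the package's
#' built-in ONNX reader.
#'
#' @param object A fitted [pseudoseg()] model or [pseudoseg_pretrain()]
#'   state.
#' @param path Output `.onnx` file path.
#' @param input_h,input_w Declared input size (defaults 64 x 128; the
#'   network itself is fully convolutional).
#' @return `path`, invisibly.
#' @export
export_onnx <- function(object, path, input_h = 64, input_w = 128) {
  stopifnot(inherits(object, c("pseudoseg", "pseudoseg_pretrain")))
  graph <- onnx_build_graph(object$params, object$model, input_h, input_w)
  opset <- c(pb_string(1, ""), pb_int(2, 13))
  model <- c(pb_int(1, 8),                       # ir_version
             pb_string(2, "pseudosegrt"),        # producer_name
             pb_string(3, "0.1.0"),
             pb_bytes(7, graph),
             pb_bytes(8, opset))
  writeBin(model, path)
  invisible(path)
}
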