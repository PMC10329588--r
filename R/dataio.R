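# Reading, writing and transforming scans and masks.  Images are plain R
# matrices indexed [row, column] with row 1 at the top of the B-scan
# (vitreous side); EBImage's (x, y) layout is transposed at the boundary.

as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

#' Collapse a multi-layer label map to a binary tissue mask
#'
#' Retinal layer annotations label each pixel with 0 (background) or a
#' layer index 1..K ordered from the internal limiting membrane down to
#' Bruch's membrane.  The boundary-segmentation task only needs tissue vs
#' background, so every layer collapses to 1.
#'
#' @param layers Integer matrix over `{0, ..., n_layers}`.
#' @param n_layers Number of retinal layers in the annotation (default 8).
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarise_layers <- function(layers, n_layers = 8) {
  stopifnot(is.matrix(layers))
  v <- as.vector(layers)
  if (anyNA(v) || any(v != floor(v)) || any(v < 0) || any(v > n_layers)) {
    stop("layer labels must be integers in 0..", n_layers)
  }
  matrix(as.integer(layers > 0), nrow(layers), ncol(layers))
}

#' Resize a scan/mask pair
#'
#' The scan is resampled bilinearly; the mask with nearest-neighbour so its
#' value set stays within `{0, 1}`.
#'
#' @param scan Numeric matrix in `[0, 1]`.
#' @param mask Integer 0/1 matrix of the same shape.
#' @param target_h,target_w Output size in pixels.
#' @return A list with resized `scan` and `mask`.
#' @export
resize_pair <- function(scan, mask, target_h, target_w) {
  stopifnot(target_h >= 1, target_w >= 1, all(dim(scan) == dim(mask)))
  s <- EBImage::resize(as_ebimage(scan), w = target_w, h = target_h,
                       filter = "bilinear")
  m <- EBImage::resize(as_ebimage(mask), w = target_w, h = target_h,
                       filter = "none")
  scan_out <- pmin(pmax(from_ebimage(s), 0), 1)
  mask_out <- matrix(as.integer(from_ebimage(m) > 0.5), target_h, target_w)
  list(scan = scan_out, mask = mask_out)
}

#' Photometric/geometric training augmentation
#'
#' Applies the identical random rotation to scan and mask (angle magnitude
#' uniform in `angle_range` degrees, sign chosen uniformly) and a brightness
#' factor uniform in `brightness_range` to the scan only, clipping back to
#' `[0, 1]`.  Out-of-canvas pixels are filled with `fill` in the scan and
#' background (0) in the mask.  Setting `angle_range = c(0, 0)` and
#' `brightness_range = c(1, 1)` disables the augmentation (identity).
#'
#' @param scan,mask The pair to augment.
#' @param seed Optional integer; when given the draw is made under a private
#'   seeded RNG stream, otherwise the current stream is consumed.
#' @param angle_range Rotation magnitude range in degrees (default 10-20).
#' @param brightness_range Multiplicative brightness range (default 1-2).
#' @param fill Scan fill intensity for pixels rotated in from outside.
#' @return A list with augmented `scan` and `mask`.
#' @export
augment_pair <- function(scan, mask, seed = NULL,
                         angle_range = c(10, 20),
                         brightness_range = c(1, 2), fill = 0) {
  stopifnot(all(dim(scan) == dim(mask)))
  draw <- function() {
    list(angle = sample(c(-1, 1), 1) * stats::runif(1, angle_range[1], angle_range[2]),
         bright = stats::runif(1, brightness_range[1], brightness_range[2]))
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (d$angle != 0) {
    si <- as_ebimage(scan)
    scan <- from_ebimage(EBImage::rotate(si, d$angle, filter = "bilinear",
                                         output.dim = dim(si), bg.col = fill))
    mi <- as_ebimage(mask)
    mask_r <- from_ebimage(EBImage::rotate(mi, d$angle, filter = "none",
                                           output.dim = dim(mi), bg.col = 0))
    mask <- matrix(as.integer(mask_r > 0.5), nrow(mask_r), ncol(mask_r))
  }
  scan <- pmin(pmax(scan * d$bright, 0), 1)
  list(scan = scan, mask = mask)
}

#' Write a dataset split to disk as PNG images plus a manifest
#'
#' Scans are written as 8-bit grayscale PNG, masks as PNG with values
#' \{0, 255\} (mapped back to \{0, 1\} on read).  A `manifest.yaml` at the
#' root lists the relative scan/mask paths per split.
#'
#' @param split An `oct_split` (see [phantom_dataset()] / [label_split()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_oct_dataset <- function(split, dir) {
  stopifnot(inherits(split, "oct_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (sp in c("train", "train_labelled", "train_unlabelled", "val",
               "test", "shifted_test")) {
    items <- split[[sp]]
    if (is.null(items) || length(items) == 0) next
    spdir <- file.path(dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    entries <- vector("list", length(items))
    for (i in seq_along(items)) {
      scan_rel <- file.path(sp, sprintf("scan_%04d.png", i))
      EBImage::writeImage(as_ebimage(items[[i]]$scan),
                          file.path(dir, scan_rel), type = "png")
      entry <- list(scan = scan_rel)
      if (!is.null(items[[i]]$mask)) {
        mask_rel <- file.path(sp, sprintf("mask_%04d.png", i))
        EBImage::writeImage(as_ebimage(items[[i]]$mask * 1.0),
                            file.path(dir, mask_rel), type = "png")
        entry$mask <- mask_rel
      }
      if (!is.null(items[[i]]$meta$onh)) entry$onh <- items[[i]]$meta$onh
      entries[[i]] <- entry
    }
    manifest[[sp]] <- entries
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset split written by [write_oct_dataset()]
#'
#' @param dir Directory containing `manifest.yaml`.
#' @return An `oct_split` with the splits listed in the manifest.
#' @export
read_oct_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  out <- list()
  for (sp in names(manifest)) {
    out[[sp]] <- lapply(manifest[[sp]], function(e) {
      scan <- from_ebimage(EBImage::readImage(file.path(dir, e$scan)))
      item <- list(scan = pmin(pmax(scan, 0), 1))
      if (!is.null(e$mask)) {
        m <- from_ebimage(EBImage::readImage(file.path(dir, e$mask)))
        item$mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
      }
      item$meta <- list(onh = isTRUE(e$onh))
      item
    })
  }
  structure(out, class = "oct_split")
}
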