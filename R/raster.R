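#' @keywords internal
"_PACKAGE"

## Class codes. Integer codes keep label rasters as plain integer matrices,
## which every downstream operation indexes directly.

#' Class label codes
#'
#' Pixel classes for retinal artery/vein (AV) classification. Arteries and
#' veins are the two "vessel" classes; background is everything else.
#' `AV_TIE` is not a pixel class: it is the value returned by
#' [multiloss_judge()] when a segment has no majority class.
#'
#' @format Integer constants: `AV_ARTERY = 1L`, `AV_VEIN = 2L`,
#'   `AV_BACKGROUND = 3L`, `AV_TIE = 0L`.
#' @export
AV_ARTERY <- 1L

#' @rdname AV_ARTERY
#' @export
AV_VEIN <- 2L

#' @rdname AV_ARTERY
#' @export
AV_BACKGROUND <- 3L

#' @rdname AV_ARTERY
#' @export
AV_TIE <- 0L

#' @rdname AV_ARTERY
#' @param code integer class code(s)
#' @return `label_name()` returns the human-readable name of a class code.
#' @export
label_name <- function(code) {
  nm <- c("TIE", "ARTERY", "VEIN", "BACKGROUND")
  nm[match(code, c(AV_TIE, AV_ARTERY, AV_VEIN, AV_BACKGROUND))]
}

av_error <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("avrefine_", class), "avrefine_error")))
}

#' Label color palette
#'
#' RGB colors used to encode class labels as PNG images. The field
#' convention for AV classification labels paints arteries red, veins blue
#' and background yellow; pure RGB values are used so that PNG round-trips
#' are lossless. Third-party label sets with other colors can supply a
#' custom palette.
#'
#' @param artery,vein,background RGB triplets, 8-bit integers in 0..255.
#' @return An object of class `av_palette`: a 3x3 numeric matrix, one row
#'   per class in the order artery, vein, background.
#' @examples
#' av_palette()
#' av_palette(artery = c(200, 30, 30))
#' @export
av_palette <- function(artery = c(255, 0, 0),
                       vein = c(0, 0, 255),
                       background = c(255, 255, 0)) {
  pal <- rbind(artery = as.numeric(artery), vein = as.numeric(vein),
               background = as.numeric(background))
  if (ncol(pal) != 3L || any(pal < 0) || any(pal > 255))
    av_error("PaletteError", "palette colors must be RGB triplets in 0..255")
  d <- as.matrix(stats::dist(pal))
  if (any(d[upper.tri(d)] == 0))
    av_error("PaletteError", "palette colors must be pairwise distinct")
  structure(pal, class = "av_palette")
}

#' Construct a label raster
#'
#' A label raster is an integer matrix of class codes ([AV_ARTERY],
#' [AV_VEIN], [AV_BACKGROUND]), row-major with the origin at the top-left;
#' pixel coordinates are `(row, col)`.
#'
#' @param pixels integer matrix of class codes.
#' @return A `label_raster` (integer matrix).
#' @export
label_raster <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L)
    av_error("DimensionError", "label raster must be non-empty")
  if (!all(pixels %in% c(AV_ARTERY, AV_VEIN, AV_BACKGROUND)))
    av_error("LabelError", "label raster pixels must be AV_ARTERY, AV_VEIN or AV_BACKGROUND")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("label_raster", "matrix", "array"))
}

#' Construct a binary vessel mask
#'
#' @param pixels logical matrix, `TRUE` = vessel.
#' @return A `vessel_mask` (logical matrix).
#' @export
vessel_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L)
    av_error("DimensionError", "vessel mask must be non-empty")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) av_error("MaskError", "vessel mask must not contain NA")
  structure(pixels, class = c("vessel_mask", "matrix", "array"))
}

#' Construct a class-probability raster
#'
#' Per-pixel class probabilities `(p_artery, p_vein, p_background)`, as a
#' softmax layer of a pixel classifier would emit. Each triplet must sum to
#' one (tolerance 1e-6) with non-negative entries; violations are rejected
#' at construction.
#'
#' @param probs numeric array `height x width x 3`, planes ordered artery,
#'   vein, background.
#' @return A `prob_raster` (numeric array).
#' @export
prob_raster <- function(probs) {
  if (length(dim(probs)) != 3L || dim(probs)[3] != 3L)
    av_error("DimensionError", "probability raster must be a height x width x 3 array")
  if (any(probs < 0))
    av_error("ProbabilityError", "probabilities must be non-negative")
  s <- probs[, , 1L] + probs[, , 2L] + probs[, , 3L]
  if (max(abs(s - 1)) > 1e-6)
    av_error("ProbabilityError", "per-pixel probabilities must sum to 1 (tolerance 1e-6)")
  structure(probs, class = c("prob_raster", "array"))
}

#' @export
as.matrix.vessel_mask <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' @export
as.matrix.label_raster <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

raster_dim <- function(x) dim(x)[1:2]

check_same_dim <- function(a, b, what = "rasters") {
  if (!identical(raster_dim(a), raster_dim(b)))
    av_error("DimensionError",
             sprintf("%s have mismatched dimensions: %dx%d vs %dx%d",
                     what, nrow(a), ncol(a), nrow(b), ncol(b)))
  invisible(TRUE)
}

#' Decode an RGB image into a label raster
#'
#' Each pixel is assigned the class whose palette color is nearest in
#' Euclidean RGB distance. A tolerance absorbs lossy-compression artifacts
#' in third-party labels; any pixel farther than `tolerance` from all three
#' palette colors is an error.
#'
#' @param image numeric array `height x width x 3`, either in `[0, 1]`
#'   (as returned by [png::readPNG()]) or 8-bit in 0..255.
#' @param palette an [av_palette()].
#' @param tolerance maximum accepted Euclidean RGB distance (8-bit scale).
#' @return A [label_raster()].
#' @export
decode_label_raster <- function(image, palette = av_palette(), tolerance = 60) {
  if (length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    image <- image[, , 1:3, drop = FALSE]
  } else {
    av_error("DimensionError", "expected a 3-channel RGB image")
  }
  if (length(image) == 0L) av_error("DimensionError", "empty image")
  if (max(image) <= 1) image <- image * 255
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- matrix(image, nrow = h * w, ncol = 3L)
  ## squared distance to each palette color; argmin per pixel
  pal_dist2 <- function(k)
    rowSums((px - matrix(unclass(palette)[k, ], h * w, 3L, byrow = TRUE))^2)
  d2 <- cbind(pal_dist2(1L), pal_dist2(2L), pal_dist2(3L))
  best <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(h * w), best)])
  if (any(mind > tolerance))
    av_error("UnrecognizedColor",
             sprintf("%d pixel(s) farther than tolerance %g from all palette colors (max distance %.1f)",
                     sum(mind > tolerance), tolerance, max(mind)))
  label_raster(matrix(c(AV_ARTERY, AV_VEIN, AV_BACKGROUND)[best], h, w))
}

#' Encode a label raster as an RGB image
#'
#' Inverse of [decode_label_raster()]: a lossless round-trip for any
#' palette whose colors are more than twice the decoding tolerance apart.
#'
#' @param labels a [label_raster()].
#' @param palette an [av_palette()].
#' @return Numeric array `height x width x 3` in `[0, 1]`, suitable for
#'   [png::writePNG()].
#' @export
encode_label_raster <- function(labels, palette = av_palette()) {
  pal <- unclass(palette) / 255
  idx <- match(as.integer(labels), c(AV_ARTERY, AV_VEIN, AV_BACKGROUND))
  array(c(pal[idx, 1L], pal[idx, 2L], pal[idx, 3L]),
        c(nrow(labels), ncol(labels), 3L))
}

#' Threshold a probability raster into hard labels and a vessel mask
#'
#' A pixel is a vessel pixel iff `max(p_artery, p_vein) >= threshold`
#' (inclusive). Vessel pixels take the argmax class over artery/vein, with
#' ties going to the class named by `tie_class`; all other pixels are
#' background.
#'
#' @param probs a [prob_raster()].
#' @param threshold vessel-probability threshold in (0, 1); default 0.5.
#' @param tie_class class taking equal artery/vein probabilities
#'   (default [AV_ARTERY]).
#' @return A list with elements `labels` ([label_raster()]) and `mask`
#'   ([vessel_mask()]); the mask marks exactly the non-background pixels.
#' @export
binarize <- function(probs, threshold = 0.5, tie_class = AV_ARTERY) {
  if (threshold <= 0 || threshold >= 1)
    av_error("ThresholdError", "threshold must be in (0, 1)")
  d <- dim(probs)
  pa <- matrix(probs[, , 1L], d[1], d[2])
  pv <- matrix(probs[, , 2L], d[1], d[2])
  vessel <- pmax(pa, pv) >= threshold
  lab <- matrix(AV_BACKGROUND, nrow(pa), ncol(pa))
  a_wins <- if (tie_class == AV_ARTERY) pa >= pv else pa > pv
  lab[vessel & a_wins] <- AV_ARTERY
  lab[vessel & !a_wins] <- AV_VEIN
  list(labels = label_raster(lab), mask = vessel_mask(vessel))
}

## ---- file IO -------------------------------------------------------------

#' Read and write label rasters, masks and probability rasters
#'
#' Label rasters travel as 8-bit RGB PNG under the palette color
#' convention; vessel masks as 8-bit grayscale PNG (0 = background,
#' 255 = vessel); probability rasters as 3-channel 32-bit float TIFF with
#' planes ordered artery, vein, background.
#'
#' @param path file path.
#' @param labels,mask,probs objects to write.
#' @param palette an [av_palette()].
#' @param tolerance decoding tolerance, see [decode_label_raster()].
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
read_label_png <- function(path, palette = av_palette(), tolerance = 60) {
  decode_label_raster(png::readPNG(path), palette, tolerance)
}

#' @rdname raster_io
#' @export
write_label_png <- function(labels, path, palette = av_palette()) {
  png::writePNG(encode_label_raster(labels, palette), path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  vessel_mask(img >= 0.5)
}

#' @rdname raster_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_prob_tiff <- function(path) {
  arr <- tiff::readTIFF(path)
  ## float32 storage can drift triplet sums by ~1e-7; renormalize
  s <- arr[, , 1L] + arr[, , 2L] + arr[, , 3L]
  prob_raster(arr / array(rep(s, 3L), dim(arr)))
}

#' @rdname raster_io
#' @export
write_prob_tiff <- function(probs, path) {
  tiff::writeTIFF(unclass(probs), path, bits.per.sample = 32L)
  invisible(path)
}
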