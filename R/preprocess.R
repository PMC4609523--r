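#' Construct an image cutout
#'
#' A square three-channel (RGB) raster centered on a candidate object,
#' together with its pixel resolution. Pixel areas of 1.0, 0.5 and
#' 0.25 um^2 correspond to the 10x, 20x and 40x objectives of the source
#' imaging setup.
#'
#' @param pixels Numeric H x W x 3 array with values in \[0, 1\]
#'   (red, green, blue), H == W.
#' @param pixel_area Area in um^2 covered by one pixel (positive).
#' @param cutout_id Identifier string.
#' @return An object of class `cutout`.
#' @export
cutout <- function(pixels, pixel_area, cutout_id = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] != dim(pixels)[2])
    stop("cutouts must be square", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_area) || pixel_area <= 0)
    stop("pixel_area must be positive", call. = FALSE)
  structure(list(pixels = pixels, pixel_area = pixel_area,
                 cutout_id = as.character(cutout_id)),
            class = "cutout")
}

#' @export
print.cutout <- function(x, ...) {
  cat(sprintf("cutout '%s': %d x %d px, %.2f um^2/px\n", x$cutout_id,
              dim(x$pixels)[1], dim(x$pixels)[2], x$pixel_area))
  invisible(x)
}

#' Read / write cutout images
#'
#' PNG (via the png package) or TIFF (via the tiff package, if
#' installed); 8- or 16-bit images are rescaled to \[0, 1\] on load. The
#' pixel resolution is not stored in the image file and must be supplied
#' (typically from a metadata sidecar).
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param pixel_area Pixel area in um^2.
#' @param cutout_id Identifier; defaults to the file name.
#' @return A [cutout()].
#' @export
read_cutout <- function(path, pixel_area, cutout_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (is.null(cutout_id)) cutout_id <- tools::file_path_sans_ext(basename(path))
  cutout(px, pixel_area, cutout_id)
}

#' @param x A [cutout()].
#' @rdname read_cutout
#' @export
write_cutout <- function(x, path) {
  stopifnot(inherits(x, "cutout"))
  png::writePNG(x$pixels, path)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param region_area Physical area of the centered crop in um^2
#'   (default 2500, i.e. a 50 um x 50 um field).
#' @param sigma Gaussian smoothing standard deviation in original-
#'   resolution pixels (default 1).
#' @param target_side Side length of the downsampled raster in pixels
#'   (default 50); the feature vector has `2 * target_side^2` entries.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(region_area = 2500, sigma = 1, target_side = 50) {
  stopifnot(region_area > 0, sigma >= 0, target_side >= 1)
  structure(list(region_area = region_area, sigma = sigma,
                 target_side = as.integer(target_side)),
            class = "preprocess_config")
}

#' Crop side length for a physical region
#'
#' @param region_area Region area in um^2.
#' @param pixel_area Pixel area in um^2.
#' @return Side length in pixels: `round(sqrt(region_area / pixel_area))`.
#' @export
#' @examples
#' crop_side(2500, c(0.25, 0.5, 1.0))  # 100 71 50
crop_side <- function(region_area, pixel_area) {
  as.integer(round(sqrt(region_area / pixel_area)))
}

#' Centered crop to a fixed physical region
#'
#' Normalizes cutouts taken at different magnifications to cover the same
#' physical region (default 2500 um^2) around the raster center, so a
#' 40x/20x/10x image becomes a 100/71/50-pixel square.
#'
#' @param x A [cutout()].
#' @param region_area Region area in um^2.
#' @return A [cutout()] with the cropped raster.
#' @export
crop_to_region <- function(x, region_area = 2500) {
  stopifnot(inherits(x, "cutout"))
  side <- crop_side(region_area, x$pixel_area)
  n <- dim(x$pixels)[1]
  if (side > n)
    stop(sprintf("requested region (%d px) exceeds raster (%d px)", side, n),
         call. = FALSE)
  # centered window; for odd remainders the extra pixel goes to the end
  start <- floor((n - side) / 2) + 1L
  idx <- seq.int(start, start + side - 1L)
  cutout(x$pixels[idx, idx, , drop = FALSE], x$pixel_area, x$cutout_id)
}

#' Discrete isotropic Gaussian kernel
#'
#' Normalized 2-D Gaussian on a (2r+1)^2 support with r = ceiling(3
#' sigma); separable outer product of sampled 1-D Gaussians.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @return A numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(seq.int(-r, r), sd = sigma)
  g <- g / sum(g)
  outer(g, g)
}

#' Gaussian smoothing of a cutout
#'
#' Convolves each channel independently with an isotropic Gaussian
#' (replicated image borders), suppressing high-frequency noise before
#' downsampling; output clipped to \[0, 1\]. `sigma = 0` is the identity.
#'
#' @param x A [cutout()].
#' @param sigma Standard deviation in pixels (>= 0).
#' @return A smoothed [cutout()].
#' @export
gaussian_smooth <- function(x, sigma = 1) {
  stopifnot(inherits(x, "cutout"))
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(x)
  k <- gaussian_kernel(sigma)
  px <- x$pixels
  for (ch in 1:3)
    px[, , ch] <- EBImage::filter2(x$pixels[, , ch], k, boundary = "replicate")
  cutout(clip01(px), x$pixel_area, x$cutout_id)
}

#' Bilinear downsampling to a fixed raster size
#'
#' Resamples the (already smoothed) cutout to `target_side` pixels per
#' side so feature vectors have fixed dimension regardless of source
#' magnification. Upsampling is refused.
#'
#' @param x A [cutout()].
#' @param target_side Target side length in pixels.
#' @return A resampled [cutout()].
#' @export
downsample <- function(x, target_side = 50) {
  stopifnot(inherits(x, "cutout"))
  n <- dim(x$pixels)[1]
  target_side <- as.integer(target_side)
  if (target_side > n)
    stop("target side exceeds source side; upsampling not supported",
         call. = FALSE)
  if (target_side == n) return(x)
  px <- EBImage::resize(x$pixels, w = target_side, h = target_side,
                        filter = "bilinear")
  cutout(clip01(px), x$pixel_area, x$cutout_id)
}

#' Hue/saturation feature vector of a cutout
#'
#' Converts the RGB raster to HSV, drops the V (intensity) channel, and
#' vectorizes the H and S planes row-major into a single feature vector:
#' all hue values first, then all saturation values. For a 50 x 50 raster
#' this gives 5000 entries, all in \[0, 1\]. Achromatic pixels (S = 0)
#' get hue 0. Hue is kept as a plain real in \[0, 1); the wraparound of
#' reds (H near 0 vs. near 1) is a known representational artifact.
#'
#' @param x A [cutout()].
#' @param expected_side If non-`NULL`, the raster side is checked against
#'   it (default 50, the standard classifier input size).
#' @return Numeric feature vector of length `2 * side^2`, named
#'   `H0001.. S0001..`.
#' @export
to_hue_saturation <- function(x, expected_side = 50) {
  stopifnot(inherits(x, "cutout"))
  side <- dim(x$pixels)[1]
  if (!is.null(expected_side) && side != expected_side)
    stop(sprintf("expected a %d x %d raster, got %d x %d",
                 expected_side, expected_side, side, side), call. = FALSE)
  # row-major scan of each plane
  r <- as.vector(t(x$pixels[, , 1]))
  g <- as.vector(t(x$pixels[, , 2]))
  b <- as.vector(t(x$pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 1)
  out <- c(hsv["h", ], hsv["s", ])
  names(out) <- c(sprintf("H%04d", seq_len(side^2)),
                  sprintf("S%04d", seq_len(side^2)))
  out
}

#' Full preprocessing pipeline
#'
#' Crop to the configured physical region, Gaussian-smooth, downsample to
#' the target raster, and vectorize hue and saturation. Deterministic.
#'
#' @param x A [cutout()].
#' @param cfg A [preprocess_config()].
#' @return Numeric feature vector of length `2 * cfg$target_side^2`.
#' @export
preprocess <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  x <- crop_to_region(x, cfg$region_area)
  x <- gaussian_smooth(x, cfg$sigma)
  x <- downsample(x, cfg$target_side)
  to_hue_saturation(x, expected_side = cfg$target_side)
}

#' Preprocess a list of cutouts into a feature matrix
#'
#' @param cutouts List of [cutout()] objects.
#' @param cfg A [preprocess_config()].
#' @return Numeric matrix, one row per cutout (row names = cutout ids),
#'   columns `H0001..` then `S0001..`.
#' @export
preprocess_batch <- function(cutouts, cfg = preprocess_config()) {
  feats <- t(vapply(cutouts, preprocess, cfg = cfg,
                    FUN.VALUE = numeric(2 * cfg$target_side^2)))
  rownames(feats) <- vapply(cutouts, function(x) x$cutout_id, character(1))
  feats
}
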