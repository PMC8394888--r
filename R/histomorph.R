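# Collagen morphometry in Masson's-trichrome sections: tissue segmentation,
# colour-threshold collagen mask, stained fraction and physical area.

#' Segment the biopsy specimen from the background
#'
#' Foreground = pixels darker than the bright slide background (mean-channel
#' lightness below `bg_lightness`), reduced to the largest connected
#' component. The specimen mask is the denominator of the collagen fraction.
#'
#' @param img 8-bit RGB image array.
#' @param bg_lightness background lightness threshold on the 0..1 scale
#'   (default 0.9); pixels with mean-channel value below it are candidate
#'   tissue.
#' @return logical matrix specimen mask.
#' @export
segment_specimen <- function(img, bg_lightness = 0.9) {
  check_image8(img)
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / (3 * 255)
  fg <- lum < bg_lightness
  if (!any(fg)) stop("segment_specimen: no foreground found (empty specimen)")
  labels <- EBImage::bwlabel(fg)
  sizes <- tabulate(labels[labels > 0])
  labels == which.max(sizes)
}

#' Colour threshold specification for collagen
#'
#' HSV bounds for aniline-blue staining plus a minimum object size for
#' morphological cleanup. Hue is on the 0..1 scale (blue near 0.6). The
#' defaults were fixed once against the synthetic trichrome phantom.
#'
#' @param h_range,s_range,v_range HSV bounds (each length 2, low <= high).
#' @param min_size_px connected components smaller than this are dropped.
#' @return list of class `threshold_spec`.
#' @export
threshold_spec <- function(h_range = c(0.50, 0.78), s_range = c(0.25, 1),
                           v_range = c(0.10, 0.95), min_size_px = 8) {
  for (r in list(h_range, s_range, v_range))
    if (length(r) != 2 || r[1] > r[2]) stop("threshold_spec: bounds must satisfy low <= high")
  if (min_size_px < 0) stop("threshold_spec: min size must be >= 0")
  structure(list(h_range = h_range, s_range = s_range, v_range = v_range,
                 min_size_px = min_size_px),
            class = "threshold_spec")
}

#' Collagen mask by colour-threshold filtering
#'
#' Marks pixels whose HSV colour lies inside the threshold bounds and inside
#' the specimen mask, then removes connected components smaller than the
#' cleanup size.
#'
#' @param img 8-bit RGB image array.
#' @param spec a [threshold_spec()].
#' @param specimen_mask logical matrix from [segment_specimen()].
#' @return logical matrix collagen mask (subset of the specimen mask).
#' @export
collagen_mask <- function(img, spec = threshold_spec(), specimen_mask) {
  check_image8(img)
  stopifnot(inherits(spec, "threshold_spec"))
  if (!all(dim(specimen_mask) == dim(img)[1:2]))
    stop("collagen_mask: specimen mask and image dimensions differ")
  hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                  as.vector(img[, , 2]),
                                  as.vector(img[, , 3])), maxColorValue = 255)
  within <- hsv["h", ] >= spec$h_range[1] & hsv["h", ] <= spec$h_range[2] &
    hsv["s", ] >= spec$s_range[1] & hsv["s", ] <= spec$s_range[2] &
    hsv["v", ] >= spec$v_range[1] & hsv["v", ] <= spec$v_range[2]
  mask <- matrix(within, dim(img)[1], dim(img)[2]) & specimen_mask
  if (spec$min_size_px > 0 && any(mask)) {
    labels <- EBImage::bwlabel(mask)
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= spec$min_size_px)
    mask <- matrix(labels %in% keep, dim(mask)[1], dim(mask)[2])
  }
  mask
}

#' Collagen fraction and physical area
#'
#' fraction = stained pixels / specimen pixels; physical area from a
#' user-supplied pixel size (never inferred from magnification).
#'
#' @param mask logical collagen mask.
#' @param specimen_mask logical specimen mask (denominator).
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @return list of class `morphometry_result` with `fraction`, `area_mm2`,
#'   `n_collagen_px`, `n_specimen_px`.
#' @export
collagen_fraction <- function(mask, specimen_mask, pixel_size_um) {
  if (pixel_size_um <= 0) stop("collagen_fraction: pixel size must be positive")
  if (!all(dim(mask) == dim(specimen_mask)))
    stop("collagen_fraction: mask dimensions differ")
  n_spec <- sum(specimen_mask)
  if (n_spec == 0) stop("collagen_fraction: empty specimen mask")
  n_col <- sum(mask & specimen_mask)
  structure(list(
    fraction = n_col / n_spec,
    area_mm2 = n_col * (pixel_size_um / 1000)^2,
    n_collagen_px = n_col, n_specimen_px = n_spec),
    class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> collagen fraction %.3f (%d / %d px), area %.4f mm2\n",
              x$fraction, x$n_collagen_px, x$n_specimen_px, x$area_mm2))
  invisible(x)
}

#' Full trichrome quantification
#'
#' Convenience wrapper: specimen segmentation, colour-threshold collagen
#' mask, fraction and area.
#'
#' @param img 8-bit RGB image array.
#' @param pixel_size_um pixel size (um/px).
#' @param spec a [threshold_spec()].
#' @param bg_lightness passed to [segment_specimen()].
#' @return `morphometry_result` with the masks attached as attributes
#'   `collagen_mask` and `specimen_mask`.
#' @export
quantify_trichrome <- function(img, pixel_size_um, spec = threshold_spec(),
                               bg_lightness = 0.9) {
  specimen <- segment_specimen(img, bg_lightness)
  mask <- collagen_mask(img, spec, specimen)
  res <- collagen_fraction(mask, specimen, pixel_size_um)
  attr(res, "collagen_mask") <- mask
  attr(res, "specimen_mask") <- specimen
  res
}
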