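# Erythema colorimetry: white-balance correction against a neutral phantom,
# RGB -> CIELAB conversion, ROI a* statistics and the relative erythema index
# delta a* = (a*_AS - a*_NS) / a*_NS * 100.
#
# Images are numeric arrays [rows, cols, 3] holding 8-bit values on the
# 0..255 scale. ROI rectangles use 0-based, half-open pixel coordinates
# [x0, x1) x [y0, y1) with x along columns and y along rows.

#' ROI rectangle
#'
#' 0-based, half-open rectangle `[x0, x1) x [y0, y1)`; x indexes columns,
#' y indexes rows (pixel-centre convention).
#'
#' @param x0,y0 inclusive top-left corner.
#' @param x1,y1 exclusive bottom-right corner.
#' @return list of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0) stop("roi_rect: rectangle must have positive extent")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "roi_rect")
}

roi_check <- function(img_dim, roi) {
  stopifnot(inherits(roi, "roi_rect"))
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > img_dim[2] || roi$y1 > img_dim[1])
    stop("roi outside image bounds")
  invisible(roi)
}

roi_slab <- function(plane, roi) {
  plane[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, drop = FALSE]
}

rois_overlap <- function(a, b) {
  a$x0 < b$x1 && b$x0 < a$x1 && a$y0 < b$y1 && b$y0 < a$y1
}

check_image8 <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an RGB image array [rows, cols, 3]")
  if (!is.numeric(img) || any(!is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop("expected 8-bit RGB values on the 0..255 scale")
  invisible(img)
}

#' White-balance correction against a neutral phantom
#'
#' Estimates per-channel gains from a white phantom placed in the frame: each
#' channel is scaled so the phantom ROI's channel means become equal (a
#' neutral gray at the phantom's mean luminance). Gains are recorded in the
#' `wb_gains` attribute of the result.
#'
#' @param img 8-bit RGB image array.
#' @param phantom_roi [roi_rect()] covering the phantom.
#' @return Corrected image (clipped to 0..255) with attribute `wb_gains`.
#' @export
white_balance_correct <- function(img, phantom_roi) {
  check_image8(img)
  roi_check(dim(img), phantom_roi)
  m <- vapply(1:3, function(ch) mean(roi_slab(img[, , ch], phantom_roi)), numeric(1))
  if (any(m >= 254))
    stop("white_balance_correct: phantom is saturated; gains unidentifiable")
  if (any(m <= 0))
    stop("white_balance_correct: phantom channel mean is zero")
  gains <- mean(m) / m
  out <- img
  for (ch in 1:3) out[, , ch] <- pmin(255, pmax(0, img[, , ch] * gains[ch]))
  attr(out, "wb_gains") <- gains
  out
}

# sRGB primaries -> XYZ (D65) matrix
.rgb2xyz_m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     nrow = 3, byrow = TRUE)

.white_point <- function(white) {
  switch(white,
         # D65 as the exact row sums of the primaries matrix, so neutral
         # inputs map to a* = b* = 0 to machine precision
         D65 = rowSums(.rgb2xyz_m),
         D50 = c(0.96422, 1.00000, 0.82521),
         stop("white must be 'D65' or 'D50'"))
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert an 8-bit RGB image to CIELAB
#'
#' Channels are normalised to \[0, 1\] and by default treated as linear RGB
#' (the acquisition protocol disables in-camera gamma correction), mapped
#' through the standard linear-RGB -> XYZ matrix (sRGB primaries, D65), then
#' the standard XYZ -> L*a*b* transform with the chosen reference white,
#' including the two-branch cube-root/linear companding function. Set
#' `gamma = "srgb"` to apply the sRGB decoding curve first.
#'
#' @param img 8-bit RGB image array (0..255).
#' @param gamma `"linear"` (default) or `"srgb"`.
#' @param white reference white, `"D65"` (default) or `"D50"`.
#' @return list of class `lab_image` with matrices `L`, `a`, `b` and a
#'   `provenance` record of the conversion parameters.
#' @export
rgb_to_lab <- function(img, gamma = c("linear", "srgb"), white = c("D65", "D50")) {
  gamma <- match.arg(gamma); white <- match.arg(white)
  check_image8(img)
  d <- dim(img)
  v <- matrix(img, ncol = 3) / 255  # pixels x 3
  if (gamma == "srgb")
    v <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- v %*% t(.rgb2xyz_m)
  wp <- .white_point(white)
  fx <- .lab_f(xyz[, 1] / wp[1])
  fy <- .lab_f(xyz[, 2] / wp[2])
  fz <- .lab_f(xyz[, 3] / wp[3])
  structure(list(
    L = matrix(116 * fy - 16, d[1], d[2]),
    a = matrix(500 * (fx - fy), d[1], d[2]),
    b = matrix(200 * (fy - fz), d[1], d[2]),
    provenance = list(gamma = gamma, white = white)),
    class = "lab_image")
}

# Inverse of rgb_to_lab for a single Lab triple; used by the image phantom
# generator to paint a target a* shift in the space it is measured in.
lab_to_rgb1 <- function(L, a, b, gamma = "linear", white = "D65") {
  wp <- .white_point(white)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- c(.lab_finv(fx) * wp[1], .lab_finv(fy) * wp[2], .lab_finv(fz) * wp[3])
  v <- as.numeric(solve(.rgb2xyz_m) %*% xyz)
  if (gamma == "srgb")
    v <- ifelse(v <= 0.0031308, v * 12.92, 1.055 * v^(1 / 2.4) - 0.055)
  v * 255
}

#' Mean a* over a region of interest
#'
#' @param lab a `lab_image`.
#' @param roi [roi_rect()] inside the image.
#' @return arithmetic mean of the a* plane over the ROI.
#' @export
roi_mean_astar <- function(lab, roi) {
  stopifnot(inherits(lab, "lab_image"))
  roi_check(dim(lab$a), roi)
  mean(roi_slab(lab$a, roi))
}

#' Relative erythema index
#'
#' delta a* = (a*_AS - a*_NS) / a*_NS * 100, in percent, where a*_AS is the
#' mean a* of the irradiated (affected) skin ROI and a*_NS that of intact
#' skin. The index is ill-conditioned when the intact-skin a* is near zero;
#' values below `floor` in magnitude raise an error.
#'
#' @param a_as mean a* of the irradiated ROI.
#' @param a_ns mean a* of the intact ROI.
#' @param floor minimum |a_ns| accepted (default 0.5).
#' @return relative index in percent.
#' @export
relative_erythema_index <- function(a_as, a_ns, floor = 0.5) {
  if (abs(a_ns) < floor)
    stop("relative_erythema_index: intact-skin a* below conditioning floor")
  (a_as - a_ns) / a_ns * 100
}

#' Per-animal relative erythema index
#'
#' Averages delta a* over four 40x40-pixel irradiated ROIs from one photo of
#' one animal, each computed against the same intact-skin ROI on the
#' non-irradiated right dorsum.
#'
#' @param lab a `lab_image`.
#' @param irradiated_rois list of [roi_rect()] (4 unless `n_expected`
#'   overridden).
#' @param intact_roi intact-skin [roi_rect()].
#' @param n_expected required number of irradiated ROIs (default 4).
#' @param floor passed to [relative_erythema_index()].
#' @return list with `delta_a` (mean), `per_roi` (vector), `a_as` (per-ROI
#'   means), `a_ns`.
#' @export
per_animal_delta_a <- function(lab, irradiated_rois, intact_roi,
                               n_expected = 4, floor = 0.5) {
  if (length(irradiated_rois) != n_expected)
    stop(sprintf("per_animal_delta_a: expected %d irradiated ROIs, got %d",
                 n_expected, length(irradiated_rois)))
  if (any(vapply(irradiated_rois, rois_overlap, TRUE, b = intact_roi)))
    warning("per_animal_delta_a: irradiated ROI overlaps the intact ROI")
  a_ns <- roi_mean_astar(lab, intact_roi)
  a_as <- vapply(irradiated_rois, function(r) roi_mean_astar(lab, r), numeric(1))
  per_roi <- vapply(a_as, relative_erythema_index, numeric(1),
                    a_ns = a_ns, floor = floor)
  list(delta_a = mean(per_roi), per_roi = per_roi, a_as = a_as, a_ns = a_ns)
}

#' Tukey HSD pairwise comparisons
#'
#' One-way ANOVA followed by Tukey's honest significant difference using the
#' studentized-range distribution; returns all pairwise comparisons. Used to
#' compare per-animal delta a* across study days within a dose group, and
#' across dose groups within a day.
#'
#' @param values numeric responses (e.g. per-animal delta a*).
#' @param groups factor or character group labels, >= 2 groups with n >= 2
#'   each.
#' @return data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_pairwise <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("tukey_pairwise: need at least 2 groups")
  n_by <- table(groups)
  if (any(n_by < 2)) stop("tukey_pairwise: every group needs n >= 2")
  if (all(tapply(values, groups, stats::sd) == 0))
    stop("tukey_pairwise: zero within-group variance everywhere")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}
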