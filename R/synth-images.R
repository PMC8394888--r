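# Image phantoms with known ground truth: a dorsum photograph with a
# controllable erythema shift on the irradiated left half plus a neutral
# white phantom patch, and a Masson's-trichrome section with a known
# aniline-blue collagen fraction.

#' Dorsum image phantom configuration
#'
#' Emulates the acute-erythema acquisition: raw 8-bit RGB, the left half of
#' the dorsum irradiated, the right half intact, and a white phantom evenly
#' scattering visible light placed in the frame for manual white balance.
#' The erythema is painted as a shift of the a* plane applied in Lab space
#' and converted back to RGB, so the target is defined in the same space in
#' which it is measured.
#'
#' @param width,height image size in pixels.
#' @param base_skin_rgb length-3, intact-skin colour (0..255).
#' @param erythema_delta_a_target target relative erythema index, percent
#'   (>= -100).
#' @param phantom_level neutral gray level of the phantom patch.
#' @param phantom_roi [roi_rect()] for the phantom patch, or `NULL` to place
#'   a patch near the top of the frame automatically.
#' @param noise_sd pixel Gaussian noise SD in digital counts.
#' @param seed integer seed.
#' @return list of class `dorsum_config`.
#' @export
dorsum_config <- function(width = 320, height = 240,
                          base_skin_rgb = c(190, 130, 110),
                          erythema_delta_a_target = 20,
                          phantom_level = 210,
                          phantom_roi = NULL,
                          noise_sd = 1.5, seed = 1L) {
  if (erythema_delta_a_target < -100)
    stop("dorsum_config: target delta a* must be >= -100")
  if (is.null(phantom_roi))
    phantom_roi <- roi_rect(round(width * 0.40), round(height * 0.03),
                            round(width * 0.60), round(height * 0.17))
  cfg <- list(width = width, height = height, base_skin_rgb = base_skin_rgb,
              erythema_delta_a_target = erythema_delta_a_target,
              phantom_level = phantom_level, phantom_roi = phantom_roi,
              noise_sd = noise_sd, seed = as.integer(seed))
  roi_check(c(height, width), phantom_roi)
  structure(cfg, class = "dorsum_config")
}

#' Generate a dorsum photograph phantom
#'
#' The left half of the frame carries the irradiated (erythematous) skin
#' colour, the right half the intact colour, and the phantom patch a neutral
#' gray. Ground truth (target index, suggested 40x40 ROIs, phantom ROI) is
#' returned alongside the image. Colours pushed out of the 8-bit gamut by the
#' erythema shift are clipped with a warning.
#'
#' @param config a [dorsum_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `dorsum_phantom`: `image` (8-bit RGB array), `rois`
#'   (list: `irradiated` = 4 ROIs, `intact`, `phantom`), `target_delta_a`,
#'   `config`.
#' @export
generate_dorsum_image <- function(config = dorsum_config(), seed = NULL) {
  stopifnot(inherits(config, "dorsum_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  w <- config$width; h <- config$height
  base <- config$base_skin_rgb
  lab0 <- rgb_to_lab(array(rep(base, each = 1), c(1, 1, 3)))
  a_ns <- lab0$a[1, 1]
  a_as <- a_ns * (1 + config$erythema_delta_a_target / 100)
  ery <- lab_to_rgb1(lab0$L[1, 1], a_as, lab0$b[1, 1])
  if (any(ery < 0 | ery > 255)) {
    warning("generate_dorsum_image: erythema colour outside the 8-bit gamut; clipping")
    ery <- pmin(255, pmax(0, ery))
  }
  img <- array(0, c(h, w, 3))
  half <- floor(w / 2)
  for (ch in 1:3) {
    img[, 1:half, ch] <- ery[ch]          # irradiated left half
    img[, (half + 1):w, ch] <- base[ch]   # intact right half
    pr <- config$phantom_roi
    img[(pr$y0 + 1):pr$y1, (pr$x0 + 1):pr$x1, ch] <- config$phantom_level
  }
  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd), dim(img))
  img <- clamp8(img)

  # suggested 40x40 ROIs clear of the phantom patch
  irr <- list(roi_rect(10, 60, 50, 100), roi_rect(70, 60, 110, 100),
              roi_rect(10, 140, 50, 180), roi_rect(70, 140, 110, 180))
  intact <- roi_rect(half + 40, 100, half + 80, 140)
  structure(list(image = img,
                 rois = list(irradiated = irr, intact = intact,
                             phantom = config$phantom_roi),
                 target_delta_a = config$erythema_delta_a_target,
                 config = config),
            class = "dorsum_phantom")
}

#' Trichrome image phantom configuration
#'
#' Emulates a Masson's-trichrome stained section: a tissue region on a bright
#' background, with fiber-like collagen streaks stained aniline blue, the
#' rest of the tissue counterstained pink-red, and scattered dark nuclei.
#'
#' @param width,height image size in pixels.
#' @param true_collagen_fraction target collagen area fraction of the tissue,
#'   in \[0, 1\].
#' @param tissue_margin background border width around the tissue rectangle.
#' @param fiber_len,fiber_thick smoothing scales (px) of the fiber field
#'   along and across the fiber direction; their ratio sets fiber elongation.
#' @param blue_hsv,pink_rgb,nuclei_rgb stain colour parameters; `blue_hsv` is
#'   a list of `h`, `s`, `v` ranges sampled per pixel.
#' @param n_nuclei number of dark nuclei disks.
#' @param pixel_size_um physical pixel size (um/px).
#' @param noise_sd pixel Gaussian noise SD in counts.
#' @param seed integer seed.
#' @return list of class `trichrome_config`.
#' @export
trichrome_config <- function(width = 256, height = 256,
                             true_collagen_fraction = 0.37,
                             tissue_margin = 20,
                             fiber_len = 21, fiber_thick = 5,
                             blue_hsv = list(h = c(0.58, 0.66),
                                             s = c(0.55, 0.9),
                                             v = c(0.35, 0.7)),
                             pink_rgb = c(215, 140, 160),
                             nuclei_rgb = c(80, 30, 60),
                             n_nuclei = 40,
                             pixel_size_um = 2,
                             noise_sd = 3, seed = 1L) {
  if (true_collagen_fraction < 0 || true_collagen_fraction > 1)
    stop("trichrome_config: collagen fraction must lie in [0, 1]")
  if (pixel_size_um <= 0) stop("trichrome_config: pixel size must be positive")
  if (2 * tissue_margin >= min(width, height))
    stop("trichrome_config: margins leave no tissue region")
  structure(list(width = width, height = height,
                 true_collagen_fraction = true_collagen_fraction,
                 tissue_margin = tissue_margin, fiber_len = fiber_len,
                 fiber_thick = fiber_thick, blue_hsv = blue_hsv,
                 pink_rgb = pink_rgb, nuclei_rgb = nuclei_rgb,
                 n_nuclei = n_nuclei, pixel_size_um = pixel_size_um,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trichrome_config")
}

# clamp to the 8-bit range and round, preserving array dimensions
clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

# moving-average smoothing of a matrix along rows then columns (reflecting
# edges), producing an anisotropic correlated field
smooth_field <- function(m, kx, ky) {
  sm1 <- function(v, k) {
    if (k <= 1) return(v)
    n <- length(v)
    pad <- c(rev(v[seq_len(k)]), v, rev(v[n + 1 - seq_len(k)]))
    stats::filter(pad, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1):(k + n)]
  }
  m <- t(apply(m, 1, sm1, k = kx))
  apply(m, 2, sm1, k = ky)
}

#' Generate a trichrome histology phantom
#'
#' Collagen fibers are realised by thresholding an anisotropic smoothed
#' noise field inside the tissue region at the quantile matching the target
#' fraction, so the ground-truth mask hits the requested collagen fraction
#' exactly up to pixel quantization. Collagen pixels are coloured inside the
#' configured aniline-blue HSV range; the remaining tissue is pink with dark
#' nuclei disks.
#'
#' @param config a [trichrome_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `trichrome_phantom`: `image` (8-bit RGB array),
#'   `truth_mask` (logical matrix, collagen), `tissue_mask` (logical matrix),
#'   `config`.
#' @export
generate_trichrome_image <- function(config = trichrome_config(), seed = NULL) {
  stopifnot(inherits(config, "trichrome_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  w <- config$width; h <- config$height; m <- config$tissue_margin
  tissue <- matrix(FALSE, h, w)
  tissue[(m + 1):(h - m), (m + 1):(w - m)] <- TRUE

  frac <- config$true_collagen_fraction
  truth <- matrix(FALSE, h, w)
  if (frac >= 1) {
    truth[tissue] <- TRUE
  } else if (frac > 0) {
    field <- smooth_field(matrix(stats::rnorm(h * w), h, w),
                          kx = config$fiber_len %/% 2,
                          ky = config$fiber_thick %/% 2)
    vals <- field[tissue]
    n_tissue <- sum(tissue)
    # fibers = field above a threshold, despeckled (fragments < 8 px dropped);
    # bisect the threshold so the cleaned mask hits the target fraction
    mask_at <- function(thr) {
      m <- matrix(FALSE, h, w)
      m[tissue] <- field[tissue] > thr
      labels <- EBImage::bwlabel(m)
      sizes <- tabulate(labels[labels > 0])
      if (length(sizes)) m <- matrix(labels %in% which(sizes >= 8), h, w)
      m
    }
    lo <- stats::quantile(vals, max(0, 1 - 2 * frac), names = FALSE)
    hi <- max(vals)
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (sum(mask_at(mid)) / n_tissue > frac) lo <- mid else hi <- mid
    }
    truth <- mask_at((lo + hi) / 2)
    if (abs(sum(truth) / n_tissue - frac) > 0.01)
      stop("generate_trichrome_image: cannot place fibers to reach the target fraction")
  }

  img <- array(0, c(h, w, 3))
  bg <- 246
  for (ch in 1:3) img[, , ch] <- bg
  # pink counterstained tissue
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[tissue] <- config$pink_rgb[ch]
    img[, , ch] <- plane
  }
  # nuclei: small dark disks in the tissue
  if (config$n_nuclei > 0) {
    cx <- stats::runif(config$n_nuclei, m + 3, w - m - 3)
    cy <- stats::runif(config$n_nuclei, m + 3, h - m - 3)
    r <- stats::runif(config$n_nuclei, 1.5, 3)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    for (i in seq_len(config$n_nuclei)) {
      disk <- (xs - cx[i])^2 + (ys - cy[i])^2 <= r[i]^2 & tissue & !truth
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[disk] <- config$nuclei_rgb[ch]
        img[, , ch] <- plane
      }
    }
  }
  # aniline-blue collagen, per-pixel colour inside the configured HSV range
  n_col <- sum(truth)
  if (n_col > 0) {
    hsv_r <- config$blue_hsv
    cols <- grDevices::col2rgb(grDevices::hsv(
      stats::runif(n_col, hsv_r$h[1], hsv_r$h[2]),
      stats::runif(n_col, hsv_r$s[1], hsv_r$s[2]),
      stats::runif(n_col, hsv_r$v[1], hsv_r$v[2])))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[truth] <- cols[ch, ]
      img[, , ch] <- plane
    }
  }
  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd), dim(img))
  img <- clamp8(img)
  structure(list(image = img, truth_mask = truth, tissue_mask = tissue,
                 config = config),
            class = "trichrome_phantom")
}
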