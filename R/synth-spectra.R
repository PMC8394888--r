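# Forward model for synthetic emission spectra.
#
# Each channel is a sum of Gaussian emission peaks plus a backscatter residue:
# the detection filter attenuates the excitation line ~1000x below its cut-on,
# leaving a residue modelled as a Gaussian whose maximum sits where the index
# operations search for I_bs (near 380 nm in the 365 nm channel, about the
# excitation line in the 535 nm channel). Amplitudes are solved numerically so
# the noiseless spectrum reproduces a requested eta exactly under the same
# readout rules the index operations use.

channel_shapes <- function(channel) {
  gauss <- function(mu, sd) function(l) exp(-(l - mu)^2 / (2 * sd^2))
  switch(channel,
    collagen = list(
      grid = seq(360, 600, by = 1),
      excitation_nm = 365,
      fluor = gauss(450, 20),
      # filter cut-on 370 nm, ~1000x attenuation below it
      bs = function(l) gauss(380, 8)(l) * ifelse(l < 370, 1e-3, 1),
      lambda_f = 450, bs_window = c(370, 390)),
    porphyrins = list(
      grid = seq(500, 800, by = 1),
      excitation_nm = 535,
      # two characteristic porphyrin peaks, 630 nm main and 710 nm secondary
      fluor = function(l) gauss(630, 15)(l) + 0.5 * gauss(710, 18)(l),
      bs = gauss(535, 6),
      lambda_f = 630, bs_window = c(525, 545)),
    stop("channel must be 'collagen' or 'porphyrins'"))
}

measured_eta <- function(grid, intensities, sh) {
  i_f <- intensities[nearest_idx(grid, sh$lambda_f)]
  in_win <- grid >= sh$bs_window[1] & grid <= sh$bs_window[2]
  i_bs <- max(intensities[in_win])
  i_f / (i_f + i_bs)
}

#' Generate a synthetic emission spectrum with a known tissue-content index
#'
#' Inverts the index definition eta = I_f/(I_f + I_bs): peak amplitudes are
#' solved so the noiseless spectrum yields exactly `target_eta` under the same
#' readout rules as [collagen_index()] / [porphyrin_index()]. Additive Gaussian
#' noise (truncated at zero) can be layered on top. The porphyrin channel
#' includes the secondary 710 nm emission peak at half the 630 nm amplitude.
#'
#' Because the fluorophore emission tail overlaps the backscatter search
#' window, the achievable index is bounded slightly below 1 (about 0.99 for
#' the collagen channel); targets beyond the bound raise an error. Targets of
#' exactly 0 or 1 are degenerate and emit a pure-backscatter or
#' pure-fluorescence spectrum with a warning.
#'
#' @param target_eta requested index in \[0, 1\].
#' @param channel `"collagen"` (excitation 365 nm) or `"porphyrins"`
#'   (excitation 535 nm).
#' @param noise_sd additive Gaussian noise SD in a.u. (base amplitude is
#'   1000 a.u.).
#' @param seed optional integer seed for the noise draw.
#' @return A [spectrum()] with `meta$target_eta` recording the ground truth.
#' @export
generate_spectrum <- function(target_eta, channel = c("collagen", "porphyrins"),
                              noise_sd = 0, seed = NULL) {
  channel <- match.arg(channel)
  if (target_eta < 0 || target_eta > 1)
    stop("generate_spectrum: target_eta must lie in [0, 1]")
  sh <- channel_shapes(channel)
  grid <- sh$grid
  f <- sh$fluor(grid)
  g <- sh$bs(grid)
  base <- 1000  # a.u. scale

  if (target_eta == 0) {
    warning("generate_spectrum: target_eta = 0 is degenerate; emitting pure backscatter")
    intens <- base * g
  } else if (target_eta == 1) {
    warning("generate_spectrum: target_eta = 1 is degenerate; emitting pure fluorescence")
    intens <- base * f
  } else {
    a_f <- base * target_eta
    h <- function(a_bs) measured_eta(grid, a_f * f + a_bs * g, sh) - target_eta
    if (h(0) < 0)
      stop(sprintf(
        "generate_spectrum: target_eta = %g exceeds the channel's achievable maximum %.4f",
        target_eta, measured_eta(grid, f, sh)))
    upper <- base * max(1, (1 - target_eta) / target_eta) * 10
    a_bs <- stats::uniroot(h, c(0, upper), tol = 1e-12)$root
    intens <- a_f * f + a_bs * g
  }

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    intens <- pmax(0, intens + stats::rnorm(length(intens), 0, noise_sd))
  }
  spectrum(grid, intens, sh$excitation_nm,
           meta = list(target_eta = target_eta, channel = channel,
                       noise_sd = noise_sd))
}
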