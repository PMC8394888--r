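#' Construct an emission spectrum
#'
#' A spectrum is a sampled emission intensity over a strictly increasing
#' wavelength grid, tagged with the excitation wavelength used to acquire it.
#' Intensities are in arbitrary units (a.u.) and must be non-negative; the
#' tissue-content index derived from them is scale-free, so no radiometric
#' calibration is assumed.
#'
#' @param wavelengths_nm numeric, strictly increasing wavelength grid (nm).
#' @param intensities numeric, non-negative signal, same length as the grid.
#' @param excitation_nm excitation wavelength lambda_e (nm).
#' @param meta free-form list of acquisition labels.
#' @return An object of class `uv_spectrum`.
#' @export
spectrum <- function(wavelengths_nm, intensities, excitation_nm, meta = list()) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) == 0L)
    stop("spectrum: empty wavelength grid")
  if (length(wavelengths_nm) != length(intensities))
    stop("spectrum: wavelengths and intensities differ in length")
  if (any(diff(wavelengths_nm) <= 0))
    stop("spectrum: wavelengths must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("spectrum: intensities must be finite and non-negative")
  structure(
    list(wavelengths_nm = wavelengths_nm, intensities = intensities,
         excitation_nm = as.numeric(excitation_nm), meta = meta),
    class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %d points, %.0f-%.0f nm, excitation %.0f nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$excitation_nm))
  invisible(x)
}

# nearest grid index to a wavelength; ties break toward the lower wavelength
nearest_idx <- function(wavelengths_nm, lambda_nm) {
  which.min(abs(wavelengths_nm - lambda_nm))
}

#' Fluorophore tissue-content index
#'
#' Computes the scale-free index eta = I_f / (I_f + I_bs), where I_f is the
#' fluorescence intensity read at the fluorophore's readout wavelength and
#' I_bs is the residual backscattered excitation light, taken as the maximum
#' intensity inside a search window (the detection filter leaves a backscatter
#' residue peaking near 380 nm in the 365 nm channel).
#'
#' I_f is the intensity at the grid point nearest `lambda_f_nm` (no local-max
#' search); nearest-neighbour ties break toward the lower wavelength.
#'
#' @param spec a [spectrum()].
#' @param lambda_f_nm readout wavelength (nm); must lie inside the grid span.
#' @param bs_window_nm length-2 numeric, wavelength window searched for the
#'   backscatter maximum; must intersect the grid.
#' @return A list of class `eta_index` with fields `eta`, `i_f`, `i_bs`,
#'   `lambda_f_nm`, `bs_window_nm`.
#' @export
tissue_content_index <- function(spec, lambda_f_nm, bs_window_nm) {
  stopifnot(inherits(spec, "uv_spectrum"))
  w <- spec$wavelengths_nm
  if (lambda_f_nm < min(w) || lambda_f_nm > max(w))
    stop(sprintf("tissue_content_index: lambda_f = %g nm outside grid span [%g, %g]",
                 lambda_f_nm, min(w), max(w)))
  bs_window_nm <- sort(as.numeric(bs_window_nm))
  in_win <- w >= bs_window_nm[1] & w <= bs_window_nm[2]
  if (!any(in_win))
    stop("tissue_content_index: backscatter window contains no grid points")
  i_f <- spec$intensities[nearest_idx(w, lambda_f_nm)]
  i_bs <- max(spec$intensities[in_win])
  if (i_f + i_bs <= 0)
    stop("tissue_content_index: degenerate spectrum, I_f + I_bs = 0 (eta undefined)")
  structure(
    list(eta = i_f / (i_f + i_bs), i_f = i_f, i_bs = i_bs,
         lambda_f_nm = lambda_f_nm, bs_window_nm = bs_window_nm),
    class = "eta_index")
}

#' @export
print.eta_index <- function(x, ...) {
  cat(sprintf("<eta_index> eta = %.4f (I_f = %.3g at %g nm, I_bs = %.3g in [%g, %g] nm)\n",
              x$eta, x$i_f, x$lambda_f_nm, x$i_bs,
              x$bs_window_nm[1], x$bs_window_nm[2]))
  invisible(x)
}

#' Collagen tissue-content index
#'
#' Reads collagen fluorescence at lambda_f = 450 nm (excitation 365 nm channel)
#' and the backscatter maximum in a window about 380 nm, default 370-390 nm.
#' Warns, but proceeds, when the spectrum's recorded excitation wavelength is
#' not 365 nm.
#'
#' @inheritParams tissue_content_index
#' @param bs_window_nm backscatter search window, default `c(370, 390)`.
#' @return An `eta_index`.
#' @export
collagen_index <- function(spec, bs_window_nm = c(370, 390)) {
  stopifnot(inherits(spec, "uv_spectrum"))
  if (!isTRUE(all.equal(spec$excitation_nm, 365)))
    warning(sprintf("collagen_index: spectrum excitation is %g nm, expected 365 nm",
                    spec$excitation_nm))
  tissue_content_index(spec, lambda_f_nm = 450, bs_window_nm = bs_window_nm)
}

#' Porphyrin tissue-content index
#'
#' Reads porphyrin fluorescence at lambda_f = 630 nm (excitation 535 nm
#' channel; porphyrin emission has characteristic peaks at 630 and 710 nm).
#' The backscatter window for this channel defaults to 525-545 nm, symmetric
#' about the excitation line.
#'
#' @inheritParams tissue_content_index
#' @param bs_window_nm backscatter search window, default `c(525, 545)`.
#' @return An `eta_index`.
#' @export
porphyrin_index <- function(spec, bs_window_nm = c(525, 545)) {
  stopifnot(inherits(spec, "uv_spectrum"))
  if (!isTRUE(all.equal(spec$excitation_nm, 535)))
    warning(sprintf("porphyrin_index: spectrum excitation is %g nm, expected 535 nm",
                    spec$excitation_nm))
  tissue_content_index(spec, lambda_f_nm = 630, bs_window_nm = bs_window_nm)
}

#' Average tissue-content indices over measurement sites
#'
#' Weekly measurements are taken at five points of the examined skin area and
#' the indices averaged; this helper pools any number of `eta_index` results
#' (or bare eta values) into a mean and standard deviation.
#'
#' @param results non-empty list of `eta_index` objects, or a numeric vector
#'   of eta values.
#' @return list with `mean`, `sd` and `n`.
#' @export
average_over_sites <- function(results) {
  if (is.numeric(results)) {
    etas <- results
  } else {
    stopifnot(is.list(results), all(vapply(results, inherits, TRUE, "eta_index")))
    etas <- vapply(results, function(r) r$eta, numeric(1))
  }
  if (length(etas) == 0L) stop("average_over_sites: empty input")
  list(mean = mean(etas), sd = if (length(etas) > 1L) stats::sd(etas) else 0, n = length(etas))
}

#' Read a spectrum from CSV
#'
#' Expects two columns `wavelength_nm,intensity` with a header. The excitation
#' wavelength may be recorded as a `# excitation_nm=<value>` comment line at
#' the top of the file, or passed explicitly (which takes precedence).
#'
#' @param path CSV file path.
#' @param excitation_nm optional override for the excitation wavelength.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, excitation_nm = NULL) {
  head_lines <- readLines(path, n = 10L)
  comment <- grep("^#\\s*excitation_nm\\s*=", head_lines, value = TRUE)
  if (is.null(excitation_nm)) {
    if (length(comment) == 0L)
      stop("read_spectrum_csv: no excitation_nm comment line and none supplied")
    excitation_nm <- as.numeric(sub("^#\\s*excitation_nm\\s*=\\s*", "", comment[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "intensity")
  if (!all(need %in% names(df)))
    stop("read_spectrum_csv: expected columns 'wavelength_nm,intensity'")
  spectrum(df$wavelength_nm, df$intensity, excitation_nm)
}

#' Write a spectrum to CSV
#'
#' @param spec a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "uv_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# excitation_nm=%g", spec$excitation_nm), con)
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelengths_nm, intensity = spec$intensities),
    con, row.names = FALSE)
  invisible(path)
}
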