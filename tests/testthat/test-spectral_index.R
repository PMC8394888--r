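# Tissue-content index eta = I_f / (I_f + I_bs) from emission spectra.

make_flat_spectrum <- function(grid, values, excitation = 365) {
  spectrum(grid, values, excitation)
}

test_that("tissue_content_index reads I_f at the nearest grid point and I_bs as the window maximum", {
  grid <- seq(360, 600, by = 1)
  intens <- numeric(length(grid))
  intens[grid == 380] <- 700
  intens[grid == 450] <- 300
  res <- tissue_content_index(spectrum(grid, intens, 365), 450, c(370, 390))
  expect_equal(res$i_f, 300)
  expect_equal(res$i_bs, 700)
  expect_equal(res$eta, 0.3)

  # zero fluorescence at the readout wavelength -> eta = 0
  intens0 <- intens; intens0[grid >= 440 & grid <= 460] <- 0
  expect_equal(tissue_content_index(spectrum(grid, intens0, 365), 450, c(370, 390))$eta, 0)

  # symmetric intensities -> eta = 0.5
  intens5 <- numeric(length(grid)); intens5[grid == 380] <- 300; intens5[grid == 450] <- 300
  expect_equal(tissue_content_index(spectrum(grid, intens5, 365), 450, c(370, 390))$eta, 0.5)
})

test_that("degenerate and out-of-range inputs are rejected", {
  grid <- seq(360, 600, by = 1)
  zero <- spectrum(grid, numeric(length(grid)), 365)
  expect_error(tissue_content_index(zero, 450, c(370, 390)), "degenerate")
  ok <- spectrum(grid, rep(1, length(grid)), 365)
  expect_error(tissue_content_index(ok, 700, c(370, 390)), "outside grid")
  expect_error(tissue_content_index(ok, 450, c(100, 200)), "no grid points")
  expect_error(spectrum(c(400, 400, 410), c(1, 1, 1), 365), "strictly increasing")
  expect_error(spectrum(c(400, 410), c(1, -1), 365), "non-negative")
})

test_that("collagen and porphyrin indices use the channel conventions and warn on excitation mismatch", {
  sp <- generate_spectrum(0.42, "collagen")
  expect_equal(collagen_index(sp)$eta, 0.42, tolerance = 1e-3)
  expect_equal(collagen_index(sp)$lambda_f_nm, 450)
  expect_equal(collagen_index(sp)$bs_window_nm, c(370, 390))

  # backscatter-only spectrum -> eta = 0
  grid <- seq(360, 600, by = 1)
  bs_only <- spectrum(grid, exp(-(grid - 380)^2 / 128), 365)
  expect_equal(collagen_index(bs_only)$eta, 0)

  pp <- generate_spectrum(0.05, "porphyrins")
  expect_equal(porphyrin_index(pp)$eta, 0.05, tolerance = 1e-3)
  expect_equal(porphyrin_index(pp)$lambda_f_nm, 630)

  wrong <- spectrum(grid, rep(1, length(grid)), 535)
  expect_warning(collagen_index(wrong), "expected 365")
  grid_p <- seq(500, 800, by = 1)
  wrong_p <- spectrum(grid_p, rep(1, length(grid_p)), 365)
  expect_warning(porphyrin_index(wrong_p), "expected 535")
})

test_that("eta is bounded, scale-free, and monotone in the fluorescence intensity", {
  set.seed(101)
  for (i in 1:20) {
    target <- runif(1, 0.02, 0.9)
    sp <- generate_spectrum(target, "collagen", noise_sd = runif(1, 0, 5))
    res <- collagen_index(sp)
    expect_gte(res$eta, 0)
    expect_lte(res$eta, 1)
    # scale invariance under positive rescaling
    scl <- runif(1, 0.1, 10)
    sp_scaled <- spectrum(sp$wavelengths_nm, sp$intensities * scl, 365)
    expect_equal(collagen_index(sp_scaled)$eta, res$eta, tolerance = 1e-12)
    # monotonicity: raising intensity at lambda_f (backscatter fixed) raises eta
    nearest <- which.min(abs(sp$wavelengths_nm - 450))
    bumped <- sp$intensities
    bumped[nearest] <- bumped[nearest] * 1.5 + 1
    expect_gte(collagen_index(spectrum(sp$wavelengths_nm, bumped, 365))$eta, res$eta)
  }
})

test_that("generator -> index round trip recovers the target within 1e-3 on a 1 nm grid", {
  for (target in seq(0.05, 0.9, by = 0.05)) {
    expect_equal(collagen_index(generate_spectrum(target, "collagen"))$eta,
                 target, tolerance = 1e-3)
    expect_equal(porphyrin_index(generate_spectrum(target, "porphyrins"))$eta,
                 target, tolerance = 1e-3)
  }
})

test_that("site averaging matches a brute-force mean", {
  five <- replicate(5, generate_spectrum(0.3, "collagen"), simplify = FALSE)
  res <- average_over_sites(lapply(five, collagen_index))
  expect_equal(res$mean, 0.3, tolerance = 1e-3)
  expect_equal(res$sd, 0)

  expect_equal(average_over_sites(c(0.2, 0.4))$mean, 0.3)

  set.seed(7)
  etas <- runif(5)
  brute <- sum(etas) / 5
  expect_equal(average_over_sites(etas)$mean, brute)
  expect_error(average_over_sites(numeric(0)), "empty")
})

test_that("spectra round-trip through CSV with excitation metadata", {
  sp <- generate_spectrum(0.3, "collagen", noise_sd = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$excitation_nm, 365)
  expect_equal(back$wavelengths_nm, sp$wavelengths_nm)
  expect_equal(back$intensities, sp$intensities, tolerance = 1e-12)
})
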