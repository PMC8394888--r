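# CIELAB conversion, white balance, ROI statistics, delta a*, Tukey HSD.

test_that("rgb_to_lab maps white to (100, 0, 0) and all neutral grays to a*=b*=0", {
  lab_w <- rgb_to_lab(pixel_image(c(255, 255, 255)))
  expect_equal(lab_w$L[1, 1], 100, tolerance = 1e-6)
  expect_equal(lab_w$a[1, 1], 0, tolerance = 1e-6)
  expect_equal(lab_w$b[1, 1], 0, tolerance = 1e-6)
  for (v in c(0, 1, 17, 64, 128, 200, 254)) {
    for (gamma in c("linear", "srgb")) {
      lab <- rgb_to_lab(pixel_image(c(v, v, v)), gamma = gamma)
      expect_lt(abs(lab$a[1, 1]), 1e-6)
      expect_lt(abs(lab$b[1, 1]), 1e-6)
    }
  }
})

test_that("rgb_to_lab matches the independent conversion oracle in both dialects", {
  px <- c(200, 80, 80)
  for (gamma in c("linear", "srgb")) for (white in c("D65", "D50")) {
    lab <- rgb_to_lab(pixel_image(px), gamma = gamma, white = white)
    oracle <- oracle_lab(px, gamma, white)
    expect_equal(lab$L[1, 1], unname(oracle["L"]), tolerance = 0.1)
    expect_equal(lab$a[1, 1], unname(oracle["a"]), tolerance = 0.1)
    expect_equal(lab$b[1, 1], unname(oracle["b"]), tolerance = 0.1)
  }
  # frozen external reference (scikit-image rgb2lab, sRGB dialect)
  lab_srgb <- rgb_to_lab(pixel_image(px), gamma = "srgb")
  expect_equal(lab_srgb$L[1, 1], 50.2152, tolerance = 1e-3)
  expect_equal(lab_srgb$a[1, 1], 47.8293, tolerance = 1e-3)
  expect_equal(lab_srgb$b[1, 1], 24.8539, tolerance = 1e-3)
  expect_error(rgb_to_lab(array(300, c(1, 1, 3))), "8-bit")
})

test_that("white balance recovers channel gains and errors on a saturated phantom", {
  img <- uniform_image(c(180, 180, 180), 20, 20)
  phantom <- roi_rect(0, 0, 10, 10)
  corrected <- white_balance_correct(img, phantom)
  expect_equal(attr(corrected, "wb_gains"), rep(1, 3), tolerance = 1e-12)
  expect_equal(corrected, img, ignore_attr = TRUE)

  gains_in <- c(1.2, 1.0, 0.8)
  skew <- img
  for (ch in 1:3) skew[, , ch] <- img[, , ch] * gains_in[ch]
  fixed <- white_balance_correct(skew, phantom)
  expect_equal(attr(fixed, "wb_gains"), 1 / gains_in, tolerance = 1e-12)
  m <- vapply(1:3, function(ch) mean(fixed[1:10, 1:10, ch]), numeric(1))
  expect_equal(max(m) - min(m), 0, tolerance = 1e-9)

  expect_error(white_balance_correct(uniform_image(c(255, 255, 255)),
                                     roi_rect(0, 0, 4, 4)), "saturated")
})

test_that("ROI a* means match a brute-force pixel loop", {
  set.seed(55)
  img <- array(runif(30 * 40 * 3, 0, 255), c(30, 40, 3))
  lab <- rgb_to_lab(img)
  roi <- roi_rect(5, 3, 25, 17)
  brute <- 0; n <- 0
  for (yy in 4:17) for (xx in 6:25) { brute <- brute + lab$a[yy, xx]; n <- n + 1 }
  expect_equal(roi_mean_astar(lab, roi), brute / n, tolerance = 1e-9)

  # half at one a*, half at another -> midpoint
  lab2 <- lab
  lab2$a[, 1:20] <- 10; lab2$a[, 21:40] <- 20
  expect_equal(roi_mean_astar(lab2, roi_rect(0, 0, 40, 30)), 15)
  expect_error(roi_mean_astar(lab, roi_rect(30, 0, 50, 10)), "bounds")
})

test_that("the relative erythema index evaluates exactly and is linear in a*_AS", {
  expect_equal(relative_erythema_index(10, 10), 0)
  expect_equal(relative_erythema_index(12, 10), 20)
  expect_equal(relative_erythema_index(5, 10), -50)
  expect_error(relative_erythema_index(5, 0.1), "floor")
  # exact linearity in a_as at fixed a_ns; zero at equality for any valid a
  set.seed(66)
  for (i in 1:10) {
    a_ns <- runif(1, 1, 30)
    expect_equal(relative_erythema_index(a_ns, a_ns), 0)
    a1 <- runif(1, -10, 40); a2 <- runif(1, -10, 40); lam <- runif(1)
    mix <- relative_erythema_index(lam * a1 + (1 - lam) * a2, a_ns)
    expect_equal(mix, lam * relative_erythema_index(a1, a_ns) +
                        (1 - lam) * relative_erythema_index(a2, a_ns),
                 tolerance = 1e-9)
  }
})

test_that("per-animal delta a* averages four ROIs against one intact reference", {
  lab <- rgb_to_lab(uniform_image(c(190, 130, 110), 100, 100))
  rois <- list(roi_rect(0, 0, 10, 10), roi_rect(20, 0, 30, 10),
               roi_rect(0, 20, 10, 30), roi_rect(20, 20, 30, 30))
  intact <- roi_rect(60, 60, 80, 80)
  r <- per_animal_delta_a(lab, rois, intact)
  expect_equal(r$delta_a, 0, tolerance = 1e-9)  # uniform image

  # constructed a* plane: four ROIs at known delta a* of 10/20/30/40 percent
  lab$a[, ] <- 10
  lab$a[1:10, 1:10] <- 11; lab$a[1:10, 21:30] <- 12
  lab$a[21:30, 1:10] <- 13; lab$a[21:30, 21:30] <- 14
  r2 <- per_animal_delta_a(lab, rois, intact)
  expect_equal(r2$per_roi, c(10, 20, 30, 40))
  expect_equal(r2$delta_a, 25)

  expect_error(per_animal_delta_a(lab, rois[1:3], intact), "expected 4")
  expect_warning(per_animal_delta_a(lab, rois, roi_rect(5, 5, 25, 25)), "overlaps")
})

test_that("full pipeline on a synthetic dorsum is accurate and gain-invariant after white balance", {
  ph <- generate_dorsum_image(dorsum_config(erythema_delta_a_target = 20), seed = 17)
  base <- per_animal_delta_a(rgb_to_lab(ph$image),
                             ph$rois$irradiated, ph$rois$intact)$delta_a
  expect_equal(base, 20, tolerance = 2)
  skew <- ph$image
  gains <- c(1.15, 1.0, 0.88)
  for (ch in 1:3) skew[, , ch] <- pmax(pmin(ph$image[, , ch] * gains[ch], 255), 0)
  fixed <- white_balance_correct(skew, ph$rois$phantom)
  after <- per_animal_delta_a(rgb_to_lab(fixed),
                              ph$rois$irradiated, ph$rois$intact)$delta_a
  expect_equal(after, base, tolerance = 1)
})

test_that("Tukey HSD matches the independent reference and flags large effects", {
  # frozen oracle: statsmodels pairwise_tukeyhsd on this 3-group dataset
  g1 <- c(24.5, 23.5, 26.4, 27.1, 29.9)
  g2 <- c(28.4, 34.2, 29.5, 32.2, 30.1)
  g3 <- c(26.1, 28.3, 24.3, 26.2, 27.8)
  tk <- tukey_pairwise(c(g1, g2, g3), rep(c("a", "b", "c"), each = 5))
  p <- setNames(tk$p_adj, tk$comparison)
  expect_lt(abs(p[["b-a"]] - 0.0144), 1e-3)
  expect_lt(abs(p[["c-a"]] - 0.9803), 1e-3)
  expect_lt(abs(p[["c-b"]] - 0.0203), 1e-3)

  # near-identical groups -> all p near 1
  set.seed(77)
  x <- rnorm(15, 10, 1)
  tk_same <- tukey_pairwise(x, rep(c("a", "b", "c"), each = 5))
  expect_true(all(tk_same$p_adj > 0.2))

  # two groups 10 within-SDs apart -> tiny p
  y <- c(rnorm(5, 0, 1), rnorm(5, 10, 1), rnorm(5, 0, 1))
  tk_far <- tukey_pairwise(y, rep(c("a", "b", "c"), each = 5))
  expect_lt(min(tk_far$p_adj), 0.001)

  expect_error(tukey_pairwise(rep(1, 6), rep(c("a", "b"), each = 3)), "variance")
  expect_error(tukey_pairwise(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})
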