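test_that("band-averaged extinctions are response-weighted means", {
  cam <- camera_model()
  tab_c <- flat_extinction_table(eps_hbo2 = 1234, eps_hb = 77)
  bx <- band_average_extinctions(tab_c, cam)
  expect_equal(bx$eps_hbo2_band, rep(1234, 16), tolerance = 1e-9)
  expect_equal(bx$eps_hb_band, rep(77, 16), tolerance = 1e-9)

  # two-peak filters against the quadrature already validated for
  # integrate_bands: band averaging is exactly that integral
  tab <- load_extinction_table()
  e <- msimon:::eps_at(tab, cam$wavelengths)
  bx2 <- band_average_extinctions(tab, cam)
  expect_equal(bx2$eps_hbo2_band, integrate_bands(e$hbo2, cam))
  expect_true(all(bx2$eps_hbo2_band >= 0 & bx2$eps_hb_band >= 0))
})

# band extinctions rescaled to unit order, so unit-scale concentration-path
# products stay within floating-point range of exp(-a)
unit_band_extinctions <- function() {
  cam <- camera_model()
  bx <- band_average_extinctions(load_extinction_table(), cam)
  structure(list(eps_hbo2_band = bx$eps_hbo2_band / 5e4,
                 eps_hb_band = bx$eps_hb_band / 5e4),
            class = "band_extinctions")
}

test_that("Beer-Lambert regression recovers noiseless parameters exactly", {
  bxu <- unit_band_extinctions()
  a <- bxu$eps_hbo2_band * 3 + bxu$eps_hb_band * 1 + 0.2
  fit <- beer_lambert_fit(exp(-a), bxu)
  expect_equal(fit$v_hbo2_l, 3, tolerance = 1e-10)
  expect_equal(fit$v_hb_l, 1, tolerance = 1e-10)
  expect_equal(fit$scatter_offset, 0.2, tolerance = 1e-10)
  expect_equal(fit$s, 0.75, tolerance = 1e-10)
  expect_equal(fit$v_hbt_l, 4, tolerance = 1e-10)

  # molar-scale extinctions with physical concentration-path products
  cam <- camera_model()
  bx <- band_average_extinctions(load_extinction_table(), cam)
  set.seed(6)
  for (i in 1:10) {
    v2 <- runif(1, 0.1, 5) * 1e-5
    v1 <- runif(1, 0.1, 5) * 1e-5
    g0 <- rnorm(1)
    fit_i <- beer_lambert_fit(exp(-(bx$eps_hbo2_band * v2 +
                                      bx$eps_hb_band * v1 + g0)), bx)
    expect_equal(fit_i$v_hbo2_l, v2, tolerance = 1e-8)
    expect_equal(fit_i$v_hb_l, v1, tolerance = 1e-8)
    expect_equal(fit_i$scatter_offset, g0, tolerance = 1e-8)
  }
})

test_that("fits report implausible values unclipped and handle edge cases", {
  bx <- unit_band_extinctions()

  # pure oxyhemoglobin absorber: s = 1
  fit1 <- beer_lambert_fit(exp(-(bx$eps_hbo2_band * 2 + 0.1)), bx)
  expect_equal(fit1$s, 1, tolerance = 1e-8)

  # crafted input with a negative deoxy component yields s > 1, unclipped
  fit2 <- beer_lambert_fit(exp(-(bx$eps_hbo2_band * 3 - bx$eps_hb_band * 1)),
                           bx)
  expect_gt(fit2$s, 1)

  # rescaling reflectance only moves the scattering offset
  r <- exp(-(bx$eps_hbo2_band * 1.5 + bx$eps_hb_band * 0.7 + 0.3))
  f_ref <- beer_lambert_fit(r, bx)
  f_scl <- beer_lambert_fit(2.5 * r, bx)
  expect_equal(f_scl$s, f_ref$s, tolerance = 1e-10)
  expect_equal(f_scl$v_hbt_l, f_ref$v_hbt_l, tolerance = 1e-8)
  expect_equal(f_scl$scatter_offset, f_ref$scatter_offset - log(2.5),
               tolerance = 1e-8)

  expect_error(beer_lambert_fit(c(rep(0.5, 15), -0.1), bx), "positive")
  bad_bx <- structure(list(eps_hbo2_band = rep(1, 16),
                           eps_hb_band = rep(1, 16)),
                      class = "band_extinctions")
  expect_error(beer_lambert_fit(rep(0.5, 16), bad_bx), "collinear")
})

test_that("baseline classification scores both parameters via AU-ROC", {
  mk <- function(s, v) structure(list(s = s, v_hbt_l = v),
                                 class = "beer_lambert_fit")
  fits <- c(lapply(c(0.8, 0.85, 0.9), function(s) mk(s, 4)),
            lapply(c(0.4, 0.45, 0.5), function(s) mk(s, 2)))
  states <- c(rep("perfused", 3), rep("ischemic", 3))
  res <- classify_by_baseline(fits, states)
  expect_equal(res[["auroc_s"]], 1)
  expect_equal(res[["auroc_vhbt"]], 1)

  # identical series: chance level
  fits0 <- lapply(1:6, function(i) mk(0.7, 3))
  expect_equal(unname(classify_by_baseline(fits0, states)), c(0.5, 0.5))

  # toy vs the pair-counting reference
  set.seed(8)
  sv <- runif(10); vv <- runif(10)
  fits_r <- lapply(1:10, function(i) mk(sv[i], vv[i]))
  states_r <- rep(c("perfused", "ischemic"), 5)
  res_r <- classify_by_baseline(fits_r, states_r)
  pos <- states_r == "ischemic"
  expect_equal(res_r[["auroc_s"]],
               auroc_bruteforce(-sv[!pos], -sv[pos]))
  expect_equal(res_r[["auroc_vhbt"]],
               auroc_bruteforce(-vv[!pos], -vv[pos]))
})
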