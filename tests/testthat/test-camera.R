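test_that("band integration reproduces constants, spikes and quadrature", {
  cam <- camera_model()
  nl <- length(cam$wavelengths)

  # weighted mean of a constant is the constant
  expect_equal(integrate_bands(rep(0.5, nl), cam), rep(0.5, 16), tolerance = 1e-12)

  # a single-sample spike filter picks out the reflectance at that wavelength
  i0 <- 120
  fr <- matrix(0, 1, nl)
  fr[1, i0] <- 1
  cam_spike <- camera_model(filter_responses = rbind(fr[rep(1, 16), ]),
                            optics_transmission = rep(1, nl),
                            illuminant = rep(1, nl))
  r <- runif(nl)
  expect_equal(integrate_bands(r, cam_spike),
               rep(r[i0], 16), tolerance = 1e-12)

  # fine-grid quadrature oracle: the weighted integrand is tabulated on the
  # camera grid, linearly interpolated to 0.1 nm and integrated by trapezoid
  set.seed(3)
  r_smooth <- 0.3 + 0.2 * sin(cam$wavelengths / 60) +
    0.1 * cos(cam$wavelengths / 23)
  fine <- seq(min(cam$wavelengths), max(cam$wavelengths), by = 0.1)
  interp <- function(y) approx(cam$wavelengths, y, xout = fine)$y
  tz <- function(y) sum(diff(fine) * (y[-1] + y[-length(y)])) / 2
  oracle <- vapply(1:16, function(k) {
    wgt <- cam$optics_transmission * cam$illuminant * cam$filter_responses[k, ]
    tz(interp(wgt * r_smooth)) / tz(interp(wgt))
  }, numeric(1))
  expect_equal(integrate_bands(r_smooth, cam), oracle, tolerance = 1e-10)
})

test_that("band integration is linear and bounded", {
  cam <- camera_model()
  nl <- length(cam$wavelengths)
  set.seed(11)
  for (i in 1:5) {
    r1 <- runif(nl)
    r2 <- runif(nl)
    a <- rnorm(1)
    b <- rnorm(1)
    expect_equal(integrate_bands(a * r1 + b * r2, cam),
                 a * integrate_bands(r1, cam) + b * integrate_bands(r2, cam),
                 tolerance = 1e-12)
    bands <- integrate_bands(r1, cam)
    expect_true(all(bands >= 0 & bands <= 1))
  }
  expect_error(
    integrate_bands(rep(0.5, nl),
                    camera_model(filter_responses =
                                   rbind(matrix(0, 1, nl),
                                         camera_model()$filter_responses[-1, ]))),
    "band 1")
})

test_that("demosaic collapses tiles in layout order and round-trips exactly", {
  cam <- camera_model()
  # toy 8x8 frame: every 4x4 tile holds 0..15 row-major, matching the layout
  tile <- matrix(0:15, 4, 4, byrow = TRUE)
  frame <- rbind(cbind(tile, tile), cbind(tile, tile))
  cube <- demosaic(frame, cam)
  expect_equal(dim(cube), c(2, 2, 16))
  expect_equal(cube[1, 1, ], 0:15)
  expect_equal(cube[2, 2, ], 0:15)

  # constant frame -> constant cube
  cube_c <- demosaic(matrix(7, 8, 8), cam)
  expect_true(all(cube_c == 7))

  # bit-exact round trip for arbitrary frames and a scrambled layout
  set.seed(4)
  cam_s <- camera_model(mosaic_layout = matrix(sample(0:15), 4, 4))
  frame_r <- matrix(sample.int(1023, 16 * 32, replace = TRUE), 16, 32)
  expect_identical(mosaic(demosaic(frame_r, cam_s), cam_s), frame_r + 0)
  expect_error(demosaic(matrix(0, 6, 8), cam), "divisible by 4")
})

test_that("RGB transform solves the least-squares problem and normalizes", {
  # 3-band camera whose effective response equals the RGB target -> identity
  w <- seq(300, 1000, by = 2)
  f_rgb <- t(vapply(c(460, 550, 640),
                    function(c0) exp(-0.5 * ((w - c0) / 42)^2), numeric(length(w))))
  cam3 <- camera_model(wavelengths = w, filter_responses = f_rgb,
                       optics_transmission = rep(1, length(w)),
                       illuminant = rep(1, length(w)))
  tf3 <- fit_rgb_transform(cam3)
  expect_equal(tf3$T, diag(3), tolerance = 1e-8, ignore_attr = TRUE)

  # 16-band camera: flat band vector maps to (1,1,1); matches pseudoinverse
  cam <- camera_model()
  tf <- fit_rgb_transform(cam)
  expect_equal(as.numeric(tf$T %*% rep(1, 16)), rep(1, 3), tolerance = 1e-9)
  fp <- tf$F_prime
  t_min_oracle <- t(solve(crossprod(fp), crossprod(fp, tf$F_rgb)))
  expect_equal(tf$T, t_min_oracle / rowSums(t_min_oracle), tolerance = 1e-8)

  # reconstruction: flat cube -> balanced channels, zero cube -> black,
  # single pixel matches the hand matrix product
  cube <- array(0.4, dim = c(2, 2, 16))
  rgb <- reconstruct_rgb(cube, tf)
  expect_lt(max(rgb) - min(rgb), 1e-9)
  expect_true(all(reconstruct_rgb(array(0, dim = c(2, 2, 16)), tf) == 0))
  px <- runif(16, 0.1, 0.6)
  cube1 <- array(px, dim = c(1, 1, 16))
  expect_equal(as.numeric(reconstruct_rgb(cube1, tf)),
               pmin(pmax(as.numeric(tf$T %*% px), 0), 1), tolerance = 1e-12)
})

test_that("transmission smoothing averages repeats and flags excluded ranges", {
  w <- 380:720
  # constant stays constant; borders and excluded ranges are flagged
  sm <- smooth_transmission(rep(0.8, length(w)), w)
  expect_equal(unique(sm$transmission[sm$valid]), 0.8)
  expect_false(any(sm$valid[sm$wavelength <= 388]))
  expect_false(any(sm$valid[sm$wavelength >= 400 & sm$wavelength <= 419]))
  expect_false(any(sm$valid[sm$wavelength >= 681 & sm$wavelength <= 700]))

  # a linear ramp is unchanged by a centered mean
  ramp <- seq(0, 1, length.out = length(w))
  smr <- smooth_transmission(ramp, w)
  expect_equal(smr$transmission[smr$valid], ramp[smr$valid], tolerance = 1e-12)

  # noisy sine vs an explicit windowed-mean oracle, repeats averaged first
  set.seed(8)
  reps <- matrix(rep(sin(w / 30), 3), nrow = 3, byrow = TRUE) +
    matrix(rnorm(3 * length(w), 0, 0.05), 3)
  sm2 <- smooth_transmission(reps, w)
  avg <- colMeans(reps)
  half <- 9
  oracle <- vapply(seq_along(w), function(i) {
    if (i <= half || i > length(w) - half) return(NA_real_)
    mean(avg[(i - half):(i + half)])
  }, numeric(1))
  expect_equal(sm2$transmission[!is.na(oracle)], oracle[!is.na(oracle)],
               tolerance = 1e-12)
  expect_error(smooth_transmission(rep(1, 5), 400:404, window_nm = 19),
               "window larger")
})
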