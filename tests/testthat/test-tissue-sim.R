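test_that("absorption coefficient follows the hemoglobin mixing rule", {
  tab <- flat_extinction_table(eps_hbo2 = 1000, eps_hb = 500)

  # no blood, no absorption
  expect_equal(absorption_coefficient(0, 0.3, 500, tab), 0)

  # direct evaluation: 0.1 * 1000 * ln(10) * 150 / 64500
  expect_equal(absorption_coefficient(0.1, 1, 500, tab),
               0.1 * 1000 * log(10) * 150 / 64500, tolerance = 1e-12)
  expect_equal(absorption_coefficient(0.1, 1, 500, tab), 0.53549,
               tolerance = 1e-4)

  # equal extinctions make mu_a independent of oxygenation
  tab_eq <- flat_extinction_table(eps_hbo2 = 800, eps_hb = 800)
  expect_equal(absorption_coefficient(0.2, 0.5, 600, tab_eq),
               absorption_coefficient(0.2, 0.9, 600, tab_eq))

  expect_error(absorption_coefficient(0.1, 0.5, 2000,
                                      load_extinction_table()),
               "outside")
})

test_that("scattering coefficient follows the Mie power law", {
  expect_equal(scattering_coefficient(20, 1.2, 0.9, 500), 200)
  expect_equal(scattering_coefficient(20, 0, 0.9, c(400, 500, 900)),
               rep(200, 3))
  expect_equal(scattering_coefficient(20, 1, 0.9, 1000),
               scattering_coefficient(20, 1, 0.9, 500) / 2)
  expect_error(scattering_coefficient(20, 1, 1, 500), "g must be")
})

test_that("tissue sampling respects ranges and is reproducible", {
  sm <- sample_tissue(1000, seed = 5)
  rg <- msimon:::tissue_param_ranges()
  all_layers <- do.call(rbind, lapply(sm, function(s) s$layers))
  for (nm in names(rg)) {
    expect_true(all(all_layers[[nm]] >= rg[[nm]][1]))
    expect_true(all(all_layers[[nm]] <= rg[[nm]][2]))
  }
  expect_identical(sample_tissue(5, seed = 7), sample_tissue(5, seed = 7))

  # uniform-mean check: E[v_hb] = 0.15 within 3 standard errors
  big <- do.call(rbind, lapply(sample_tissue(10000, seed = 9),
                               function(s) s$layers))
  se <- (0.30 / sqrt(12)) / sqrt(nrow(big))
  expect_lt(abs(mean(big$v_hb) - 0.15), 3 * se)
})

test_that("photon transport reproduces the Beer attenuation limit", {
  # mus = 0, matched indices: no diffuse reflectance, T = exp(-mua * d)
  set.seed(21)
  res <- msimon:::mc_multilayer(matrix(1, 1, 3), matrix(0, 1, 3),
                                rep(0.9, 3), rep(1, 3),
                                c(0.5, 0.3, 0.2), 50000L)
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / 50000)
  expect_equal(res$reflectance, 0)
  expect_lt(abs(res$transmittance - p), 3 * se)
})

test_that("photon transport conserves energy and recovers zero-absorption", {
  set.seed(22)
  s <- sample_tissue(1, seed = 31)[[1]]
  sp <- simulate_reflectance(s, wavelengths = seq(450, 650, by = 25),
                             n_photons = 1e4)
  expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 1))
  budget <- sp$reflectance + sp$transmittance + sp$absorbed
  expect_lt(max(abs(budget - 1)), 1e-3)

  # zero absorption, matched indices, optically thick: nearly all light returns
  set.seed(23)
  res <- msimon:::mc_multilayer(matrix(0, 1, 3), matrix(100, 1, 3),
                                rep(0.9, 3), rep(1, 3), c(4, 3, 3), 1e4L)
  expect_gte(res$reflectance, 0.98)
})

test_that("reflectance decreases with top-layer absorption and seeds fix it", {
  mua_sweep <- c(0.5, 2, 5, 10, 20, 40)
  refl <- vapply(mua_sweep, function(ma) {
    set.seed(77)
    msimon:::mc_multilayer(matrix(ma, 1, 3), matrix(150, 1, 3),
                          rep(0.9, 3), rep(1.4, 3), c(0.1, 0.1, 0.1),
                          1e4L)$reflectance
  }, numeric(1))
  expect_equal(cor(mua_sweep, refl, method = "spearman"), -1)

  s <- sample_tissue(1, seed = 12)[[1]]
  a <- simulate_reflectance(s, wavelengths = c(500, 600), n_photons = 2000,
                            seed = 99)
  b <- simulate_reflectance(s, wavelengths = c(500, 600), n_photons = 2000,
                            seed = 99)
  expect_identical(a$reflectance, b$reflectance)
})

test_that("transport matches an independent photon-loop reference", {
  mua <- 10; mus <- 90; g <- 0.75; d <- 0.02
  set.seed(41)
  mine <- msimon:::mc_multilayer(matrix(mua, 1, 3), matrix(mus, 1, 3),
                                 rep(g, 3), rep(1, 3), rep(d / 3, 3),
                                 10000L)$reflectance
  set.seed(42)
  oracle <- mc_slab_oracle(mua, mus, g, d, 10000)
  se <- sqrt(oracle * (1 - oracle) / 10000)
  expect_lt(abs(mine - oracle), 3 * sqrt(2) * se)
})

test_that("Monte-Carlo error scales like one over the square root of photons", {
  run_r <- function(n, seed) {
    set.seed(seed)
    msimon:::mc_multilayer(matrix(5, 1, 3), matrix(80, 1, 3), rep(0.85, 3),
                          rep(1, 3), rep(0.05, 3), as.integer(n))$reflectance
  }
  r_small <- vapply(1:24, function(i) run_r(500, 1000 + i), numeric(1))
  r_large <- vapply(1:24, function(i) run_r(2000, 2000 + i), numeric(1))
  ratio <- sd(r_small) / sd(r_large)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("pretraining corpus has the right shape, range and physics", {
  cam <- camera_model()
  corpus <- build_pretraining_corpus(30, cam, n_photons = 300,
                                     wavelength_step = 20, seed = 55,
                                     l2 = FALSE)
  expect_equal(dim(corpus), c(30, 16))
  expect_true(all(corpus >= 0 & corpus <= 1))
  expect_length(attr(corpus, "params"), 30)

  # higher top-layer blood volume lowers reflectance in high-extinction bands
  set.seed(56)
  n <- 60
  vhb <- runif(n, 0.01, 0.30)
  grid <- seq(300, 1000, by = 25)
  refl <- vapply(seq_len(n), function(i) {
    smp <- uniform_tissue(vhb[i], 0.7, 25, 1.2, 0.88, 1.4, 0.3)
    sp <- simulate_reflectance(smp, wavelengths = grid, n_photons = 400,
                               seed = 70 + i)
    fine <- approx(grid, sp$reflectance, xout = cam$wavelengths, rule = 2)$y
    integrate_bands(fine, cam)[6]   # band in the strong-absorption green
  }, numeric(1))
  expect_lt(cor(vhb, refl, method = "spearman"), 0)
})
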