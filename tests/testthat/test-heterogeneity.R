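test_that("PCA projection reports scores and explained variance", {
  # rank-1 data: first component explains everything
  set.seed(1)
  base <- runif(16)
  X <- outer(rnorm(50), base)
  pc <- pca_project(X)
  expect_equal(pc$explained[1], 1, tolerance = 1e-10)

  # isotropic 2-d data: two equal fractions
  Y <- cbind(rnorm(10000), rnorm(10000))
  pc2 <- pca_project(Y)
  expect_equal(unname(pc2$explained[1:2]), c(0.5, 0.5), tolerance = 0.05)

  # scores match an explicit eigen-decomposition of the covariance
  Z <- matrix(rnorm(200 * 5), 200, 5) %*% diag(c(3, 2, 1, 0.5, 0.2))
  pcz <- pca_project(Z, n_pc = 2)
  ev <- eigen(cov(Z))
  ctr <- scale(Z, center = TRUE, scale = FALSE)
  for (k in 1:2) {
    ref <- as.numeric(ctr %*% ev$vectors[, k])
    got <- pcz$scores[, k]
    expect_equal(abs(cor(ref, got)), 1, tolerance = 1e-10)
    expect_equal(sort(abs(got)), sort(abs(ref)), tolerance = 1e-8)
  }
  # row order only permutes scores (up to sign)
  perm <- sample(nrow(Z))
  pcp <- pca_project(Z[perm, ], n_pc = 2)
  expect_equal(abs(pcp$scores[order(perm), 1]), abs(pcz$scores[, 1]),
               tolerance = 1e-8)
})

simulate_cohort_df <- function(beta, sigma_delta, sigma_eps, n_pat = 10,
                               n_frames = 100, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pat), function(i) {
    delta <- rnorm(1, 0, sigma_delta)
    S <- rep(c(0, 1), each = n_frames / 2)
    data.frame(patient = i, sequence = ifelse(S == 1, "ischemic", "perfused_2"),
               frame = seq_len(n_frames), state = S,
               band_01 = 0.5 + beta * S + delta +
                 rnorm(n_frames, 0, sigma_eps))
  })
  do.call(rbind, rows)
}

test_that("mixed model attributes variance to the generating components", {
  # pure residual: no state effect, no patient effect
  coh <- simulate_cohort_df(beta = 0, sigma_delta = 0, sigma_eps = 1)
  f <- fit_mixed_model(coh, 1)
  expect_true(f$converged)
  expect_gte(f$residual_prop, 0.95)

  # dominant patient effect: recovered proportion within 0.1 of truth
  coh2 <- simulate_cohort_df(beta = 0, sigma_delta = 3, sigma_eps = 1,
                             seed = 2)
  f2 <- fit_mixed_model(coh2, 1)
  expect_true(f2$converged)
  expect_lt(abs(f2$patient_prop - 9 / 10), 0.1)

  # proportions always sum to one and ignore location shifts
  coh3 <- simulate_cohort_df(beta = 1, sigma_delta = 1, sigma_eps = 0.5,
                             seed = 3)
  f3 <- fit_mixed_model(coh3, 1)
  expect_equal(f3$state_prop + f3$patient_prop + f3$residual_prop, 1,
               tolerance = 1e-9)
  coh3b <- coh3
  coh3b$band_01 <- coh3$band_01 + 10
  f3b <- fit_mixed_model(coh3b, 1)
  expect_equal(f3b$alpha, f3$alpha + 10, tolerance = 1e-6)
  # invariant up to optimizer tolerance
  expect_equal(f3b$state_prop, f3$state_prop, tolerance = 1e-6)
  expect_equal(f3b$patient_prop, f3$patient_prop, tolerance = 1e-6)

  expect_error(fit_mixed_model(coh3[coh3$patient == 1, ], 1), "2 patients")
  expect_error(fit_mixed_model(coh3[coh3$state == 0, ], 1), "both")
})

test_that("the fixed state effect is recovered within its standard error", {
  beta_true <- 0.8
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort_df(beta = beta_true, sigma_delta = 1,
                              sigma_eps = 1, n_pat = 10, n_frames = 40,
                              seed = 100 + r)
    fit <- lme4::lmer(band_01 ~ state + (1 | patient), data = coh,
                      REML = TRUE)
    est <- lme4::fixef(fit)[["state"]]
    se <- stats::coef(summary(fit))["state", "Std. Error"]
    if (abs(est - beta_true) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("2-d KDE surfaces integrate to one and localize mass", {
  # near-point mass peaks at the point
  pts <- cbind(rnorm(50, 2, 1e-3), rnorm(50, -1, 1e-3))
  kd <- kde_density_2d(pts, rep("a", 50))
  peak <- which(kd$a$z == max(kd$a$z), arr.ind = TRUE)
  expect_equal(kd$a$x[peak[1]], 2, tolerance = 0.05)
  expect_equal(kd$a$y[peak[2]], -1, tolerance = 0.05)

  # standard normal sample: density at the origin near 1/(2 pi)
  set.seed(12)
  X <- cbind(rnorm(10000), rnorm(10000))
  kd2 <- kde_density_2d(X, rep("s", 10000))
  io <- which.min(abs(kd2$s$x))
  jo <- which.min(abs(kd2$s$y))
  expect_equal(kd2$s$z[io, jo], 1 / (2 * pi), tolerance = 0.2 / (2 * pi))
  integral <- sum(kd2$s$z) * diff(kd2$s$x[1:2]) * diff(kd2$s$y[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)

  # disjoint clusters have negligible overlap
  a <- cbind(rnorm(500, -6, 0.3), rnorm(500, 0, 0.3))
  b <- cbind(rnorm(500, 6, 0.3), rnorm(500, 0, 0.3))
  kd3 <- kde_density_2d(rbind(a, b), rep(c("a", "b"), each = 500))
  expect_lt(kde_overlap(kd3$a, kd3$b), 0.05)
})
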