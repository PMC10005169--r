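# Shared fixtures: small camera / sessions keep the suite fast while
# exercising the same code paths as the full-scale defaults.

small_camera <- function() camera_model(sensor_shape = c(136L, 256L))

small_patient_config <- function(seed = 1L, ...) {
  patient_config(seed = seed, cam = small_camera(), roi_size = 12L,
                 frames_per_sequence = 40L, ...)
}

small_study_config <- function(n_patients = 2, base_seed = 1L,
                               profile = "clear", eval_frames = 30L,
                               frames_per_sequence = 35L, ...) {
  study_config(n_patients = n_patients, base_seed = base_seed,
               profile = profile, pretrain = FALSE,
               eval_frames = eval_frames, cam = small_camera(),
               roi_size = 12L, frames_per_sequence = frames_per_sequence,
               ...)
}

# constant-extinction table for closed-form absorption checks
flat_extinction_table <- function(eps_hbo2 = 1000, eps_hb = 500) {
  structure(list(wavelengths = c(300, 1000),
                 eps_hbo2 = rep(eps_hbo2, 2),
                 eps_hb = rep(eps_hb, 2)),
            class = "extinction_table")
}

# single-layer tissue wrapped in the 3-slab container (all slabs identical)
uniform_tissue <- function(v_hb, s, a_mie, b_mie, g, n, d) {
  msimon:::tissue_sample_from_layers(
    data.frame(v_hb = rep(v_hb, 3), s = rep(s, 3), a_mie = rep(a_mie, 3),
               b_mie = rep(b_mie, 3), g = rep(g, 3), n = rep(n, 3),
               d = rep(d / 3, 3)))
}

# Independent straightforward photon-loop reference for a single uniform
# slab with matched refractive indices: plain R, no carried-step bookkeeping
# (the step is resampled after boundary reflections, which is unbiased for a
# homogeneous medium).
mc_slab_oracle <- function(mua, mus, g, d, n_photons) {
  mt <- mua + mus
  refl <- 0
  for (p in seq_len(n_photons)) {
    w <- 1
    z <- 0
    u <- c(0, 0, 1)
    repeat {
      step <- -log(runif(1)) / mt
      znew <- z + step * u[3]
      if (znew < 0) { refl <- refl + w; break }
      if (znew > d) break
      z <- znew
      w <- w * mus / mt
      if (w < 1e-4) {
        if (runif(1) < 0.1) w <- w * 10 else break
      }
      # Henyey-Greenstein deflection
      if (abs(g) < 1e-6) {
        ct <- 2 * runif(1) - 1
      } else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * runif(1))
        ct <- (1 + g^2 - tmp^2) / (2 * g)
      }
      st <- sqrt(max(0, 1 - ct^2))
      phi <- 2 * pi * runif(1)
      if (abs(u[3]) > 0.99999) {
        u <- c(st * cos(phi), st * sin(phi), sign(u[3]) * ct)
      } else {
        den <- sqrt(1 - u[3]^2)
        u <- c(st * (u[1] * u[3] * cos(phi) - u[2] * sin(phi)) / den + u[1] * ct,
               st * (u[2] * u[3] * cos(phi) + u[1] * sin(phi)) / den + u[2] * ct,
               -st * cos(phi) * den + u[3] * ct)
      }
    }
  }
  refl / n_photons
}

# exhaustive pair-counting AU-ROC reference
auroc_bruteforce <- function(negatives, positives) {
  tot <- 0
  for (p in positives) {
    for (n in negatives) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(positives) * length(negatives))
}
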