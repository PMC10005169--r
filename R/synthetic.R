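#' Configuration for one synthetic patient session
#'
#' Defines the forward model of a synthetic recording session: a perfused
#' three-layer tissue state drawn from physiologically plausible sub-ranges,
#' an ischemic state derived from it by an oxygenation drop and a blood
#' volume scale factor, per-patient spectral offsets, illumination rescaling
#' between sequences (emulating laparoscope reinsertion), sensor count noise
#' and saturation defects.
#'
#' @param seed Integer seed; the whole session is a deterministic function of
#'   the configuration.
#' @param frames_per_sequence Frames per recorded sequence (default 80).
#' @param roi_size ROI edge length in band-cube pixels (default 30).
#' @param delta_s Absolute oxygenation change of the ischemic state
#'   (default -0.30).
#' @param vhb_scale Blood-volume scale factor of the ischemic state
#'   (default 0.5).
#' @param illum_range Range of the per-sequence illumination scale.
#' @param noise_sd_frac Relative sensor noise SD as a fraction of the signal
#'   (shot-noise-dominated regime; default 0.01, i.e. SNR 100).
#' @param sat_defect_frac Fraction of mosaic pixels forced to full scale per
#'   frame (default 0.001).
#' @param jitter_sd SD of the per-pixel lognormal reflectance jitter
#'   (default 0.02).
#' @param band_offset_sd SD of the per-patient (smoothed, multiplicative)
#'   band offset shared by all sequences (default 0.08).
#' @param n_photons Photons per wavelength for the per-state MC runs.
#' @param wavelength_step MC grid step in nm (interpolated to the camera grid
#'   before band integration).
#' @param dark_level,white_level Dark counts and white-minus-dark span.
#' @param saturation_limit Full-scale counts (default 1023, 10-bit).
#' @param cam Optional [camera_model()] (default camera if NULL).
#' @return Object of class `patient_config`.
#' @export
patient_config <- function(seed = 1L, frames_per_sequence = 80L,
                           roi_size = 30L, delta_s = -0.30, vhb_scale = 0.5,
                           illum_range = c(0.85, 1.0), noise_sd_frac = 0.01,
                           sat_defect_frac = 0.001, jitter_sd = 0.02,
                           band_offset_sd = 0.08, n_photons = 1500,
                           wavelength_step = 8, dark_level = 50,
                           white_level = 900, saturation_limit = 1023,
                           cam = NULL) {
  stopifnot(delta_s <= 0, delta_s >= -1, vhb_scale >= 0, vhb_scale <= 1,
            frames_per_sequence >= 1, roi_size >= 1)
  structure(as.list(environment()), class = "patient_config")
}

smooth_band_offset <- function(n_bands, sd) {
  raw <- stats::rnorm(n_bands, 0, sd)
  sm <- stats::filter(raw, rep(1 / 3, 3), sides = 2, circular = TRUE)
  exp(as.numeric(sm))
}

draw_perfused_layers <- function() {
  data.frame(v_hb = stats::runif(3, 0.05, 0.25),
             s = stats::runif(3, 0.50, 0.90),
             a_mie = stats::runif(3, 10, 40),
             b_mie = stats::runif(3, 0.5, 2),
             g = stats::runif(3, 0.85, 0.90),
             n = stats::runif(3, 1.36, 1.44),
             d = stats::runif(3, 0.01, 0.15))
}

check_layer_ranges <- function(layers) {
  rg <- tissue_param_ranges()
  for (nm in names(rg)) {
    if (any(layers[[nm]] < rg[[nm]][1] - 1e-12) ||
        any(layers[[nm]] > rg[[nm]][2] + 1e-12)) {
      stop(sprintf("layer parameter '%s' outside the sampling range", nm))
    }
  }
  invisible(TRUE)
}

random_roi_track <- function(n_frames, roi_size, row_lim, col_lim) {
  if (row_lim[2] - row_lim[1] - roi_size + 1L < 1L ||
      col_lim[2] - col_lim[1] - roi_size + 1L < 1L) {
    stop("roi_size does not fit within the band-cube bounds")
  }
  top <- sample.int(row_lim[2] - row_lim[1] - roi_size + 1L, 1L) +
    row_lim[1] - 1L
  left <- sample.int(col_lim[2] - col_lim[1] - roi_size + 1L, 1L) +
    col_lim[1] - 1L
  tops <- integer(n_frames)
  lefts <- integer(n_frames)
  for (t in seq_len(n_frames)) {
    top <- min(max(top + sample(-2:2, 1L), row_lim[1]),
               row_lim[2] - roi_size + 1L)
    left <- min(max(left + sample(-2:2, 1L), col_lim[1]),
                col_lim[2] - roi_size + 1L)
    tops[t] <- top
    lefts[t] <- left
  }
  data.frame(frame = seq_len(n_frames), top = tops, left = lefts,
             height = roi_size, width = roi_size, valid = TRUE)
}

#' Generate one full synthetic patient session
#'
#' Runs the forward model: Monte-Carlo reflectance spectra of the perfused
#' and ischemic tissue states (simulated with common random numbers, so a
#' null ischemia profile yields bit-identical state spectra), band
#' integration through the camera model, a per-patient multiplicative band
#' offset, per-pixel lognormal jitter, per-sequence illumination rescaling
#' with small per-frame flicker, mosaic assembly, additive Gaussian count
#' noise, saturation defects and quantization. White and dark reference
#' frames (averaged over 5 simulated repeats) and two non-overlapping
#' drifting ROI tracks per sequence are emitted alongside ground truth.
#'
#' @param cfg A [patient_config()].
#' @return Object of class `msi_session` with elements `sequences`
#'   (perfused_1, perfused_2, ischemic; integer frame arrays H x W x T),
#'   `references` (white/dark mosaic frames), `tracks` (data.frame),
#'   `camera`, `saturation_limit`, and `truth`.
#' @export
generate_patient <- function(cfg) {
  stopifnot(inherits(cfg, "patient_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  cam <- cfg$cam %||% camera_model()
  h <- cam$sensor_shape[1] %/% 4L
  w <- cam$sensor_shape[2] %/% 4L
  sat <- cfg$saturation_limit

  perf <- draw_perfused_layers()
  isch <- perf
  isch$s <- pmin(pmax(isch$s + cfg$delta_s, 0), 1)
  isch$v_hb <- isch$v_hb * cfg$vhb_scale
  check_layer_ranges(perf)
  check_layer_ranges(isch)

  offset <- smooth_band_offset(cam$n_bands, cfg$band_offset_sd)
  illum <- stats::setNames(
    stats::runif(3, cfg$illum_range[1], cfg$illum_range[2]),
    c("perfused_1", "perfused_2", "ischemic"))

  # common random numbers across states: same MC seed for both runs
  mc_seed <- (cfg$seed + 499979L) %% .Machine$integer.max
  grid <- seq(min(cam$wavelengths), max(cam$wavelengths),
              by = cfg$wavelength_step)
  sp_perf <- simulate_reflectance(tissue_sample_from_layers(perf),
                                  wavelengths = grid,
                                  n_photons = cfg$n_photons, seed = mc_seed)
  sp_isch <- simulate_reflectance(tissue_sample_from_layers(isch),
                                  wavelengths = grid,
                                  n_photons = cfg$n_photons, seed = mc_seed)
  band_of <- function(sp) {
    fine <- stats::approx(grid, sp$reflectance, xout = cam$wavelengths,
                          rule = 2)$y
    b <- integrate_bands(fine, cam) * offset
    pmin(pmax(b, 0), 1)
  }
  rb <- list(perfused = band_of(sp_perf), ischemic = band_of(sp_isch))

  n_t <- cfg$frames_per_sequence
  n_px <- h * w
  sequences <- list()
  tracks <- list()
  for (sq in c("perfused_1", "perfused_2", "ischemic")) {
    state <- if (sq == "ischemic") "ischemic" else "perfused"
    base <- rb[[state]]
    frames <- array(0L, dim = c(cam$sensor_shape[1], cam$sensor_shape[2], n_t))
    for (t in seq_len(n_t)) {
      flick <- stats::runif(1, 0.97, 1.03)
      jit <- exp(stats::rnorm(n_px * cam$n_bands, 0, cfg$jitter_sd))
      cube <- array(rep(base, each = n_px) * jit, dim = c(h, w, cam$n_bands))
      cube <- cube * (illum[[sq]] * flick)
      signal <- cfg$white_level * mosaic(cube, cam)
      # shot-noise-dominated sensor: noise scales with the signal, so the
      # relative noise level is independent of the illumination intensity
      signal <- signal * (1 + stats::rnorm(length(signal), 0, cfg$noise_sd_frac))
      counts <- cfg$dark_level + signal
      if (cfg$sat_defect_frac > 0) {
        bad <- stats::runif(length(counts)) < cfg$sat_defect_frac
        counts[bad] <- sat
      }
      counts[counts < 0] <- 0
      counts[counts > sat] <- sat
      frames[, , t] <- as.integer(round(counts))
    }
    sequences[[sq]] <- list(frames = frames)
    margin <- 3L
    tr1 <- random_roi_track(n_t, cfg$roi_size, c(1L + margin, h - margin),
                            c(1L + margin, w %/% 2L - 1L))
    tr2 <- random_roi_track(n_t, cfg$roi_size, c(1L + margin, h - margin),
                            c(w %/% 2L + 1L, w - margin))
    tr1$roi_id <- 1L
    tr2$roi_id <- 2L
    tr <- rbind(tr1, tr2)
    tr$sequence <- sq
    tracks[[sq]] <- tr
  }

  ref_frac <- cfg$noise_sd_frac / sqrt(5)   # 5 averaged repeats
  dims <- cam$sensor_shape
  white <- matrix(cfg$dark_level + cfg$white_level *
                    (1 + stats::rnorm(prod(dims), 0, ref_frac)),
                  dims[1], dims[2])
  dark <- matrix(cfg$dark_level *
                   (1 + stats::rnorm(prod(dims), 0, ref_frac)),
                 dims[1], dims[2])

  structure(
    list(sequences = sequences,
         references = list(white = white, dark = dark),
         tracks = do.call(rbind, tracks),
         camera = cam,
         saturation_limit = sat,
         truth = list(config = cfg, perfused_layers = perf,
                      ischemic_layers = isch, band_offset = offset,
                      illumination = illum,
                      band_perfused = rb$perfused,
                      band_ischemic = rb$ischemic)),
    class = "msi_session")
}

#' @exportS3Method base::print
print.msi_session <- function(x, ...) {
  cat(sprintf("msi_session: %d sequences x %d frames, sensor %dx%d, seed %d\n",
              length(x$sequences), dim(x$sequences[[1]]$frames)[3],
              dim(x$sequences[[1]]$frames)[1], dim(x$sequences[[1]]$frames)[2],
              x$truth$config$seed))
  invisible(x)
}

#' Per-patient configurations of a synthetic cohort
#'
#' Derives one deterministic [patient_config()] per patient from a base seed
#' and a separation profile: "clear" applies a clearly separated ischemic
#' state to every patient (oxygenation -0.30, blood volume halved), "hard"
#' additionally turns the last patient into a near-null case with almost no
#' state separation, and "null" removes the state difference entirely.
#'
#' @param n_patients Number of patients (default 10).
#' @param base_seed Base seed.
#' @param profile "clear", "hard" or "null".
#' @param ... Further arguments forwarded to [patient_config()].
#' @return List of `patient_config` objects.
#' @export
cohort_configs <- function(n_patients = 10, base_seed = 1L,
                           profile = c("clear", "hard", "null"), ...) {
  profile <- match.arg(profile)
  lapply(seq_len(n_patients), function(i) {
    seed_i <- as.integer((base_seed + i * 7919) %% .Machine$integer.max)
    if (profile == "null") {
      patient_config(seed = seed_i, delta_s = 0, vhb_scale = 1, ...)
    } else if (profile == "hard" && i == n_patients) {
      patient_config(seed = seed_i, delta_s = -0.02, vhb_scale = 0.95, ...)
    } else {
      patient_config(seed = seed_i, ...)
    }
  })
}

#' Generate a synthetic cohort of patient sessions
#'
#' @inheritParams cohort_configs
#' @return List of `msi_session` objects (one per patient).
#' @export
generate_cohort <- function(n_patients = 10, base_seed = 1L,
                            profile = c("clear", "hard", "null"), ...) {
  cfgs <- cohort_configs(n_patients, base_seed, match.arg(profile), ...)
  lapply(cfgs, generate_patient)
}
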