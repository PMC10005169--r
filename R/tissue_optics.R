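#' Load a hemoglobin extinction-coefficient table
#'
#' Reads a CSV with columns `wavelength_nm,eps_hbo2,eps_hb` (molar extinction
#' coefficients in L mol^-1 cm^-1) and linearly interpolates it onto an
#' optional target wavelength grid. The bundled default table
#' (`hb_extinction_approx.csv`) is an approximate compilation assembled for
#' simulation use: it reproduces the standard qualitative landmarks of the
#' oxy-/deoxyhemoglobin curves (Soret band near 414/430 nm, alpha/beta bands
#' near 540-577 nm, isosbestic points near 500, 569 and 800 nm) but is not a
#' metrology-grade reference.
#'
#' @param path CSV path; default is the bundled approximate table.
#' @param wavelengths Optional target grid (nm) to interpolate onto.
#' @return Object of class `extinction_table`: list with `wavelengths`,
#'   `eps_hbo2`, `eps_hb`.
#' @export
load_extinction_table <- function(path = system.file("extdata",
                                                     "hb_extinction_approx.csv",
                                                     package = "msimon"),
                                  wavelengths = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hb") %in% names(df)))
  if (any(df$eps_hbo2 < 0) || any(df$eps_hb < 0)) {
    stop("extinction coefficients must be nonnegative")
  }
  if (!is.null(wavelengths)) {
    if (min(wavelengths) < min(df$wavelength_nm) ||
        max(wavelengths) > max(df$wavelength_nm)) {
      stop("requested wavelengths outside the table range")
    }
    e2 <- stats::approx(df$wavelength_nm, df$eps_hbo2, xout = wavelengths)$y
    e1 <- stats::approx(df$wavelength_nm, df$eps_hb, xout = wavelengths)$y
    tab <- list(wavelengths = wavelengths, eps_hbo2 = e2, eps_hb = e1)
  } else {
    tab <- list(wavelengths = df$wavelength_nm, eps_hbo2 = df$eps_hbo2,
                eps_hb = df$eps_hb)
  }
  structure(tab, class = "extinction_table")
}

eps_at <- function(tab, lambda) {
  if (any(lambda < min(tab$wavelengths)) || any(lambda > max(tab$wavelengths))) {
    stop("wavelength outside the extinction table range")
  }
  list(hbo2 = stats::approx(tab$wavelengths, tab$eps_hbo2, xout = lambda)$y,
       hb = stats::approx(tab$wavelengths, tab$eps_hb, xout = lambda)$y)
}

#' Blood absorption coefficient of a tissue layer
#'
#' mu_a = v_hb \[s eps_HbO2 + (1 - s) eps_Hb\] ln(10) c_Hb / M_Hb with a
#' whole-blood hemoglobin concentration of 150 g/L and a hemoglobin molar
#' mass of 6.45e4 g/mol.
#'
#' @param v_hb Blood volume fraction in \[0, 1\].
#' @param s Oxygenation fraction in \[0, 1\].
#' @param lambda Wavelength(s) in nm, within the table range.
#' @param tab An [load_extinction_table()] result.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
absorption_coefficient <- function(v_hb, s, lambda,
                                   tab = load_extinction_table()) {
  stopifnot(v_hb >= 0, v_hb <= 1, s >= 0, s <= 1)
  e <- eps_at(tab, lambda)
  v_hb * (s * e$hbo2 + (1 - s) * e$hb) * log(10) * 150 / 64500
}

#' Mie-type scattering coefficient
#'
#' mu_s = a_mie / (1 - g) * (lambda / 500 nm)^(-b_mie), where a_mie is the
#' reduced scattering coefficient at 500 nm and g the scattering anisotropy.
#'
#' @param a_mie Reduced scattering at 500 nm (cm^-1).
#' @param b_mie Scattering power (unitless).
#' @param g Henyey-Greenstein anisotropy, strictly below 1.
#' @param lambda Wavelength(s) in nm.
#' @return Scattering coefficient(s) in cm^-1.
#' @export
scattering_coefficient <- function(a_mie, b_mie, g, lambda) {
  if (any(g >= 1)) stop("anisotropy g must be < 1")
  a_mie / (1 - g) * (lambda / 500)^(-b_mie)
}

tissue_param_ranges <- function() {
  list(v_hb = c(0, 0.30), s = c(0, 1), a_mie = c(5, 50), b_mie = c(0.3, 3),
       g = c(0.80, 0.95), n = c(1.33, 1.54), d = c(0.002, 0.2))
}

#' Sample random three-layer tissue configurations
#'
#' Draws, independently for each of the three slabs, uniform physiological
#' and optical parameters: blood volume fraction v_hb in \[0, 0.30\],
#' oxygenation s in \[0, 1\], reduced scattering at 500 nm a_mie in \[5, 50\]
#' cm^-1, scattering power b_mie in \[0.3, 3\], anisotropy g in \[0.80,
#' 0.95\], refractive index n in \[1.33, 1.54\] and thickness d in \[0.002,
#' 0.2\] cm.
#'
#' @param n Number of tissue samples.
#' @param seed Optional integer seed (local to this call).
#' @return List of `tissue_sample` objects; each holds `layers`, a 3-row
#'   data.frame with columns v_hb, s, a_mie, b_mie, g, n, d.
#' @export
sample_tissue <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  rg <- tissue_param_ranges()
  lapply(seq_len(n), function(i) {
    layers <- as.data.frame(lapply(rg, function(r) stats::runif(3, r[1], r[2])))
    structure(list(layers = layers), class = "tissue_sample")
  })
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

tissue_sample_from_layers <- function(layers) {
  stopifnot(nrow(layers) == 3)
  structure(list(layers = layers), class = "tissue_sample")
}

#' Simulate the diffuse reflectance spectrum of layered tissue
#'
#' Monte-Carlo photon transport through infinitely wide slabs: photons are
#' launched normally from an ambient medium (n = 1), lose the specular
#' fraction at entry, take exponentially distributed steps with mu_t = mu_a +
#' mu_s, scatter by Henyey-Greenstein phase functions, undergo Fresnel
#' reflection/refraction at layer boundaries (ambient n = 1 below the last
#' layer), and are terminated by Russian roulette (survival probability 0.1
#' below weight 1e-4). The reported reflectance is the total fraction of
#' launched weight escaping through the top surface (specular plus diffuse).
#'
#' @param sample A `tissue_sample` (see [sample_tissue()]).
#' @param wavelengths Simulation grid in nm (default 300-1000 by 2).
#' @param n_photons Photons per wavelength (>= 100).
#' @param tab Extinction table for the absorption coefficients.
#' @param seed Optional integer seed (local to this call).
#' @return Object of class `simulated_spectrum`: list with `wavelengths`,
#'   `reflectance`, `transmittance`, `absorbed`, `n_photons`.
#' @export
simulate_reflectance <- function(sample, wavelengths = seq(300, 1000, by = 2),
                                 n_photons = 1e4,
                                 tab = load_extinction_table(),
                                 seed = NULL) {
  stopifnot(inherits(sample, "tissue_sample"), n_photons >= 100)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  ly <- sample$layers
  mua <- vapply(seq_len(3), function(l) {
    absorption_coefficient(ly$v_hb[l], ly$s[l], wavelengths, tab)
  }, numeric(length(wavelengths)))
  mus <- vapply(seq_len(3), function(l) {
    scattering_coefficient(ly$a_mie[l], ly$b_mie[l], ly$g[l], wavelengths)
  }, numeric(length(wavelengths)))
  if (any(!is.finite(mua)) || any(!is.finite(mus))) {
    stop("non-finite optical coefficients")
  }
  res <- mc_multilayer(mua, mus, ly$g, ly$n, ly$d, as.integer(n_photons))
  structure(
    list(wavelengths = wavelengths,
         reflectance = res$reflectance,
         transmittance = res$transmittance,
         absorbed = res$absorbed,
         n_photons = n_photons),
    class = "simulated_spectrum")
}

#' Build a corpus of simulated camera band spectra for flow pretraining
#'
#' Samples random tissue configurations, simulates their reflectance spectra
#' by Monte-Carlo transport on a (possibly coarser) wavelength grid, linearly
#' interpolates each spectrum onto the camera grid, integrates it into the 16
#' camera bands, and optionally l2-normalizes the band vectors to match the
#' representation of preprocessed patient spectra.
#'
#' @param n_samples Number of tissue samples.
#' @param cam A [camera_model()].
#' @param n_photons Photons per wavelength for each sample.
#' @param wavelength_step MC simulation grid step in nm (interpolated back to
#'   the camera grid before band integration).
#' @param tab Extinction table.
#' @param l2 Logical; l2-normalize the band vectors (default TRUE).
#' @param seed Optional integer seed (local to this call).
#' @return n_samples x n_bands matrix; tissue parameters are attached as the
#'   `params` attribute (list of layer data.frames).
#' @export
build_pretraining_corpus <- function(n_samples, cam, n_photons = 2000,
                                     wavelength_step = 6,
                                     tab = load_extinction_table(),
                                     l2 = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  grid <- seq(min(cam$wavelengths), max(cam$wavelengths), by = wavelength_step)
  samples <- sample_tissue(n_samples)
  out <- matrix(NA_real_, n_samples, cam$n_bands)
  for (i in seq_len(n_samples)) {
    sp <- simulate_reflectance(samples[[i]], wavelengths = grid,
                               n_photons = n_photons, tab = tab)
    r_fine <- stats::approx(grid, sp$reflectance, xout = cam$wavelengths,
                            rule = 2)$y
    bands <- integrate_bands(r_fine, cam)
    if (l2) {
      nb <- sqrt(sum(bands^2))
      if (nb <= 0) stop("degenerate zero spectrum in corpus")
      bands <- bands / nb
    }
    out[i, ] <- bands
  }
  attr(out, "params") <- lapply(samples, function(s) s$layers)
  attr(out, "n_photons") <- n_photons
  out
}
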