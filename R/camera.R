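#' Snapshot-mosaic multispectral camera model
#'
#' Bundles everything needed to map a high-resolution reflectance spectrum to
#' the 16 band measurements of a 4x4 snapshot-mosaic sensor: the per-band
#' filter response curves, the combined transmission of the optics train
#' (laparoscope, bandpass filter, C-Mount adapter), the relative irradiance of
#' the light source, and the spatial layout of the mosaic on the sensor.
#'
#' All curves are tabulated on a common wavelength grid (default 300-1000 nm
#' in 2 nm steps). The default filter responses are synthetic Gaussians; bands
#' 6 to 13 (1-based) additionally carry a secondary transmission peak at lower
#' wavelengths, mimicking the second-order peaks of Fabry-Perot mosaic
#' filters. The default optics transmission models a 335-610 nm bandpass with
#' soft edges, and the default illuminant is spectrally flat.
#'
#' @param wavelengths Wavelength grid in nm (regular, increasing).
#' @param filter_responses 16 x length(wavelengths) nonnegative matrix of
#'   filter response curves, one row per band.
#' @param optics_transmission Combined transmission of all optical components
#'   on the wavelength grid (one value per wavelength, in \[0, 1\]).
#' @param illuminant Relative spectral irradiance of the light source.
#' @param mosaic_layout 4x4 integer matrix assigning a band index 0-15 to each
#'   offset of the repeating mosaic; must be a permutation of 0..15.
#' @param sensor_shape Integer vector c(rows, cols), both divisible by 4.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(wavelengths = seq(300, 1000, by = 2),
                         filter_responses = NULL,
                         optics_transmission = NULL,
                         illuminant = NULL,
                         mosaic_layout = matrix(0:15, 4, 4, byrow = TRUE),
                         sensor_shape = c(272L, 512L)) {
  stopifnot(is.numeric(wavelengths), length(wavelengths) >= 2,
            all(diff(wavelengths) > 0))
  nl <- length(wavelengths)
  if (is.null(filter_responses)) {
    filter_responses <- default_filter_responses(wavelengths)
  }
  if (is.null(optics_transmission)) {
    optics_transmission <- default_optics_transmission(wavelengths)
  }
  if (is.null(illuminant)) {
    illuminant <- rep(1, nl)
  }
  filter_responses <- as.matrix(filter_responses)
  if (ncol(filter_responses) != nl) {
    stop("filter_responses must have one column per wavelength")
  }
  if (any(filter_responses < 0)) stop("filter_responses must be nonnegative")
  n_bands <- nrow(filter_responses)
  if (length(optics_transmission) != nl || length(illuminant) != nl) {
    stop("all curves must share the wavelength grid")
  }
  mosaic_layout <- matrix(as.integer(mosaic_layout), 4, 4)
  if (n_bands == 16L && !identical(sort(as.integer(mosaic_layout)), 0:15)) {
    stop("mosaic_layout must be a permutation of 0..15")
  }
  sensor_shape <- as.integer(sensor_shape)
  if (any(sensor_shape %% 4L != 0L)) {
    stop("sensor_shape must be divisible by 4 in both axes")
  }
  structure(
    list(wavelengths = wavelengths,
         filter_responses = filter_responses,
         optics_transmission = as.numeric(optics_transmission),
         illuminant = as.numeric(illuminant),
         mosaic_layout = mosaic_layout,
         sensor_shape = sensor_shape,
         n_bands = n_bands),
    class = "camera_model")
}

#' @exportS3Method base::print
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %d bands, %d wavelengths (%g-%g nm), sensor %dx%d\n",
              x$n_bands, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$sensor_shape[1], x$sensor_shape[2]))
  invisible(x)
}

#' Default synthetic filter responses of the 16-band mosaic sensor
#'
#' Gaussian primary peaks spread over the visible range covered by the
#' bandpass filter; bands 6-13 carry an additional second-order peak.
#'
#' @param wavelengths Wavelength grid in nm.
#' @param centers Primary peak centers (nm), one per band.
#' @param sd Primary peak standard deviation (nm).
#' @param second_order_bands 1-based band indices that carry a secondary peak.
#' @param second_order_shift Offset of the secondary peak below the primary (nm).
#' @param second_order_amp Relative amplitude of the secondary peak.
#' @return 16 x length(wavelengths) response matrix.
#' @export
default_filter_responses <- function(wavelengths,
                                     centers = seq(462, 618, length.out = 16),
                                     sd = 12,
                                     second_order_bands = 6:13,
                                     second_order_shift = 140,
                                     second_order_amp = 0.35) {
  resp <- t(vapply(seq_along(centers), function(k) {
    f <- exp(-0.5 * ((wavelengths - centers[k]) / sd)^2)
    if (k %in% second_order_bands) {
      f <- f + second_order_amp *
        exp(-0.5 * ((wavelengths - (centers[k] - second_order_shift)) / (sd * 0.8))^2)
    }
    f
  }, numeric(length(wavelengths))))
  resp
}

#' Default combined optics transmission
#'
#' Smooth product of a 335-610 nm bandpass filter (logistic edges), a
#' laparoscope transmission rising slowly with wavelength, and a flat C-Mount
#' adapter.
#'
#' @param wavelengths Wavelength grid in nm.
#' @return Transmission in (0, 1) per wavelength.
#' @export
default_optics_transmission <- function(wavelengths) {
  bandpass <- stats::plogis((wavelengths - 335) / 8) *
    stats::plogis((610 - wavelengths) / 8)
  scope <- 0.55 + 0.35 * stats::plogis((wavelengths - 420) / 60)
  cmount <- 0.95
  bandpass * scope * cmount
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Integrate a reflectance spectrum into camera band measurements
#'
#' Computes, for each band k, the weighted mean reflectance
#' r_k = int T(l) I(l) f_k(l) r(l) dl / int T(l) I(l) f_k(l) dl
#' by trapezoidal quadrature on the camera wavelength grid. The weighting
#' folds the optics transmission and illuminant into the effective band
#' response, so a spectrally flat reflectance maps to that same constant in
#' every band.
#'
#' @param spectrum Reflectance per wavelength, on `cam$wavelengths`.
#' @param cam A [camera_model()].
#' @return Numeric vector of band measurements (length `cam$n_bands`).
#' @export
integrate_bands <- function(spectrum, cam) {
  stopifnot(inherits(cam, "camera_model"))
  if (length(spectrum) != length(cam$wavelengths)) {
    stop("spectrum must be defined on the camera wavelength grid")
  }
  w <- cam$wavelengths
  base <- cam$optics_transmission * cam$illuminant
  out <- numeric(cam$n_bands)
  for (k in seq_len(cam$n_bands)) {
    wk <- base * cam$filter_responses[k, ]
    den <- trapz(w, wk)
    if (!is.finite(den) || den <= 0) {
      stop(sprintf("band %d has zero weighted response", k))
    }
    out[k] <- trapz(w, wk * spectrum) / den
  }
  out
}

#' Collapse a mosaic frame into a band cube
#'
#' Each non-overlapping 4x4 tile of the sensor becomes one multispectral
#' pixel; the band order of the output follows the camera band indexing, using
#' `cam$mosaic_layout` to locate each band within the tile. No spatial
#' interpolation is performed, so the cube is 1/4 of the sensor resolution in
#' each axis and the operation is exactly invertible (see [mosaic()]).
#'
#' @param frame Matrix of sensor counts with `dim(frame) == cam$sensor_shape`
#'   (any matrix with dimensions divisible by 4 is accepted).
#' @param cam A [camera_model()].
#' @return Array (rows/4) x (cols/4) x 16 of per-band values.
#' @export
demosaic <- function(frame, cam) {
  stopifnot(inherits(cam, "camera_model"), is.matrix(frame))
  h <- nrow(frame); w <- ncol(frame)
  if (h %% 4L != 0L || w %% 4L != 0L) {
    stop("frame dimensions must be divisible by 4")
  }
  cube <- array(0, dim = c(h %/% 4L, w %/% 4L, 16L))
  for (i in 1:4) {
    for (j in 1:4) {
      b <- cam$mosaic_layout[i, j] + 1L
      cube[, , b] <- frame[seq.int(i, h, by = 4L), seq.int(j, w, by = 4L)]
    }
  }
  cube
}

#' Reassemble a mosaic frame from a band cube (inverse of demosaic)
#'
#' @param cube Array h x w x 16 of band values.
#' @param cam A [camera_model()].
#' @return Matrix (4h) x (4w) of mosaic values.
#' @export
mosaic <- function(cube, cam) {
  stopifnot(inherits(cam, "camera_model"), length(dim(cube)) == 3,
            dim(cube)[3] == 16L)
  h <- dim(cube)[1] * 4L; w <- dim(cube)[2] * 4L
  frame <- matrix(0, h, w)
  for (i in 1:4) {
    for (j in 1:4) {
      b <- cam$mosaic_layout[i, j] + 1L
      frame[seq.int(i, h, by = 4L), seq.int(j, w, by = 4L)] <- cube[, , b]
    }
  }
  frame
}

#' Fit the multispectral-to-RGB reconstruction transform
#'
#' Builds an artificial RGB camera from three Gaussian filters (default
#' centers 460/550/640 nm, SD 42 nm), scales the multispectral filter
#' responses by the optics transmission to obtain the effective camera
#' response, solves the least-squares problem F_rgb ~ F' T' for the 16 -> 3
#' transform, and normalizes each RGB channel so that a spectrally flat band
#' vector maps to (1, 1, 1).
#'
#' @param cam A [camera_model()].
#' @param centers RGB target filter centers in nm.
#' @param sd RGB target filter standard deviation in nm.
#' @return Object of class `rgb_transform` with elements `T` (3 x n_bands),
#'   `F_prime`, `F_rgb` and the normalizer `N`.
#' @export
fit_rgb_transform <- function(cam, centers = c(460, 550, 640), sd = 42) {
  stopifnot(inherits(cam, "camera_model"))
  w <- cam$wavelengths
  f_prime <- t(sweep(cam$filter_responses, 2, cam$optics_transmission, `*`))
  # f_prime: n_wavelengths x n_bands
  f_rgb <- vapply(centers, function(c0) exp(-0.5 * ((w - c0) / sd)^2),
                  numeric(length(w)))
  qrd <- qr(f_prime)
  if (qrd$rank < ncol(f_prime)) {
    stop("effective camera response is rank deficient")
  }
  t_min <- t(qr.coef(qrd, f_rgb))      # 3 x n_bands
  norm_vec <- rowSums(t_min)
  if (any(abs(norm_vec) < .Machine$double.eps * 100)) {
    stop("degenerate RGB normalization vector")
  }
  structure(
    list(T = t_min / norm_vec, F_prime = f_prime, F_rgb = f_rgb, N = norm_vec),
    class = "rgb_transform")
}

#' Reconstruct an RGB image from a band cube
#'
#' Per-pixel matrix product with the fitted transform, clipped to \[0, 1\].
#'
#' @param cube Array h x w x B of band values.
#' @param tf An [fit_rgb_transform()] result.
#' @return Array h x w x 3 with values in \[0, 1\].
#' @export
reconstruct_rgb <- function(cube, tf) {
  stopifnot(inherits(tf, "rgb_transform"), length(dim(cube)) == 3)
  if (dim(cube)[3] != ncol(tf$T)) stop("band count does not match transform")
  d <- dim(cube)
  flat <- matrix(cube, d[1] * d[2], d[3])
  rgb <- flat %*% t(tf$T)
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  array(rgb, dim = c(d[1], d[2], 3))
}

#' Smooth a measured transmission profile
#'
#' Averages repeated spectrometer measurements, applies a centered rolling
#' mean of approximately 19 nm width, and flags samples near the grid borders
#' (where no full window exists) and in the 400-419 nm and 681-700 nm ranges
#' as invalid to avoid smoothing border effects.
#'
#' @param raw Numeric vector (single measurement) or matrix with one
#'   measurement repeat per row.
#' @param wavelengths Regular wavelength grid in nm.
#' @param window_nm Rolling window width in nm (default 19).
#' @param exclude List of c(lo, hi) wavelength ranges to flag invalid.
#' @return data.frame with columns `wavelength`, `transmission`, `valid`;
#'   `transmission` is NA where no full window exists.
#' @export
smooth_transmission <- function(raw, wavelengths, window_nm = 19,
                                exclude = list(c(400, 419), c(681, 700))) {
  if (is.matrix(raw)) {
    if (ncol(raw) != length(wavelengths)) stop("raw repeats must match grid")
    avg <- colMeans(raw)
  } else {
    if (length(raw) != length(wavelengths)) stop("raw must match grid")
    avg <- as.numeric(raw)
  }
  step <- diff(wavelengths)
  if (max(step) - min(step) > 1e-8) stop("wavelength grid must be regular")
  step <- step[1]
  half <- max(1L, floor(window_nm / step / 2))
  win <- 2L * half + 1L
  n <- length(avg)
  if (win > n) stop("smoothing window larger than the measurement support")
  sm <- as.numeric(stats::filter(avg, rep(1 / win, win), sides = 2))
  valid <- !is.na(sm)
  for (rg in exclude) {
    valid[wavelengths >= rg[1] & wavelengths <= rg[2]] <- FALSE
  }
  data.frame(wavelength = wavelengths, transmission = sm, valid = valid)
}

#' Read a spectral curve or filter-response table from CSV
#'
#' Expects a header `wavelength_nm` followed by one column per curve (for
#' filter responses: `band_00` .. `band_15`); single-column files yield a
#' vector curve.
#'
#' @param path CSV file path.
#' @return list with `wavelengths` and either `curve` (vector) or `responses`
#'   (bands x wavelengths matrix).
#' @export
read_spectral_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) stop("missing wavelength_nm column")
  w <- df$wavelength_nm
  vals <- df[, setdiff(names(df), "wavelength_nm"), drop = FALSE]
  if (ncol(vals) == 1L) {
    list(wavelengths = w, curve = vals[[1]])
  } else {
    list(wavelengths = w, responses = t(as.matrix(vals)))
  }
}
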