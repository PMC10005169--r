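#' White/dark reference normalization
#'
#' Converts raw counts into reflectance estimates per pixel and band via
#' (I - D) / (W - D). Pixels where the white and dark references coincide in
#' any band are flagged invalid rather than raising an error.
#'
#' @param I Raw values (vector, matrix or array).
#' @param W White reference, same shape as `I` (averaged over repeats).
#' @param D Dark reference, same shape as `I`.
#' @return List with `values` (same shape as `I`, NA where invalid) and
#'   `valid` (logical, FALSE where W == D).
#' @export
reference_normalize <- function(I, W, D) {
  if (!identical(dim(I), dim(W)) || !identical(dim(I), dim(D)) ||
      length(I) != length(W) || length(I) != length(D)) {
    stop("I, W and D must have identical shapes")
  }
  den <- W - D
  valid <- den != 0
  vals <- (I - D) / den
  vals[!valid] <- NA_real_
  list(values = vals, valid = valid)
}

#' l2-normalize a spectrum
#'
#' Scales a band vector to unit Euclidean norm, making spectra invariant to
#' positive rescaling of the illumination intensity.
#'
#' @param spectrum Numeric vector (or matrix with one spectrum per row).
#' @return Same shape as the input; rows with zero (or non-finite) norm are
#'   returned as NA and flagged via the `valid` attribute.
#' @export
l2_normalize <- function(spectrum) {
  if (is.matrix(spectrum)) {
    nrm <- sqrt(rowSums(spectrum^2))
    valid <- is.finite(nrm) & nrm > 0
    out <- spectrum / nrm
    out[!valid, ] <- NA_real_
    attr(out, "valid") <- valid
    return(out)
  }
  nrm <- sqrt(sum(spectrum^2))
  if (!is.finite(nrm) || nrm <= 0) {
    out <- rep(NA_real_, length(spectrum))
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- spectrum / nrm
  attr(out, "valid") <- TRUE
  out
}

#' Saturation-based validity mask for an ROI
#'
#' A pixel is valid iff the raw counts of all its bands lie strictly inside
#' (low_thresh, high_thresh). A tracked sequence is accepted when at least 95%
#' of all tracked pixels are valid.
#'
#' @param counts N x M x B array (or pixels x B matrix) of raw counts.
#' @param low_thresh Undersaturation threshold in counts.
#' @param high_thresh Oversaturation threshold in counts.
#' @param accept_frac Minimum valid fraction for sequence acceptance.
#' @return List with `mask` (logical N x M or vector), `valid_fraction`, and
#'   `accepted`.
#' @export
valid_pixel_mask <- function(counts, low_thresh, high_thresh,
                             accept_frac = 0.95) {
  if (length(dim(counts)) == 3) {
    ok <- apply(counts > low_thresh & counts < high_thresh, c(1, 2), all)
  } else {
    m <- as.matrix(counts)
    ok <- rowSums(m > low_thresh & m < high_thresh) == ncol(m)
  }
  frac <- mean(ok)
  list(mask = ok, valid_fraction = frac, accepted = frac >= accept_frac)
}

#' Median spectrum of a normalized ROI
#'
#' Per-band median over the valid pixels of an ROI.
#'
#' @param spectra Pixels x B matrix of (normalized) spectra.
#' @param valid Logical vector of pixel validity (default all valid).
#' @return B-vector of medians.
#' @export
roi_median_spectrum <- function(spectra, valid = rep(TRUE, nrow(spectra))) {
  spectra <- as.matrix(spectra)
  keep <- valid & rowSums(!is.finite(spectra)) == 0
  if (!any(keep)) stop("ROI has no valid pixels")
  apply(spectra[keep, , drop = FALSE], 2, stats::median)
}

#' Extract normalized ROI spectra from a session sequence
#'
#' For each requested frame, demosaics the mosaic frame, cuts out each
#' tracked ROI in band-cube coordinates, normalizes it with the session's
#' (demosaiced) white and dark references, applies the saturation validity
#' rule on raw counts, and l2-normalizes the per-pixel band vectors.
#'
#' @param session An `msi_session` (see [generate_patient()]).
#' @param sequence One of "perfused_1", "perfused_2", "ischemic".
#' @param frames Frame indices to process (default first 70).
#' @param low_frac,high_frac Saturation thresholds as fractions of the
#'   saturation limit (defaults 0.05 and 0.98).
#' @return List with one element per ROI, each containing `spectra`
#'   (valid pixels x B, l2-normalized), `reflectance` (same rows, before l2),
#'   `frame` (frame index per row), `valid_fraction`, `accepted`.
#' @export
extract_roi_spectra <- function(session, sequence, frames = 1:70,
                                low_frac = 0.05, high_frac = 0.98) {
  stopifnot(inherits(session, "msi_session"))
  seq_data <- session$sequences[[sequence]]
  if (is.null(seq_data)) stop(sprintf("missing sequence '%s'", sequence))
  cam <- session$camera
  sat <- session$saturation_limit
  lo <- low_frac * sat
  hi <- high_frac * sat
  w_cube <- demosaic(session$references$white, cam)
  d_cube <- demosaic(session$references$dark, cam)
  tracks <- session$tracks[session$tracks$sequence == sequence, , drop = FALSE]
  if (nrow(tracks) == 0) stop(sprintf("missing ROI track for '%s'", sequence))
  roi_ids <- sort(unique(tracks$roi_id))
  n_frames_avail <- dim(seq_data$frames)[3]
  frames <- frames[frames <= n_frames_avail]

  out <- vector("list", length(roi_ids))
  names(out) <- paste0("roi", roi_ids)
  for (ri in seq_along(roi_ids)) {
    spec_list <- list()
    refl_list <- list()
    frame_ids <- integer(0)
    n_valid <- 0L
    n_total <- 0L
    for (t in frames) {
      rect <- tracks[tracks$roi_id == roi_ids[ri] & tracks$frame == t, ]
      if (nrow(rect) != 1 || !rect$valid) next
      cube <- demosaic(seq_data$frames[, , t], cam)
      rows <- rect$top:(rect$top + rect$height - 1L)
      cols <- rect$left:(rect$left + rect$width - 1L)
      sub <- cube[rows, cols, , drop = FALSE]
      sub_w <- w_cube[rows, cols, , drop = FALSE]
      sub_d <- d_cube[rows, cols, , drop = FALSE]
      np <- length(rows) * length(cols)
      nb <- dim(sub)[3]
      counts <- matrix(sub, np, nb)
      vm <- valid_pixel_mask(counts, lo, hi)
      rn <- reference_normalize(counts, matrix(sub_w, np, nb),
                                matrix(sub_d, np, nb))
      pix_valid <- vm$mask & rowSums(!rn$valid) == 0
      refl <- rn$values
      l2 <- l2_normalize(refl)
      pix_valid <- pix_valid & attr(l2, "valid")
      n_valid <- n_valid + sum(pix_valid)
      n_total <- n_total + np
      if (any(pix_valid)) {
        spec_list[[length(spec_list) + 1L]] <- l2[pix_valid, , drop = FALSE]
        refl_list[[length(refl_list) + 1L]] <- refl[pix_valid, , drop = FALSE]
        frame_ids <- c(frame_ids, rep.int(t, sum(pix_valid)))
      }
    }
    frac <- if (n_total > 0) n_valid / n_total else 0
    out[[ri]] <- list(spectra = do.call(rbind, spec_list),
                      reflectance = do.call(rbind, refl_list),
                      frame = frame_ids,
                      valid_fraction = frac,
                      accepted = frac >= 0.95)
  }
  out
}

#' Assemble the training tensor from the first perfused sequence
#'
#' Stacks the l2-normalized valid pixel spectra of all ROIs over the first
#' `n_frames` frames of perfused_1, the data used to fine-tune the per-patient
#' flow ensemble.
#'
#' @param session An `msi_session`.
#' @param n_frames Number of frames (default 70).
#' @param max_spectra Optional cap; a random subsample (under `seed`) is taken
#'   when more spectra are available.
#' @param seed Seed for the subsampling.
#' @return Matrix spectra x B.
#' @export
training_spectra <- function(session, n_frames = 70, max_spectra = NULL,
                             seed = 1L) {
  rois <- extract_roi_spectra(session, "perfused_1", frames = seq_len(n_frames))
  X <- do.call(rbind, lapply(rois, function(r) r$spectra))
  if (!is.null(max_spectra) && nrow(X) > max_spectra) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    X <- X[sample.int(nrow(X), max_spectra), , drop = FALSE]
  }
  X
}
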