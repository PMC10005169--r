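#' Assemble per-frame cohort spectra from sessions
#'
#' For every frame of the selected sequences of each session, takes the
#' median l2-normalized spectrum of each tracked ROI and averages the medians
#' across ROIs, yielding one row per patient, sequence and frame, labeled
#' with the perfusion state (perfused sequences 0, ischemic 1).
#'
#' @param sessions List of `msi_session` objects.
#' @param sequences Sequences to include (default all three).
#' @param n_frames Frames per sequence (default 70).
#' @return data.frame with columns patient, sequence, frame, state and one
#'   column per band (`band_01` ...).
#' @export
cohort_spectra <- function(sessions,
                           sequences = c("perfused_1", "perfused_2",
                                         "ischemic"),
                           n_frames = 70) {
  rows <- list()
  for (pi in seq_along(sessions)) {
    ses <- sessions[[pi]]
    for (sq in sequences) {
      rois <- extract_roi_spectra(ses, sq, frames = seq_len(n_frames))
      med_by_frame <- lapply(rois, function(r) {
        if (is.null(r$spectra)) return(NULL)
        frames <- sort(unique(r$frame))
        m <- t(vapply(frames, function(t) {
          apply(r$spectra[r$frame == t, , drop = FALSE], 2, stats::median)
        }, numeric(ncol(r$spectra))))
        rownames(m) <- frames
        m
      })
      frames <- sort(unique(unlist(lapply(med_by_frame, rownames))))
      for (t in frames) {
        mats <- lapply(med_by_frame, function(m) {
          if (!is.null(m) && t %in% rownames(m)) m[t, ] else NULL
        })
        mats <- mats[!vapply(mats, is.null, logical(1))]
        if (length(mats) == 0) next
        avg <- colMeans(do.call(rbind, mats))
        df <- data.frame(patient = pi, sequence = sq, frame = as.integer(t),
                         state = if (sq == "ischemic") 1L else 0L)
        df[paste0("band_", sprintf("%02d", seq_along(avg)))] <- as.list(avg)
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  do.call(rbind, rows)
}

#' PCA projection of cohort spectra
#'
#' Centered principal component analysis over all rows, reporting the scores
#' on the first two components and the per-component explained-variance
#' fractions.
#'
#' @param cohort data.frame from [cohort_spectra()], or a plain numeric
#'   matrix of spectra.
#' @param n_pc Number of components to keep (default 2).
#' @return List with `scores` (rows x n_pc), `explained` (variance fractions,
#'   all components), `rotation`, and the label columns of the input (if any).
#' @export
pca_project <- function(cohort, n_pc = 2) {
  if (is.data.frame(cohort)) {
    bands <- grep("^band_", names(cohort), value = TRUE)
    X <- as.matrix(cohort[, bands])
    labels <- cohort[, setdiff(names(cohort), bands), drop = FALSE]
  } else {
    X <- as.matrix(cohort)
    labels <- NULL
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE],
       explained = expl, rotation = pc$rotation, labels = labels)
}

#' Mixed-model variance decomposition for one band
#'
#' Fits the random-intercept model r_ij = alpha + beta S_ij + delta_i +
#' eps_ij by REML (delta_i: random patient effect; S_ij: 0/1 perfusion
#' state), and decomposes the variability into a fixed-state component
#' (beta^2 times the population variance of S over the design), the patient
#' variance sigma_delta^2 and the residual variance sigma_eps^2, normalized
#' to proportions.
#'
#' @param cohort data.frame from [cohort_spectra()].
#' @param band 1-based band index.
#' @return List with `alpha`, `beta`, `sigma_delta2`, `sigma_eps2`,
#'   `state_prop`, `patient_prop`, `residual_prop`, `converged`.
#' @export
fit_mixed_model <- function(cohort, band) {
  col <- paste0("band_", sprintf("%02d", band))
  stopifnot(col %in% names(cohort))
  if (length(unique(cohort$patient)) < 2) {
    stop("mixed model needs at least 2 patients")
  }
  if (length(unique(cohort$state)) < 2) {
    stop("mixed model needs both perfusion states")
  }
  df <- data.frame(r = cohort[[col]], S = cohort$state,
                   patient = factor(cohort$patient))
  fit <- tryCatch(
    lme4::lmer(r ~ S + (1 | patient), data = df, REML = TRUE),
    error = function(e) NULL)
  # boundary (singular) fits are valid REML solutions with a zero variance
  # component, not convergence failures
  msgs <- if (!is.null(fit)) unlist(fit@optinfo$conv$lme4) else "failed"
  conv <- length(msgs) == 0 || all(grepl("boundary", msgs))
  if (is.null(fit)) {
    return(list(alpha = NA, beta = NA, sigma_delta2 = NA, sigma_eps2 = NA,
                state_prop = NA, patient_prop = NA, residual_prop = NA,
                converged = FALSE))
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sig_d2 <- vc$vcov[vc$grp == "patient"]
  sig_e2 <- vc$vcov[vc$grp == "Residual"]
  var_s <- mean(df$S) * (1 - mean(df$S))
  v_state <- fe[["S"]]^2 * var_s
  tot <- v_state + sig_d2 + sig_e2
  props <- c(v_state, sig_d2, sig_e2) / tot
  list(alpha = fe[["(Intercept)"]], beta = fe[["S"]],
       sigma_delta2 = sig_d2, sigma_eps2 = sig_e2,
       state_prop = if (conv) props[1] else NA,
       patient_prop = if (conv) props[2] else NA,
       residual_prop = if (conv) props[3] else NA,
       converged = conv)
}

#' Variance decomposition across all bands
#'
#' @param cohort data.frame from [cohort_spectra()].
#' @return data.frame with one row per band: band, state_prop, patient_prop,
#'   residual_prop, converged.
#' @export
variance_decomposition <- function(cohort) {
  bands <- grep("^band_", names(cohort), value = TRUE)
  res <- lapply(seq_along(bands), function(k) {
    f <- fit_mixed_model(cohort, k)
    data.frame(band = k, state_prop = f$state_prop,
               patient_prop = f$patient_prop,
               residual_prop = f$residual_prop, converged = f$converged)
  })
  do.call(rbind, res)
}

#' Two-dimensional kernel density estimates per state
#'
#' Gaussian product-kernel KDE (normal-reference bandwidth) of 2-D scores,
#' evaluated per state on a shared grid wide enough that each surface
#' integrates to ~1.
#'
#' @param scores N x 2 matrix of (e.g. PCA) scores.
#' @param states Per-row state labels.
#' @param n_grid Grid resolution per axis (default 128).
#' @param pad Grid padding beyond the data range, in multiples of the
#'   bandwidth (default 4).
#' @return List per state: `x`, `y`, `z` (density surface), plus the shared
#'   `grid` ranges.
#' @export
kde_density_2d <- function(scores, states, n_grid = 128, pad = 4) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) == length(states))
  bw <- c(MASS::bandwidth.nrd(scores[, 1]), MASS::bandwidth.nrd(scores[, 2]))
  bw[bw <= 0] <- 1e-3
  lims <- c(min(scores[, 1]) - pad * bw[1], max(scores[, 1]) + pad * bw[1],
            min(scores[, 2]) - pad * bw[2], max(scores[, 2]) + pad * bw[2])
  out <- list()
  for (st in unique(states)) {
    pts <- scores[states == st, , drop = FALSE]
    bws <- c(MASS::bandwidth.nrd(pts[, 1]), MASS::bandwidth.nrd(pts[, 2]))
    for (i in 1:2) {
      if (!is.finite(bws[i]) || bws[i] <= 0) bws[i] <- bw[i]
    }
    kd <- MASS::kde2d(pts[, 1], pts[, 2], h = bws, n = n_grid, lims = lims)
    out[[as.character(st)]] <- kd
  }
  attr(out, "lims") <- lims
  out
}

#' Overlap integral of two density surfaces
#'
#' Integrates min(d1, d2) over the shared grid; 0 for disjoint, 1 for
#' identical densities.
#'
#' @param kd1,kd2 Surfaces from [kde_density_2d()] (elements with x, y, z).
#' @return Overlap integral in \[0, 1\].
#' @export
kde_overlap <- function(kd1, kd2) {
  stopifnot(identical(kd1$x, kd2$x), identical(kd1$y, kd2$y))
  dx <- diff(kd1$x[1:2])
  dy <- diff(kd1$y[1:2])
  sum(pmin(kd1$z, kd2$z)) * dx * dy
}
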