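#' Widely applicable information criterion of an ensemble
#'
#' WAIC(x) = Var_members\[log P(x)\] - E_members\[log P(x)\], using the
#' population variance over the ensemble members (the criterion is a moment
#' of the parameter distribution, not a sample estimate; set
#' `var_type = "sample"` for the n-1 convention). Higher values indicate
#' samples further out of distribution.
#'
#' @param member_logps Numeric vector of per-member log densities for one
#'   sample, or a members x N matrix for N samples.
#' @param var_type "population" (default) or "sample".
#' @return Scalar (vector input) or length-N vector (matrix input).
#' @export
waic <- function(member_logps, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (is.matrix(member_logps)) {
    k <- nrow(member_logps)
    if (k < 2) stop("WAIC needs at least 2 ensemble members")
    m <- colMeans(member_logps)
    v <- colMeans(member_logps^2) - m^2
    if (var_type == "sample") v <- v * k / (k - 1)
    return(v - m)
  }
  k <- length(member_logps)
  if (k < 2) stop("WAIC needs at least 2 ensemble members")
  m <- mean(member_logps)
  v <- mean((member_logps - m)^2)
  if (var_type == "sample") v <- v * k / (k - 1)
  v - m
}

#' Aggregate a per-pixel WAIC map over an ROI
#'
#' @param map Numeric vector or matrix of per-pixel WAIC values.
#' @param valid Logical mask of the same length (default all valid).
#' @return Median WAIC over the valid pixels.
#' @export
roi_waic <- function(map, valid = NULL) {
  vals <- as.numeric(map)
  if (!is.null(valid)) vals <- vals[as.logical(valid)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("ROI WAIC map has no valid pixels")
  stats::median(vals)
}

#' Frame-level ischemia index from two ROI WAIC values
#'
#' The mean of the two per-ROI WAIC medians. If one ROI is unavailable (NA),
#' the index falls back to the remaining ROI's value with a warning, so that
#' live monitoring does not halt on a lost track.
#'
#' @param roi1_waic,roi2_waic Scalars (NA allowed for one of them).
#' @return The frame's ischemia index.
#' @export
ischemia_index <- function(roi1_waic, roi2_waic) {
  ok1 <- length(roi1_waic) == 1 && is.finite(roi1_waic)
  ok2 <- length(roi2_waic) == 1 && is.finite(roi2_waic)
  if (ok1 && ok2) return((roi1_waic + roi2_waic) / 2)
  if (ok1 || ok2) {
    warning("only one ROI available; ischemia index falls back to its value")
    return(if (ok1) roi1_waic else roi2_waic)
  }
  stop("no valid ROI WAIC value for this frame")
}

#' Min-max normalize an index series
#'
#' (v - min) / (max - min) over a patient's evaluated frames; a strictly
#' monotone transform, so ranking metrics such as the AU-ROC are unchanged.
#'
#' @param series Numeric vector with at least two distinct values.
#' @return Normalized series in \[0, 1\].
#' @export
minmax_normalize <- function(series) {
  r <- range(series, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("min-max normalization needs at least two distinct values")
  }
  (series - r[1]) / (r[2] - r[1])
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Probability that a random positive (ischemic) score exceeds a random
#' negative (perfused) score, counting ties as 1/2; identical to exhaustive
#' pair counting.
#'
#' @param negatives Scores of the negative (perfused) class.
#' @param positives Scores of the positive (ischemic) class.
#' @return AU-ROC in \[0, 1\].
#' @export
evaluate_auroc <- function(negatives, positives) {
  negatives <- negatives[is.finite(negatives)]
  positives <- positives[is.finite(positives)]
  n0 <- length(negatives)
  n1 <- length(positives)
  if (n0 == 0 || n1 == 0) stop("both score groups must be non-empty")
  r <- rank(c(negatives, positives))
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Create an ensemble of coupling flows
#'
#' Members share the architecture and (after training) the normalization
#' statistics, and differ only in their random seed (`base_seed + member
#' index`), which drives initialization, permutations, batching, and noise
#' augmentation.
#'
#' @param n_members Ensemble size (default 5).
#' @param d,n_blocks,hidden,clamp Architecture, see [new_coupling_flow()].
#' @param base_seed Base seed; member m uses `base_seed + m`.
#' @return Object of class `flow_ensemble`.
#' @export
flow_ensemble <- function(n_members = 5L, d = 16L, n_blocks = 20L,
                          hidden = 256L, clamp = 2, base_seed = 1L) {
  if (n_members < 2) stop("an ensemble needs at least 2 members")
  members <- lapply(seq_len(n_members), function(m) {
    new_coupling_flow(d = d, n_blocks = n_blocks, hidden = hidden,
                      clamp = clamp, seed = base_seed + m)
  })
  structure(list(members = members, base_seed = base_seed),
            class = "flow_ensemble")
}

#' Train every member of an ensemble
#'
#' @param ensemble A [flow_ensemble()].
#' @param X Training spectra (N x d).
#' @param epochs,lr,weight_decay,noise_sd,batch_size See [train_flow()].
#' @param estimate_znorm Re-estimate the z-score statistics from `X` (used
#'   when fine-tuning on patient data so that inference is comparable to the
#'   patient training distribution).
#' @return The trained ensemble.
#' @export
train_ensemble <- function(ensemble, X, epochs = 10, lr = 1e-3,
                           weight_decay = 1e-4, noise_sd = 0.05,
                           batch_size = 512, estimate_znorm = TRUE) {
  stopifnot(inherits(ensemble, "flow_ensemble"))
  ensemble$members <- lapply(seq_along(ensemble$members), function(m) {
    train_flow(ensemble$members[[m]], X, epochs = epochs, lr = lr,
               weight_decay = weight_decay, noise_sd = noise_sd,
               batch_size = batch_size, seed = ensemble$base_seed + 100L + m,
               estimate_znorm = estimate_znorm)
  })
  ensemble
}

#' Per-member log likelihoods of an ensemble
#'
#' @param ensemble A trained [flow_ensemble()].
#' @param X N x d matrix of spectra.
#' @return members x N matrix of log densities.
#' @export
ensemble_logp <- function(ensemble, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  t(vapply(ensemble$members, function(fl) log_likelihood(fl, X),
           numeric(nrow(X))))
}

#' Score the test sequences of a session with a trained ensemble
#'
#' For the first `n_frames` frames of each test sequence, computes per-pixel
#' WAIC values over each tracked ROI, aggregates them by the ROI median, and
#' averages the two ROIs into the frame-level ischemia index. A min-max
#' normalized copy (pooled over both test sequences of the patient) is
#' appended.
#'
#' @param ensemble A trained [flow_ensemble()] (fine-tuned on this patient's
#'   perfused_1 spectra).
#' @param session An `msi_session`.
#' @param sequences Sequences to score (default perfused_2 and ischemic).
#' @param n_frames Frames per sequence (default 70).
#' @return data.frame with columns sequence, frame, roi1_waic, roi2_waic,
#'   index, index_minmax.
#' @export
score_session <- function(ensemble, session,
                          sequences = c("perfused_2", "ischemic"),
                          n_frames = 70) {
  stopifnot(inherits(ensemble, "flow_ensemble"),
            inherits(session, "msi_session"))
  rows <- list()
  for (sq in sequences) {
    rois <- extract_roi_spectra(session, sq, frames = seq_len(n_frames))
    roi_frame_waic <- lapply(rois, function(r) {
      if (is.null(r$spectra) || nrow(r$spectra) == 0) {
        return(stats::setNames(numeric(0), character(0)))
      }
      lp <- ensemble_logp(ensemble, r$spectra)
      wv <- waic(lp)
      tapply(wv, r$frame, stats::median)
    })
    for (t in seq_len(n_frames)) {
      key <- as.character(t)
      w1 <- roi_frame_waic[[1]][key]
      w2 <- if (length(roi_frame_waic) >= 2) roi_frame_waic[[2]][key] else NA
      w1 <- if (is.null(w1) || is.na(w1)) NA_real_ else as.numeric(w1)
      w2 <- if (is.null(w2) || is.na(w2)) NA_real_ else as.numeric(w2)
      idx <- if (is.finite(w1) || is.finite(w2)) {
        ischemia_index(w1, w2)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sq, frame = t, roi1_waic = w1, roi2_waic = w2, index = idx)
    }
  }
  out <- do.call(rbind, rows)
  out$index_minmax <- rep(NA_real_, nrow(out))
  fin <- is.finite(out$index)
  if (sum(fin) >= 2 && length(unique(out$index[fin])) >= 2) {
    out$index_minmax[fin] <- minmax_normalize(out$index[fin])
  }
  out
}
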