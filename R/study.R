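#' Configuration of an end-to-end cohort study
#'
#' Bundles the cohort definition, flow architecture and training
#' hyperparameters of a full simulate -> pretrain -> fine-tune -> score ->
#' evaluate run. The default architecture is the reduced study profile
#' (8 coupling blocks, 64 hidden units, at most 2000 training spectra per
#' patient); `paper_scale = TRUE` restores 20 blocks / 256 hidden units and
#' unlimited training spectra.
#'
#' @param n_patients,base_seed,profile Cohort definition, see
#'   [cohort_configs()].
#' @param members Ensemble size (default 5).
#' @param n_blocks,hidden,clamp Flow architecture (reduced defaults).
#' @param max_train_spectra Per-patient training subsample cap.
#' @param pretrain Pretrain the ensemble on a simulated tissue corpus.
#' @param corpus_n,corpus_photons,corpus_step Corpus size and MC settings.
#' @param pretrain_epochs,finetune_epochs Training epochs for the two stages.
#' @param lr,weight_decay,noise_sd,batch_size See [train_flow()].
#' @param train_frames Frames of perfused_1 used for fine-tuning.
#' @param eval_frames Frames per test sequence entering the evaluation
#'   (default 70).
#' @param paper_scale Use the full-scale architecture instead of the reduced
#'   profile.
#' @param ... Further arguments forwarded to [patient_config()] for every
#'   patient (e.g. `frames_per_sequence`).
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_patients = 10, base_seed = 1L,
                         profile = c("clear", "hard", "null"),
                         members = 5L, n_blocks = 8L, hidden = 64L,
                         clamp = 2, max_train_spectra = 2000L,
                         pretrain = TRUE, corpus_n = 192L,
                         corpus_photons = 400L, corpus_step = 10,
                         pretrain_epochs = 100L, finetune_epochs = 10L,
                         lr = 1e-3, weight_decay = 1e-4, noise_sd = 0.05,
                         batch_size = 512L, train_frames = 70L,
                         eval_frames = 70L, paper_scale = FALSE, ...) {
  profile <- match.arg(profile)
  if (paper_scale) {
    n_blocks <- 20L
    hidden <- 256L
    max_train_spectra <- NULL
  }
  patient_args <- list(...)
  cfg <- list(n_patients = n_patients, base_seed = as.integer(base_seed),
              profile = profile, members = members, n_blocks = n_blocks,
              hidden = hidden, clamp = clamp,
              max_train_spectra = max_train_spectra, pretrain = pretrain,
              corpus_n = corpus_n, corpus_photons = corpus_photons,
              corpus_step = corpus_step, pretrain_epochs = pretrain_epochs,
              finetune_epochs = finetune_epochs, lr = lr,
              weight_decay = weight_decay, noise_sd = noise_sd,
              batch_size = batch_size, train_frames = train_frames,
              eval_frames = eval_frames, patient_args = patient_args)
  structure(cfg, class = "study_config")
}

seq_summary <- function(v) {
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  c(min = q[[1]], q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]],
    mean = mean(v, na.rm = TRUE))
}

study_pretrained_ensemble <- function(config, cam) {
  ens <- flow_ensemble(config$members, d = cam$n_bands,
                       n_blocks = config$n_blocks, hidden = config$hidden,
                       clamp = config$clamp,
                       base_seed = config$base_seed + 300L)
  if (config$pretrain) {
    corpus <- build_pretraining_corpus(config$corpus_n, cam,
                                       n_photons = config$corpus_photons,
                                       wavelength_step = config$corpus_step,
                                       seed = config$base_seed + 901L)
    ens <- train_ensemble(ens, corpus, epochs = config$pretrain_epochs,
                          lr = config$lr,
                          weight_decay = config$weight_decay,
                          noise_sd = config$noise_sd,
                          batch_size = config$batch_size,
                          estimate_znorm = TRUE)
  }
  ens
}

#' Run a full synthetic cohort study of the WAIC ischemia index
#'
#' Generates the configured synthetic cohort one patient at a time, and for
#' each patient: fine-tunes a (shared, optionally pretrained) coupling-flow
#' ensemble on the patient's perfused_1 pixel spectra, scores the first
#' `eval_frames` frames of perfused_2 and ischemic via per-pixel WAIC -> ROI
#' median -> two-ROI mean, and computes the per-patient AU-ROC with ischemic
#' as the positive class. Failed patients are reported and excluded with a
#' logged reason, never silently dropped.
#'
#' @param config A [study_config()].
#' @return Object of class `msimon_study`: list with `scores` (all frame
#'   indices), `per_patient` (AU-ROC per patient), `summaries` (per patient
#'   and sequence: min, quartiles, median, mean of the normalized index),
#'   `median_auroc`, `mean_auroc`, `failures`, `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cam <- do.call(patient_config, c(list(seed = 1L), config$patient_args))$cam %||%
    camera_model()
  ens0 <- study_pretrained_ensemble(config, cam)
  cfgs <- do.call(cohort_configs,
                  c(list(n_patients = config$n_patients,
                         base_seed = config$base_seed,
                         profile = config$profile),
                    config$patient_args))
  scores <- list()
  per_patient <- list()
  summaries <- list()
  failures <- list()
  for (i in seq_along(cfgs)) {
    res <- tryCatch({
      session <- generate_patient(cfgs[[i]])
      X <- training_spectra(session, n_frames = config$train_frames,
                            max_spectra = config$max_train_spectra,
                            seed = cfgs[[i]]$seed + 7L)
      ens <- train_ensemble(ens0, X, epochs = config$finetune_epochs,
                            lr = config$lr,
                            weight_decay = config$weight_decay,
                            noise_sd = config$noise_sd,
                            batch_size = config$batch_size,
                            estimate_znorm = TRUE)
      sc <- score_session(ens, session, n_frames = config$eval_frames)
      sc <- cbind(patient = i, sc)
      auroc <- evaluate_auroc(
        sc$index[sc$sequence == "perfused_2" & is.finite(sc$index)],
        sc$index[sc$sequence == "ischemic" & is.finite(sc$index)])
      list(scores = sc, auroc = auroc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        patient = i, reason = conditionMessage(res))
      next
    }
    scores[[length(scores) + 1L]] <- res$scores
    per_patient[[length(per_patient) + 1L]] <- data.frame(
      patient = i, auroc = res$auroc)
    for (sq in unique(res$scores$sequence)) {
      v <- res$scores$index_minmax[res$scores$sequence == sq]
      summaries[[length(summaries) + 1L]] <- data.frame(
        patient = i, sequence = sq, t(seq_summary(v)))
    }
  }
  per_patient <- do.call(rbind, per_patient)
  structure(
    list(scores = do.call(rbind, scores),
         per_patient = per_patient,
         summaries = do.call(rbind, summaries),
         median_auroc = if (!is.null(per_patient))
           stats::median(per_patient$auroc) else NA_real_,
         mean_auroc = if (!is.null(per_patient))
           mean(per_patient$auroc) else NA_real_,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         config = config),
    class = "msimon_study")
}

#' @exportS3Method base::print
print.msimon_study <- function(x, ...) {
  cat(sprintf("msimon_study: %d patients evaluated, median AU-ROC %.3f, mean %.3f\n",
              if (is.null(x$per_patient)) 0 else nrow(x$per_patient),
              x$median_auroc, x$mean_auroc))
  if (!is.null(x$failures)) {
    cat(sprintf("  %d patient(s) failed and were excluded\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Write a study's frame scores to CSV
#'
#' Columns: patient, sequence, frame, roi1_waic, roi2_waic, index,
#' index_minmax. Numeric values are written at full precision, so re-running
#' an identical configuration reproduces the file byte for byte.
#'
#' @param study A [run_study()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(study, path) {
  df <- study$scores
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the Beer-Lambert baseline over a synthetic cohort
#'
#' Applies the same acquisition protocol as [run_study()], but scores each
#' frame with the Beer-Lambert estimates instead of the WAIC index: per test
#' frame, the ROI-median reference-normalized reflectances (before l2
#' normalization) are averaged across ROIs and regressed on the
#' band-averaged extinction coefficients; the per-patient AU-ROC is computed
#' once with the fitted oxygenation and once with the total hemoglobin
#' product as (negated) decision scores.
#'
#' @param config A [study_config()] (flow settings are ignored).
#' @return List with `per_patient` (patient, auroc_s, auroc_vhbt), medians,
#'   `failures` and `config`.
#' @export
run_baseline_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  tab <- load_extinction_table()
  cfgs <- do.call(cohort_configs,
                  c(list(n_patients = config$n_patients,
                         base_seed = config$base_seed,
                         profile = config$profile),
                    config$patient_args))
  per_patient <- list()
  failures <- list()
  for (i in seq_along(cfgs)) {
    res <- tryCatch({
      session <- generate_patient(cfgs[[i]])
      bx <- band_average_extinctions(tab, session$camera)
      fits <- list()
      states <- character(0)
      for (sq in c("perfused_2", "ischemic")) {
        rois <- extract_roi_spectra(session, sq,
                                    frames = seq_len(config$eval_frames))
        frames <- sort(unique(unlist(lapply(rois, function(r) r$frame))))
        for (t in frames) {
          meds <- lapply(rois, function(r) {
            rws <- r$frame == t
            if (!any(rws)) return(NULL)
            apply(r$reflectance[rws, , drop = FALSE], 2, stats::median)
          })
          meds <- meds[!vapply(meds, is.null, logical(1))]
          if (length(meds) == 0) next
          spec <- colMeans(do.call(rbind, meds))
          fits[[length(fits) + 1L]] <- beer_lambert_fit(spec, bx)
          states <- c(states, if (sq == "ischemic") "ischemic" else "perfused")
        }
      }
      classify_by_baseline(fits, states)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        patient = i, reason = conditionMessage(res))
      next
    }
    per_patient[[length(per_patient) + 1L]] <- data.frame(
      patient = i, auroc_s = res[["auroc_s"]],
      auroc_vhbt = res[["auroc_vhbt"]])
  }
  per_patient <- do.call(rbind, per_patient)
  list(per_patient = per_patient,
       median_auroc_s = if (!is.null(per_patient))
         stats::median(per_patient$auroc_s) else NA_real_,
       median_auroc_vhbt = if (!is.null(per_patient))
         stats::median(per_patient$auroc_vhbt) else NA_real_,
       failures = if (length(failures)) do.call(rbind, failures) else NULL,
       config = config)
}
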