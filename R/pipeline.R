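# End-to-end glue: recordings -> epochs -> ROI series -> feature/graph
# samples ready for training, plus the 8-configuration ablation runner.

#' Build model samples from preprocessed epochs
#'
#' For each non-artifact epoch: reconstruct ROI source series through
#' the inverse operator (or use scalp channels directly when
#' `cortical = FALSE`, the scalp-level ablation), assemble the N x 32
#' feature matrix, and build the Pearson-threshold normalized adjacency
#' from the broadband series.
#'
#' @param epochs list of epochs from [preprocess_recording()] /
#'   [epoch_split()].
#' @param inverse_op an [build_inverse_operator()] result (required when
#'   `cortical = TRUE`).
#' @param cortical reconstruct cortical ROI series (TRUE) or compute
#'   features on scalp channels (FALSE).
#' @param phi Pearson adjacency threshold.
#' @param plv_threshold PLV binarization threshold for graph features.
#' @param bands analysis bands.
#' @param drop_artifacts skip epochs flagged artifactual.
#' @return list of samples (`X`, `A_hat`, `label`, `subject_id`,
#'   `epoch_index`).
#' @export
epochs_to_samples <- function(epochs, inverse_op = NULL, cortical = TRUE,
                              phi = 0.3, plv_threshold = 0.5,
                              bands = default_bands(),
                              drop_artifacts = TRUE) {
  if (cortical && is.null(inverse_op)) {
    stop("cortical = TRUE requires an inverse operator")
  }
  out <- list()
  for (ep in epochs) {
    if (drop_artifacts && isTRUE(ep$artifact)) next
    series <- if (cortical) {
      source_roi_series(inverse_op, ep$data)
    } else {
      ep$data
    }
    fx <- assemble_features(series, ep$sampling_rate, bands = bands,
                            plv_threshold = plv_threshold)
    adj <- build_adjacency(series, phi)
    out[[length(out) + 1]] <- list(
      X = fx$X, A_hat = adj$A_hat, label = ep$label,
      subject_id = ep$subject_id, epoch_index = ep$epoch_index)
  }
  out
}

#' Normalize feature columns across samples
#'
#' Z-scores every feature column over all samples (statistics from the
#' samples given, typically the training pool), guarding zero-variance
#' columns. Returns the samples with standardized `X`.
#'
#' @param samples list of samples from [epochs_to_samples()].
#' @param stats optional precomputed list with `mu` and `sd` (to apply
#'   training statistics to held-out data).
#' @return list with `samples` and the `stats` used.
#' @export
normalize_features <- function(samples, stats = NULL) {
  if (is.null(stats)) {
    all <- do.call(rbind, lapply(samples, `[[`, "X"))
    mu <- colMeans(all)
    sd_ <- apply(all, 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    stats <- list(mu = mu, sd = sd_)
  }
  samples <- lapply(samples, function(s) {
    s$X <- sweep(sweep(s$X, 2, stats$mu), 2, stats$sd, "/")
    s$X[!is.finite(s$X)] <- 0
    s
  })
  list(samples = samples, stats = stats)
}

#' Ablation study over module toggles
#'
#' Runs the 8 on/off configurations of the three modules: CFE (cortical
#' features vs scalp-channel features), FA (attention stack on/off) and
#' FADA (focal + adversarial + center losses vs plain cross-entropy).
#' Configurations are numbered S1 (all off) .. S8 (all on) following
#' the toggle table `(CFE, FA, FADA)`:
#' S1 ---, S2 C--, S3 -F-, S4 --A, S5 CF-, S6 C-A, S7 -FA, S8 CFA.
#'
#' @param roi_samples cortical-feature samples ([epochs_to_samples()]
#'   with `cortical = TRUE`).
#' @param scalp_samples scalp-feature samples (`cortical = FALSE`).
#' @param cfg base [train_config()]; FADA-off runs override
#'   `gamma_focal = 0`, `beta = c(1, 1)`, `lambda = 0`,
#'   `gamma_center = 0`.
#' @param configs subset of configuration names to run (default all 8).
#' @return data.frame with one row per configuration: toggles and test
#'   metrics.
#' @export
ablation_run <- function(roi_samples, scalp_samples, cfg = train_config(),
                         configs = paste0("S", 1:8)) {
  toggles <- list(
    S1 = c(FALSE, FALSE, FALSE), S2 = c(TRUE, FALSE, FALSE),
    S3 = c(FALSE, TRUE, FALSE), S4 = c(FALSE, FALSE, TRUE),
    S5 = c(TRUE, TRUE, FALSE), S6 = c(TRUE, FALSE, TRUE),
    S7 = c(FALSE, TRUE, TRUE), S8 = c(TRUE, TRUE, TRUE))
  rows <- list()
  for (nm in configs) {
    tg <- toggles[[nm]]
    ccfg <- cfg
    ccfg$use_fa <- tg[2]
    if (!tg[3]) {
      ccfg$gamma_focal <- 0
      ccfg$beta <- c(1, 1)
      ccfg$lambda <- 0
      ccfg$gamma_center <- 0
    }
    samples <- if (tg[1]) roi_samples else scalp_samples
    fit <- train_fada(samples, ccfg)
    r <- fit$test_report
    rows[[nm]] <- data.frame(
      config = nm, CFE = tg[1], FA = tg[2], FADA = tg[3],
      ACC = r$ACC, F1 = r$F1, REC = r$REC, PRE = r$PRE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
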