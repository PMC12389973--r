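# Synthetic multi-subject EEG with a known forward model.
#
# The generator stands in for a boundary-element head model and a real
# clinical cohort: a random full-row-rank lead field maps band-limited
# cortical source activity to scalp channels, depressed subjects get
# extra theta-band oscillatory power in a designated "affected" ROI set,
# and a per-subject multiplicative gain offset induces the subject-level
# distribution shift that the adversarial branch is meant to absorb.

#' Synthetic dataset configuration
#'
#' Defaults emulate the structure of the clinical cohort the pipeline
#' targets: 46 depressed vs 74 healthy subjects, 64 channels sampled at
#' 500 Hz, 300 s of rest per subject (150 two-second epochs). Tests use
#' much smaller values.
#'
#' @param n_subjects_dp,n_subjects_hc subjects per class (depressed /
#'   healthy control).
#' @param n_channels number of scalp electrodes L.
#' @param n_sources number of cortical sources S (>= n_rois and >=
#'   n_channels).
#' @param n_rois number of atlas regions N.
#' @param sampling_rate Hz.
#' @param duration seconds per subject.
#' @param noise_sd sd of additive scalp sensor noise.
#' @param class_effect amplitude of the extra theta oscillation injected
#'   into affected ROIs of depressed subjects (0 = no class signal).
#' @param domain_shift_sd sd of the per-subject multiplicative gain
#'   offset (0 = no domain shift).
#' @param affected_rois indices of ROIs receiving the class signal.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_subjects_dp = 46, n_subjects_hc = 74,
                             n_channels = 64, n_sources = 256,
                             n_rois = 68, sampling_rate = 500,
                             duration = 300, noise_sd = 0.5,
                             class_effect = 1, domain_shift_sd = 0.1,
                             affected_rois = c(1, 2), seed = 1) {
  cfg <- list(n_subjects_dp = n_subjects_dp, n_subjects_hc = n_subjects_hc,
              n_channels = n_channels, n_sources = n_sources,
              n_rois = n_rois, sampling_rate = sampling_rate,
              duration = duration, noise_sd = noise_sd,
              class_effect = class_effect,
              domain_shift_sd = domain_shift_sd,
              affected_rois = affected_rois, seed = seed)
  if (cfg$n_channels < 2) stop("need at least 2 channels")
  if (cfg$n_rois < 2) stop("need at least 2 ROIs")
  if (cfg$n_sources < cfg$n_rois) stop("need n_sources >= n_rois")
  if (cfg$n_channels > cfg$n_sources) {
    stop("underdetermined-forward-impossible: need n_channels <= n_sources")
  }
  n_samp <- cfg$duration * cfg$sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("duration x sampling_rate must be an integer sample count")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$affected_rois < 1) || any(cfg$affected_rois > cfg$n_rois)) {
    stop("affected_rois out of range")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic lead field
#'
#' Gaussian gain matrix with rows orthonormalized (so the forward
#' operator has full row rank and a benign condition number) and then
#' perturbed to break exact orthogonality. Sources are assigned to ROIs
#' in contiguous blocks of `floor(S/N)` with the remainder going to the
#' last ROI. Not a head-model solution: the inverse mathematics
#' downstream is agnostic to how the gain matrix arose.
#'
#' @param config a [synthetic_config()].
#' @return a `lead_field` list: `K` (channels x sources gain),
#'   `roi_of_source` (integer ROI index per source), `roi_names`.
#' @export
make_lead_field <- function(config) {
  L <- config$n_channels
  S <- config$n_sources
  N <- config$n_rois
  set.seed(config$seed)
  for (attempt in 1:4) {
    G <- matrix(stats::rnorm(L * S), L, S)
    # orthonormal rows + small perturbation
    K <- qr.Q(qr(t(G)))[, seq_len(L), drop = FALSE]
    K <- t(K) + 0.05 * matrix(stats::rnorm(L * S), L, S)
    M <- K %*% t(K)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) <= 1e6) break
    if (attempt == 4) stop("underdetermined-forward-impossible")
  }
  block <- S %/% N
  roi_of_source <- pmin(((seq_len(S) - 1L) %/% block) + 1L, N)
  structure(
    list(K = K, roi_of_source = roi_of_source,
         roi_names = default_roi_names(N)),
    class = "lead_field"
  )
}

#' Default ROI labels
#'
#' For 68 regions, the 34 Desikan-Killiany cortical parcel names
#' suffixed `-lh`/`-rh`; otherwise generic `roi<k>` labels.
#'
#' @param n number of ROIs.
#' @return character vector of length `n`.
#' @export
default_roi_names <- function(n) {
  dk <- c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
          "cuneus", "entorhinal", "fusiform", "inferiorparietal",
          "inferiortemporal", "isthmuscingulate", "lateraloccipital",
          "lateralorbitofrontal", "lingual", "medialorbitofrontal",
          "middletemporal", "parahippocampal", "paracentral",
          "parsopercularis", "parsorbitalis", "parstriangularis",
          "pericalcarine", "postcentral", "posteriorcingulate",
          "precentral", "precuneus", "rostralanteriorcingulate",
          "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
          "superiortemporal", "supramarginal", "frontalpole",
          "temporalpole", "transversetemporal", "insula")
  if (n == 68) {
    c(paste0(dk, "-lh"), paste0(dk, "-rh"))
  } else {
    paste0("roi", seq_len(n))
  }
}

# Band-limited (4-80 Hz) Gaussian source activity, one row per source.
.simulate_sources <- function(config, lead_field, label) {
  S <- config$n_sources
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  f <- butter_design(4, c(4, min(80, fs / 2 * 0.95)) / (fs / 2), "pass")
  J <- matrix(stats::rnorm(S * n), S, n)
  J <- t(apply(J, 1, function(x) filtfilt_iir(f$b, f$a, x)))
  if (label == 0L && config$class_effect != 0) {
    # depressed subjects: theta (6 Hz) bursts in affected-ROI sources
    tt <- seq_len(n) / fs
    idx <- which(lead_field$roi_of_source %in% config$affected_rois)
    for (i in idx) {
      phase <- stats::runif(1, 0, 2 * pi)
      env <- 0.6 + 0.4 * sin(2 * pi * 0.2 * tt + stats::runif(1, 0, 2 * pi))
      J[i, ] <- J[i, ] + config$class_effect * env * sin(2 * pi * 6 * tt + phase)
    }
  }
  J
}

#' Simulate a labeled multi-subject EEG dataset
#'
#' Each subject gets one recording of `duration` seconds: scalp data =
#' `K %*% sources + noise`. Depressed subjects (label 0, generated
#' first) receive extra theta-band oscillatory power in the affected
#' ROIs, scaled by `class_effect`; a per-subject gain offset
#' `~ Normal(0, domain_shift_sd)` multiplies the source amplitudes,
#' modelling subject-level shift. Domain id equals subject id.
#'
#' @param config a [synthetic_config()].
#' @param lead_field a [make_lead_field()] result consistent with
#'   `config`.
#' @param keep_sources if TRUE each recording carries its source matrix
#'   as attribute `"sources"` (for forward-consistency checks).
#' @param subject_seeds optional integer vector overriding the
#'   per-subject RNG seeds (default: drawn from `config$seed`).
#' @return list of [eeg_recording()] objects, depressed subjects first.
#' @export
simulate_dataset <- function(config, lead_field = make_lead_field(config),
                             keep_sources = FALSE, subject_seeds = NULL) {
  stopifnot(nrow(lead_field$K) == config$n_channels,
            ncol(lead_field$K) == config$n_sources)
  labels <- c(rep(0L, config$n_subjects_dp), rep(1L, config$n_subjects_hc))
  set.seed(config$seed + 1L)
  seeds <- if (is.null(subject_seeds)) {
    sample.int(.Machine$integer.max, length(labels))
  } else {
    rep_len(subject_seeds, length(labels))
  }
  recs <- vector("list", length(labels))
  for (s in seq_along(labels)) {
    set.seed(seeds[s])
    J <- .simulate_sources(config, lead_field, labels[s])
    gain <- 1 + stats::rnorm(1, 0, config$domain_shift_sd)
    J <- gain * J
    phi <- lead_field$K %*% J
    if (config$noise_sd > 0) {
      phi <- phi + matrix(stats::rnorm(length(phi), 0, config$noise_sd),
                          nrow(phi), ncol(phi))
    }
    sid <- sprintf("sub%03d", s)
    rec <- eeg_recording(phi, config$sampling_rate,
                         subject_id = sid, label = labels[s],
                         domain_id = sid)
    if (keep_sources) attr(rec, "sources") <- J
    recs[[s]] <- rec
  }
  recs
}
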