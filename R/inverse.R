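# EEG inverse problem: Tikhonov-regularized minimum-norm estimation and
# sLORETA standardization.
#
# Forward model: Phi = K J + eps, with K the channels x sources gain.
# The minimum-norm estimate is J_hat = K' (K K' + alpha I)^{-1} Phi, and
# sLORETA divides each source's estimate by the square root of its
# model-implied variance v_i = [K' (K K' + alpha I)^{-1} K]_{ii}. With
# fixed scalar source orientations this standardization gives zero
# localization error for a single noiseless source.

#' Build a regularized inverse operator
#'
#' Precomputes the transfer matrix `T = K' (K K' + alpha I)^{-1}` and the
#' per-source sLORETA variances `v_i = [T K]_{ii}` (the diagonal of the
#' resolution matrix, using the model covariance `K K' + alpha I`).
#'
#' @param lead_field a [make_lead_field()] result (or any list with a
#'   numeric `K` and `roi_of_source`).
#' @param alpha Tikhonov regularization parameter, > 0 (default 0.05).
#' @return an `inverse_operator` list with `Tmat` (sources x channels),
#'   `v` (per-source variance), `alpha`, and the lead field.
#' @export
build_inverse_operator <- function(lead_field, alpha = 0.05) {
  if (alpha <= 0) stop("alpha must be > 0")
  K <- lead_field$K
  if (any(!is.finite(K))) stop("lead field must be finite")
  L <- nrow(K)
  M <- K %*% t(K) + diag(alpha, L)
  Tmat <- t(solve(M, K))          # K' M^{-1}, sources x channels
  v <- rowSums(Tmat * t(K))       # diag(K' M^{-1} K)
  if (any(v <= 0)) stop("non-positive sLORETA variance; check lead field")
  structure(
    list(Tmat = Tmat, v = v, alpha = alpha, lead_field = lead_field),
    class = "inverse_operator"
  )
}

#' Minimum-norm source estimate
#'
#' `J_hat = T %*% Phi`, the unique minimizer of
#' `||Phi - K J||_F^2 + alpha ||J||_F^2`.
#'
#' @param op an [build_inverse_operator()] result.
#' @param phi scalp data, channels x time.
#' @return sources x time matrix of current estimates.
#' @export
apply_minimum_norm <- function(op, phi) {
  phi <- as.matrix(phi)
  if (nrow(phi) != ncol(op$Tmat)) {
    stop("phi must have one row per channel of the lead field")
  }
  op$Tmat %*% phi
}

#' sLORETA standardization
#'
#' Divides each source's minimum-norm estimate by the square root of its
#' model-implied variance, removing the depth/amplitude bias of the raw
#' minimum-norm solution.
#'
#' @param op the operator that produced `j_hat`.
#' @param j_hat sources x time minimum-norm estimate.
#' @return sources x time standardized estimate.
#' @export
sloreta_standardize <- function(op, j_hat) {
  if (nrow(j_hat) != length(op$v)) {
    stop("j_hat rows must match the operator's source count")
  }
  j_hat / sqrt(op$v)
}

#' Aggregate source currents into ROI time series
#'
#' Signed mean of the (standardized) current density over the sources
#' assigned to each ROI; set `rectify = TRUE` for the absolute-value
#' mean.
#'
#' @param j sources x time matrix (typically sLORETA-standardized).
#' @param lead_field lead field carrying `roi_of_source`.
#' @param rectify take `abs()` before averaging.
#' @return ROIs x time matrix, rownames from `roi_names` when present.
#' @export
aggregate_rois <- function(j, lead_field, rectify = FALSE) {
  roi <- lead_field$roi_of_source
  if (length(roi) != nrow(j)) stop("roi_of_source must cover all sources")
  if (rectify) j <- abs(j)
  n_roi <- max(roi)
  out <- matrix(0, n_roi, ncol(j))
  for (r in seq_len(n_roi)) {
    idx <- which(roi == r)
    out[r, ] <- if (length(idx) == 1) j[idx, ] else colMeans(j[idx, , drop = FALSE])
  }
  if (!is.null(lead_field$roi_names)) rownames(out) <- lead_field$roi_names
  out
}

#' Scalp epoch to ROI time series
#'
#' Convenience wrapper: minimum norm, sLORETA standardization, ROI
#' aggregation in one call.
#'
#' @inheritParams apply_minimum_norm
#' @inheritParams aggregate_rois
#' @return ROIs x time matrix.
#' @export
source_roi_series <- function(op, phi, rectify = FALSE) {
  aggregate_rois(sloreta_standardize(op, apply_minimum_norm(op, phi)),
                 op$lead_field, rectify = rectify)
}
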