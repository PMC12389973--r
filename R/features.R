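# Multi-band cortical features on ROI time series.
#
# Four analysis bands (theta/alpha/beta/gamma), and per band eight
# features per ROI: two graph metrics from the thresholded
# phase-locking-value network (clustering coefficient, local
# efficiency), two temporal (absolute peak, skewness), two spectral
# (Welch band power, relative power), two nonlinear (sample entropy,
# fuzzy entropy). The assembled matrix is N ROIs x 32 columns.

#' Default analysis bands
#'
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz. The beta/gamma
#' boundary is made contiguous at 30 Hz (no dead zone).
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       gamma = c(30, 80))
}

.band_filter <- function(x, band, fs, order = 4) {
  nyq <- fs / 2
  hi <- min(band[2], nyq * 0.99)
  filtfilt_iir_cached(order, c(band[1], hi) / nyq, x)
}

# cache band-pass designs: the same (order, Wn) pair is reused for every
# ROI and epoch, and filter design is pure
.filter_cache <- new.env(parent = emptyenv())
filtfilt_iir_cached <- function(order, Wn, x) {
  key <- paste0(order, "|", paste(format(Wn, digits = 12), collapse = ","))
  f <- .filter_cache[[key]]
  if (is.null(f)) {
    f <- butter_design(order, Wn, "pass")
    .filter_cache[[key]] <- f
  }
  filtfilt_iir(f$b, f$a, x)
}

#' Phase-locking value between two signals in a band
#'
#' Both signals are band-passed, instantaneous phases are taken from the
#' analytic signal, and the PLV is the modulus of the time-averaged unit
#' phasor of the phase difference:
#' `PLV = |mean_t exp(i (phi_x(t) - phi_y(t)))|` in `[0, 1]`.
#'
#' @param x,y numeric vectors of equal length (>= 64 samples).
#' @param band `c(low, high)` in Hz.
#' @param fs sampling rate in Hz.
#' @return scalar in `[0, 1]`.
#' @export
plv <- function(x, y, band, fs) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 64) stop("signals too short for phase estimation")
  px <- Arg(analytic_signal(.band_filter(x, band, fs)))
  py <- Arg(analytic_signal(.band_filter(y, band, fs)))
  Mod(mean(exp(1i * (px - py))))
}

#' Pairwise PLV matrix over ROI time series
#'
#' @param roi_series ROIs x time matrix.
#' @inheritParams plv
#' @return symmetric N x N matrix with unit diagonal.
#' @export
plv_matrix <- function(roi_series, band, fs) {
  n <- nrow(roi_series)
  phases <- t(apply(roi_series, 1, function(x) {
    Arg(analytic_signal(.band_filter(x, band, fs)))
  }))
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- Mod(mean(exp(1i * (phases[i, ] - phases[j, ]))))
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Binarize a PLV matrix into an adjacency matrix
#'
#' `adjacency[i, j] = 1` iff `plv[i, j] >= threshold` and `i != j`.
#'
#' @param plv_mat symmetric PLV matrix.
#' @param threshold binarization threshold in `[0, 1]` (default 0.5).
#' @return binary symmetric matrix with zero diagonal.
#' @export
binarize_plv <- function(plv_mat, threshold = 0.5) {
  adj <- (plv_mat >= threshold) * 1
  diag(adj) <- 0
  adj
}

#' Clustering coefficient of a node
#'
#' `Cp(i) = 2 E_i / (k_i (k_i - 1))` with `E_i` the number of edges among
#' the neighbours of `i` and `k_i` its degree; 0 for degree < 2.
#'
#' @param adj binary symmetric adjacency matrix, zero diagonal.
#' @param i node index.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj, i) {
  nb <- which(adj[i, ] != 0)
  k <- length(nb)
  if (k < 2) return(0)
  e <- sum(adj[nb, nb]) / 2
  2 * e / (k * (k - 1))
}

# all-pairs shortest path lengths in an unweighted graph (BFS per node)
.bfs_dists <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] != 0))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Local efficiency of a node
#'
#' Mean inverse shortest-path length between the neighbours of `i`,
#' computed within the subgraph induced by those neighbours;
#' disconnected pairs contribute 0; 0 for degree < 2.
#'
#' @inheritParams clustering_coefficient
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(adj, i) {
  nb <- which(adj[i, ] != 0)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- adj[nb, nb, drop = FALSE]
  d <- .bfs_dists(sub)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (k * (k - 1))
}

#' Absolute peak value
#' @param x numeric vector.
#' @return `max(abs(x))`.
#' @export
peak_value <- function(x) max(abs(x))

#' Skewness (population moment convention)
#' @param x numeric vector.
#' @return central third moment divided by the cubed population sd.
#' @export
skewness <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) return(0)
  mean((x - mu)^3) / s2^1.5
}

#' Band power from the Welch periodogram
#'
#' Integral of the Welch PSD over `[low, high)`.
#'
#' @param x numeric vector.
#' @param band `c(low, high)` in Hz.
#' @param fs sampling rate.
#' @return scalar power.
#' @export
band_power <- function(x, band, fs) {
  w <- welch_psd(x, fs)
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[w$freq >= band[1] & w$freq < band[2]]) * df
}

#' Relative band power
#'
#' Band power normalized by the total power over the analysis band
#' (default 4-80 Hz).
#'
#' @inheritParams band_power
#' @param total_band normalization band in Hz.
#' @return scalar in `[0, 1]`.
#' @export
relative_power <- function(x, band, fs, total_band = c(4, 80)) {
  w <- welch_psd(x, fs)
  df <- w$freq[2] - w$freq[1]
  tot <- sum(w$psd[w$freq >= total_band[1] & w$freq < total_band[2]]) * df
  if (tot <= 0) stop("zero-total-power")
  bp <- sum(w$psd[w$freq >= band[1] & w$freq < band[2]]) * df
  bp / tot
}

.template_counts <- function(x, m, r) {
  # number of template pairs (i < j) within Chebyshev distance r, for
  # template lengths m and m + 1, self-matches excluded; both counts use
  # the same n - m templates (Richman-Moorman convention)
  n <- length(x)
  ntpl <- n - m
  # rows of embed() are templates (column order is irrelevant for the
  # Chebyshev distance); dist(method = "maximum") does the pair sweep in C
  tplA <- stats::embed(x, m + 1)            # ntpl rows, length m+1
  tplB <- tplA[, -1, drop = FALSE]          # same ntpl rows, length m
  B <- sum(stats::dist(tplB, method = "maximum") <= r)
  A <- sum(stats::dist(tplA, method = "maximum") <= r)
  c(B = B, A = A)
}

#' Sample entropy
#'
#' `-log(A / B)` where `B` (`A`) counts template pairs of length `m`
#' (`m + 1`) within Chebyshev tolerance `r * sd(x)`; self-matches
#' excluded, population sd.
#'
#' @param x numeric vector, length >= `10 * (m + 1)`.
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the series sd (default 0.2).
#' @return non-negative scalar; 0 when every length-m match extends
#'   (e.g. a constant series); `Inf` when no template pair extends.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  if (n < 10 * (m + 1)) stop("series too short for sample entropy")
  s <- sqrt(mean((x - mean(x))^2))
  tol <- r * s
  if (s == 0) return(0)
  cnt <- .template_counts(x, m, tol)
  if (cnt["B"] == 0) return(Inf)
  if (cnt["A"] == 0) return(Inf)
  unname(-log(cnt["A"] / cnt["B"]))
}

#' Fuzzy entropy
#'
#' Like sample entropy but on mean-removed templates with a smooth
#' Gaussian membership `exp(-(d / r)^2)` in place of the hard tolerance,
#' emphasizing the continuity of local features.
#'
#' @inheritParams sample_entropy
#' @return non-negative scalar.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  if (n < 10 * (m + 1)) stop("series too short for fuzzy entropy")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(0)
  tol <- r * s
  phi <- function(mm) {
    ntpl <- n - m
    # mean-removed templates as rows
    tpl <- sapply(seq_len(mm), function(k) x[(seq_len(ntpl)) + k - 1])
    tpl <- tpl - rowMeans(tpl)
    d <- stats::dist(tpl, method = "maximum")
    2 * sum(exp(-(d / tol)^2)) / (ntpl * (ntpl - 1))
  }
  # use common template count (n - m templates for both lengths)
  p_m <- phi(m)
  p_m1 <- phi(m + 1)
  if (p_m1 <= 0 || p_m <= 0) return(Inf)
  max(0, log(p_m) - log(p_m1))
}

#' Per-band feature names
#' @return character vector of the 8 feature names in column order.
#' @export
feature_names <- function() {
  c("clustering", "local_efficiency", "peak", "skewness",
    "band_power", "relative_power", "sample_entropy", "fuzzy_entropy")
}

#' Assemble the ROI x feature matrix
#'
#' For each band (theta, alpha, beta, gamma in order) computes the PLV
#' network on the band-passed ROI series, binarizes it at
#' `plv_threshold`, and fills per-ROI columns
#' `[Cp, Eloc, peak, skewness, band_power, relative_power, SampEn,
#' FuzzyEn]`. Temporal/spectral/nonlinear features are computed on the
#' band-passed ROI series (spectral ones from the broadband series
#' restricted to the band).
#'
#' @param roi_series ROIs x time matrix (broadband, 4-80 Hz).
#' @param fs sampling rate in Hz.
#' @param bands named list of bands (default [default_bands()]).
#' @param plv_threshold PLV binarization threshold.
#' @param entropy_m,entropy_r sample/fuzzy entropy parameters.
#' @return list with `X` (N x 4*8 matrix, named columns), `graphs`
#'   (per-band list of `list(plv, adjacency, band)`).
#' @export
assemble_features <- function(roi_series, fs, bands = default_bands(),
                              plv_threshold = 0.5, entropy_m = 2,
                              entropy_r = 0.2) {
  n <- nrow(roi_series)
  nf <- length(feature_names())
  X <- matrix(NA_real_, n, nf * length(bands))
  colnames(X) <- unlist(lapply(names(bands), function(b) {
    paste(b, feature_names(), sep = "_")
  }))
  graphs <- list()
  col0 <- 0
  for (bname in names(bands)) {
    band <- bands[[bname]]
    pm <- plv_matrix(roi_series, band, fs)
    adj <- binarize_plv(pm, plv_threshold)
    graphs[[bname]] <- list(plv = pm, adjacency = adj, band = band)
    for (i in seq_len(n)) {
      xb <- .band_filter(roi_series[i, ], band, fs)
      X[i, col0 + 1] <- clustering_coefficient(adj, i)
      X[i, col0 + 2] <- local_efficiency(adj, i)
      X[i, col0 + 3] <- peak_value(xb)
      X[i, col0 + 4] <- skewness(xb)
      X[i, col0 + 5] <- band_power(roi_series[i, ], band, fs)
      X[i, col0 + 6] <- relative_power(roi_series[i, ], band, fs)
      X[i, col0 + 7] <- sample_entropy(xb, entropy_m, entropy_r)
      X[i, col0 + 8] <- fuzzy_entropy(xb, entropy_m, entropy_r)
    }
    col0 <- col0 + nf
  }
  rownames(X) <- rownames(roi_series)
  list(X = X, graphs = graphs)
}
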