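# Shared fixtures and independent oracles, built in code at test time.

# tiny synthetic world used across module tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects_dp = 2, n_subjects_hc = 3, n_channels = 8,
                   n_sources = 16, n_rois = 4, sampling_rate = 250,
                   duration = 4, noise_sd = 0.2, class_effect = 3,
                   domain_shift_sd = 0.05, seed = 101)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

rms <- function(x) sqrt(mean(x^2))

# naive O(T^2) double-loop sample entropy (independent oracle)
naive_sample_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  s <- sqrt(mean((x - mean(x))^2))
  tol <- r * s
  cnt <- function(mm) {
    tot <- 0
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= tol) {
          tot <- tot + 1
        }
      }
    }
    tot
  }
  -log(cnt(m + 1) / cnt(m))
}

# naive double-loop fuzzy entropy with mean-removed templates
naive_fuzzy_entropy <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  s <- sqrt(mean((x - mean(x))^2))
  tol <- r * s
  phi <- function(mm) {
    ntpl <- n - m
    tot <- 0
    for (i in 1:(ntpl - 1)) {
      ti <- x[i:(i + mm - 1)]; ti <- ti - mean(ti)
      for (j in (i + 1):ntpl) {
        tj <- x[j:(j + mm - 1)]; tj <- tj - mean(tj)
        tot <- tot + exp(-(max(abs(ti - tj)) / tol)^2)
      }
    }
    2 * tot / (ntpl * (ntpl - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.45) {
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  A
}

# igraph-based oracles for the graph metrics
igraph_clustering <- function(A, i) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  v <- igraph::transitivity(g, type = "local", isolates = "zero")[i]
  if (is.nan(v)) 0 else v
}

igraph_local_efficiency <- function(A, i) {
  nb <- which(A[i, ] != 0)
  if (length(nb) < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(A[nb, nb, drop = FALSE],
                                           mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (length(nb) * (length(nb) - 1))
}

# quick gaussian-feature sample builder for training tests (bypasses the
# signal pipeline; subject-level shift + class mean separation)
make_feature_samples <- function(n_dp, n_hc, n_ep, n_nodes = 5, d = 10,
                                 sep = 2, subject_sd = 0.3, seed = 1) {
  set.seed(seed)
  out <- list()
  sid <- 0
  for (lab in c(rep(0L, n_dp), rep(1L, n_hc))) {
    sid <- sid + 1
    shift <- stats::rnorm(d, 0, subject_sd)
    for (e in seq_len(n_ep)) {
      X <- matrix(stats::rnorm(n_nodes * d), n_nodes, d) +
        rep(shift, each = n_nodes)
      if (lab == 0L) X[, 1:3] <- X[, 1:3] + sep
      A <- build_adjacency(matrix(stats::rnorm(n_nodes * 60), n_nodes, 60),
                           0)$A_hat
      out[[length(out) + 1]] <- list(X = X, A_hat = A, label = lab,
                                     subject_id = sprintf("s%02d", sid))
    }
  }
  out
}

# small fast train config for tests
test_train_config <- function(...) {
  args <- list(...)
  defaults <- list(batch_size = 16, lr = 2e-3, epochs = 20, patience = 8,
                   gcn_dims = c(16, 16), disc_hidden = 8, dropout = 0.2,
                   heads = 4, fa_layers = 2, seed = 7)
  do.call(train_config, utils::modifyList(defaults, args))
}
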