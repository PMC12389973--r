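# Attention-enhanced graph convolutional classifier with a
# gradient-reversal domain discriminator.
#
# Architecture, per sample (one epoch):
#   X [N rois x D feats]
#     -> 4 x multi-head self-attention layers with residual + ReLU
#        (feature attention stack, shape-preserving)
#     -> 2 x graph convolution ReLU(A_hat H W) over the Pearson-threshold
#        ROI graph of the epoch
#     -> mean-pool over nodes -> feature vector f
#     -> linear classifier (2 logits)
#     -> gradient-reversal layer -> 2-layer MLP domain discriminator
#
# Gradients are hand-derived reverse-mode; finite-difference agreement
# is part of the test suite.

#' Model configuration
#'
#' Defaults mirror the reference hyper-parameters: 4 attention heads,
#' 4 attention layers, hidden dimension 512, dropout 0.3. Tests use
#' smaller hidden sizes.
#'
#' @param d_in input feature dimension D (32 for the default feature
#'   set).
#' @param n_domains number of source domains K (training subjects).
#' @param heads attention heads per layer.
#' @param fa_layers attention layers.
#' @param gcn_dims output dims of the graph-convolution layers.
#' @param disc_hidden hidden width of the domain discriminator.
#' @param dropout dropout rate applied after the first GCN layer during
#'   training.
#' @param use_fa include the attention stack (FALSE bypasses it).
#' @param phi Pearson threshold for adjacency construction.
#' @return a `model_config` list.
#' @export
model_config <- function(d_in = 32, n_domains = 2, heads = 4,
                         fa_layers = 4, gcn_dims = c(512, 512),
                         disc_hidden = 256, dropout = 0.3,
                         use_fa = TRUE, phi = 0.3) {
  d_h <- if (d_in %% heads == 0) d_in %/% heads else d_in
  structure(
    list(d_in = d_in, n_domains = n_domains, heads = heads,
         fa_layers = fa_layers, d_h = d_h, gcn_dims = gcn_dims,
         disc_hidden = disc_hidden, dropout = dropout, use_fa = use_fa,
         phi = phi),
    class = "model_config"
  )
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases; deterministic given `seed`.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed.
#' @return nested list of parameter matrices.
#' @export
init_params <- function(cfg, seed = 1) {
  set.seed(seed)
  D <- cfg$d_in
  dh <- cfg$d_h
  fa <- lapply(seq_len(cfg$fa_layers), function(l) {
    heads <- lapply(seq_len(cfg$heads), function(h) {
      list(Wq = .glorot(D, dh), Wk = .glorot(D, dh), Wv = .glorot(D, dh))
    })
    list(heads = heads, Wo = .glorot(cfg$heads * dh, D))
  })
  dims <- c(D, cfg$gcn_dims)
  gcn <- lapply(seq_len(length(cfg$gcn_dims)), function(l) {
    list(W = .glorot(dims[l], dims[l + 1]))
  })
  dtop <- dims[length(dims)]
  list(
    fa = fa,
    gcn = gcn,
    clf = list(W = .glorot(dtop, 2), b = rep(0, 2)),
    disc = list(W1 = .glorot(dtop, cfg$disc_hidden),
                b1 = rep(0, cfg$disc_hidden),
                W2 = .glorot(cfg$disc_hidden, cfg$n_domains),
                b2 = rep(0, cfg$n_domains))
  )
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Single self-attention head
#'
#' `softmax(Q K' / sqrt(d_k)) V` with `Q = X Wq`, `K = X Wk`,
#' `V = X Wv`.
#'
#' @param X input matrix, nodes x features.
#' @param params list with `Wq`, `Wk`, `Wv`.
#' @return nodes x d_h output matrix.
#' @export
attention_head <- function(X, params) {
  .attention_head_fwd(X, params)$O
}

.attention_head_fwd <- function(X, params) {
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  dk <- ncol(K)
  P <- .softmax_rows(Q %*% t(K) / sqrt(dk))
  list(O = P %*% V, Q = Q, K = K, V = V, P = P, dk = dk)
}

#' One feature-attention layer
#'
#' Multi-head attention, concatenation, output projection, residual
#' connection, ReLU: `ReLU(X + Concat(heads) Wo)`. Shape-preserving.
#'
#' @param X nodes x D input.
#' @param layer_params list with `heads` (per-head weights) and `Wo`.
#' @return nodes x D output, entries >= 0.
#' @export
fa_layer <- function(X, layer_params) {
  .fa_layer_fwd(X, layer_params)$Y
}

.fa_layer_fwd <- function(X, layer_params) {
  hs <- lapply(layer_params$heads, function(hp) .attention_head_fwd(X, hp))
  C <- do.call(cbind, lapply(hs, `[[`, "O"))
  pre <- X + C %*% layer_params$Wo
  list(Y = pmax(pre, 0), X = X, heads = hs, C = C, pre = pre)
}

#' Four-layer feature-attention stack
#'
#' @param X nodes x D input.
#' @param fa_params list of layer parameter sets (from
#'   [init_params()]`$fa`).
#' @return enhanced features, same shape as `X`.
#' @export
fa_stack <- function(X, fa_params) {
  for (lp in fa_params) X <- fa_layer(X, lp)
  X
}

#' Pearson-threshold ROI adjacency with symmetric normalization
#'
#' `A[m, n] = 1` iff the Pearson correlation of ROI series m and n is
#' `>= phi` (m != n; the diagonal is forced to 0 so the explicit
#' self-loop added by the normalization is not doubled). Returns also
#' `A_hat = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of
#' `A + I`.
#'
#' @param roi_series ROIs x time matrix.
#' @param phi correlation threshold (default 0.3).
#' @return list with `A` (binary) and `A_hat` (normalized), both N x N.
#' @export
build_adjacency <- function(roi_series, phi = 0.3) {
  n <- nrow(roi_series)
  if (n < 2) stop("need at least 2 ROI series")
  sds <- apply(roi_series, 1, stats::sd)
  if (any(sds == 0)) stop("constant series: correlation undefined")
  A <- (stats::cor(t(roi_series)) >= phi) * 1
  dimnames(A) <- NULL
  diag(A) <- 0
  Ai <- A + diag(n)
  dd <- rowSums(Ai)
  Dih <- diag(1 / sqrt(dd), n)
  list(A = A, A_hat = Dih %*% Ai %*% Dih)
}

#' One graph-convolution layer
#'
#' `ReLU(A_hat %*% H %*% W)`.
#'
#' @param H node features, N x d_in.
#' @param A_hat normalized adjacency.
#' @param W weight matrix d_in x d_out.
#' @return N x d_out matrix.
#' @export
gcn_layer <- function(H, A_hat, W) {
  pmax(A_hat %*% H %*% W, 0)
}

#' Classifier head: mean-pool + linear
#'
#' @param H node embeddings, N x d.
#' @param clf list with `W` (d x 2) and `b`.
#' @return length-2 logit vector.
#' @export
classify <- function(H, clf) {
  f <- colMeans(H)
  drop(f %*% clf$W) + clf$b
}

#' Gradient reversal layer (forward)
#'
#' Identity in the forward pass; in the backward pass (see the training
#' code) the gradient flowing back through it is multiplied by
#' `-lambda`.
#'
#' @param x input.
#' @param lambda reversal strength (unused in the forward pass).
#' @return `x`, unchanged.
#' @export
grl <- function(x, lambda = 1) x

#' Domain discriminator logits
#'
#' 2-layer perceptron on (gradient-reversed) pooled features.
#'
#' @param f pooled feature vector.
#' @param disc list with `W1`, `b1`, `W2`, `b2`.
#' @return length-K domain logit vector.
#' @export
discriminate <- function(f, disc) {
  g <- pmax(drop(f %*% disc$W1) + disc$b1, 0)
  drop(g %*% disc$W2) + disc$b2
}

# ---- full forward/backward with cache ------------------------------------

.forward_sample <- function(params, X, A_hat, cfg, drop_mask = NULL) {
  cache <- list(X0 = X)
  if (cfg$use_fa) {
    fa_caches <- vector("list", length(params$fa))
    H <- X
    for (l in seq_along(params$fa)) {
      fc <- .fa_layer_fwd(H, params$fa[[l]])
      fa_caches[[l]] <- fc
      H <- fc$Y
    }
    cache$fa <- fa_caches
    Xh <- H
  } else {
    Xh <- X
  }
  cache$Xh <- Xh

  gcn_caches <- vector("list", length(params$gcn))
  H <- Xh
  for (l in seq_along(params$gcn)) {
    M <- A_hat %*% H
    pre <- M %*% params$gcn[[l]]$W
    Hout <- pmax(pre, 0)
    if (l == 1 && !is.null(drop_mask)) Hout <- Hout * drop_mask
    gcn_caches[[l]] <- list(Hin = H, M = M, pre = pre, Hout = Hout)
    H <- Hout
  }
  cache$gcn <- gcn_caches
  cache$A_hat <- A_hat
  cache$drop_mask <- drop_mask

  f <- colMeans(H)
  z <- drop(f %*% params$clf$W) + params$clf$b
  g1pre <- drop(f %*% params$disc$W1) + params$disc$b1
  g1 <- pmax(g1pre, 0)
  zd <- drop(g1 %*% params$disc$W2) + params$disc$b2
  cache$f <- f
  cache$z <- z
  cache$g1pre <- g1pre
  cache$g1 <- g1
  cache$zd <- zd
  cache
}

# Backward for one sample. dz: grad wrt class logits; dzd: grad wrt
# domain logits (as seen by the DISCRIMINATOR, i.e. +dL_adv); df_extra:
# additional grad on the pooled feature (center loss); lambda: GRL
# strength. Accumulates into `grads` (same structure as params) and
# returns it.
.backward_sample <- function(params, cfg, cache, grads, dz, dzd,
                             df_extra = 0, lambda = 0) {
  f <- cache$f
  # classifier
  grads$clf$W <- grads$clf$W + outer(f, dz)
  grads$clf$b <- grads$clf$b + dz
  df <- drop(params$clf$W %*% dz)
  # discriminator (minimizes L_adv)
  dg1 <- drop(params$disc$W2 %*% dzd)
  dg1pre <- dg1 * (cache$g1pre > 0)
  grads$disc$W2 <- grads$disc$W2 + outer(cache$g1, dzd)
  grads$disc$b2 <- grads$disc$b2 + dzd
  grads$disc$W1 <- grads$disc$W1 + outer(f, dg1pre)
  grads$disc$b1 <- grads$disc$b1 + dg1pre
  df_disc <- drop(params$disc$W1 %*% dg1pre)
  # gradient reversal: extractor sees -lambda * dL_adv/df
  df <- df + df_extra - lambda * df_disc

  ng <- length(params$gcn)
  Htop <- cache$gcn[[ng]]$Hout
  n_nodes <- nrow(Htop)
  dH <- matrix(df / n_nodes, n_nodes, length(df), byrow = TRUE)
  for (l in rev(seq_len(ng))) {
    gc <- cache$gcn[[l]]
    if (l == 1 && !is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
    dpre <- dH * (gc$pre > 0)
    grads$gcn[[l]]$W <- grads$gcn[[l]]$W + t(gc$M) %*% dpre
    dM <- dpre %*% t(params$gcn[[l]]$W)
    dH <- t(cache$A_hat) %*% dM
  }

  if (cfg$use_fa) {
    dY <- dH
    for (l in rev(seq_along(params$fa))) {
      fc <- cache$fa[[l]]
      lp <- params$fa[[l]]
      dpre <- dY * (fc$pre > 0)
      dX <- dpre  # residual path
      grads$fa[[l]]$Wo <- grads$fa[[l]]$Wo + t(fc$C) %*% dpre
      dC <- dpre %*% t(lp$Wo)
      dh <- cfg$d_h
      for (h in seq_along(lp$heads)) {
        hc <- fc$heads[[h]]
        cols <- ((h - 1) * dh + 1):(h * dh)
        dO <- dC[, cols, drop = FALSE]
        dV <- t(hc$P) %*% dO
        dP <- dO %*% t(hc$V)
        drow <- rowSums(dP * hc$P)
        dS <- hc$P * (dP - drow) / sqrt(hc$dk)
        dQ <- dS %*% hc$K
        dK <- t(dS) %*% hc$Q
        Xin <- fc$X
        grads$fa[[l]]$heads[[h]]$Wq <- grads$fa[[l]]$heads[[h]]$Wq + t(Xin) %*% dQ
        grads$fa[[l]]$heads[[h]]$Wk <- grads$fa[[l]]$heads[[h]]$Wk + t(Xin) %*% dK
        grads$fa[[l]]$heads[[h]]$Wv <- grads$fa[[l]]$heads[[h]]$Wv + t(Xin) %*% dV
        dX <- dX + dQ %*% t(lp$heads[[h]]$Wq) +
          dK %*% t(lp$heads[[h]]$Wk) + dV %*% t(lp$heads[[h]]$Wv)
      }
      dY <- dX
    }
  }
  grads
}

.zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

# flatten/unflatten parameter pytrees for Adam and finite differences
.flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

.unflatten_params <- function(template, v) {
  i <- 0
  rapply(template, function(x) {
    out <- v[(i + 1):(i + length(x))]
    i <<- i + length(x)
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }, how = "replace")
}
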