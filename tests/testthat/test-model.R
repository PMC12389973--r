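# Neural architecture: attention algebra, adjacency normalization,
# graph convolution, GRL semantics, permutation equivariance.

test_that("attention with zero queries averages the value rows", {
  set.seed(1)
  N <- 4; D <- 6; dh <- 3
  X <- matrix(rnorm(N * D), N, D)
  p <- list(Wq = matrix(0, D, dh),
            Wk = matrix(rnorm(D * dh), D, dh),
            Wv = matrix(rnorm(D * dh), D, dh))
  out <- attention_head(X, p)
  V <- X %*% p$Wv
  expect_equal(out, matrix(rep(colMeans(V), each = N), N, dh),
               tolerance = 1e-12)
})

test_that("attention matches a hand-evaluated 2x2 softmax computation", {
  X <- matrix(c(1, 0, 0, 2), 2, 2)
  p <- list(Wq = matrix(c(1, 0), 2, 1), Wk = matrix(c(0, 1), 2, 1),
            Wv = matrix(c(1, 1), 2, 1))
  # Q = (1, 0)', K = (0, 2)', V = (1, 2)'; scores/sqrt(1):
  # row1: (0, 2) -> softmax (1/(1+e^2), e^2/(1+e^2)); row2: (0, 0) -> (.5, .5)
  w <- exp(2) / (1 + exp(2))
  expected <- matrix(c((1 - w) * 1 + w * 2, 1.5), 2, 1)
  expect_equal(attention_head(X, p), expected, tolerance = 1e-12)
})

test_that("softmax rows of the attention weights sum to one", {
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(rnorm(5 * 8), 5, 8)
    p <- list(Wq = matrix(rnorm(16), 8, 2), Wk = matrix(rnorm(16), 8, 2),
              Wv = matrix(rnorm(16), 8, 2))
    fwd <- corticlass:::.attention_head_fwd(X, p)
    expect_equal(rowSums(fwd$P), rep(1, 5), tolerance = 1e-6)
  }
})

test_that("fa_layer preserves shape, applies residual + ReLU", {
  set.seed(3)
  cfg <- model_config(d_in = 32, heads = 4)
  params <- init_params(cfg, seed = 1)
  X <- matrix(rnorm(68 * 32), 68, 32)
  Y <- fa_layer(X, params$fa[[1]])
  expect_equal(dim(Y), c(68, 32))
  expect_true(all(Y >= 0))
  # zero input with zero heads -> zero output
  zero_layer <- rapply(params$fa[[1]], function(w) w * 0, how = "replace")
  expect_equal(fa_layer(matrix(0, 5, 32), zero_layer), matrix(0, 5, 32))
  # heads forced to zero: residual path gives ReLU(X)
  zero_heads <- params$fa[[1]]
  zero_heads$heads <- rapply(zero_heads$heads, function(w) w * 0,
                             how = "replace")
  expect_equal(fa_layer(X, zero_heads), pmax(X, 0), tolerance = 1e-12)
})

test_that("fa_stack composes four layers and differs from one layer", {
  set.seed(4)
  cfg <- model_config(d_in = 8, heads = 2, fa_layers = 4)
  params <- init_params(cfg, seed = 2)
  X <- matrix(rnorm(5 * 8), 5, 8)
  out4 <- fa_stack(X, params$fa)
  expect_equal(dim(out4), dim(X))
  out1 <- fa_layer(X, params$fa[[1]])
  expect_gt(max(abs(out4 - out1)), 1e-6)
  # zero-head setting: stack = ReLU composed 4x = ReLU
  zp <- lapply(params$fa, function(lp) {
    lp$heads <- rapply(lp$heads, function(w) w * 0, how = "replace")
    lp
  })
  expect_equal(fa_stack(X, zp), pmax(X, 0), tolerance = 1e-12)
})

test_that("adjacency construction follows the threshold + normalization", {
  t <- seq_len(200) / 100
  x <- sin(2 * pi * 3 * t)
  # identical series: A = offdiag ones, A_hat = 0.5 * ones
  adj <- build_adjacency(rbind(x, x), 0.3)
  expect_equal(adj$A, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(adj$A_hat, matrix(0.5, 2, 2), tolerance = 1e-12)
  # orthogonal sinusoids: no edges, self-loops only
  y <- cos(2 * pi * 3 * t)
  adj2 <- build_adjacency(rbind(x, y), 0.3)
  expect_equal(adj2$A, matrix(0, 2, 2))
  expect_equal(adj2$A_hat, diag(2), tolerance = 1e-12)
  expect_error(build_adjacency(rbind(x, rep(1, 200)), 0.3), "constant")
  # spectral radius <= 1 on random instances
  set.seed(5)
  for (i in 1:50) {
    rs <- matrix(rnorm(5 * 80), 5, 80)
    ah <- build_adjacency(rs, runif(1, -0.2, 0.6))$A_hat
    expect_equal(ah, t(ah), tolerance = 1e-12)
    ev <- eigen(ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-8 & ev <= 1 + 1e-8))
  }
})

test_that("gcn_layer computes ReLU(A_hat H W)", {
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(gcn_layer(H, diag(2), diag(2)), H)
  expect_equal(gcn_layer(H, diag(2), matrix(0, 2, 2)), matrix(0, 2, 2))
  A_hat <- matrix(0.5, 2, 2)
  W <- matrix(c(1, -1, 0, 2), 2, 2)
  expect_equal(gcn_layer(H, A_hat, W), pmax((A_hat %*% H) %*% W, 0))
})

test_that("GRL is the identity forward and reverses gradients backward", {
  x <- rnorm(5)
  expect_identical(grl(x, lambda = 0.7), x)
  # backward: gradient of sum(GRL(f)) wrt f is -lambda * 1, via the
  # training-path backward against finite differences
  set.seed(6)
  N <- 4; D <- 6; K <- 3
  mcfg <- model_config(d_in = D, n_domains = K, heads = 2, fa_layers = 1,
                       gcn_dims = c(5, 5), disc_hidden = 4, dropout = 0)
  params <- init_params(mcfg, seed = 3)
  s <- list(X = matrix(rnorm(N * D), N, D),
            A_hat = diag(N), label = 0L, domain = 2L, subject_id = "a")
  lam <- 0.6
  # gradients of the adversarial term alone, flowing through the GRL
  cb <- corticlass:::.compute_batch(params, list(s), mcfg,
                                    gamma_focal = 0, beta = c(1, 1),
                                    lambda = lam, gamma_center = 0,
                                    centers = matrix(0, 2, 5),
                                    component_scale = c(0, 1, 0))
  # finite differences of -lam * L_adv wrt an extractor weight
  flat <- corticlass:::.flatten_params(params)
  gflat <- corticlass:::.flatten_params(cb$grads)
  adv_of <- function(p) {
    corticlass:::.compute_batch(p, list(s), mcfg, 0, c(1, 1), lam, 0,
                                matrix(0, 2, 5))$losses[["adv"]]
  }
  h <- 1e-5
  set.seed(7)
  # pick indices in the GCN weights (extractor side)
  for (rep in 1:5) {
    i <- sample(length(corticlass:::.flatten_params(params$fa)) +
                  seq_len(length(corticlass:::.flatten_params(params$gcn))), 1)
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    num <- (adv_of(corticlass:::.unflatten_params(params, fp)) -
              adv_of(corticlass:::.unflatten_params(params, fm))) / (2 * h)
    expect_equal(gflat[i], -lam * num, tolerance = 1e-4)
  }
  # lambda = 0: no adversarial gradient reaches the extractor
  cb0 <- corticlass:::.compute_batch(params, list(s), mcfg, 0, c(1, 1),
                                     0, 0, matrix(0, 2, 5),
                                     component_scale = c(0, 1, 0))
  expect_equal(max(abs(corticlass:::.flatten_params(cb0$grads$gcn))), 0)
  expect_equal(max(abs(corticlass:::.flatten_params(cb0$grads$fa))), 0)
  # but the discriminator still learns
  expect_gt(max(abs(corticlass:::.flatten_params(cb0$grads$disc))), 0)
})

test_that("pooled logits are invariant to joint node permutation", {
  set.seed(8)
  N <- 6; D <- 8
  mcfg <- model_config(d_in = D, n_domains = 2, heads = 2, fa_layers = 2,
                       gcn_dims = c(7, 7), disc_hidden = 4, dropout = 0)
  params <- init_params(mcfg, seed = 4)
  X <- matrix(rnorm(N * D), N, D)
  A <- build_adjacency(matrix(rnorm(N * 60), N, 60), 0.1)$A_hat
  perm <- sample(N)
  c1 <- corticlass:::.forward_sample(params, X, A, mcfg)
  c2 <- corticlass:::.forward_sample(params, X[perm, ], A[perm, perm], mcfg)
  expect_equal(c2$z, c1$z, tolerance = 1e-10)
  # node embeddings permute identically
  expect_equal(c2$gcn[[2]]$Hout, c1$gcn[[2]]$Hout[perm, ],
               tolerance = 1e-10)
  # deterministic forward without dropout
  c3 <- corticlass:::.forward_sample(params, X, A, mcfg)
  expect_identical(c1$z, c3$z)
})

test_that("classify and discriminate have the declared shapes", {
  set.seed(9)
  cfg <- model_config(d_in = 6, n_domains = 5, gcn_dims = c(8, 8),
                      disc_hidden = 4)
  p <- init_params(cfg, seed = 5)
  H <- matrix(rnorm(3 * 8), 3, 8)
  expect_length(classify(H, p$clf), 2)
  expect_length(discriminate(colMeans(H), p$disc), 5)
})
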