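# Loss functions: hand-evaluated values, reductions, gradient
# decomposition of the joint objective, two-term update equivalence.

test_that("focal loss matches hand evaluations and reduces to CE", {
  # gamma = 0, p = 0.5 -> ln 2
  expect_equal(focal_loss(0.5, 0L, beta = c(1, 1), gamma = 0), log(2),
               tolerance = 1e-12)
  # gamma = 2, p = 0.9 -> 0.01 * (-ln 0.9)
  expect_equal(focal_loss(0.9, 0L, beta = c(1, 1), gamma = 2),
               0.01 * -log(0.9), tolerance = 1e-10)
  # p -> 1 drives the loss to zero
  expect_lt(focal_loss(1 - 1e-9, 1L, gamma = 2), 1e-8)
  # gamma = 0 equals weighted cross-entropy for a batch
  set.seed(1)
  p <- runif(8, 0.1, 0.95)
  lab <- sample(0:1, 8, replace = TRUE)
  beta <- c(1.5, 0.5)
  expect_equal(focal_loss(p, lab, beta, gamma = 0, reduction = "sum"),
               -sum(beta[lab + 1] * log(p)), tolerance = 1e-12)
  # sum vs mean conventions
  expect_equal(focal_loss(p, lab, beta, 2, "sum") / 8,
               focal_loss(p, lab, beta, 2, "mean"), tolerance = 1e-12)
  # monotone decreasing in p on a grid
  grid <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(grid, function(pp) focal_loss(pp, 0L, gamma = 2), 0)
  expect_true(all(diff(vals) < 0))
  expect_warning(focal_loss(0, 0L), "clamped")
})

test_that("adversarial loss matches hand evaluations", {
  expect_equal(adversarial_loss(matrix(0.5, 1, 2), 1L), log(2),
               tolerance = 1e-12)
  expect_lt(suppressWarnings(
    adversarial_loss(matrix(c(1, 0), 1), 1L)), 1e-10)
  q <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.3, 0.3, 0.4))
  d <- c(1L, 2L, 3L)
  expect_equal(adversarial_loss(q, d, reduction = "sum"),
               -(log(0.7) + log(0.8) + log(0.4)), tolerance = 1e-12)
  expect_error(adversarial_loss(matrix(c(0.5, 0.2), 1), 1L), "sum to 1")
})

test_that("center loss is the squared distance to class centers", {
  centers <- rbind(c(0, 0), c(1, 1))
  f <- rbind(c(0, 0), c(1, 1))
  expect_equal(center_loss(f, c(0L, 1L), centers, "sum"), 0)
  expect_equal(center_loss(matrix(c(2, 0), 1), 0L, centers, "sum"), 4)
  f3 <- rbind(c(1, 0), c(0, 1), c(3, 1))
  lab3 <- c(0L, 1L, 1L)
  hand <- sum((f3[1, ] - centers[1, ])^2) +
    sum((f3[2, ] - centers[2, ])^2) + sum((f3[3, ] - centers[2, ])^2)
  expect_equal(center_loss(f3, lab3, centers, "sum"), hand,
               tolerance = 1e-12)
})

test_that("joint loss combines components with the documented signs", {
  expect_equal(joint_loss(1, 1, 1, gamma_center = 0.5, lambda = 0.2), 1.3)
  expect_equal(joint_loss(0.7, 2, 3, gamma_center = 0, lambda = 0), 0.7)
})

test_that("joint gradient decomposes into its three terms", {
  set.seed(2)
  N <- 4; D <- 6; K <- 3
  mcfg <- model_config(d_in = D, n_domains = K, heads = 2, fa_layers = 1,
                       gcn_dims = c(5, 5), disc_hidden = 4, dropout = 0)
  params <- init_params(mcfg, seed = 11)
  centers <- matrix(rnorm(10), 2, 5)
  batch <- lapply(1:3, function(i) {
    list(X = matrix(rnorm(N * D), N, D),
         A_hat = build_adjacency(matrix(rnorm(N * 50), N, 50), 0)$A_hat,
         label = i %% 2, domain = (i %% K) + 1L, subject_id = "s")
  })
  gf <- 2; beta <- c(1.2, 0.9); lam <- 0.3; gc <- 0.05
  g_joint <- corticlass:::.compute_batch(params, batch, mcfg, gf, beta,
                                         lam, gc, centers)$grads
  g_focal <- corticlass:::.compute_batch(params, batch, mcfg, gf, beta,
                                         lam, gc, centers,
                                         component_scale = c(1, 0, 0))$grads
  g_adv <- corticlass:::.compute_batch(params, batch, mcfg, gf, beta,
                                       -1, gc, centers,
                                       component_scale = c(0, 1, 0))$grads
  g_cen <- corticlass:::.compute_batch(params, batch, mcfg, gf, beta,
                                       lam, gc, centers,
                                       component_scale = c(0, 0, 1))$grads
  # extractor blocks: joint = focal + center - lam * adv
  for (block in c("fa", "gcn", "clf")) {
    gj <- corticlass:::.flatten_params(g_joint[[block]])
    gsum <- corticlass:::.flatten_params(g_focal[[block]]) +
      corticlass:::.flatten_params(g_cen[[block]]) -
      lam * corticlass:::.flatten_params(g_adv[[block]])
    expect_equal(gj, gsum, tolerance = 1e-10)
  }
  # finite differences on the extractor objective
  obj <- function(p) {
    l <- corticlass:::.compute_batch(p, batch, mcfg, gf, beta, lam, gc,
                                     centers)$losses
    l[["focal"]] + gc * l[["center"]] - lam * l[["adv"]]
  }
  flat <- corticlass:::.flatten_params(params)
  gflat <- corticlass:::.flatten_params(g_joint)
  h <- 1e-6
  set.seed(3)
  n_ext <- length(flat) -
    length(corticlass:::.flatten_params(params$disc))
  for (rep in 1:8) {
    i <- sample(n_ext, 1)
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    num <- (obj(corticlass:::.unflatten_params(params, fp)) -
              obj(corticlass:::.unflatten_params(params, fm))) / (2 * h)
    expect_equal(gflat[i], num, tolerance = 1e-4)
  }
})

test_that("GRL step equals the explicit two-term update", {
  set.seed(4)
  N <- 4; D <- 6; K <- 2
  mcfg <- model_config(d_in = D, n_domains = K, heads = 2, fa_layers = 1,
                       gcn_dims = c(5, 5), disc_hidden = 4, dropout = 0)
  params <- init_params(mcfg, seed = 21)
  centers <- matrix(0, 2, 5)
  batch <- lapply(1:4, function(i) {
    list(X = matrix(rnorm(N * D), N, D),
         A_hat = build_adjacency(matrix(rnorm(N * 50), N, 50), 0)$A_hat,
         label = i %% 2, domain = (i %% K) + 1L, subject_id = "s")
  })
  lam <- 0.4; eta <- 0.01
  # one SGD step with the GRL in place (gamma_center = 0)
  g <- corticlass:::.compute_batch(params, batch, mcfg, 2, c(1, 1), lam,
                                   0, centers)$grads
  theta_grl <- corticlass:::.flatten_params(params) -
    eta * corticlass:::.flatten_params(g)
  # explicit: theta <- theta - eta (dL_focal - lam dL_adv) on the
  # extractor; discriminator takes +dL_adv
  gf <- corticlass:::.compute_batch(params, batch, mcfg, 2, c(1, 1), 0,
                                    0, centers,
                                    component_scale = c(1, 0, 0))$grads
  ga <- corticlass:::.compute_batch(params, batch, mcfg, 2, c(1, 1), -1,
                                    0, centers,
                                    component_scale = c(0, 1, 0))$grads
  two_term <- params
  for (block in c("fa", "gcn", "clf")) {
    two_term[[block]] <- corticlass:::.unflatten_params(
      params[[block]],
      corticlass:::.flatten_params(params[[block]]) -
        eta * (corticlass:::.flatten_params(gf[[block]]) -
                 lam * corticlass:::.flatten_params(ga[[block]])))
  }
  two_term$disc <- corticlass:::.unflatten_params(
    params$disc,
    corticlass:::.flatten_params(params$disc) -
      eta * corticlass:::.flatten_params(ga$disc))
  expect_equal(theta_grl,
               corticlass:::.flatten_params(two_term), tolerance = 1e-6)
})
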