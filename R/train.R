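# Adversarial training loop: focal classification loss + GRL domain
# adversary + class-center constraint, Adam optimizer, subject-wise
# splits, early stopping on validation accuracy.

#' Training configuration
#'
#' Defaults mirror the reference hyper-parameters (batch 16, Adam at
#' 5e-5, 70 epochs, patience 15, dropout 0.3, 4 heads, hidden 512).
#' Tests shrink the network and raise the learning rate for speed.
#'
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param gamma_focal focal-loss focusing exponent.
#' @param beta class-balance factors; NULL = inverse class frequency on
#'   the training split, normalized to mean 1.
#' @param lambda adversarial weight (maximum of the ramp).
#' @param lambda_ramp ramp lambda from 0 with the standard sigmoid
#'   schedule `2 / (1 + exp(-10 p)) - 1` over training progress `p`.
#' @param gamma_center center-loss weight.
#' @param center_momentum exponential-moving-average momentum for the
#'   class-center update.
#' @param dropout dropout rate.
#' @param split subject-wise train/val/test fractions.
#' @param heads,fa_layers,gcn_dims,disc_hidden,use_fa,phi model
#'   architecture settings (see [model_config()]).
#' @param seed RNG seed controlling initialization, splits, shuffling
#'   and dropout.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 16, lr = 5e-5, epochs = 70,
                         patience = 15, gamma_focal = 2, beta = NULL,
                         lambda = 0.1, lambda_ramp = TRUE,
                         gamma_center = 0.01, center_momentum = 0.9,
                         dropout = 0.3, split = c(0.7, 0.15, 0.15),
                         heads = 4, fa_layers = 4, gcn_dims = c(512, 512),
                         disc_hidden = 256, use_fa = TRUE, phi = 0.3,
                         seed = 1, verbose = FALSE) {
  structure(as.list(environment()), class = "train_config")
}

# subject-wise stratified split: subjects (not epochs) are assigned to
# train/val/test so no subject leaks across partitions
.subject_split <- function(samples, split, seed) {
  subj <- vapply(samples, `[[`, "", "subject_id")
  lab <- vapply(samples, function(s) as.integer(s$label), integer(1))
  sub_lab <- tapply(lab, subj, function(x) x[1])
  set.seed(seed)
  parts <- list(train = character(), val = character(), test = character())
  for (cl in unique(sub_lab)) {
    ss <- sample(names(sub_lab)[sub_lab == cl])
    n <- length(ss)
    if (n < 2) stop("need at least 2 subjects per class")
    if (n == 2) {
      # too few subjects for 3 disjoint partitions: validation subject
      # doubles as the test subject
      warning("only 2 subjects in a class: validation and test share one")
      parts$train <- c(parts$train, ss[1])
      parts$val <- c(parts$val, ss[2])
      parts$test <- c(parts$test, ss[2])
      next
    }
    n_tr <- max(1, round(split[1] * n))
    n_va <- max(1, round(split[2] * n))
    if (n_tr + n_va >= n) {
      n_tr <- max(1, n - 2)
      n_va <- 1
    }
    parts$train <- c(parts$train, ss[seq_len(n_tr)])
    parts$val <- c(parts$val, ss[n_tr + seq_len(n_va)])
    parts$test <- c(parts$test, ss[(n_tr + n_va + 1):n])
  }
  lapply(parts, function(p) which(subj %in% p))
}

# loss gradients wrt class logits for the focal loss (mean reduction
# handled by the caller through `scale`)
.focal_dlogits <- function(z, label, beta, gamma) {
  p <- exp(z - max(z))
  p <- p / sum(p)
  ti <- label + 1L
  pt <- max(p[ti], 1e-12)
  b <- beta[label + 1L]
  # dL/dpt for L = -b (1-pt)^gamma log(pt)
  dpt <- b * (gamma * (1 - pt)^(max(gamma - 1, 0)) * log(pt) -
                (1 - pt)^gamma / pt)
  onehot <- c(0, 0)
  onehot[ti] <- 1
  list(dz = dpt * pt * (onehot - p), p = p, pt = pt)
}

.softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# forward + loss + gradients over a batch. component_scale lets tests
# isolate the focal / adversarial / center contributions.
.compute_batch <- function(params, batch, mcfg, gamma_focal, beta,
                           lambda, gamma_center, centers,
                           drop_masks = NULL, reduction = "mean",
                           component_scale = c(1, 1, 1)) {
  M <- length(batch)
  sc <- if (reduction == "mean") 1 / M else 1
  grads <- .zero_like(params)
  l_focal <- l_adv <- l_center <- 0
  feats <- matrix(NA_real_, M, nrow(params$clf$W))
  preds <- integer(M)
  for (i in seq_len(M)) {
    s <- batch[[i]]
    cache <- .forward_sample(params, s$X, s$A_hat, mcfg,
                             drop_mask = drop_masks[[i]])
    feats[i, ] <- cache$f
    fd <- .focal_dlogits(cache$z, s$label, beta, gamma_focal)
    preds[i] <- which.max(fd$p) - 1L
    l_focal <- l_focal + sc * (-beta[s$label + 1L] *
                                 (1 - fd$pt)^gamma_focal * log(fd$pt))
    dz <- component_scale[1] * sc * fd$dz

    qd <- .softmax_vec(cache$zd)
    dzd <- rep(0, length(qd))
    if (!is.null(s$domain) && !is.na(s$domain)) {
      qt <- max(qd[s$domain], 1e-12)
      l_adv <- l_adv + sc * (-log(qt))
      onehot <- rep(0, length(qd))
      onehot[s$domain] <- 1
      dzd <- component_scale[2] * sc * (qd - onehot)
    }

    cvec <- centers[s$label + 1L, ]
    l_center <- l_center + sc * sum((cache$f - cvec)^2)
    df_extra <- component_scale[3] * sc * gamma_center * 2 * (cache$f - cvec)

    grads <- .backward_sample(params, mcfg, cache, grads, dz, dzd,
                              df_extra = df_extra, lambda = lambda)
  }
  list(grads = grads,
       losses = c(focal = l_focal, adv = l_adv, center = l_center,
                  joint = joint_loss(l_focal, l_center, l_adv,
                                     gamma_center, lambda)),
       features = feats, preds = preds)
}

#' Predict class labels for a set of samples
#'
#' @param state a `fada_model` from [train_fada()].
#' @param samples list of samples (`X`, `A_hat`, optionally labels).
#' @return list with `labels` (predicted 0/1), `probs` (M x 2), and
#'   `features` (pooled embeddings).
#' @export
predict_fada <- function(state, samples) {
  M <- length(samples)
  probs <- matrix(NA_real_, M, 2)
  feats <- matrix(NA_real_, M, nrow(state$params$clf$W))
  for (i in seq_len(M)) {
    cache <- .forward_sample(state$params, samples[[i]]$X,
                             samples[[i]]$A_hat, state$model_cfg)
    probs[i, ] <- .softmax_vec(cache$z)
    feats[i, ] <- cache$f
  }
  list(labels = max.col(probs) - 1L, probs = probs, features = feats)
}

#' Train the focal adversarial domain adaptation model
#'
#' Subject-wise stratified split, Adam updates of the joint objective
#' (focal loss + gamma_center * center loss - lambda * adversarial
#' loss via the gradient-reversal layer; the discriminator itself
#' descends the adversarial loss), exponential-moving-average class
#' centers, early stopping on validation accuracy. Fully reproducible
#' given `cfg$seed`.
#'
#' @param samples list of samples; each is a list with `X` (N x D
#'   feature matrix), `A_hat` (normalized adjacency), `label` (0/1),
#'   `subject_id`.
#' @param cfg a [train_config()].
#' @return a `fada_model` list: best `params`, `model_cfg`, `centers`,
#'   per-epoch `history` data frame, split indices, and the evaluation
#'   report on the held-out test subjects.
#' @export
train_fada <- function(samples, cfg = train_config()) {
  labs <- vapply(samples, function(s) as.integer(s$label), integer(1))
  if (length(unique(labs)) < 2) stop("dataset must contain both classes")
  idx <- .subject_split(samples, cfg$split, cfg$seed)
  tr <- samples[idx$train]

  # one domain per training subject
  subj_tr <- vapply(tr, `[[`, "", "subject_id")
  dom_levels <- sort(unique(subj_tr))
  for (i in seq_along(tr)) tr[[i]]$domain <- match(subj_tr[i], dom_levels)

  lab_tr <- vapply(tr, function(s) as.integer(s$label), integer(1))
  beta <- cfg$beta
  if (is.null(beta)) {
    freq <- c(mean(lab_tr == 0), mean(lab_tr == 1))
    beta <- (1 / freq) / mean(1 / freq)
  }

  d_in <- ncol(tr[[1]]$X)
  mcfg <- model_config(d_in = d_in, n_domains = length(dom_levels),
                       heads = cfg$heads, fa_layers = cfg$fa_layers,
                       gcn_dims = cfg$gcn_dims,
                       disc_hidden = cfg$disc_hidden,
                       dropout = cfg$dropout, use_fa = cfg$use_fa,
                       phi = cfg$phi)
  params <- init_params(mcfg, seed = cfg$seed)
  d_top <- nrow(params$clf$W)
  centers <- matrix(0, 2, d_top)

  # Adam state
  flat <- .flatten_params(params)
  m <- v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  n_nodes <- nrow(tr[[1]]$X)
  hist <- list()
  best_acc <- -Inf; best_params <- params; best_centers <- centers
  wait <- 0
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    prog <- ep / cfg$epochs
    lam <- if (cfg$lambda_ramp) {
      cfg$lambda * (2 / (1 + exp(-10 * prog)) - 1)
    } else cfg$lambda
    ord <- sample(length(tr))
    ep_losses <- c(focal = 0, adv = 0, center = 0, joint = 0)
    nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      batch <- tr[bidx]
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(batch, function(s) {
          matrix(stats::rbinom(n_nodes * cfg$gcn_dims[1], 1,
                               1 - cfg$dropout) / (1 - cfg$dropout),
                 n_nodes, cfg$gcn_dims[1])
        })
      }
      cb <- .compute_batch(params, batch, mcfg, cfg$gamma_focal, beta,
                           lam, cfg$gamma_center, centers,
                           drop_masks = masks)
      step <- step + 1
      g <- .flatten_params(cb$grads)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      flat <- .flatten_params(params) - cfg$lr * mh / (sqrt(vh) + eps)
      params <- .unflatten_params(params, flat)
      # EMA center update from batch class means
      blab <- vapply(batch, function(s) as.integer(s$label), integer(1))
      for (cl in 0:1) {
        if (any(blab == cl)) {
          mu <- colMeans(cb$features[blab == cl, , drop = FALSE])
          centers[cl + 1, ] <- cfg$center_momentum * centers[cl + 1, ] +
            (1 - cfg$center_momentum) * mu
        }
      }
      ep_losses <- ep_losses + cb$losses
      nb <- nb + 1
    }
    ep_losses <- ep_losses / nb

    state_now <- list(params = params, model_cfg = mcfg)
    val_pred <- predict_fada(state_now, samples[idx$val])
    val_acc <- mean(val_pred$labels ==
                      vapply(samples[idx$val], function(s) s$label,
                             integer(1)))
    hist[[ep]] <- data.frame(epoch = ep, l_focal = ep_losses["focal"],
                             l_adv = ep_losses["adv"],
                             l_center = ep_losses["center"],
                             l_fada = ep_losses["joint"],
                             lambda = lam, val_acc = val_acc)
    if (cfg$verbose) {
      message(sprintf("epoch %3d  focal %.4f adv %.4f center %.4f  val %.3f",
                      ep, ep_losses["focal"], ep_losses["adv"],
                      ep_losses["center"], val_acc))
    }
    if (val_acc > best_acc + 1e-12) {
      best_acc <- val_acc
      best_params <- params
      best_centers <- centers
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }

  state <- structure(
    list(params = best_params, model_cfg = mcfg, centers = best_centers,
         beta = beta, cfg = cfg,
         history = do.call(rbind, hist), split = idx,
         domain_levels = dom_levels),
    class = "fada_model"
  )
  te <- samples[idx$test]
  te_pred <- predict_fada(state, te)
  state$test_report <- evaluate_predictions(
    te_pred$labels, vapply(te, function(s) as.integer(s$label), integer(1)))
  state
}

#' @export
print.fada_model <- function(x, ...) {
  cat(sprintf(
    "<fada_model> %d epochs trained, best val ACC %.2f%%, test ACC %.2f%%\n",
    nrow(x$history), 100 * max(x$history$val_acc), x$test_report$ACC))
  invisible(x)
}
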