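# Loss functions for focal adversarial domain adaptation.

.clamp_probs <- function(p) {
  if (any(p <= 0)) {
    warning("probabilities clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  p
}

#' Focal loss
#'
#' `-sum_i beta_{tau_i} (1 - p_i)^gamma log(p_i)` over the per-sample
#' true-class probabilities `p_i`; reduces to (weighted) cross-entropy
#' at `gamma = 0`. Down-weights well-classified samples so training
#' focuses on the minority class and boundary cases.
#'
#' @param p per-sample probability assigned to the true class.
#' @param labels integer class labels (0 = depressed, 1 = healthy),
#'   used to select the class-balance factor.
#' @param beta length-2 class-balance factors `c(beta_0, beta_1)`.
#' @param gamma focusing exponent, >= 0.
#' @param reduction `"mean"` (default, batch-scale stable) or `"sum"`
#'   (the plain summation convention).
#' @return non-negative scalar.
#' @export
focal_loss <- function(p, labels, beta = c(1, 1), gamma = 2,
                       reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (gamma < 0) stop("gamma must be >= 0")
  p <- .clamp_probs(p)
  b <- beta[labels + 1L]
  l <- -b * (1 - p)^gamma * log(p)
  if (reduction == "mean") mean(l) else sum(l)
}

#' Adversarial (domain-classification) loss
#'
#' Multi-class cross-entropy of the domain discriminator over K source
#' domains. The discriminator minimizes it; the feature extractor, via
#' the gradient-reversal layer, maximizes it.
#'
#' @param domain_probs M x K matrix of predicted domain probabilities
#'   (rows sum to 1).
#' @param domain_labels integer vector in `1..K`.
#' @param reduction `"mean"` or `"sum"`.
#' @return non-negative scalar.
#' @export
adversarial_loss <- function(domain_probs, domain_labels,
                             reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  domain_probs <- as.matrix(domain_probs)
  rs <- rowSums(domain_probs)
  if (any(abs(rs - 1) > 1e-6)) stop("domain_probs rows must sum to 1")
  p <- domain_probs[cbind(seq_along(domain_labels), domain_labels)]
  p <- .clamp_probs(p)
  l <- -log(p)
  if (reduction == "mean") mean(l) else sum(l)
}

#' Center loss
#'
#' Sum of squared distances between each sample's pooled feature vector
#' and its class center, promoting intra-class compactness.
#'
#' @param features M x d matrix of feature vectors.
#' @param labels integer class labels (0/1).
#' @param centers 2 x d matrix, row 1 = center of class 0, row 2 =
#'   center of class 1.
#' @param reduction `"mean"` or `"sum"`.
#' @return non-negative scalar; 0 iff every feature equals its center.
#' @export
center_loss <- function(features, labels, centers,
                        reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  features <- as.matrix(features)
  d2 <- rowSums((features - centers[labels + 1L, , drop = FALSE])^2)
  if (reduction == "mean") mean(d2) else sum(d2)
}

#' Joint FADA objective
#'
#' `L = L_focal + gamma_center * L_center - lambda * L_adv`, the
#' objective seen by the feature extractor. The discriminator itself
#' minimizes `L_adv`; the sign flip is realized by the gradient-reversal
#' layer during training.
#'
#' @param focal,center,adv the three component losses.
#' @param gamma_center center-loss weight.
#' @param lambda adversarial weight.
#' @return scalar.
#' @export
joint_loss <- function(focal, center, adv, gamma_center = 0.01,
                       lambda = 0.1) {
  focal + gamma_center * center - lambda * adv
}
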