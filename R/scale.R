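#' Heritability on the latent (liability) scale
#'
#' For a probit threshold model the latent-scale heritability is the
#' additive variance over the total latent variance, including the link
#' variance of the standard normal residual:
#' `h2 = Va / (Va + sum(other) + link_variance)`.
#'
#' @param Va Additive genetic variance on the latent scale.
#' @param other_random_variances Numeric vector of the remaining random
#'   variance components (permanent environment, family, dish, ...).
#' @param link_variance Residual link variance; 1 for probit models.
#' @return Latent-scale heritability in \[0, 1\].
#' @export
#' @examples
#' h2_latent(1, 0)          # 0.5
#' h2_latent(0.163, 1)      # 0.0754
h2_latent <- function(Va, other_random_variances = numeric(), link_variance = 1) {
  if (Va < 0 || any(other_random_variances < 0) || link_variance < 0)
    stop("variance components must be non-negative")
  denom <- Va + sum(other_random_variances) + link_variance
  if (denom == 0) stop("total latent variance is zero")
  Va / denom
}

#' Heritability of a Gaussian trait
#'
#' Identity-link ratio `Va / (Va + sum(components))`; no link variance is
#' added for a Gaussian response.
#'
#' @param Va Additive genetic variance.
#' @param components Remaining variance components (residual included).
#' @return Heritability in \[0, 1\].
#' @export
gaussian_h2 <- function(Va, components) {
  if (Va < 0 || any(components < 0))
    stop("variance components must be non-negative")
  denom <- Va + sum(components)
  if (denom == 0) stop("total variance is zero")
  Va / denom
}

#' Observed-scale heritability for a binary probit trait
#'
#' Converts latent-scale parameters of a probit threshold model to the
#' observed 0/1 scale.  With the linear predictor
#' `l ~ Normal(mu, Vrand_total)` and residual link variance 1,
#' the expected trait frequency is `p_bar = E[pnorm(l)]`, the average
#' derivative of the inverse link is `Psi = E[dnorm(l)]`, the phenotypic
#' variance on the observed scale is `p_bar * (1 - p_bar)`, and
#' `h2_observed = Psi^2 * Va / (p_bar * (1 - p_bar))`.  Expectations are
#' evaluated by Gauss-Hermite quadrature.
#'
#' @param mu Latent intercept (marginal mean of the linear predictor).
#' @param Va Additive genetic variance on the latent scale.
#' @param Vrand_total Total variance of the linear predictor: the sum of
#'   ALL random components (additive, permanent environment, family, dish,
#'   family:site), excluding the link variance.  Must be at least `Va`.
#' @param nodes Number of Gauss-Hermite nodes (>= 32 recommended).
#' @return An object of class `"scale_result"`: list with `h2_latent`,
#'   `h2_observed`, `p_bar`, `psi`.
#' @export
#' @examples
#' binary_observed_scale(mu = 0.206, Va = 0.163, Vrand_total = 0.163)
binary_observed_scale <- function(mu, Va, Vrand_total, nodes = 48) {
  if (Va < 0) stop("Va must be non-negative")
  if (Vrand_total < Va)
    stop("Vrand_total must include Va and so cannot be smaller than it")
  if (Vrand_total == 0) {
    p_bar <- stats::pnorm(mu)
    psi <- stats::dnorm(mu)
  } else {
    gh <- pracma::gaussHermite(nodes)
    l <- mu + sqrt(2 * Vrand_total) * gh$x
    w <- gh$w / sqrt(pi)
    p_bar <- sum(w * stats::pnorm(l))
    psi <- sum(w * stats::dnorm(l))
  }
  if (p_bar <= .Machine$double.eps || p_bar >= 1 - 1e-12)
    stop("phenotype is numerically fixed (p_bar is 0 or 1); ",
         "observed-scale heritability undefined")
  structure(list(
    h2_latent = Va / (Vrand_total + 1),
    h2_observed = psi^2 * Va / (p_bar * (1 - p_bar)),
    p_bar = p_bar,
    psi = psi
  ), class = "scale_result")
}

#' @export
print.scale_result <- function(x, digits = 4, ...) {
  cat("Latent -> observed scale conversion (probit)\n")
  cat("  p_bar       :", format(round(x$p_bar, digits)), "\n")
  cat("  Psi         :", format(round(x$psi, digits)), "\n")
  cat("  h2 latent   :", format(round(x$h2_latent, digits)), "\n")
  cat("  h2 observed :", format(round(x$h2_observed, digits)), "\n")
  invisible(x)
}

#' Category probabilities of the 2-dimensional latent categorical model
#'
#' Baseline-category multinomial probit with two latent contrasts and
#' identity residual covariance: with utilities `w1 = eta1 + e1`,
#' `w2 = eta2 + e2`, `e ~ N(0, I)`, the observed category is the argmax of
#' `(0, w1, w2)`.  Probabilities are computed by 1-D quadrature of
#' `P(cat j) = int_0^inf dnorm(t - eta_j) * pnorm(t - eta_other) dt`.
#'
#' @param eta1,eta2 Linear predictors of the two non-baseline categories.
#'   Vectorized (recycled to common length).
#' @return Matrix with columns `p0` (baseline), `p1`, `p2`, rows summing
#'   to 1.
#' @export
categorical_probs <- function(eta1, eta2) {
  n <- max(length(eta1), length(eta2))
  eta1 <- rep_len(eta1, n); eta2 <- rep_len(eta2, n)
  gl <- pracma::gaussLegendre(64, 0, 1)
  tail_int <- function(ea, eb) {
    # int_0^inf dnorm(t - ea) pnorm(t - eb) dt, mapped to (0,1) via t = u/(1-u)
    t <- gl$x / (1 - gl$x)
    jac <- 1 / (1 - gl$x)^2
    vapply(seq_len(n), function(i) {
      sum(gl$w * jac * stats::dnorm(t - ea[i]) * stats::pnorm(t - eb[i]))
    }, numeric(1))
  }
  p1 <- tail_int(eta1, eta2)
  p2 <- tail_int(eta2, eta1)
  p0 <- stats::pnorm(-eta1) * stats::pnorm(-eta2)
  cbind(p0 = p0, p1 = p1, p2 = p2)
}

#' Observed-scale heritability per category of a categorical trait
#'
#' Monte-Carlo integration over the two latent dimensions of the
#' baseline-category probit model.  For each category `c`, the expected
#' frequency `p_bar_c = E[q_c(eta)]`, the average derivatives
#' `Psi_cj = E[d q_c / d eta_j]`, and
#' `h2_obs_c = sum_j Psi_cj^2 * Va_j / (p_bar_c (1 - p_bar_c))`, treating
#' the two latent dimensions as independent.
#'
#' @param mu Length-2 vector of latent intercepts (category 1 and 2 vs the
#'   baseline).
#' @param Va Length-2 vector of additive variances per latent dimension.
#' @param Vrand_total Length-2 vector of total random variance per latent
#'   dimension (each at least the matching `Va`).
#' @param n_mc Number of Monte-Carlo draws of the linear predictors.
#' @param eps Step for the central finite difference in `eta`.
#' @return Data frame with rows baseline/cat1/cat2: `p_bar`, `h2_observed`.
#'   Categories with `Va = 0` on both dimensions get `h2_observed = 0`.
#' @export
categorical_observed_scale <- function(mu, Va, Vrand_total,
                                       n_mc = 4000, eps = 1e-3) {
  stopifnot(length(mu) == 2L, length(Va) == 2L, length(Vrand_total) == 2L)
  if (any(Va < 0) || any(Vrand_total < Va))
    stop("need Vrand_total >= Va >= 0 on both latent dimensions")
  e1 <- mu[1] + sqrt(Vrand_total[1]) * stats::rnorm(n_mc)
  e2 <- mu[2] + sqrt(Vrand_total[2]) * stats::rnorm(n_mc)
  p <- categorical_probs(e1, e2)
  p_bar <- colMeans(p)
  # average derivative of each category probability wrt each latent dim
  d1 <- (categorical_probs(e1 + eps, e2) - categorical_probs(e1 - eps, e2)) /
    (2 * eps)
  d2 <- (categorical_probs(e1, e2 + eps) - categorical_probs(e1, e2 - eps)) /
    (2 * eps)
  psi1 <- colMeans(d1)
  psi2 <- colMeans(d2)
  v_obs <- p_bar * (1 - p_bar)
  h2 <- (psi1^2 * Va[1] + psi2^2 * Va[2]) / v_obs
  h2[v_obs <= .Machine$double.eps] <- NA_real_
  data.frame(category = c("baseline", "cat1", "cat2"),
             p_bar = p_bar, h2_observed = h2,
             row.names = NULL, stringsAsFactors = FALSE)
}
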