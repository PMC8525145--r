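#' Bayesian liability animal model by Gibbs sampling
#'
#' Fits a generalized linear mixed "animal" model in which an individual's
#' additive genetic value is a random effect with covariance proportional
#' to a relationship matrix A, by single-site conjugate Gibbs sampling.
#' Three response families are supported:
#'
#' * `"gaussian"` — identity link; the residual variance is sampled.
#' * `"binary"` — probit threshold model fitted by data augmentation: each
#'   sweep draws the latent liability from the truncated normal consistent
#'   with the 0/1 observation; the residual (link) variance is fixed at 1
#'   for identification.
#' * `"categorical"` — baseline-category multinomial probit with two
#'   latent dimensions (category utilities `w_j = eta_j + e_j`,
#'   `e ~ N(0, I)`, observed category = argmax of `(0, w_1, w_2)`); each
#'   latent dimension carries its own fixed and random effects and
#'   variance components, residual variance fixed at 1.
#'
#' Fixed effects get independent `N(0, prior_fixed_var)` priors (default 1
#' for Gaussian, 1000 for threshold/categorical); variance components get
#' weakly informative priors (see `variance_prior`).  Mixing of the
#' variance components relies on an ancillarity-sufficiency interweaving
#' (ASIS) rescaling move applied to every random term each sweep.
#' Posterior `pMCMC` for fixed effects is twice the smaller tail
#' proportion, floored at `1/n_draws`.
#'
#' @param formula Model formula, e.g. `y ~ salinity`.  The response is the
#'   phenotype column in `data`; for `"binary"` it must be 0/1 (or
#'   logical), for `"categorical"` a factor/character with up to 3 levels
#'   (first level, after ordering `P < L < M` when those levels are used,
#'   is the baseline).
#' @param data Data frame, one row per observation unit (egg mass for the
#'   Gaussian clutch-level model, individual for the binary model).  Rows
#'   with missing response are dropped with a message.
#' @param A Relationship matrix over individuals (from
#'   [relationship_matrix()]), with dimnames; when supplied, an additive
#'   genetic ("animal") random term keyed by `data[[id_col]]` is included.
#' @param random RHS-only formula of further random terms over columns of
#'   `data`, interactions allowed, e.g. `~ id + family + dish +
#'   family:site`.  `NULL` for none.
#' @param response Response family.
#' @param id_col Column linking rows to the rows of `A` (default `"id"`).
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning.  The
#'   defaults (603000 / 10000 / 10) follow standard practice for these
#'   models; scale them down for exploratory fits.
#' @param prior_fixed_var Fixed-effect prior variance; `NULL` picks 1
#'   (gaussian) or 1000 (binary/categorical).
#' @param variance_prior Prior family for the variance components:
#'   `"half_normal"` (default) places a half-normal(`hc_scale`) prior on
#'   each random-effect standard deviation, `"half_cauchy"` a
#'   half-Cauchy(`hc_scale`), and `"inverse_gamma"` the classical
#'   IG(`ig_shape`, `ig_rate`) prior on the variance.  With a single
#'   binary record per individual the additive variance of a threshold
#'   model is only weakly identified, and heavy-tailed priors
#'   (half-Cauchy, and especially near-improper inverse-gamma) leave
#'   substantial posterior mass at scientifically absurd variances; the
#'   proper half-normal on the unit liability scale is therefore the
#'   default, with the others available for sensitivity analysis.
#' @param hc_scale Scale of the half-normal / half-Cauchy prior on each
#'   sd; `NULL` picks 1 for threshold/categorical models (unit liability
#'   scale) and `sd(y)` for Gaussian responses.
#' @param ig_shape,ig_rate Inverse-gamma prior parameters when
#'   `variance_prior = "inverse_gamma"`.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return Object of class `"animal_model"` with elements `draws` (matrix
#'   of retained draws, named columns), `deviance` (per-draw deviance),
#'   `eta_mean` (posterior mean linear predictor per observation and
#'   latent dimension), `response`, `terms` (random-term names), `y`,
#'   `ess`, and the chain settings.  Variance columns are named `Va`
#'   (animal), `V<term>`, and `Vr` (residual/link); for the categorical
#'   model columns carry suffixes `.1`/`.2` for the two latent dimensions.
#' @seealso [summary.animal_model()], [dic()], [heritability()],
#'   [model_diagnostics()]
#' @export
animal_model <- function(formula, data, A = NULL, random = NULL,
                         response = c("gaussian", "binary", "categorical"),
                         id_col = "id",
                         n_iter = 603000L, burn_in = 10000L, thin = 10L,
                         prior_fixed_var = NULL,
                         variance_prior = c("half_normal", "half_cauchy", "inverse_gamma"),
                         hc_scale = NULL,
                         ig_shape = 0.001, ig_rate = 0.001,
                         seed = NULL) {
  response <- match.arg(response)
  variance_prior <- match.arg(variance_prior)
  stopifnot(n_iter > burn_in, thin >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(prior_fixed_var))
    prior_fixed_var <- if (response == "gaussian") 1 else 1000

  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y_raw <- stats::model.response(mf)
  keep <- !is.na(y_raw)
  if (!all(keep)) {
    message("[animal_model] dropping ", sum(!keep),
            " rows with missing response")
    data <- data[keep, , drop = FALSE]
    mf <- mf[keep, , drop = FALSE]
    y_raw <- y_raw[keep]
  }
  n <- length(y_raw)

  cat_levels <- NULL
  if (response == "gaussian") {
    y <- as.numeric(y_raw)
  } else if (response == "binary") {
    y <- as.numeric(y_raw)
    if (!all(y %in% c(0, 1))) stop("binary response must be 0/1")
    if (all(y == 0) || all(y == 1))
      stop("binary response is constant: intercept unidentified")
  } else {
    f <- as.character(y_raw)
    lev <- unique(f)
    pref <- c("P", "L", "M")
    cat_levels <- c(intersect(pref, lev), sort(setdiff(lev, pref)))
    if (length(cat_levels) < 2L)
      stop("categorical response needs at least 2 observed categories")
    if (length(cat_levels) > 3L)
      stop("categorical response supports at most 3 categories")
    if (length(cat_levels) == 2L) {
      warning("only 2 categories observed: third contrast dropped, ",
              "model reduces to a binary probit on ", cat_levels[2L],
              " vs ", cat_levels[1L])
      y <- as.numeric(f == cat_levels[2L])
      fit <- animal_model(stats::update(formula, .bin_y ~ .),
                          data = transform(data, .bin_y = y),
                          A = A, random = random, response = "binary",
                          id_col = id_col, n_iter = n_iter,
                          burn_in = burn_in, thin = thin,
                          prior_fixed_var = prior_fixed_var,
                          variance_prior = variance_prior,
                          hc_scale = hc_scale,
                          ig_shape = ig_shape, ig_rate = ig_rate)
      fit$cat_levels <- cat_levels
      return(fit)
    }
    y <- as.numeric(factor(f, levels = cat_levels)) - 1  # 0 = baseline
  }

  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           data)
  fixed_names <- colnames(X)

  z_index <- list(); z_nlev <- integer(); term_names <- character()
  anim_index <- integer(0)
  G <- matrix(0, 0, 0)
  c_split <- 0
  has_animal <- !is.null(A)
  if (has_animal) {
    if (!id_col %in% names(data))
      stop("column '", id_col, "' needed to link data to A")
    ids <- as.character(data[[id_col]])
    if (!all(ids %in% rownames(A)))
      stop("some individuals are missing from the relationship matrix")
    used <- unique(ids)
    Ause <- unclass(A)[used, used, drop = FALSE]
    eig <- eigen(Ause, symmetric = TRUE)
    if (min(eig$values) < -1e-8)
      stop("relationship matrix is not positive semi-definite")
    # split off the isotropic remainder c*I: it is marginalized into the
    # residual, leaving the structured part for the sampler (see the
    # sampler notes); essential for mixing with one record per individual
    c_split <- max(0, min(eig$values))
    lam <- pmax(eig$values - c_split, 0)
    keep_ev <- lam > 1e-9 * max(lam, 1e-12)
    G <- eig$vectors[, keep_ev, drop = FALSE] %*%
      diag(sqrt(lam[keep_ev]), sum(keep_ev))
    anim_index <- match(ids, used) - 1L
  }
  if (!is.null(random)) {
    labs <- attr(stats::terms(random), "term.labels")
    for (lab in labs) {
      vars <- strsplit(lab, ":", fixed = TRUE)[[1]]
      if (!all(vars %in% names(data)))
        stop("random term '", lab, "' refers to columns absent from data")
      fac <- interaction(data[vars], drop = TRUE, sep = ":")
      z_index[[length(z_index) + 1L]] <- as.integer(fac) - 1L
      z_nlev[length(z_nlev) + 1L] <- nlevels(fac)
      term_names[length(term_names) + 1L] <- lab
    }
  }

  if (is.null(hc_scale))
    hc_scale <- if (response == "gaussian") max(stats::sd(y), 1e-3) else 1
  gl <- pracma::gaussLegendre(40, 0, 1)
  res_code <- match(response, c("gaussian", "binary", "categorical")) - 1L
  prior_code <- c(half_cauchy = 0L, inverse_gamma = 1L,
                  half_normal = 2L)[[variance_prior]]
  out <- .gibbs_animal(y, res_code, X, z_index, as.integer(z_nlev),
                       as.integer(anim_index), G, c_split,
                       prior_fixed_var, prior_code, ig_shape, ig_rate,
                       hc_scale, as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), gl$x, gl$w)

  vnames <- c(if (has_animal) "Va",
              if (length(term_names)) paste0("V", gsub(":", "_", term_names)),
              "Vr")
  par_names <- c(fixed_names, vnames)
  if (response == "categorical")
    par_names <- c(paste0(par_names, ".1"), paste0(par_names, ".2"))
  colnames(out$draws) <- par_names

  fit <- list(draws = out$draws, deviance = out$deviance,
              eta_mean = out$eta_mean,
              response = response, fixed_names = fixed_names,
              term_names = term_names, has_animal = has_animal,
              y = y, n = n, cat_levels = cat_levels,
              n_iter = n_iter, burn_in = burn_in, thin = thin,
              prior_fixed_var = prior_fixed_var,
              ig_shape = ig_shape, ig_rate = ig_rate,
              formula = formula, random = random,
              call = match.call())
  fit$ess <- apply(fit$draws, 2L, ess)
  class(fit) <- "animal_model"
  low <- fit$ess < 1000
  if (any(low))
    warning("effective sample size below 1000 for: ",
            paste(names(fit$ess)[low], collapse = ", "))
  fit
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Liability animal model (", x$response, " response)\n", sep = "")
  cat("  observations:", x$n, "  retained draws:", nrow(x$draws), "\n")
  cat("  chain:", x$n_iter, "iterations, burn-in", x$burn_in,
      ", thin", x$thin, "\n")
  cat("  posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Posterior summary of an animal model
#'
#' @param object An `"animal_model"` fit.
#' @param prob Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Object of class `"summary.animal_model"`: data frame with
#'   posterior mean, median, credible bounds, ESS, and `pMCMC` (fixed
#'   effects only; twice the smaller tail proportion, floored at
#'   1/n_draws).
#' @export
summary.animal_model <- function(object, prob = 0.95, ...) {
  d <- object$draws
  a <- (1 - prob) / 2
  nd <- nrow(d)
  is_fixed <- colnames(d) %in% object$fixed_names |
    sub("\\.[12]$", "", colnames(d)) %in% object$fixed_names
  pmcmc <- vapply(seq_len(ncol(d)), function(j) {
    if (!is_fixed[j]) return(NA_real_)
    max(2 * min(mean(d[, j] > 0), mean(d[, j] < 0)), 1 / nd)
  }, numeric(1))
  out <- data.frame(
    mean = colMeans(d),
    median = apply(d, 2, stats::median),
    lower = apply(d, 2, stats::quantile, probs = a),
    upper = apply(d, 2, stats::quantile, probs = 1 - a),
    ess = object$ess,
    pMCMC = pmcmc
  )
  structure(list(table = out, prob = prob, response = object$response,
                 dic = dic(object)),
            class = "summary.animal_model")
}

#' @export
print.summary.animal_model <- function(x, digits = 4, ...) {
  cat("Posterior summary (", x$response, " response), ",
      100 * x$prob, "% credible intervals\n", sep = "")
  print(round(x$table, digits))
  cat("DIC:", format(x$dic, digits = 8), "\n")
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) {
  d <- object$draws
  want <- colnames(d) %in% object$fixed_names |
    sub("\\.[12]$", "", colnames(d)) %in% object$fixed_names
  colMeans(d[, want, drop = FALSE])
}

#' @export
plot.animal_model <- function(x, pars = colnames(x$draws), ...) {
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in pars) {
    v <- x$draws[, p]
    graphics::plot(v, type = "l", ylab = p, xlab = "", ...)
    graphics::plot(stats::density(v), main = "", xlab = "", ylab = "")
  }
  invisible(x)
}

#' Fitted response-scale predictions
#'
#' Posterior-mean linear predictors mapped to the response scale:
#' identity (gaussian), `pnorm` (binary), or the three category
#' probabilities via [categorical_probs()].
#'
#' @param object An `"animal_model"` fit.
#' @param ... Unused.
#' @return Numeric vector, or a matrix of category probabilities.
#' @export
predict.animal_model <- function(object, ...) {
  eta <- object$eta_mean
  switch(object$response,
         gaussian = eta[, 1L],
         binary = stats::pnorm(eta[, 1L]),
         categorical = {
           p <- categorical_probs(eta[, 1L], eta[, 2L])
           colnames(p) <- object$cat_levels
           p
         })
}

#' Deviance information criterion of an animal model
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - Dhat`, where `Dhat` is the deviance at the posterior means
#' (posterior-mean linear predictors and, for the Gaussian model, the
#' posterior-mean residual variance).
#'
#' @param object An `"animal_model"` fit.
#' @return Scalar DIC.
#' @export
dic <- function(object) {
  stopifnot(inherits(object, "animal_model"))
  dbar <- mean(object$deviance)
  eta <- object$eta_mean
  y <- object$y
  dhat <- switch(object$response,
    gaussian = {
      ve <- mean(object$draws[, "Vr"])
      -2 * sum(stats::dnorm(y, eta[, 1L], sqrt(ve), log = TRUE))
    },
    binary = {
      pr <- pmin(pmax(stats::pnorm(eta[, 1L]), 1e-12), 1 - 1e-12)
      -2 * sum(ifelse(y > 0.5, log(pr), log(1 - pr)))
    },
    categorical = {
      p <- categorical_probs(eta[, 1L], eta[, 2L])
      pr <- p[cbind(seq_along(y), y + 1L)]
      -2 * sum(log(pmin(pmax(pr, 1e-12), 1 - 1e-12)))
    })
  2 * dbar - dhat
}

#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence: the
#' integrated autocorrelation time sums consecutive lag pairs of the
#' empirical autocorrelation while their sums stay positive, and
#' `ESS = n / (1 + 2 * sum(rho))`.  Constant chains get ESS 0.
#'
#' @param x Numeric vector of draws (>= 100 recommended).
#' @return Scalar ESS (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(0)
  rho <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  npair <- floor(length(rho) / 2)
  noise <- 2 / sqrt(n)   # pair sums below sampling noise end the sequence
  s <- 0
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= noise) break
    s <- s + g
  }
  min(n / (1 + 2 * s), n)
}

#' Convergence diagnostics of an animal model
#'
#' Per-parameter effective sample sizes with a flag for parameters below
#' the conventional ESS threshold of 1000, plus trace summaries (means of
#' the first and second half of each chain, as a crude drift check).
#'
#' @param object An `"animal_model"` fit.
#' @param ess_threshold Flagging threshold, default 1000.
#' @return Data frame with `ess`, `flag`, `mean_first_half`,
#'   `mean_second_half`.
#' @export
model_diagnostics <- function(object, ess_threshold = 1000) {
  d <- object$draws
  half <- floor(nrow(d) / 2)
  data.frame(
    ess = object$ess,
    flag = object$ess < ess_threshold,
    mean_first_half = colMeans(d[seq_len(half), , drop = FALSE]),
    mean_second_half = colMeans(d[(half + 1):nrow(d), , drop = FALSE])
  )
}

#' Heritability from a fitted animal model
#'
#' Computes heritability on the latent and (for binary fits) observed
#' scale from the posterior draws.  `method = "per_draw"` applies the
#' conversion to every retained draw and averages (the recommended
#' convention); `"point"` plugs the posterior means in once.
#'
#' Gaussian fits return `Va / (Va + sum(other V) + Vr)` (no link
#' variance).  Binary fits return the latent-scale ratio
#' `Va / (sum(all V) + 1)` and the observed-scale conversion of
#' [binary_observed_scale()], with `mu` the intercept draw and
#' `Vrand_total` the sum of all random components.
#'
#' @param object An `"animal_model"` fit with an animal term.
#' @param method `"per_draw"` or `"point"`.
#' @return List with `h2_latent` (and for binary `h2_observed`, `p_bar`);
#'   for gaussian fits `h2` only.  Each entry carries the posterior mean
#'   and 95% interval when `method = "per_draw"`.
#' @export
heritability <- function(object, method = c("per_draw", "point")) {
  stopifnot(inherits(object, "animal_model"))
  method <- match.arg(method)
  if (!object$has_animal) stop("model has no additive genetic term")
  d <- object$draws
  if (object$response == "categorical")
    stop("use categorical_observed_scale() on the per-dimension draws ",
         "for categorical fits")
  vcols <- grep("^V", colnames(d), value = TRUE)
  other <- setdiff(vcols, c("Va", "Vr"))
  summarize <- function(v) c(mean = mean(v),
                             lower = unname(stats::quantile(v, 0.025)),
                             upper = unname(stats::quantile(v, 0.975)))
  if (object$response == "gaussian") {
    h2 <- d[, "Va"] / rowSums(d[, vcols, drop = FALSE])
    if (method == "point")
      h2 <- mean(d[, "Va"]) / sum(colMeans(d[, vcols, drop = FALSE]))
    return(list(h2 = if (method == "per_draw") summarize(h2) else h2,
                scale = "observed (identity link)"))
  }
  vr_total <- rowSums(d[, setdiff(vcols, "Vr"), drop = FALSE])
  h2_lat <- d[, "Va"] / (vr_total + 1)
  mu <- d[, "(Intercept)"]
  if (method == "point") {
    res <- binary_observed_scale(mean(mu), mean(d[, "Va"]), mean(vr_total))
    return(list(h2_latent = mean(d[, "Va"]) / (mean(vr_total) + 1),
                h2_observed = res$h2_observed, p_bar = res$p_bar))
  }
  conv <- vapply(seq_len(nrow(d)), function(i) {
    res <- tryCatch(binary_observed_scale(mu[i], d[i, "Va"], vr_total[i]),
                    error = function(e) list(h2_observed = NA_real_,
                                             p_bar = NA_real_))
    c(res$h2_observed, res$p_bar)
  }, numeric(2))
  list(h2_latent = summarize(h2_lat),
       h2_observed = summarize(conv[1L, ][!is.na(conv[1L, ])]),
       p_bar = summarize(conv[2L, ][!is.na(conv[2L, ])]))
}
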