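# chain settings for test-scale fits
TI <- 8000L; TB <- 2000L; TT <- 5L

test_that("gaussian sampler matches the exact no-random-effect posterior", {
  set.seed(9)
  n <- 80
  x <- rnorm(n)
  y <- 0.5 + 0.9 * x + rnorm(n, 0, 0.8)
  dat <- data.frame(x = x, y = y)
  fit <- suppressWarnings(animal_model(y ~ x, dat, response = "gaussian",
                                       n_iter = 40000, burn_in = 4000,
                                       thin = 4))
  # oracle: numeric integration over sigma2 of the conditional normal
  # posterior for beta under the same N(0, 1) prior and IG(0.001, 0.001)
  X <- cbind(1, x); vb <- 1
  lgrid <- seq(log(0.1), log(3), length.out = 300)
  lp <- vapply(lgrid, function(lt) {
    s2 <- exp(lt)
    V <- s2 * diag(n) + vb * tcrossprod(X)
    as.numeric(-0.5 * determinant(V)$modulus - 0.5 * crossprod(y, solve(V, y))
               - 0.001 * lt - 0.001 / s2)
  }, numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  bgrid <- vapply(lgrid, function(lt) {
    s2 <- exp(lt)
    as.numeric(solve(crossprod(X) / s2 + diag(2) / vb,
                     crossprod(X, y) / s2))
  }, numeric(2))
  exact_beta <- as.numeric(bgrid %*% w)
  exact_s2 <- sum(w * exp(lgrid))
  expect_equal(unname(coef(fit)), exact_beta, tolerance = 0.02)
  expect_equal(mean(fit$draws[, "Vr"]), exact_s2, tolerance = 0.02)
})

test_that("gaussian animal model recovers heritability over replicate fits", {
  set.seed(7)
  nf <- 100; npf <- 6
  ped <- make_family_pedigree(nf, npf)
  A <- relationship_matrix(ped, assumption = "full_sib_outcrossed")
  reps <- 20
  res <- replicate(reps, {
    a <- rnorm(nf, 0, sqrt(0.5 * 0.4))[rep(1:nf, each = npf)] +
      rnorm(nf * npf, 0, sqrt(0.5 * 0.4))
    y <- 1 + a + rnorm(nf * npf, 0, sqrt(0.6))
    dat <- data.frame(id = ped$id, y = y)
    fit <- suppressWarnings(animal_model(y ~ 1, dat, A = A,
                                         response = "gaussian",
                                         n_iter = TI, burn_in = TB,
                                         thin = TT))
    h2 <- fit$draws[, "Va"] / (fit$draws[, "Va"] + fit$draws[, "Vr"])
    c(mean(h2), quantile(h2, c(0.025, 0.975)))
  })
  expect_equal(mean(res[1, ]), 0.4, tolerance = 0.1)
  expect_gte(mean(res[2, ] <= 0.4 & res[3, ] >= 0.4), 0.9)
})

test_that("gaussian fit with zero additive truth concentrates Va near zero", {
  set.seed(15)
  ped <- make_family_pedigree(60, 12)
  A <- relationship_matrix(ped, assumption = "full_sib_outcrossed")
  y <- rnorm(720, 5, 1)
  fit <- suppressWarnings(animal_model(y ~ 1, data.frame(id = ped$id, y = y),
                                       A = A, response = "gaussian",
                                       n_iter = TI, burn_in = TB, thin = TT))
  vp <- mean(fit$draws[, "Va"] + fit$draws[, "Vr"])
  expect_lt(median(fit$draws[, "Va"]), 0.05 * vp)
})

test_that("a deterministic salinity effect is detected by the threshold model", {
  set.seed(21)
  n <- 200
  sal <- rep(c("low16", "high32"), each = n / 2)
  y <- as.numeric(sal == "high32")
  y[sample(which(y == 1), 4)] <- 0  # avoid complete separation
  y[sample(which(y == 0), 4)] <- 1
  dat <- data.frame(salinity = sal, y = y)
  fit <- suppressWarnings(animal_model(y ~ salinity, dat, response = "binary",
                                       n_iter = TI, burn_in = TB, thin = TT))
  s <- summary(fit)$table
  expect_lt(s["salinitylow16", "pMCMC"], 0.01)
  expect_true(s["salinitylow16", "upper"] < 0)
})

test_that("relabelling the binary response negates location, keeps variances", {
  set.seed(22)
  dat <- sim_binary_halfsib(12, 20, Va = 0.8, Vdish = 0, mu = -0.4,
                            beta = 0.5)
  ped <- make_family_pedigree(12, 20)
  A <- relationship_matrix(ped, assumption = "half_sib")
  f1 <- suppressWarnings(animal_model(y ~ salinity, dat, A = A,
                                      response = "binary", n_iter = TI,
                                      burn_in = TB, thin = TT, seed = 5))
  dat$y <- 1 - dat$y
  f2 <- suppressWarnings(animal_model(y ~ salinity, dat, A = A,
                                      response = "binary", n_iter = TI,
                                      burn_in = TB, thin = TT, seed = 5))
  m1 <- colMeans(f1$draws); m2 <- colMeans(f2$draws)
  expect_equal(m1["(Intercept)"], -m2["(Intercept)"], tolerance = 0.15)
  expect_equal(m1["salinitylow16"], -m2["salinitylow16"], tolerance = 0.15)
  expect_equal(m1["Va"], m2["Va"], tolerance = 0.3 * m1["Va"] + 0.05)
  expect_error(animal_model(y ~ 1, data.frame(y = rep(1, 20)),
                            response = "binary"), "constant")
})

test_that("prior predictive of the threshold model is the attenuated probit", {
  # P(y = 1) = pnorm(mu / sqrt(1 + total latent variance))
  set.seed(30)
  mu <- 0.7; Va <- 0.9; Vfam <- 0.3
  n <- 2e5
  eta <- mu + rnorm(n, 0, sqrt(Va)) + rnorm(n, 0, sqrt(Vfam))
  y <- as.numeric(eta + rnorm(n) > 0)
  expect_equal(mean(y), pnorm(mu / sqrt(1 + Va + Vfam)),
               tolerance = 3 / sqrt(n) + 0.003)
})

test_that("categorical model agrees with the binary model on 2-category data", {
  set.seed(31)
  dat <- sim_binary_halfsib(15, 20, Va = 0.9, Vdish = 0, mu = -0.2,
                            beta = 0)
  ped <- make_family_pedigree(15, 20)
  A <- relationship_matrix(ped, assumption = "half_sib")
  dat$mode <- ifelse(dat$y == 1, "L", "P")
  fb <- suppressWarnings(animal_model(y ~ 1, dat, A = A, response = "binary",
                                      n_iter = TI, burn_in = TB, thin = TT,
                                      seed = 6))
  expect_warning(fc <- animal_model(mode ~ 1, dat, A = A,
                                    response = "categorical",
                                    n_iter = TI, burn_in = TB, thin = TT,
                                    seed = 6),
                 "2 categories")
  h_b <- mean(fb$draws[, "Va"] / (fb$draws[, "Va"] + 1))
  h_c <- mean(fc$draws[, "Va"] / (fc$draws[, "Va"] + 1))
  expect_equal(h_b, h_c, tolerance = 0.1)
})

test_that("categorical model recovers symmetric and rare-category frequencies", {
  set.seed(32)
  # exactly balanced categories: fitted probabilities must be ~ 1/3 each
  mode <- sample(rep(c("P", "L", "M"), each = 300))
  fit <- suppressWarnings(animal_model(mode ~ 1, data.frame(mode = mode),
                                       response = "categorical",
                                       n_iter = TI, burn_in = TB, thin = TT))
  p <- predict(fit)
  expect_equal(unname(colMeans(p)), rep(1 / 3, 3), tolerance = 0.03)

  # rare third category (~5%)
  set.seed(33)
  w1 <- 0.3 + rnorm(1000); w2 <- -1.55 + rnorm(1000)
  mode <- ifelse(w1 > pmax(0, w2), "L", ifelse(w2 > pmax(0, w1), "M", "P"))
  fit2 <- suppressWarnings(animal_model(mode ~ 1, data.frame(mode = mode),
                                        response = "categorical",
                                        n_iter = TI, burn_in = TB,
                                        thin = TT))
  p2 <- predict(fit2)
  expect_equal(mean(p2[, "M"]), mean(mode == "M"), tolerance = 0.03)
})

test_that("DIC prefers informative structure and is reproducible", {
  set.seed(41)
  n <- 400
  g <- factor(rep(1:20, each = 20))
  y <- 2 + rnorm(20, 0, 1.5)[g] + rnorm(n, 0, 0.7)
  dat <- data.frame(g = g, y = y)
  fit_g <- suppressWarnings(animal_model(y ~ 1, dat, random = ~ g,
                                         response = "gaussian", n_iter = TI,
                                         burn_in = TB, thin = TT, seed = 2))
  fit_0 <- suppressWarnings(animal_model(y ~ 1, dat, response = "gaussian",
                                         n_iter = TI, burn_in = TB,
                                         thin = TT, seed = 2))
  expect_lt(dic(fit_g), dic(fit_0) - 50)
  refit <- suppressWarnings(animal_model(y ~ 1, dat, random = ~ g,
                                         response = "gaussian", n_iter = TI,
                                         burn_in = TB, thin = TT, seed = 3))
  expect_lt(abs(dic(fit_g) - dic(refit)), 10)
})

test_that("adding an uninformative nested term barely changes DIC", {
  set.seed(43)
  deltas <- replicate(3, {
    n <- 300
    fam <- factor(rep(1:15, each = 20))
    site <- factor(rep(c("A", "B", "C"), each = 100))
    y <- 1 + rnorm(15, 0, 0.8)[fam] + rnorm(n, 0, 1)
    dat <- data.frame(fam = fam, site = site, y = y)
    f_flat <- suppressWarnings(animal_model(y ~ 1, dat, random = ~ fam,
                                            response = "gaussian",
                                            n_iter = TI, burn_in = TB,
                                            thin = TT))
    f_nest <- suppressWarnings(animal_model(y ~ 1, dat,
                                            random = ~ fam + fam:site,
                                            response = "gaussian",
                                            n_iter = TI, burn_in = TB,
                                            thin = TT))
    dic(f_nest) - dic(f_flat)
  })
  expect_gte(sum(abs(deltas) < 5), 2)
})

test_that("effective sample size behaves like the AR(1) closed form", {
  set.seed(50)
  x <- rnorm(5000)
  expect_equal(ess(x), 5000, tolerance = 0.1 * 5000)
  n <- 20000; rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(ess(ar), n * (1 - rho) / (1 + rho), tolerance = 0.25 * 1053)
  expect_equal(ess(rep(2, 500)), 0)
})

test_that("diagnostics flag low-ESS parameters and report drift summaries", {
  set.seed(51)
  dat <- data.frame(y = rnorm(60, 1, 1))
  fit <- suppressWarnings(animal_model(y ~ 1, dat, response = "gaussian",
                                       n_iter = 3000, burn_in = 500,
                                       thin = 1))
  dg <- model_diagnostics(fit)
  expect_true(all(c("ess", "flag", "mean_first_half", "mean_second_half")
                  %in% names(dg)))
  expect_identical(dg$flag, unname(fit$ess < 1000))
})

test_that("structural errors are caught before sampling", {
  dat <- data.frame(id = c("a", "b"), y = c(0, 1))
  A_bad <- matrix(c(1, 2, 2, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(animal_model(y ~ 1, dat, A = A_bad, response = "binary"),
               "positive semi-definite")
  A_ok <- diag(2); dimnames(A_ok) <- list(c("x", "z"), c("x", "z"))
  expect_error(animal_model(y ~ 1, dat, A = A_ok, response = "binary"),
               "missing from the relationship matrix")
  expect_error(animal_model(y ~ 1, dat, random = ~ nope,
                            response = "binary"), "absent from data")
})
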