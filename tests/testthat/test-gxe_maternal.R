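make_norm_data <- function(fam_counts) {
  # fam_counts: list(family = c(nL_low, n_low, nL_high, n_high))
  ped <- list(); em <- list()
  for (f in names(fam_counts)) {
    cc <- fam_counts[[f]]
    n_low <- cc[2]; n_high <- cc[4]
    ids <- paste0(f, "_", seq_len(n_low + n_high))
    ped[[f]] <- data.frame(
      id = ids, dam = NA_character_, sire = NA_character_, selfed = FALSE,
      family = f, site = "synthetic", dish = "D",
      salinity = rep(c("low16", "high32"), c(n_low, n_high)),
      generation = "P", survived = TRUE, stringsAsFactors = FALSE)
    modes <- c(rep(c("L", "P"), c(cc[1], n_low - cc[1])),
               rep(c("L", "P"), c(cc[3], n_high - cc[3])))
    em[[f]] <- data.frame(eggmass_id = paste0(f, "_em", seq_along(ids)),
                          individual_id = ids, order_index = 1L,
                          mode = modes, stringsAsFactors = FALSE)
  }
  list(pedigree = do.call(rbind, ped), eggmasses = do.call(rbind, em))
}

test_that("reaction norms are direct per-family counts", {
  d <- make_norm_data(list(F1 = c(4, 10, 6, 10), F2 = c(0, 8, 0, 12)))
  norms <- family_reaction_norms(d, min_n = 10)
  f1 <- norms[norms$family == "F1", ]
  expect_equal(f1$prop_L_low, 0.4)
  expect_equal(f1$prop_L_high, 0.6)
  expect_equal(f1$slope, 0.2)
  f2 <- norms[norms$family == "F2", ]
  expect_equal(c(f2$prop_L_low, f2$prop_L_high), c(0, 0))
  expect_true(f2$small_sample)   # n_low = 8 < 10
  expect_false(f1$small_sample)
})

test_that("families absent from one environment are dropped with a warning", {
  d <- make_norm_data(list(F1 = c(2, 6, 3, 6)))
  extra <- data.frame(id = "solo", dam = NA_character_, sire = NA_character_,
                      selfed = FALSE, family = "F9", site = "synthetic",
                      dish = "D", salinity = "low16", generation = "P",
                      survived = TRUE, stringsAsFactors = FALSE)
  d$pedigree <- rbind(d$pedigree, extra)
  d$eggmasses <- rbind(d$eggmasses,
                       data.frame(eggmass_id = "solo_em", individual_id = "solo",
                                  order_index = 1L, mode = "L",
                                  stringsAsFactors = FALSE))
  expect_warning(norms <- family_reaction_norms(d), "F9")
  expect_false("F9" %in% norms$family)
})

test_that("simulated salinity effect produces positive mean reaction-norm slope", {
  p <- sim_params(n_families = 150, n_per_family_per_env = 10, seed = 61)
  d <- simulate_base_population(p)
  norms <- suppressWarnings(family_reaction_norms(d))
  expect_gt(mean(norms$slope), 0)
  bt <- binom.test(sum(norms$slope > 0), nrow(norms), 0.5, "greater")
  expect_lt(bt$p.value, 0.01)
  # conservation: proportions recompute from raw counts
  em <- d$eggmasses; ped <- d$pedigree
  i <- match(em$individual_id, ped$id)
  f1 <- norms$family[1]
  sel <- ped$family[i] == f1 & ped$salinity[i] == "low16"
  expect_equal(norms$prop_L_low[1], mean(em$mode[sel] == "L"))
})

test_that("cross-environment regression handles exact and degenerate inputs", {
  norms <- data.frame(family = paste0("F", 1:5), site = "s",
                      n_low = 20, n_high = 20,
                      prop_L_low = c(0.1, 0.3, 0.5, 0.2, 0.4),
                      prop_L_high = c(0.1, 0.3, 0.5, 0.2, 0.4))
  fit <- cross_env_correlation(norms)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$pearson_r, 1)
  norms$prop_L_high <- 0.3
  expect_error(cross_env_correlation(norms), "zero variance")
  expect_error(cross_env_correlation(norms[1:2, ]), "3 families")
})

test_that("cross-environment slope estimates the generative family regression", {
  set.seed(62)
  # null: independent family effects across environments -> slope ~ 0
  slopes0 <- replicate(40, {
    norms <- data.frame(prop_L_low = runif(17, 0.05, 0.6),
                        prop_L_high = runif(17, 0.05, 0.6))
    coef(lm(prop_L_low ~ prop_L_high, norms))[2]
  })
  expect_lt(abs(mean(slopes0)), 3 * sd(slopes0) / sqrt(40))
  # correlated truth at many families: slope is unbiased for the
  # generative regression coefficient
  b_true <- 0.63
  slopes1 <- replicate(40, {
    g <- rnorm(200, 0, 0.1)
    high <- 0.45 + g
    low <- 0.2 + b_true * g + rnorm(200, 0, 0.02)
    norms <- data.frame(family = paste0("F", 1:200), site = "s",
                        n_low = 20, n_high = 20,
                        prop_L_low = low, prop_L_high = high)
    cross_env_correlation(norms)$slope
  })
  expect_lt(abs(mean(slopes1) - b_true), 0.03)
})

test_that("maternal-effect model coefficients are cell means on a balanced design", {
  cells <- expand.grid(generation = c("P", "S1"),
                       rearing_env = c("low16", "high32"),
                       rep = 1:4, stringsAsFactors = FALSE)
  mu <- c(P.low16 = 0.2, S1.low16 = 0.3, P.high32 = 0.35, S1.high32 = 0.6)
  key <- paste(cells$generation, cells$rearing_env, sep = ".")
  set.seed(63)
  cells$prop_L <- mu[key] + rnorm(nrow(cells), 0, 1e-9)
  fit <- maternal_effect_model(cells)
  cf <- coef(fit$fit)
  # generation main effects are the cell means of the baseline rearing level
  base_env <- levels(factor(cells$rearing_env))[1]
  expect_equal(unname(cf["generationP"]), unname(mu[paste0("P.", base_env)]),
               tolerance = 1e-6)
  expect_equal(unname(cf["generationS1"]),
               unname(mu[paste0("S1.", base_env)]), tolerance = 1e-6)
  expect_equal(unname(fitted(fit$fit)), unname(mu[key]), tolerance = 1e-6)
  # duplicating rows keeps estimates, shrinks standard errors
  set.seed(64)
  cells$prop_L <- mu[key] + rnorm(nrow(cells), 0, 0.05)
  f1 <- maternal_effect_model(cells)
  f2 <- maternal_effect_model(rbind(cells, cells))
  expect_equal(f2$coefficients[, 1], f1$coefficients[, 1], tolerance = 1e-9)
  expect_true(all(f2$coefficients[, 2] < f1$coefficients[, 2]))
})

test_that("maternal-effect null term has uniform p-values across replicates", {
  set.seed(65)
  pvals <- replicate(120, {
    cells <- expand.grid(generation = c("P", "S1"),
                         rearing_env = c("low16", "high32"),
                         rep = 1:5, stringsAsFactors = FALSE)
    cells$prop_L <- 0.3 + 0.2 * (cells$rearing_env == "high32") +
      rnorm(nrow(cells), 0, 0.08)  # no generation (maternal) effect
    fit <- maternal_effect_model(cells)
    s <- fit$coefficients
    # contrast P vs S1 within the no-intercept parameterization
    est <- s["generationP", 1] - s["generationS1", 1]
    se <- sqrt(s["generationP", 2]^2 + s["generationS1", 2]^2)
    2 * pt(-abs(est / se), df = fit$df[2])
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("survival regressions behave at the documented edges", {
  fams <- data.frame(family = rep(paste0("F", 1:6), 2),
                     salinity = rep(c("low16", "high32"), each = 6),
                     survival = rep(c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 2),
                     prop_L = NA_real_)
  fams$prop_L <- fams$survival * 0.5 + 0.1  # collinear
  res <- survival_proportion_regression(fams)
  expect_equal(res$r2, c(1, 1), tolerance = 1e-9)
  set.seed(66)
  fams$prop_L <- runif(12, 0.1, 0.5)        # independent
  res2 <- survival_proportion_regression(fams)
  expect_true(all(res2$r2 >= 0 & res2$r2 <= 1))
  fams$survival <- 0.7
  expect_error(survival_proportion_regression(fams), "zero variance")
})
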