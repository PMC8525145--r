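test_that("parameter validation catches impossible settings", {
  expect_error(sim_params(Va = -1), "variances")
  expect_error(sim_params(Ve = 0), "variances")
  expect_error(sim_params(p_mixed = 1.2), "probabilities")
  expect_error(sim_params(capsule_mode_L = 140), "150")
  p <- sim_params()
  expect_equal(total_liability_variance(p), with(p, Va + Vm + Vdish + Vid + Ve))
})

test_that("degenerate liability parameters force deterministic modes", {
  p <- sim_params(n_families = 3, n_per_family_per_env = 5,
                  mu_liability = 10, beta_salinity = 0,
                  Va = 0, Vm = 0, Vdish = 0, Vid = 0, Ve = 1e-6,
                  p_mixed = 0, seed = 4)
  d <- simulate_base_population(p)
  expect_true(all(d$eggmasses$mode == "L"))
  p2 <- sim_params(n_families = 40, n_per_family_per_env = 15,
                   mu_liability = 0, beta_salinity = 0,
                   Va = 0, Vm = 0, Vdish = 0, Vid = 0, Ve = 1,
                   p_mixed = 0, survival_low = 1, survival_high = 1, seed = 4)
  d2 <- simulate_base_population(p2)
  lec <- mean(d2$eggmasses$mode == "L")
  expect_equal(lec, 0.5, tolerance = 3 / sqrt(nrow(d2$eggmasses)))
})

test_that("marginal proportion above threshold follows the probit of the scaled mean", {
  p <- sim_params(n_families = 250, n_per_family_per_env = 10,
                  p_mixed = 0, seed = 9)
  d <- simulate_base_population(p)
  ped <- d$pedigree; em <- d$eggmasses
  env <- ped$salinity[match(em$individual_id, ped$id)]
  sdT <- sqrt(total_liability_variance(p))
  for (e in c("low16", "high32")) {
    expected <- pnorm((p$mu_liability +
                         p$beta_salinity * (e == "high32")) / sdT)
    got <- mean(em$mode[env == e] == "L")
    expect_lt(abs(got - expected), 0.015)
  }
})

test_that("a fixed seed makes simulation output byte-identical", {
  p <- sim_params(n_families = 3, n_per_family_per_env = 4,
                  n_generations = 2, seed = 33)
  d1 <- simulate_selection_experiment(p)
  d2 <- simulate_selection_experiment(p)
  f1 <- tempfile(); f2 <- tempfile()
  write_phenotypes(d1, f1); write_phenotypes(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("selection raises the proportion lecithotrophic only when Va > 0", {
  base <- list(n_families = 8, n_per_family_per_env = 6,
               n_generations = 2, n_offspring_per_parent = 8,
               n_parents_per_line = 10, mu_liability = -0.6,
               beta_salinity = 0.3)
  delta <- function(Va, seed) {
    p <- do.call(sim_params, c(base, list(Va = Va, seed = seed)))
    d <- simulate_selection_experiment(p)
    q <- suppressMessages(generation_proportions(d, "high32"))
    if (length(q) < 2) return(NA_real_)
    unname(q[2] - q[1])
  }
  d_va <- vapply(1:50, function(s) delta(1.3, s), numeric(1))
  d_0 <- vapply(51:100, function(s) delta(0, s - 50), numeric(1))
  d_va <- d_va[!is.na(d_va)]; d_0 <- d_0[!is.na(d_0)]
  # sign test: with heritable variation the response is positive
  bt <- binom.test(sum(d_va > 0), length(d_va), 0.5, "greater")
  expect_lt(bt$p.value, 1e-4)
  # without it the expected change is zero
  expect_lt(abs(mean(d_0)), 3 * sd(d_0) / sqrt(length(d_0)))
})

test_that("selfed offspring track parents, inbreeding and Mendelian variance", {
  p <- sim_params(n_families = 6, n_per_family_per_env = 10,
                  n_generations = 3, n_offspring_per_parent = 10,
                  seed = 12)
  d <- simulate_selection_experiment(p)
  ped <- d$pedigree; tr <- d$truth$individuals
  s1 <- ped$generation == "S1"
  expect_true(all(ped$selfed[s1]))
  expect_true(all(ped$dam[s1] == ped$sire[s1]))
  # parents of S1 are exactly lecithotrophic layers of P
  em <- d$eggmasses
  lec_layers <- unique(em$individual_id[em$mode == "L"])
  expect_true(all(ped$dam[s1] %in% lec_layers))
  # inbreeding: F = 0.5 in S1, 0.75 in S2
  expect_equal(unique(tr$Fcoef[match(ped$id[s1], tr$id)]), 0.5)
  s2 <- ped$generation == "S2"
  if (any(s2))
    expect_equal(unique(tr$Fcoef[match(ped$id[s2], tr$id)]), 0.75)
  # Mendelian deviations have variance ~ Va/2 for non-inbred parents
  dev <- tr$a[match(ped$id[s1], tr$id)] -
    tr$a[match(ped$dam[s1], tr$id)]
  expect_equal(var(dev), 0.5 * p$Va, tolerance = 0.25 * p$Va)
})

test_that("a line with no lecithotrophic layers terminates with a message", {
  p <- sim_params(n_families = 4, n_per_family_per_env = 4,
                  mu_liability = -30, beta_salinity = 0, Va = 0.1,
                  Vm = 0, Vdish = 0, Vid = 0, p_mixed = 0,
                  n_generations = 2, seed = 5)
  expect_message(d <- simulate_selection_experiment(p), "terminated")
  expect_true(all(d$pedigree$generation == "P"))
})

test_that("egg-mass records and phenotypes are structurally consistent", {
  p <- sim_params(n_families = 5, n_per_family_per_env = 6, seed = 21)
  d <- simulate_base_population(p)
  expect_true(all(unlist(d$eggmasses$capsule_diams_um) > 0))
  n_caps <- lengths(d$eggmasses$capsule_diams_um)
  expect_true(all(n_caps[d$eggmasses$mode != "M"] ==
                    p$n_capsules_per_clutch))
  expect_true(all(n_caps[d$eggmasses$mode == "M"] ==
                    2 * p$n_capsules_per_clutch))
  # conservation: phenotype table counts match raw egg-mass counts
  cnt <- table(d$eggmasses$individual_id)
  ph <- d$phenotypes
  expect_equal(ph$n_eggmasses[match(names(cnt), ph$id)],
               as.integer(cnt))
  expect_true(all(ph$n_eggmasses[!ph$id %in% names(cnt)] == 0))
  # non-survivors laid nothing
  dead <- d$pedigree$id[!d$pedigree$survived]
  expect_false(any(d$eggmasses$individual_id %in% dead))
})
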