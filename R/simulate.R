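#' Parameters of the split-brood liability simulator
#'
#' Collects, with field-realistic defaults, everything the forward
#' simulator needs: the liability model (intercept, salinity shift,
#' variance components), the clutch phenotype model (bimodal capsule
#' diameters, mixed-clutch rate, egg diameters), the design (families,
#' individuals per family per salinity, clutches per individual), survival,
#' and the selection scheme (generations, offspring per selfing parent).
#'
#' Defaults emulate a 17-family split-brood experiment: capsule modes at
#' 113 and 182 um with within-mode SD 9.7 um, eggs 68 +/- 4 um
#' (planktotrophic) and 105 +/- 5 um (lecithotrophic), survival to laying
#' 0.63 in low and 0.81 in high salinity, and liability parameters chosen
#' so the marginal proportions of lecithotrophic egg masses are about
#' 17.6% (16 ppt) and 25.7% (32 ppt); see the methods vignette for the
#' derivation.  The residual liability variance defaults to 1 so simulated
#' truth lives on the same scale the probit sampler assumes.
#'
#' @param n_families Number of maternal families.
#' @param n_per_family_per_env Individuals per family in each salinity.
#' @param mu_liability Liability intercept (low-salinity mean).
#' @param beta_salinity Liability shift of high (32 ppt) vs low (16 ppt).
#' @param Va,Vm,Vdish,Vid,Ve Variance components: additive genetic,
#'   maternal/family, culture dish, permanent environment (individual),
#'   and clutch-level residual.
#' @param p_mixed Probability a clutch is mixed (contains both egg
#'   classes) irrespective of its liability.
#' @param capsule_mode_P,capsule_mode_L Capsule-diameter modes (um).
#' @param capsule_within_sd Within-mode capsule SD (um).
#' @param egg_mean_L,egg_sd_L,egg_mean_P,egg_sd_P Egg-diameter moments (um).
#' @param survival_low,survival_high Probability of surviving to lay.
#' @param n_eggmasses_mean Mean clutches per surviving individual
#'   (1 + Poisson(n_eggmasses_mean - 1)).
#' @param n_capsules_per_clutch Capsules measured per single-mode clutch
#'   (mixed clutches measure this many of each class).
#' @param n_generations Total generations including the parental one.
#' @param n_offspring_per_parent Offspring reared per selected selfing
#'   parent in the selection experiment.
#' @param n_parents_per_line Rearing capacity: at most this many selected
#'   parents contribute offspring per salinity line per generation (a
#'   random subset of the lecithotrophic layers when more are available).
#' @param assumption Within-clutch relatedness of the founding families:
#'   `"half_sib"` (default), `"full_sib_outcrossed"`, `"full_sib_selfed"`
#'   or `"heterogeneous"`.
#' @param het_props Mixture proportions for `"heterogeneous"`.
#' @param switch_rate Optional environment-dependent Markov flip
#'   probability, length 2 (low, high): after each clutch the individual's
#'   liability offset sign is flipped with this probability, adding
#'   explicit egg-mass-type lability beyond residual noise. `c(0, 0)`
#'   disables it.
#' @param seed Integer seed used by the simulate functions.
#' @return Object of class `"sim_params"`.
#' @export
sim_params <- function(n_families = 17L,
                       n_per_family_per_env = 15L,
                       mu_liability = -1.533,
                       beta_salinity = 0.497,
                       Va = 1.3, Vm = 0.2, Vdish = 0.1, Vid = 0.4, Ve = 1,
                       p_mixed = 0.065,
                       capsule_mode_P = 113, capsule_mode_L = 182,
                       capsule_within_sd = 9.7,
                       egg_mean_L = 105, egg_sd_L = 5,
                       egg_mean_P = 68, egg_sd_P = 4,
                       survival_low = 0.63, survival_high = 0.81,
                       n_eggmasses_mean = 4.5,
                       n_capsules_per_clutch = 3L,
                       n_generations = 3L,
                       n_offspring_per_parent = 12L,
                       n_parents_per_line = 12L,
                       assumption = c("half_sib", "full_sib_outcrossed",
                                      "full_sib_selfed", "heterogeneous"),
                       het_props = c(1, 1, 1) / 3,
                       switch_rate = c(0, 0),
                       seed = 1L) {
  assumption <- match.arg(assumption)
  p <- list(n_families = as.integer(n_families),
            n_per_family_per_env = as.integer(n_per_family_per_env),
            mu_liability = mu_liability, beta_salinity = beta_salinity,
            Va = Va, Vm = Vm, Vdish = Vdish, Vid = Vid, Ve = Ve,
            p_mixed = p_mixed,
            capsule_mode_P = capsule_mode_P, capsule_mode_L = capsule_mode_L,
            capsule_within_sd = capsule_within_sd,
            egg_mean_L = egg_mean_L, egg_sd_L = egg_sd_L,
            egg_mean_P = egg_mean_P, egg_sd_P = egg_sd_P,
            survival_low = survival_low, survival_high = survival_high,
            n_eggmasses_mean = n_eggmasses_mean,
            n_capsules_per_clutch = as.integer(n_capsules_per_clutch),
            n_generations = as.integer(n_generations),
            n_offspring_per_parent = as.integer(n_offspring_per_parent),
            n_parents_per_line = as.integer(n_parents_per_line),
            assumption = assumption, het_props = het_props,
            switch_rate = switch_rate, seed = as.integer(seed))
  with(p, {
    if (any(c(Va, Vm, Vdish, Vid) < 0) || Ve <= 0)
      stop("variances must be non-negative (Ve strictly positive)")
    probs <- c(p_mixed, survival_low, survival_high, switch_rate)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (!(capsule_mode_L > 150 && capsule_mode_P < 150))
      stop("capsule modes must straddle the 150 um threshold")
  })
  class(p) <- "sim_params"
  p
}

#' Total latent liability variance of a parameter set
#' @param params A [sim_params()] object.
#' @return `Va + Vm + Vdish + Vid + Ve`.
#' @export
total_liability_variance <- function(params) {
  with(params, Va + Vm + Vdish + Vid + Ve)
}

# within-family decomposition of breeding values matching the declared
# within-clutch relatedness: cov(sibs) = rel * Va
founder_breeding_values <- function(n, Va, mode) {
  rel <- switch(mode, half_sib = 0.25, full_sib_outcrossed = 0.5,
                full_sib_selfed = 1)
  shared <- stats::rnorm(1, 0, sqrt(rel * Va))
  tot <- if (mode == "full_sib_selfed") 1.5 * Va else Va
  shared + stats::rnorm(n, 0, sqrt(max(tot - rel * Va, 0)))
}

founder_F <- function(mode) if (mode == "full_sib_selfed") 0.5 else 0

#' Simulate the parental split-brood generation
#'
#' Draws one generation of the liability model: for individual `i`,
#' `l_i = mu + beta * high_i + a_i + m_fam(i) + d_dish(i) + id_i`, to which
#' each clutch adds its own residual `e ~ N(0, Ve)`.  Clutches are mixed
#' with probability `p_mixed`; otherwise the clutch is lecithotrophic when
#' its liability is positive.  Capsule diameters are drawn from the
#' corresponding mode (normal truncated at zero); mixed clutches interleave
#' both modes equally.  Survival to laying is Bernoulli by salinity.
#'
#' @param params A [sim_params()] object.
#' @return A `"poecilogony_data"` object (see [read_phenotypes()]) with an
#'   extra element `truth`: per-individual breeding values, inbreeding
#'   coefficients and liability components, plus the generative parameters.
#' @export
simulate_base_population <- function(params) {
  set.seed(params$seed)
  sim <- sim_generation_P(params)
  finish_sim(sim$pedigree, sim$truth, sim$eggmasses, params)
}

sim_generation_P <- function(params) {
  p <- params
  n_env <- p$n_per_family_per_env
  rows <- list(); truth <- list(); k <- 0L
  for (f in seq_len(p$n_families)) {
    fam <- sprintf("F%02d", f)
    fam_mode <- if (p$assumption == "heterogeneous")
      sample(c("half_sib", "full_sib_outcrossed", "full_sib_selfed"), 1L,
             prob = p$het_props) else p$assumption
    n_f <- 2L * n_env
    a <- founder_breeding_values(n_f, p$Va, fam_mode)
    m <- stats::rnorm(1, 0, sqrt(p$Vm))
    env <- rep(c("low16", "high32"), each = n_env)
    for (i in seq_len(n_f)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = sprintf("%s_P_%03d", fam, i), dam = NA_character_,
        sire = NA_character_, selfed = FALSE, family = fam,
        site = "synthetic", dish = "", salinity = env[i], generation = "P",
        survived = NA, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(a = a[i], m = m, Fcoef = founder_F(fam_mode),
                               stringsAsFactors = FALSE)
    }
  }
  ped <- do.call(rbind, rows)
  tr <- do.call(rbind, truth)
  tr$id <- ped$id
  list(pedigree = ped, truth = tr, eggmasses = NULL)
}

# assign dishes (12-well plates) within salinity, draw dish effects,
# survival, clutches; returns completed pedigree/truth/eggmass tables
lay_clutches <- function(ped, tr, params, gen_tag) {
  p <- params
  for (env in unique(ped$salinity)) {
    idx <- which(ped$salinity == env)
    ped$dish[idx] <- sprintf("%s_%s_D%03d", gen_tag, env,
                             ceiling(seq_along(idx) / 12))
  }
  dishes <- unique(ped$dish)
  d_eff <- stats::setNames(stats::rnorm(length(dishes), 0, sqrt(p$Vdish)),
                           dishes)
  tr$d <- unname(d_eff[ped$dish])
  tr$id_eff <- stats::rnorm(nrow(ped), 0, sqrt(p$Vid))
  surv_p <- ifelse(ped$salinity == "high32", p$survival_high, p$survival_low)
  ped$survived <- stats::runif(nrow(ped)) < surv_p
  tr$eta <- p$mu_liability + p$beta_salinity * (ped$salinity == "high32") +
    tr$a + tr$m + tr$d + tr$id_eff

  em <- list(); k <- 0L
  sw_p <- ifelse(ped$salinity == "high32", p$switch_rate[2], p$switch_rate[1])
  for (i in which(ped$survived)) {
    n_cl <- 1L + stats::rpois(1, max(p$n_eggmasses_mean - 1, 0))
    flip <- 1
    for (j in seq_len(n_cl)) {
      l <- tr$eta[i] * flip + stats::rnorm(1, 0, sqrt(p$Ve))
      mixed <- stats::runif(1) < p$p_mixed
      lec <- l > 0
      nc <- p$n_capsules_per_clutch
      caps <- if (mixed) {
        c(rtnorm0(nc, p$capsule_mode_L, p$capsule_within_sd),
          rtnorm0(nc, p$capsule_mode_P, p$capsule_within_sd))
      } else if (lec) rtnorm0(nc, p$capsule_mode_L, p$capsule_within_sd)
        else rtnorm0(nc, p$capsule_mode_P, p$capsule_within_sd)
      big <- caps >= 150
      eggs <- ifelse(big, stats::rnorm(length(caps), p$egg_mean_L, p$egg_sd_L),
                     stats::rnorm(length(caps), p$egg_mean_P, p$egg_sd_P))
      k <- k + 1L
      em[[k]] <- list(eggmass_id = paste0(ped$id[i], "_em", j),
                      individual_id = ped$id[i], order_index = j,
                      caps = caps, eggs = pmax(eggs, 1))
      if (stats::runif(1) < sw_p[i]) flip <- -flip
    }
  }
  eggmasses <- if (k) {
    data.frame(
      eggmass_id = vapply(em, `[[`, character(1), "eggmass_id"),
      individual_id = vapply(em, `[[`, character(1), "individual_id"),
      order_index = vapply(em, `[[`, integer(1), "order_index"),
      stringsAsFactors = FALSE)
  } else data.frame(eggmass_id = character(), individual_id = character(),
                    order_index = integer(), stringsAsFactors = FALSE)
  eggmasses$capsule_diams_um <- I(lapply(em, `[[`, "caps"))
  eggmasses$egg_diams_um <- I(lapply(em, `[[`, "eggs"))
  eggmasses$mode <- vapply(eggmasses$capsule_diams_um,
                           function(v) classify_egg_mass(v)$mode,
                           character(1))
  list(pedigree = ped, truth = tr, eggmasses = eggmasses)
}

rtnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

finish_sim <- function(ped, tr, eggmasses, params) {
  done <- lay_clutches(ped, tr, params, gen_tag = "P")
  out <- list(pedigree = done$pedigree,
              eggmasses = done$eggmasses,
              phenotypes = phenotype_table(done$pedigree, done$eggmasses),
              truth = list(individuals = done$truth, params = params,
                           h2_latent_true = with(params,
                             Va / (Va + Vm + Vdish + Vid + Ve))))
  class(out) <- "poecilogony_data"
  out
}

#' Simulate the full truncation-selection-with-selfing experiment
#'
#' Generation 1 is a [simulate_base_population()] draw.  In each later
#' generation the parents are exactly the lecithotrophic layers of the
#' previous one (individuals that survived and laid at least one
#' lecithotrophic egg mass); each contributes `n_offspring_per_parent`
#' self-fertilized offspring reared in the parent's salinity.  Offspring
#' breeding values follow `a_child = a_parent + mendelian`, with Mendelian
#' sampling variance `0.5 * Va * (1 - F_parent)`; inbreeding accumulates
#' as `F_child = 0.5 * (1 + F_parent)`.  A salinity line with no
#' lecithotrophic layers terminates with a logged message (as happens in
#' practice when a low-salinity line is lost).
#'
#' @param params A [sim_params()] object with `n_generations >= 2`.
#' @return A `"poecilogony_data"` object covering all generations, with
#'   `truth` as in [simulate_base_population()].
#' @export
simulate_selection_experiment <- function(params) {
  p <- params
  if (p$n_generations < 2L) stop("need n_generations >= 2")
  set.seed(p$seed)
  g1 <- sim_generation_P(p)
  cur <- lay_clutches(g1$pedigree, g1$truth, p, gen_tag = "P")
  ped_all <- cur$pedigree; tr_all <- cur$truth; em_all <- cur$eggmasses
  for (g in seq_len(p$n_generations - 1L)) {
    gen_tag <- paste0("S", g)
    lec_ids <- unique(em_all$individual_id[em_all$mode == "L" &
      em_all$individual_id %in% cur$pedigree$id])
    sel <- cur$pedigree[cur$pedigree$id %in% lec_ids, ]
    rows <- list(); truth <- list(); k <- 0L
    for (env in c("low16", "high32")) {
      parents <- sel[sel$salinity == env, , drop = FALSE]
      if (nrow(parents) > p$n_parents_per_line)
        parents <- parents[sample.int(nrow(parents), p$n_parents_per_line), ,
                           drop = FALSE]
      if (nrow(parents) == 0L) {
        if (env %in% cur$pedigree$salinity)
          message("[simulate] ", env, " line terminated at generation ",
                  gen_tag, ": no lecithotrophic layers to select")
        next
      }
      for (pi in seq_len(nrow(parents))) {
        par_id <- parents$id[pi]
        ti <- cur$truth[cur$pedigree$id == par_id, ]
        mend_sd <- sqrt(0.5 * p$Va * (1 - ti$Fcoef))
        for (o in seq_len(p$n_offspring_per_parent)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            id = sprintf("%s_%s_%02d", par_id, gen_tag, o), dam = par_id,
            sire = par_id, selfed = TRUE, family = parents$family[pi],
            site = parents$site[pi], dish = "", salinity = env,
            generation = gen_tag, survived = NA, stringsAsFactors = FALSE)
          truth[[k]] <- data.frame(
            a = ti$a + stats::rnorm(1, 0, mend_sd), m = ti$m,
            Fcoef = 0.5 * (1 + ti$Fcoef), stringsAsFactors = FALSE)
        }
      }
    }
    if (k == 0L) {
      message("[simulate] experiment ended at generation ", gen_tag,
              ": no lineage left")
      break
    }
    ped_g <- do.call(rbind, rows)
    tr_g <- do.call(rbind, truth)
    tr_g$id <- ped_g$id
    cur <- lay_clutches(ped_g, tr_g, p, gen_tag = gen_tag)
    ped_all <- rbind(ped_all, cur$pedigree)
    tr_all <- rbind(tr_all, cur$truth)
    em_all <- rbind(em_all, cur$eggmasses)
  }
  out <- list(pedigree = ped_all, eggmasses = em_all,
              phenotypes = phenotype_table(ped_all, em_all),
              truth = list(individuals = tr_all, params = p,
                           h2_latent_true = with(p,
                             Va / (Va + Vm + Vdish + Vid + Ve))))
  class(out) <- "poecilogony_data"
  out
}

#' Simulate paired egg and capsule diameters
#'
#' Eggs are drawn from the two-mode mixture (planktotrophic and
#' lecithotrophic egg-size distributions) and capsule diameter follows
#' `capsule = alpha + beta * egg + noise`, with the noise variance set so
#' that the population r-squared of the linear relation equals
#' `r2_target`.  `alpha` and `beta` are chosen so the egg modes map onto
#' the capsule modes.
#'
#' @param params A [sim_params()] object.
#' @param n Number of pairs (>= 2).
#' @param r2_target Population coefficient of determination; 1 means
#'   noise-free.
#' @param p_lec Mixture weight of the lecithotrophic egg mode.
#' @param beta Slope; default maps the egg modes onto the capsule modes.
#' @return Data frame with columns `egg_um`, `capsule_um`.
#' @export
simulate_egg_capsule_pairs <- function(params, n, r2_target = 0.85,
                                       p_lec = 0.5, beta = NULL) {
  if (n < 2L) stop("need n >= 2")
  p <- params
  if (is.null(beta))
    beta <- (p$capsule_mode_L - p$capsule_mode_P) /
      (p$egg_mean_L - p$egg_mean_P)
  alpha <- p$capsule_mode_P - beta * p$egg_mean_P
  lec <- stats::runif(n) < p_lec
  egg <- ifelse(lec, stats::rnorm(n, p$egg_mean_L, p$egg_sd_L),
                stats::rnorm(n, p$egg_mean_P, p$egg_sd_P))
  v_egg <- p_lec * (1 - p_lec) * (p$egg_mean_L - p$egg_mean_P)^2 +
    p_lec * p$egg_sd_L^2 + (1 - p_lec) * p$egg_sd_P^2
  noise_var <- if (r2_target >= 1) 0 else if (beta == 0) 1 else
    beta^2 * v_egg * (1 - r2_target) / r2_target
  cap <- alpha + beta * egg + stats::rnorm(n, 0, sqrt(noise_var))
  data.frame(egg_um = egg, capsule_um = pmax(cap, 1))
}
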