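#' Classify one egg mass from its capsule diameters
#'
#' Capsules at least `threshold` micrometres across are scored as the
#' large (lecithotrophic) class.  A clutch whose capsules are all large is
#' lecithotrophic (`"L"`), all small is planktotrophic (`"P"`), and a
#' clutch containing both classes is mixed (`"M"`).  The boundary value
#' (exactly 150 um) is scored large; see the methods vignette for the
#' boundary policy.
#'
#' @param capsule_diams_um Numeric vector of capsule diameters (um),
#'   all positive, at least one value.
#' @param threshold Size boundary between the classes (um), default 150.
#' @return A list of class `"mode_call"`: `mode` (`"L"`, `"P"` or `"M"`),
#'   `n_large`, `n_small`.
#' @export
#' @examples
#' classify_egg_mass(c(182, 180, 185))$mode        # "L"
#' classify_egg_mass(c(182, 113, 185, 110))$mode   # "M"
classify_egg_mass <- function(capsule_diams_um, threshold = 150) {
  if (length(capsule_diams_um) == 0L)
    stop("no capsule diameters supplied")
  if (!is.numeric(capsule_diams_um) || anyNA(capsule_diams_um) ||
      any(capsule_diams_um <= 0))
    stop("capsule diameters must be positive numbers")
  n_large <- sum(capsule_diams_um >= threshold)
  n_small <- length(capsule_diams_um) - n_large
  mode <- if (n_large > 0L && n_small > 0L) "M"
          else if (n_large > 0L) "L" else "P"
  structure(list(mode = mode, n_large = n_large, n_small = n_small),
            class = "mode_call")
}

#' Binary developmental-mode score for an individual
#'
#' An individual is scored lecithotrophic (`1`) when its mean capsule
#' diameter across egg masses is at least 150 um, planktotrophic (`0`)
#' otherwise.  The boundary 150 um is assigned to the lecithotrophic class,
#' consistently with [classify_egg_mass()].
#'
#' @param mean_capsule_um Mean capsule diameter (um), positive. Vectorized.
#' @param threshold Boundary (um), default 150.
#' @return Integer 0/1 vector.
#' @export
classify_individual <- function(mean_capsule_um, threshold = 150) {
  if (any(mean_capsule_um <= 0, na.rm = TRUE))
    stop("mean capsule diameter must be positive")
  as.integer(mean_capsule_um >= threshold)
}

#' Ordinary least squares of capsule diameter on egg diameter
#'
#' Egg diameter can only be measured before cleavage, so capsule diameter
#' serves as the proxy for developmental mode; this regression quantifies
#' how closely capsule size tracks egg size.
#'
#' @param egg_um Egg diameters (um), the predictor.
#' @param capsule_um Capsule diameters (um), the response; same length.
#' @return List with `slope`, `intercept`, `r2`, `p` (slope t-test) and the
#'   underlying `lm` fit.
#' @export
capsule_egg_regression <- function(egg_um, capsule_um) {
  if (length(egg_um) != length(capsule_um))
    stop("egg and capsule vectors must have equal length")
  if (length(egg_um) < 3L) stop("need at least 3 pairs")
  if (stats::var(egg_um) == 0)
    stop("zero variance in egg diameter: regression undefined")
  fit <- stats::lm(capsule_um ~ egg_um)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2L) NA_real_ else sm$coefficients[2L, 4L]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = sm$r.squared, p = p, fit = fit)
}

#' Per-individual lability profiles of egg-mass type
#'
#' Summarizes, for every individual with at least one classified egg mass,
#' which modes it laid over its lifetime and whether it ever switched.
#' Patterns are the seven non-empty subsets of \{L, P, M\}, written
#' `L_only`, `P_only`, `M_only`, `LP`, `PM`, `LM`, `LPM`.
#'
#' @param eggmasses Data frame with columns `individual_id` and `mode`
#'   (values `"L"`, `"P"`, `"M"`), one row per egg mass.
#' @return List with `profiles` (data frame: `individual_id`, `pattern`,
#'   `switched`, `n_eggmasses`) and `pattern_freq` (named numeric vector of
#'   relative frequencies summing to 1).
#' @export
lability_profiles <- function(eggmasses) {
  stopifnot(all(c("individual_id", "mode") %in% names(eggmasses)))
  if (nrow(eggmasses) == 0L) stop("no egg masses supplied")
  if (!all(eggmasses$mode %in% c("L", "P", "M")))
    stop("mode must be one of 'L', 'P', 'M'")
  sets <- split(eggmasses$mode, eggmasses$individual_id)
  pat_of <- function(m) {
    has <- c(L = "L" %in% m, P = "P" %in% m, M = "M" %in% m)
    key <- paste(names(has)[has], collapse = "")
    switch(key, L = "L_only", P = "P_only", M = "M_only",
           LP = "LP", PM = "PM", LM = "LM", LPM = "LPM")
  }
  pattern <- vapply(sets, pat_of, character(1))
  profiles <- data.frame(
    individual_id = names(sets),
    pattern = unname(pattern),
    switched = unname(!pattern %in% c("L_only", "P_only", "M_only")),
    n_eggmasses = unname(lengths(sets)),
    stringsAsFactors = FALSE
  )
  lev <- c("L_only", "P_only", "M_only", "LP", "PM", "LM", "LPM")
  freq <- table(factor(profiles$pattern, levels = lev))
  list(profiles = profiles,
       pattern_freq = c(freq) / nrow(profiles))
}

#' Logistic regression of switching on experimental covariates
#'
#' Fits a binomial GLM (probability of an individual ever switching
#' egg-mass type) on the covariates supplied, by iteratively reweighted
#' least squares via [stats::glm()].  Complete or quasi-complete separation
#' is flagged with a warning (detected from divergent coefficients or
#' fitted probabilities pinned at 0/1), and coefficients are still
#' reported.
#'
#' @param profiles The `profiles` data frame from [lability_profiles()].
#' @param covariates Data frame keyed by `individual_id` with the covariate
#'   columns to use (e.g. `salinity`, `generation`, `site`).
#' @param formula RHS-only formula over covariate columns; default uses all
#'   covariate columns additively.
#' @return List with `coefficients` (estimate, SE, z, p), `aic`,
#'   `separation` (logical) and the `glm` fit.
#' @export
switching_glm <- function(profiles, covariates, formula = NULL) {
  stopifnot("individual_id" %in% names(covariates))
  dat <- merge(profiles[c("individual_id", "switched")], covariates,
               by = "individual_id")
  vars <- setdiff(names(covariates), "individual_id")
  for (v in vars) {
    if (length(unique(dat[[v]])) < 2L)
      stop("covariate '", v, "' has fewer than 2 levels")
  }
  if (is.null(formula))
    formula <- stats::reformulate(vars, response = "switched")
  fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(),
                                     data = dat))
  mu <- stats::fitted(fit)
  sep <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(mu < 1e-8 | mu > 1 - 1e-8)
  if (sep)
    warning("possible complete separation: some coefficients or fitted ",
            "probabilities are at the boundary")
  sm <- summary(fit)
  list(coefficients = sm$coefficients, aic = stats::AIC(fit),
       separation = sep, fit = fit)
}
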