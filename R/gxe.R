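#' Family reaction norms of the proportion lecithotrophic
#'
#' For every maternal family with classified egg masses in both
#' salinities, the proportion of lecithotrophic egg masses (egg-mass
#' level) in each environment; the slope of the reaction norm is the high
#' minus the low proportion.  Families observed in only one environment
#' are dropped with a warning; families with fewer than `min_n` egg masses
#' in either environment are flagged (small families are known to drive
#' spurious negative slopes).
#'
#' @param data A `"poecilogony_data"` object, or a list with `pedigree`
#'   and `eggmasses` in that layout.
#' @param min_n Flagging threshold for per-environment egg-mass counts.
#' @param level `"eggmass"` (default: proportion of lecithotrophic egg
#'   masses) or `"individual"` (proportion of individuals scored
#'   lecithotrophic from their mean capsule diameter).
#' @return Data frame of class `"reaction_norms"`: `family`, `site`,
#'   `n_low`, `n_high`, `prop_L_low`, `prop_L_high`, `slope`,
#'   `small_sample`.
#' @export
family_reaction_norms <- function(data, min_n = 10L,
                                  level = c("eggmass", "individual")) {
  level <- match.arg(level)
  ped <- data$pedigree
  if (level == "eggmass") {
    em <- data$eggmasses
    i <- match(em$individual_id, ped$id)
    units <- data.frame(family = ped$family[i], site = ped$site[i],
                        salinity = ped$salinity[i],
                        lec = em$mode == "L", stringsAsFactors = FALSE)
  } else {
    ph <- data$phenotypes
    i <- match(ph$id, ped$id)
    ok <- !is.na(ph$y)
    units <- data.frame(family = ped$family[i][ok], site = ped$site[i][ok],
                        salinity = ped$salinity[i][ok],
                        lec = ph$y[ok] == 1L, stringsAsFactors = FALSE)
  }
  agg_n <- stats::aggregate(lec ~ family + site + salinity, units, length)
  agg_l <- stats::aggregate(lec ~ family + site + salinity, units, sum)
  wide_n <- stats::reshape(agg_n, idvar = c("family", "site"),
                           timevar = "salinity", direction = "wide")
  wide_l <- stats::reshape(agg_l, idvar = c("family", "site"),
                           timevar = "salinity", direction = "wide")
  wide <- merge(wide_n, wide_l, by = c("family", "site"),
                suffixes = c(".n", ".sum"))
  need <- c("lec.low16.n", "lec.high32.n", "lec.low16.sum", "lec.high32.sum")
  for (col in need) if (!col %in% names(wide)) wide[[col]] <- NA_real_
  both <- !is.na(wide$lec.low16.n) & !is.na(wide$lec.high32.n)
  if (any(!both))
    warning("dropping ", sum(!both), " family(ies) absent from one ",
            "environment: ", paste(wide$family[!both], collapse = ", "))
  wide <- wide[both, , drop = FALSE]
  if (nrow(wide) == 0L)
    stop("no family has classified records in both environments")
  out <- data.frame(
    family = wide$family, site = wide$site,
    n_low = wide$lec.low16.n, n_high = wide$lec.high32.n,
    prop_L_low = wide$lec.low16.sum / wide$lec.low16.n,
    prop_L_high = wide$lec.high32.sum / wide$lec.high32.n,
    stringsAsFactors = FALSE
  )
  out$slope <- out$prop_L_high - out$prop_L_low
  out$small_sample <- out$n_low < min_n | out$n_high < min_n
  out <- out[order(out$family), ]
  rownames(out) <- NULL
  class(out) <- c("reaction_norms", "data.frame")
  out
}

#' Cross-environment genetic correlation from family means
#'
#' Treats the trait expressed in the two salinities as two characters and
#' regresses the family proportion lecithotrophic in low salinity on the
#' proportion in high salinity (least squares), following the family-mean
#' method: the slope predicts the correlated response in low salinity per
#' unit of direct response in high salinity.  The direction-free Pearson
#' correlation is reported alongside.
#'
#' @param norms A [family_reaction_norms()] table (>= 3 families).
#' @return List of class `"cross_env_fit"`: `slope`, `intercept`, `r2`,
#'   `p`, `pearson_r`, `n_families`, and the `lm` fit.
#' @export
cross_env_correlation <- function(norms) {
  if (nrow(norms) < 3L) stop("need at least 3 families")
  if (stats::var(norms$prop_L_high) == 0)
    stop("zero variance in the high-salinity proportions")
  fit <- stats::lm(prop_L_low ~ prop_L_high, data = norms)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r2 = sm$r.squared,
              p = sm$coefficients[2L, 4L],
              pearson_r = stats::cor(norms$prop_L_low, norms$prop_L_high),
              n_families = nrow(norms),
              fit = fit)
  class(out) <- "cross_env_fit"
  out
}

#' @export
print.cross_env_fit <- function(x, digits = 3, ...) {
  cat("Cross-environment family regression (low on high salinity)\n")
  cat("  families:", x$n_families, "\n")
  cat("  slope:", round(x$slope, digits),
      " intercept:", round(x$intercept, digits), "\n")
  cat("  r2:", round(x$r2, digits), " p:", format.pval(x$p), "\n")
  cat("  Pearson r:", round(x$pearson_r, digits), "\n")
  invisible(x)
}

#' Maternal-effect model on per-cell proportions after selection
#'
#' Ordinary least squares of the proportion lecithotrophic on
#' `generation * rearing_environment` without an intercept, so that under
#' a balanced design the coefficients are the cell means and the
#' parental-generation term directly measures the maternal (parental
#' environment) contribution.
#'
#' @param cells Data frame with columns `prop_L`, `generation`,
#'   `rearing_env` (and optionally more covariates, ignored), one row per
#'   family-by-generation-by-rearing-environment cell.
#' @return List with `coefficients` (estimate, SE, t, p), `F`, `df`, `p`,
#'   `r2`, and the `lm` fit.
#' @export
maternal_effect_model <- function(cells) {
  stopifnot(all(c("prop_L", "generation", "rearing_env") %in% names(cells)))
  cells$generation <- factor(cells$generation)
  cells$rearing_env <- factor(cells$rearing_env)
  fit <- stats::lm(prop_L ~ generation * rearing_env - 1, data = cells)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = sm$coefficients,
       F = unname(fstat[1L]),
       df = unname(fstat[2:3]),
       p = stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
       r2 = sm$r.squared,
       fit = fit)
}

#' Per-environment regression of proportion lecithotrophic on survival
#'
#' Tests, separately in each salinity, whether family survival predicts
#' the family proportion of lecithotrophic egg masses (it should not if
#' mortality is nonselective with respect to developmental mode).
#'
#' @param families Data frame with columns `family`, `salinity`
#'   (`low16`/`high32`), `survival` (proportion surviving to lay) and
#'   `prop_L`.
#' @return Data frame with one row per environment: `salinity`, `slope`,
#'   `r2`, `p`, `n`.
#' @export
survival_proportion_regression <- function(families) {
  stopifnot(all(c("salinity", "survival", "prop_L") %in% names(families)))
  res <- lapply(split(families, families$salinity), function(d) {
    if (nrow(d) < 3L) stop("need at least 3 families per environment")
    if (stats::var(d$survival) == 0)
      stop("zero variance in survival for ", d$salinity[1L])
    fit <- stats::lm(prop_L ~ survival, data = d)
    sm <- summary(fit)
    data.frame(salinity = d$salinity[1L],
               slope = unname(stats::coef(fit)[2L]),
               r2 = sm$r.squared,
               p = sm$coefficients[2L, 4L],
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-generation proportions lecithotrophic from simulated or real data
#'
#' Convenience aggregation for the selection-response analysis: the
#' egg-mass-level proportion lecithotrophic per generation within one
#' salinity, in generation order.
#'
#' @param data A `"poecilogony_data"` object.
#' @param salinity `"low16"` or `"high32"`.
#' @param generations Order of generation labels; default sorts `P` first
#'   then `S1, S2, ...`.
#' @return Named numeric vector of proportions (generations with no egg
#'   masses are dropped).
#' @export
generation_proportions <- function(data, salinity,
                                   generations = NULL) {
  ped <- data$pedigree
  em <- data$eggmasses
  i <- match(em$individual_id, ped$id)
  sel <- ped$salinity[i] == salinity
  gen <- ped$generation[i][sel]
  lec <- em$mode[sel] == "L"
  if (is.null(generations)) {
    generations <- unique(ped$generation)
    generations <- generations[order(match(generations, "P"),
                                     generations)]
  }
  props <- vapply(generations, function(g) {
    if (!any(gen == g)) return(NA_real_)
    mean(lec[gen == g])
  }, numeric(1))
  props[!is.na(props)]
}
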