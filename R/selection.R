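#' Mean liability implied by a trait frequency
#'
#' For a threshold trait with unit-variance normal liability and the
#' threshold fixed at zero, the population mean liability `u` is determined
#' by the proportion `q` of individuals above threshold: `u = qnorm(q)`,
#' so that `pnorm(u) = q` (equivalently, `P(liability > 0) = q` for a
#' liability with mean `u` and unit variance).
#'
#' @param q Proportion of individuals expressing the threshold trait
#'   (here, laying lecithotrophic egg masses). Must lie strictly in (0, 1).
#' @return Mean liability in liability standard-deviation units.
#' @seealso [selection_differential_threshold()], [realized_heritability()]
#' @export
#' @examples
#' liability_mean(0.5)   # 0
#' liability_mean(0.19)  # -0.88
liability_mean <- function(q) {
  check_interior_proportion(q)
  stats::qnorm(q)
}

#' Selection differential under truncation selection on a threshold trait
#'
#' When exactly the above-threshold fraction `q` of a unit-variance normal
#' liability distribution is selected to breed, the mean liability of the
#' selected parents exceeds the population mean by
#' `S = dnorm(qnorm(q)) / q` (the mean of the upper tail of a standard
#' normal truncated at its `1 - q` quantile).
#'
#' @inheritParams liability_mean
#' @return Selection differential in liability standard-deviation units.
#' @export
#' @examples
#' selection_differential_threshold(0.10)  # 1.75
#' selection_differential_threshold(0.5)   # dnorm(0)/0.5 = 0.798
selection_differential_threshold <- function(q) {
  check_interior_proportion(q)
  stats::dnorm(stats::qnorm(q)) / q
}

#' Response to selection on the liability scale
#'
#' The between-generation change in mean liability implied by the change in
#' trait frequency: `R = qnorm(q_post) - qnorm(q_pre)`.
#'
#' @param q_pre Trait frequency in the parental generation, before selection.
#' @param q_post Trait frequency in the offspring generation.
#' @return Response in liability standard-deviation units.
#' @export
threshold_response <- function(q_pre, q_post) {
  check_interior_proportion(q_pre)
  check_interior_proportion(q_post)
  stats::qnorm(q_post) - stats::qnorm(q_pre)
}

#' Realized heritability of a threshold trait under truncation selection
#'
#' Applies the probit-transformed breeder's equation to a sequence of trait
#' frequencies observed across consecutive generations of truncation
#' selection in which every above-threshold individual is selected.  For
#' each step the observed frequencies give the liability means
#' `u = qnorm(q)`, the selection differential `S = dnorm(qnorm(q))/q`, the
#' response `R = u_next - u`, and the per-step realized heritability
#' `h2 = R/S`.  The summed realized heritability is `sum(R)/sum(S)` over the
#' available consecutive steps.
#'
#' @param q Numeric vector (length >= 2) of proportions expressing the
#'   trait in consecutive generations, all strictly inside (0, 1).
#' @param generations Optional character vector of generation labels,
#'   length `length(q)`; defaults to `"P", "S1", "S2", ...` reflecting
#'   selfed generations after an outcrossed parental one.
#' @return An object of class `"realized_h2"`: a list with a per-step
#'   data frame `steps` (columns `generation`, `q`, `u`, `S`, `R`, `h2`)
#'   and the scalar `summed_h2`.
#' @export
#' @examples
#' # high-salinity selected line: 19% -> 32% -> 51% lecithotrophic
#' realized_heritability(c(0.19, 0.32, 0.51))
realized_heritability <- function(q, generations = NULL) {
  if (length(q) < 2L)
    stop("need at least two generations of trait frequencies")
  check_interior_proportion(q)
  n <- length(q)
  if (is.null(generations))
    generations <- c("P", paste0("S", seq_len(n - 1L)))
  if (length(generations) != n)
    stop("'generations' must have one label per element of 'q'")
  u <- stats::qnorm(q)
  S <- c(stats::dnorm(stats::qnorm(q[-n])) / q[-n], NA_real_)
  R <- c(diff(u), NA_real_)
  h2 <- R / S
  steps <- data.frame(
    generation = generations, q = q, u = u, S = S, R = R, h2 = h2,
    stringsAsFactors = FALSE
  )
  out <- list(
    steps = steps,
    summed_h2 = sum(R, na.rm = TRUE) / sum(S, na.rm = TRUE),
    trait = "proportion lecithotrophic (liability scale)"
  )
  class(out) <- "realized_h2"
  out
}

#' Realized heritability of a continuous trait from a selection experiment
#'
#' Mean-difference breeder's equation for a continuous trait (egg-capsule
#' diameter).  For each generation with a next generation available,
#' `S = mean_selected - mean_all` and `R = mean_all[next] - mean_all`;
#' per-step `h2 = R/S` and `summed_h2 = sum(R)/sum(S)` over steps where
#' both are defined.  Means are supplied in micrometres; `S` and `R` are
#' reported both in micrometres and in millimetres (the conventional
#' reporting scale for this trait).
#'
#' @param mean_all Per-generation population mean capsule diameter (um).
#'   `NA` marks a generation that was lost (summation then runs over the
#'   available consecutive steps only).
#' @param mean_selected Per-generation mean capsule diameter of the selected
#'   parents (um); last element unused, may be `NA`.
#' @param generations Optional labels as in [realized_heritability()].
#' @return An object of class `"realized_h2"` with per-step columns
#'   `generation`, `mean_um`, `S_um`, `R_um`, `S_mm`, `R_mm`, `h2`.
#'   Steps with `S == 0` get `h2 = NA` with a warning.
#' @export
realized_heritability_continuous <- function(mean_all, mean_selected,
                                             generations = NULL) {
  n <- length(mean_all)
  if (n < 2L) stop("need at least two generations")
  if (length(mean_selected) != n)
    stop("'mean_selected' must align with 'mean_all'")
  if (is.null(generations))
    generations <- c("P", paste0("S", seq_len(n - 1L)))
  S_um <- mean_selected - mean_all
  R_um <- c(mean_all[-1L] - mean_all[-n], NA_real_)
  S_um[n] <- NA_real_
  ok <- !is.na(S_um) & !is.na(R_um)
  if (any(ok & S_um == 0)) {
    warning("selection differential is zero for at least one step; ",
            "h2 undefined there")
  }
  h2 <- ifelse(ok & S_um != 0, R_um / S_um, NA_real_)
  steps <- data.frame(
    generation = generations, mean_um = mean_all,
    S_um = S_um, R_um = R_um,
    S_mm = S_um / 1000, R_mm = R_um / 1000,
    h2 = h2, stringsAsFactors = FALSE
  )
  use <- ok & S_um != 0
  out <- list(
    steps = steps,
    summed_h2 = sum(R_um[use]) / sum(S_um[use]),
    trait = "egg-capsule diameter"
  )
  class(out) <- "realized_h2"
  out
}

#' @export
print.realized_h2 <- function(x, digits = 2, ...) {
  cat("Realized heritability under truncation selection\n")
  cat("Trait:", x$trait, "\n\n")
  steps <- x$steps
  num <- vapply(steps, is.numeric, logical(1))
  steps[num] <- lapply(steps[num], round, digits = digits)
  print(steps, row.names = FALSE)
  cat("\nSummed realized h2 (sum R / sum S):",
      format(round(x$summed_h2, digits)), "\n")
  invisible(x)
}

check_interior_proportion <- function(q) {
  if (!is.numeric(q) || anyNA(q))
    stop("proportions must be numeric and non-missing")
  if (any(q <= 0 | q >= 1))
    stop("proportions must lie strictly in (0, 1): the probit ",
         "transformation is undefined at 0 and 1")
  invisible(q)
}
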