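#' Read a combined phenotype/pedigree CSV
#'
#' Parses the flat interchange format used throughout the package: one row
#' per egg mass, with the layer's identity, family, collection site,
#' culture dish, salinity treatment, generation, pedigree links and the
#' semicolon-joined capsule (and optional egg) diameters in micrometres.
#' Individuals that laid no egg masses appear as rows with empty
#' `capsule_diams`.
#'
#' Required columns: `eggmass_id`, `individual_id`, `family`, `site`,
#' `dish`, `salinity`, `generation`, `dam`, `sire`, `selfed`,
#' `order_index`, `capsule_diams`; optional: `egg_diams`, `survived`.
#' Unknown columns are ignored with a warning.  Individuals must appear
#' after their parents (pedigree order).
#'
#' @param path Path to the CSV file.
#' @return An object of class `"poecilogony_data"`: list with
#'   `pedigree` (id, dam, sire, selfed, family, site, dish, salinity,
#'   generation, survived), `eggmasses` (eggmass_id, individual_id,
#'   order_index, mode, and list-columns `capsule_diams_um`,
#'   `egg_diams_um`), and `phenotypes` (per-individual mean capsule,
#'   binary and categorical mode, number of egg masses) built by
#'   [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("eggmass_id", "individual_id", "family", "site", "dish",
                "salinity", "generation", "dam", "sire", "selfed",
                "order_index", "capsule_diams")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  optional <- c("egg_diams", "survived")
  unknown <- setdiff(names(raw), c(required, optional))
  if (length(unknown)) {
    warning("[io] ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  blank_na <- function(x) { x[x == ""] <- NA_character_; x }
  raw$dam <- blank_na(raw$dam)
  raw$sire <- blank_na(raw$sire)

  ind_rows <- raw[!duplicated(raw$individual_id), ]
  pedigree <- data.frame(
    id = ind_rows$individual_id,
    dam = ind_rows$dam,
    sire = ind_rows$sire,
    selfed = as.logical(ind_rows$selfed),
    family = ind_rows$family,
    site = ind_rows$site,
    dish = ind_rows$dish,
    salinity = ind_rows$salinity,
    generation = ind_rows$generation,
    survived = if (is.null(ind_rows$survived)) NA else
      as.logical(ind_rows$survived),
    stringsAsFactors = FALSE
  )
  validate_pedigree(pedigree)
  if (!all(pedigree$salinity %in% c("low16", "high32")))
    stop("salinity must be 'low16' or 'high32'")

  has_em <- raw$capsule_diams != ""
  em <- raw[has_em, ]
  caps <- lapply(em$capsule_diams, parse_diams, what = "capsule_diams")
  eggs <- if (!is.null(em$egg_diams)) {
    lapply(em$egg_diams, function(s)
      if (is.na(s) || s == "") NULL else parse_diams(s, "egg_diams"))
  } else rep(list(NULL), nrow(em))
  eggmasses <- data.frame(
    eggmass_id = em$eggmass_id,
    individual_id = em$individual_id,
    order_index = as.integer(em$order_index),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(eggmasses$eggmass_id))
    stop("duplicated eggmass_id")
  if (any(is.na(eggmasses$order_index) | eggmasses$order_index < 1L))
    stop("order_index must be an integer >= 1")
  eggmasses$capsule_diams_um <- I(caps)
  eggmasses$egg_diams_um <- I(eggs)
  eggmasses$mode <- vapply(caps, function(v) classify_egg_mass(v)$mode,
                           character(1))
  out <- list(pedigree = pedigree, eggmasses = eggmasses,
              phenotypes = phenotype_table(pedigree, eggmasses))
  class(out) <- "poecilogony_data"
  out
}

parse_diams <- function(s, what) {
  v <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  if (anyNA(v) || any(v <= 0))
    stop("invalid ", what, " entry '", s, "': diameters must be ",
         "positive numbers")
  v
}

#' Per-individual phenotype summary
#'
#' Collapses egg-mass records to the per-individual phenotypes the animal
#' models use: mean capsule diameter across all the individual's measured
#' capsules, the binary developmental-mode score (mean >= 150 um), the
#' modal category of its egg masses (`L`/`P`/`M`, ties broken L > M > P),
#' and the number of egg masses laid.  Individuals without egg masses get
#' `NA` phenotypes and `n_eggmasses = 0`.
#'
#' @param pedigree Individual table as in `read_phenotypes()$pedigree`.
#' @param eggmasses Egg-mass table with `individual_id`, `mode` and
#'   list-column `capsule_diams_um`.
#' @return Data frame keyed by `id`.
#' @export
phenotype_table <- function(pedigree, eggmasses) {
  caps <- split(unlist(eggmasses$capsule_diams_um),
                rep(eggmasses$individual_id,
                    lengths(eggmasses$capsule_diams_um)))
  modes <- split(eggmasses$mode, eggmasses$individual_id)
  mean_cap <- vapply(caps, mean, numeric(1))
  cat_of <- function(m) {
    tab <- table(factor(m, levels = c("L", "M", "P")))
    names(tab)[which.max(tab)]
  }
  ph <- data.frame(
    id = pedigree$id,
    mean_capsule_um = unname(mean_cap[pedigree$id]),
    n_eggmasses = 0L,
    stringsAsFactors = FALSE
  )
  nem <- table(eggmasses$individual_id)
  ph$n_eggmasses <- ifelse(ph$id %in% names(nem),
                           as.integer(nem[ph$id]), 0L)
  ph$y <- ifelse(is.na(ph$mean_capsule_um), NA_integer_,
                 classify_individual(pmax(ph$mean_capsule_um, 1e-9)))
  ph$mode_cat <- NA_character_
  has <- ph$id %in% names(modes)
  ph$mode_cat[has] <- vapply(modes[ph$id[has]], cat_of, character(1))
  extra <- setdiff(unique(eggmasses$individual_id), pedigree$id)
  if (length(extra))
    stop("egg masses reference individuals absent from the pedigree: ",
         paste(utils::head(extra), collapse = ", "))
  ph
}

#' Write phenotype data back to the interchange CSV
#'
#' Inverse of [read_phenotypes()]: emits one row per egg mass plus one row
#' (with empty `capsule_diams`) per individual that laid none.  Column
#' order and number formatting are fixed so that repeated writes of the
#' same data are byte-identical.
#'
#' @param data A `"poecilogony_data"` object (or a list with `pedigree`
#'   and `eggmasses` in the same layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  ped <- data$pedigree
  em <- data$eggmasses
  fmt <- function(v) paste(formatC(v, format = "fg", digits = 10),
                           collapse = ";")
  rows_em <- if (nrow(em)) data.frame(
    eggmass_id = em$eggmass_id,
    individual_id = em$individual_id,
    order_index = em$order_index,
    capsule_diams = vapply(em$capsule_diams_um, fmt, character(1)),
    egg_diams = vapply(em$egg_diams_um, function(v)
      if (is.null(v)) "" else fmt(v), character(1)),
    stringsAsFactors = FALSE
  ) else NULL
  layers <- unique(em$individual_id)
  silent <- setdiff(ped$id, layers)
  if (length(silent)) {
    rows_s <- data.frame(eggmass_id = "", individual_id = silent,
                         order_index = NA_integer_, capsule_diams = "",
                         egg_diams = "", stringsAsFactors = FALSE)
    rows_em <- rbind(rows_em, rows_s)
  }
  if (is.null(rows_em)) {
    rows_em <- data.frame(eggmass_id = character(), individual_id = character(),
                          order_index = integer(), capsule_diams = character(),
                          egg_diams = character(), stringsAsFactors = FALSE)
  }
  i <- match(rows_em$individual_id, ped$id)
  out <- data.frame(
    eggmass_id = rows_em$eggmass_id,
    individual_id = rows_em$individual_id,
    family = ped$family[i], site = ped$site[i], dish = ped$dish[i],
    salinity = ped$salinity[i], generation = ped$generation[i],
    dam = ifelse(is.na(ped$dam[i]), "", ped$dam[i]),
    sire = ifelse(is.na(ped$sire[i]), "", ped$sire[i]),
    selfed = tolower(as.character(ped$selfed[i])),
    survived = tolower(as.character(ped$survived[i])),
    order_index = rows_em$order_index,
    capsule_diams = rows_em$capsule_diams,
    egg_diams = rows_em$egg_diams,
    stringsAsFactors = FALSE
  )
  # stable order: pedigree position, then clutch order
  out <- out[order(match(out$individual_id, ped$id),
                   out$order_index, na.last = TRUE), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a pedigree CSV
#'
#' @param pedigree Pedigree data frame (`id`, `dam`, `sire`, `selfed`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(
    id = pedigree$id,
    dam = ifelse(is.na(pedigree$dam), "", pedigree$dam),
    sire = ifelse(is.na(pedigree$sire), "", pedigree$sire),
    selfed = tolower(as.character(pedigree$selfed)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree CSV
#'
#' @param path Path to a CSV with columns `id`, `dam`, `sire`, `selfed`.
#' @return Validated pedigree data frame.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("id", "dam", "sire", "selfed")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  raw$dam[raw$dam == ""] <- NA_character_
  raw$sire[raw$sire == ""] <- NA_character_
  raw$selfed <- as.logical(raw$selfed)
  validate_pedigree(raw)
}

#' @export
print.poecilogony_data <- function(x, ...) {
  cat("Developmental-mode phenotype data\n")
  cat("  individuals:", nrow(x$pedigree),
      " egg masses:", nrow(x$eggmasses), "\n")
  tab <- table(factor(x$eggmasses$mode, levels = c("L", "P", "M")))
  cat("  egg-mass modes: L =", tab["L"], " P =", tab["P"],
      " M =", tab["M"], "\n")
  cat("  generations:",
      paste(unique(x$pedigree$generation), collapse = ", "), "\n")
  invisible(x)
}
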