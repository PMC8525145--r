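#' Additive relationship matrix from a pedigree
#'
#' Builds the numerator relationship matrix A by the tabular method:
#' individuals are processed in pedigree order (parents before offspring)
#' with
#' `a_xy = 0.5 * (a_x,sire(y) + a_x,dam(y))` for `x` earlier than `y`, and
#' `a_yy = 1 + 0.5 * a_sire(y),dam(y)`, so the diagonal is `1 + F` with `F`
#' the inbreeding coefficient.  Self-fertilization is expressed as
#' `dam == sire` and needs no special casing.
#'
#' Founders (both parents missing) are taken as unrelated and non-inbred
#' unless `assumption` replaces their unknown within-clutch relationships:
#' founders sharing a `family` label are then connected through phantom
#' parents so that full sibs of an outcrossed pair have `a = 0.5`, maternal
#' half sibs `a = 0.25`, and offspring of one selfing non-inbred parent
#' `a = 1` with diagonal 1.5.  `"heterogeneous"` draws one of the three
#' structures independently per clutch (uses the RNG).
#'
#' @param pedigree Data frame with columns `id`, `dam`, `sire` (character;
#'   `NA` for unknown) and optionally `family` (required for non-pedigree
#'   assumptions).  Parents must appear as `id` before their offspring.
#' @param assumption One of `"pedigree"`, `"half_sib"`,
#'   `"full_sib_outcrossed"`, `"full_sib_selfed"`, `"heterogeneous"`.
#' @param het_props Probabilities of (half_sib, full_sib_outcrossed,
#'   full_sib_selfed) for `"heterogeneous"`.
#' @return An object of class `"relationship_matrix"`: the A matrix over
#'   the pedigree ids (phantom parents dropped), with attribute
#'   `assumption`.
#' @export
#' @examples
#' ped <- data.frame(id = c("p", "x", "y"),
#'                   dam = c(NA, "p", "p"), sire = c(NA, "p", "p"))
#' relationship_matrix(ped)["x", "y"]   # 1: full sibs from selfing
relationship_matrix <- function(pedigree,
                                assumption = c("pedigree", "half_sib",
                                               "full_sib_outcrossed",
                                               "full_sib_selfed",
                                               "heterogeneous"),
                                het_props = c(1, 1, 1) / 3) {
  assumption <- match.arg(assumption)
  ped <- validate_pedigree(pedigree)
  keep <- ped$id
  if (assumption != "pedigree") {
    if (is.null(ped$family))
      stop("assumption-based matrices need a 'family' column")
    ped <- add_phantom_parents(ped, assumption, het_props)
  }
  A <- tabular_A(ped)
  A <- A[keep, keep, drop = FALSE]
  structure(A, assumption = assumption, class = c("relationship_matrix",
                                                  "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("Additive relationship matrix (", nrow(x), " individuals, assumption: ",
      attr(x, "assumption"), ")\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# tabular method over a topologically ordered pedigree
tabular_A <- function(ped) {
  n <- nrow(ped)
  id <- ped$id
  pos <- seq_len(n)
  names(pos) <- id
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (y in seq_len(n)) {
    d <- di[y]; s <- si[y]
    if (y > 1L) {
      x <- seq_len(y - 1L)
      axd <- if (d > 0L) A[x, d] else 0
      axs <- if (s > 0L) A[x, s] else 0
      axy <- 0.5 * (axd + axs)
      A[x, y] <- axy
      A[y, x] <- axy
    }
    A[y, y] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
  }
  A
}

validate_pedigree <- function(pedigree) {
  stopifnot(is.data.frame(pedigree),
            all(c("id", "dam", "sire") %in% names(pedigree)))
  ped <- pedigree
  ped$id <- as.character(ped$id)
  ped$dam <- as.character(ped$dam)
  ped$sire <- as.character(ped$sire)
  ped$dam[ped$dam %in% c("", "NA")] <- NA_character_
  ped$sire[ped$sire %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(ped$id))
    stop("duplicated individual ids in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$dam[i], ped$sire[i])) {
      if (!is.na(p) && !(p %in% seen))
        stop("parent '", p, "' of '", ped$id[i],
             "' does not precede it in the pedigree (or is missing); ",
             "pedigrees must be topologically ordered and acyclic")
    }
    seen <- c(seen, ped$id[i])
  }
  if (!is.null(ped$selfed)) {
    bad <- ped$selfed & !is.na(ped$dam) & !is.na(ped$sire) &
      ped$dam != ped$sire
    if (any(bad))
      stop("selfed individuals must have dam == sire: ",
           paste(ped$id[bad], collapse = ", "))
  }
  ped
}

# connect founders of each maternal family through phantom parents so the
# within-clutch additive relationship matches the declared assumption
add_phantom_parents <- function(ped, assumption, het_props) {
  founders <- is.na(ped$dam) & is.na(ped$sire)
  fams <- unique(ped$family[founders])
  head_rows <- list()
  k <- 0L
  for (f in fams) {
    rows <- which(founders & ped$family == f)
    if (length(rows) < 2L) next
    mode <- if (assumption == "heterogeneous") {
      sample(c("half_sib", "full_sib_outcrossed", "full_sib_selfed"), 1L,
             prob = het_props)
    } else assumption
    k <- k + 1L
    dam_id <- paste0(".phantom_dam_", k)
    head_rows[[length(head_rows) + 1L]] <-
      data.frame(id = dam_id, dam = NA_character_, sire = NA_character_,
                 family = f, stringsAsFactors = FALSE)
    if (mode == "half_sib") {
      # shared phantom dam, distinct unknown sires: a = 0.25
      ped$dam[rows] <- dam_id
    } else if (mode == "full_sib_outcrossed") {
      sire_id <- paste0(".phantom_sire_", k)
      head_rows[[length(head_rows) + 1L]] <-
        data.frame(id = sire_id, dam = NA_character_, sire = NA_character_,
                   family = f, stringsAsFactors = FALSE)
      ped$dam[rows] <- dam_id
      ped$sire[rows] <- sire_id
    } else {  # full_sib_selfed: one selfing, non-inbred phantom parent
      ped$dam[rows] <- dam_id
      ped$sire[rows] <- dam_id
    }
  }
  if (length(head_rows)) {
    extra <- do.call(rbind, head_rows)
    common <- intersect(names(ped), names(extra))
    ped <- rbind(extra[common],
                 ped[common])
  }
  ped
}

#' Validate a relationship matrix
#'
#' Checks symmetry, diagonal at least 1 and positive semi-definiteness
#' (smallest eigenvalue >= -1e-8).
#'
#' @param A Matrix (or `"relationship_matrix"`).
#' @return Invisibly `TRUE`; stops otherwise.
#' @export
check_relationship_matrix <- function(A) {
  if (!isSymmetric(unclass(A), tol = 1e-10))
    stop("relationship matrix must be symmetric")
  if (any(diag(A) < 1 - 1e-10))
    stop("relationship matrix diagonal must be at least 1")
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("relationship matrix is not positive semi-definite ",
         "(min eigenvalue ", format(ev), ")")
  invisible(TRUE)
}
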