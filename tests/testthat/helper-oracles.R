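# strip the class/assumption decoration for exact matrix comparison
bare_matrix <- function(A) {
  a <- unclass(A)
  attr(a, "assumption") <- NULL
  a
}

# Independent brute-force oracle for the additive relationship matrix:
# recursive coancestry (kinship) with memoisation; A = 2 * kinship,
# a completely different algorithm from the tabular method in the package.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  dam <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  sire <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (x == 0L || y == 0L) return(0)
    if (x > y) { t <- x; x <- y; y <- t }
    key <- paste(x, y)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      0.5 * (1 + phi(dam[x], sire[x]))
    } else {
      # y is the later individual: recurse through y's parents
      0.5 * (phi(x, dam[y]) + phi(x, sire[y]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# fixture pedigrees (<= 10 individuals) incl. selfing chains
fixture_pedigrees <- function() {
  P <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(id = m[, 1],
               dam = ifelse(m[, 2] == "-", NA, m[, 2]),
               sire = ifelse(m[, 3] == "-", NA, m[, 3]),
               stringsAsFactors = FALSE)
  }
  list(
    founders = P("a", "-", "-", "b", "-", "-", "c", "-", "-"),
    half_sibs = P("d", "-", "-", "s1", "-", "-", "s2", "-", "-",
                  "x", "d", "s1", "y", "d", "s2"),
    full_sibs = P("d", "-", "-", "s", "-", "-", "x", "d", "s", "y", "d", "s"),
    selfing_pair = P("p", "-", "-", "x", "p", "p", "y", "p", "p"),
    selfing_chain = P("p", "-", "-", "s1", "p", "p", "s2", "s1", "s1",
                      "s3", "s2", "s2"),
    mixed = P("a", "-", "-", "b", "-", "-", "c", "a", "b", "d", "a", "b",
              "e", "c", "d", "f", "e", "e", "g", "f", "f"),
    three_gen = P("a", "-", "-", "b", "-", "-", "c", "-", "-",
                  "x", "a", "b", "y", "a", "c", "z", "x", "y",
                  "w", "z", "z", "v", "w", "w"),
    backcross = P("a", "-", "-", "b", "-", "-", "x", "a", "b", "y", "a", "x")
  )
}

# half-sib family pedigree over phenotyped individuals only
make_family_pedigree <- function(n_fam, n_per, prefix = "i") {
  fam <- rep(sprintf("F%03d", seq_len(n_fam)), each = n_per)
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n_fam * n_per)),
             dam = NA_character_, sire = NA_character_, family = fam,
             stringsAsFactors = FALSE)
}

# liability-scale data for sampler recovery tests: half-sib families plus a
# crossed dish effect, unit residual
sim_binary_halfsib <- function(n_fam, n_per, Va, Vdish, mu, beta) {
  n <- n_fam * n_per
  fam_idx <- rep(seq_len(n_fam), each = n_per)
  a <- rnorm(n_fam, 0, sqrt(0.25 * Va))[fam_idx] +
    rnorm(n, 0, sqrt(0.75 * Va))
  n_dish <- ceiling(n / 12)
  dish <- sample(rep(seq_len(n_dish), length.out = n))
  d_eff <- rnorm(n_dish, 0, sqrt(Vdish))[dish]
  sal <- rep(rep(c("low16", "high32"), length.out = n_per), n_fam)
  eta <- mu + beta * (sal == "high32") + a + d_eff
  y <- as.numeric(eta + rnorm(n) > 0)
  data.frame(id = sprintf("i%04d", seq_len(n)),
             family = sprintf("F%03d", fam_idx),
             dish = factor(dish), salinity = sal, y = y,
             stringsAsFactors = FALSE)
}
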