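# Additive relationship machinery and the diversity parameters derived from
# common ancestors: F, AR, individual increases in inbreeding/co-ancestry
# and the two effective population size estimators.

# Tabular (recursive) numerator relationship matrix over all records,
# phantoms included; relationship values are exact dyadic rationals and are
# carried in double precision without rounding.
.amatrix_all <- function(ped) {
  if (isTRUE(attr(ped, "cyclic"))) stop("pedigree contains an ancestry cycle")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (x in seq_len(n)) {
    s <- si[x]; d <- di[x]
    if (x > 1) {
      y <- seq_len(x - 1)
      row <- numeric(x - 1)
      if (!is.na(s)) row <- row + 0.5 * A[s, y]
      if (!is.na(d)) row <- row + 0.5 * A[d, y]
      A[x, y] <- row
      A[y, x] <- row
    }
    A[x, x] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Additive relationship matrix and kinship summary
#'
#' Builds Wright's numerator relationship matrix by the tabular method over
#' the pedigree (internally including phantom founders, which are unrelated
#' to everything), and derives the per-animal inbreeding coefficient
#' `F = a_ii - 1`, average relatedness `AR`, equivalent complete
#' generations `t` and individual increase in inbreeding `dF`.
#'
#' @param ped a `pedigree`.
#' @param ids animals to report (default: all non-phantom animals).
#' @return An object of class `kinship_summary`: list with the symmetric
#'   matrix `A` (restricted to `ids`), and per-animal vectors `F`, `AR`,
#'   `dF`, `t`. Co-ancestry between j and k is `A[j,k]/2`.
#' @export
relationship_matrix <- function(ped, ids = NULL) {
  stopifnot(is_pedigree(ped))
  real <- ped$id[!ped$phantom]
  if (is.null(ids)) ids <- real
  if (!all(ids %in% ped$id)) stop("unknown id(s): ",
                                  paste(setdiff(ids, ped$id), collapse = ", "))
  A <- .amatrix_all(ped)
  Areal <- A[real, real, drop = FALSE]
  Fcoef <- diag(Areal) - 1
  # AR_i: mean relationship of i to the whole (real) pedigree, halved --
  # the probability that a random allele from the population belongs to i.
  AR <- rowSums(Areal) / (2 * length(real))
  t <- equivalent_generations(ped)[real]
  dF <- ifelse(t > 1, 1 - (1 - Fcoef)^(1 / (t - 1)), NA_real_)
  structure(list(A = A[ids, ids, drop = FALSE], F = Fcoef[ids], AR = AR[ids],
                 dF = dF[ids], t = t[ids], ids = ids),
            class = "kinship_summary")
}

#' @export
print.kinship_summary <- function(x, ...) {
  cat(sprintf("Kinship summary for %d animals\n", length(x$ids)))
  cat(sprintf("  mean F  = %.4f   mean AR = %.4f\n", mean(x$F), mean(x$AR)))
  cat(sprintf("  mean dF = %.4f (over %d animals with t > 1)\n",
              mean(x$dF, na.rm = TRUE), sum(!is.na(x$dF))))
  invisible(x)
}

#' Inbreeding coefficients
#'
#' `F_i = a_ii - 1` from the tabular relationship matrix: the probability
#' that the two alleles of an animal are identical by descent. Founders and
#' animals with an unknown parent have `F = 0`.
#'
#' @param ped a `pedigree`.
#' @param ids animals to report (default all non-phantom).
#' @return Named numeric vector.
#' @export
inbreeding <- function(ped, ids = NULL) {
  ks <- relationship_matrix(ped, ids)
  ks$F
}

#' Average relatedness coefficients
#'
#' `AR_i = (1/2n) * sum_j a_ij` over all n animals of the pedigree
#' (including i itself): the probability that an allele picked at random
#' from the whole pedigree belongs to animal i. A long-term inbreeding
#' proxy used to rank candidates for mating plans.
#'
#' @inheritParams inbreeding
#' @return Named numeric vector in `(0, 1]`.
#' @export
average_relatedness <- function(ped, ids = NULL) {
  ks <- relationship_matrix(ped, ids)
  ks$AR
}

#' Individual increase in inbreeding
#'
#' `dF_i = 1 - (1 - F_i)^(1/(t_i - 1))` with `t_i` the equivalent complete
#' generations; undefined (NA, excluded from averages) when `t_i <= 1`.
#'
#' @inheritParams inbreeding
#' @return Named numeric vector with NA where undefined.
#' @export
delta_f_individual <- function(ped, ids = NULL) {
  ks <- relationship_matrix(ped, ids)
  ks$dF
}

#' Generation-mean increase in inbreeding
#'
#' The classical rate form `(F_t - F_{t-1}) / (1 - F_{t-1})` on mean
#' inbreeding per discrete generation, with animals binned by rounded
#' equivalent complete generations (or an explicit generation vector).
#'
#' @param ped a `pedigree`.
#' @param generations optional named integer vector of discrete
#'   generations; default bins by `round(equivalent_generations())`.
#' @return List with the per-generation table (`generation`, `n`,
#'   `mean_F`, `dF`) and `dF_mean`, the mean rate over consecutive
#'   generation pairs.
#' @export
delta_f_generations <- function(ped, generations = NULL) {
  stopifnot(is_pedigree(ped))
  Fc <- inbreeding(ped)
  if (is.null(generations)) {
    generations <- round(equivalent_generations(ped))
  }
  generations <- generations[names(Fc)]
  gens <- sort(unique(generations))
  mF <- vapply(gens, function(g) mean(Fc[generations == g]), 0)
  nn <- vapply(gens, function(g) sum(generations == g), 0L)
  dF <- c(NA_real_, (mF[-1] - mF[-length(mF)]) / (1 - mF[-length(mF)]))
  list(table = data.frame(generation = gens, n = nn, mean_F = mF, dF = dF),
       dF_mean = if (length(gens) > 1) mean(dF[-1]) else NA_real_)
}

#' Effective population size from individual increases in inbreeding
#'
#' `Ne = 1 / (2 * mean(dF_i))` over the animals of the reference set with a
#' defined `dF`; infinite when the mean increase is zero.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all
#'   animals when none are flagged).
#' @return List with `ne` and `n_used`.
#' @export
ne_from_delta_f <- function(ped, ids = NULL) {
  ids <- .default_ref(ped, ids)
  dF <- delta_f_individual(ped, ids)
  dF <- dF[!is.na(dF)]
  if (length(dF) == 0) stop("no animal with a defined increase in inbreeding")
  m <- mean(dF)
  list(ne = if (m <= 0) Inf else 1 / (2 * m), n_used = length(dF))
}

#' Effective population size from increases in co-ancestry
#'
#' For every unordered pair (j, k) of the reference set,
#' `dc_jk = 1 - (1 - c_jk)^(1 / ((g_j + g_k)/2))` with `c_jk` the pair
#' co-ancestry and `g` the discrete equivalent generations; then
#' `Ne = 1 / (2 * mean(dc))`. Pairs with a non-positive mean generation are
#' excluded.
#'
#' @inheritParams ne_from_delta_f
#' @return List with `ne` and `n_used` (number of pairs).
#' @export
ne_from_coancestry <- function(ped, ids = NULL) {
  ids <- .default_ref(ped, ids)
  if (length(ids) < 2) stop("need at least two reference animals")
  ks <- relationship_matrix(ped, ids)
  g <- round(equivalent_generations(ped)[ids])
  n <- length(ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  c_jk <- ks$A[pairs] / 2
  gbar <- (g[pairs[, 1]] + g[pairs[, 2]]) / 2
  use <- gbar > 0
  if (!any(use)) stop("no usable pair (all mean generations are zero)")
  dc <- 1 - (1 - c_jk[use])^(1 / gbar[use])
  m <- mean(dc)
  list(ne = if (m <= 0) Inf else 1 / (2 * m), n_used = sum(use))
}

#' Both effective-size estimators at once
#'
#' @inheritParams ne_from_delta_f
#' @return An `ne_estimates` object: list with `ne_deltaF`,
#'   `ne_coancestry` and `n_used` counts.
#' @export
ne_estimates <- function(ped, ids = NULL) {
  ids <- .default_ref(ped, ids)
  a <- ne_from_delta_f(ped, ids)
  b <- ne_from_coancestry(ped, ids)
  structure(list(ne_deltaF = a$ne, ne_coancestry = b$ne,
                 n_used = c(animals = a$n_used, pairs = b$n_used)),
            class = "ne_estimates")
}

#' @export
print.ne_estimates <- function(x, ...) {
  cat(sprintf("Ne (individual dF): %.2f  [%d animals]\n",
              x$ne_deltaF, x$n_used["animals"]))
  cat(sprintf("Ne (co-ancestry):   %.2f  [%d pairs]\n",
              x$ne_coancestry, x$n_used["pairs"]))
  invisible(x)
}

.default_ref <- function(ped, ids) {
  stopifnot(is_pedigree(ped))
  if (!is.null(ids)) return(ids)
  ids <- reference_ids(ped)
  if (length(ids) == 0) ids <- ped$id[!ped$phantom]
  ids
}

#' Classify animals into inbreeding classes
#'
#' Counts per inbreeding class and sex. The default class edges follow the
#' common studbook convention: non-inbred, mildly inbred (1-13%), and
#' highly inbred (>= 13%).
#'
#' @param f named numeric vector of inbreeding coefficients.
#' @param sex named character vector of sexes aligned with `f` (optional).
#' @param bounds increasing internal class edges in (0, 1); default
#'   `c(0.01, 0.13)` giving classes `[0, 0.01)`, `[0.01, 0.13)`,
#'   `[0.13, 1]`.
#' @return Data frame of counts with one row per class, one column per sex
#'   plus `total`.
#' @export
inbreeding_classes <- function(f, sex = NULL, bounds = c(0.01, 0.13)) {
  if (is.unsorted(bounds, strictly = TRUE) || any(bounds <= 0) || any(bounds >= 1))
    stop("bounds must be strictly increasing and inside (0, 1)")
  edges <- c(0, bounds, 1 + 1e-9)
  labels <- sprintf("[%g, %g)", edges[-length(edges)], edges[-1])
  labels[length(labels)] <- sprintf("[%g, 1]", edges[length(edges) - 1])
  cls <- cut(f, breaks = edges, right = FALSE, labels = labels,
             include.lowest = TRUE)
  if (is.null(sex)) sex <- rep("unknown", length(f))
  tab <- table(class = cls, sex = factor(sex, levels = unique(c(.SEXES, sex))))
  out <- as.data.frame.matrix(tab)
  out <- out[, colSums(out) > 0 | colnames(out) %in% c("male", "female"), drop = FALSE]
  out$total <- as.integer(table(cls))
  cbind(data.frame(class = labels, stringsAsFactors = FALSE), out,
        row.names = NULL)
}
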