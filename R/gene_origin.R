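# Probability-of-gene-origin parameters: founder contributions, effective
# numbers of founders and ancestors, founder genome equivalents and the
# partition of genetic diversity loss. Phantom founders participate exactly
# like real founders (the founder convention: unknown parents = founders).

# Expected genetic contribution of every animal (rows = pedigree order) to
# each founder (columns), by downward gene flow. Rows sum to 1 exactly
# because every non-founder has both parent slots filled (phantoms).
.founder_shares <- function(ped) {
  founders <- founder_ids(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  M <- matrix(0, n, length(founders), dimnames = list(ped$id, founders))
  fi <- match(founders, ped$id)
  M[cbind(fi, seq_along(founders))] <- 1
  for (x in seq_len(n)) {
    if (!is.na(si[x])) M[x, ] <- 0.5 * M[si[x], ] + 0.5 * M[di[x], ]
  }
  M
}

#' Expected founder contributions to a reference population
#'
#' The expected proportion of the reference gene pool deriving from each
#' founder (phantom founders included), computed by gene-flow recursion
#' (a founder contributes 1 to itself and half of its share per meiosis).
#' Contributions sum to 1 exactly.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @return Named numeric vector over founders, summing to 1.
#' @export
founder_contributions <- function(ped, ids = NULL) {
  ids <- .default_ref(ped, ids)
  if (!all(ids %in% ped$id)) stop("unknown id(s)")
  M <- .founder_shares(ped)
  q <- colMeans(M[ids, , drop = FALSE])
  q
}

#' Effective number of founders
#'
#' `fe = 1 / sum(q_k^2)`: the number of equally contributing founders that
#' would yield the observed founder-contribution diversity. Equals the
#' founder count exactly when contributions are balanced.
#'
#' @param q founder contribution vector summing to 1.
#' @return `fe`, a positive number `<=` the number of founders.
#' @export
effective_founders <- function(q) {
  if (length(q) == 0) stop("empty contribution vector")
  if (abs(sum(q) - 1) > 1e-6) stop("contributions must sum to 1")
  1 / sum(q^2)
}

#' Effective number of ancestors
#'
#' Greedy iterative selection of the ancestors (founders or not) with the
#' largest marginal contribution to the reference gene pool. At each round
#' the marginal contribution of a candidate is its gene-flow contribution
#' computed with all previously selected ancestors acting as founders
#' (their parent links masked, so genes passing through them are credited
#' to them), times the fraction of the candidate's own genome not already
#' explained by selected ancestors. `fa = 1 / sum(p_j^2)` over the marginal
#' contributions; `n50` is the smallest number of ancestors explaining half
#' of the gene pool. Sensitive to bottlenecks: all of the reference
#' descending from one couple gives `fa = 2` regardless of deeper founders.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @param tol stop when the largest remaining marginal contribution falls
#'   below this residual (default 1e-9).
#' @return List with `fa`, `marginal` (named, in selection order) and
#'   `n50`.
#' @export
effective_ancestors <- function(ped, ids = NULL, tol = 1e-9) {
  ids <- .default_ref(ped, ids)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ref_idx <- match(ids, ped$id)

  # Candidates: proper ancestors of the reference, plus founders that are
  # themselves reference members (their genome is not explained by anyone
  # else). Non-founder reference animals are fully explained by their
  # parents and are not ancestors of themselves.
  anc <- ancestor_closure(ped, ids, include_self = FALSE)
  anc <- union(anc, intersect(ids, founder_ids(ped)))
  cand <- match(ped$id[ped$id %in% anc], ped$id)  # topological order

  selected <- integer(0)
  marginal <- numeric(0)
  # contribution of every animal's genome to the reference mean, with the
  # current selected set masked (selected animals act as founders).
  contrib_masked <- function(sel) {
    # B[x, a]: share of candidate a in animal x under masking. Computed for
    # all candidates at once by downward recursion.
    B <- matrix(0, n, length(cand))
    B[cbind(cand, seq_along(cand))] <- 1
    for (x in seq_len(n)) {
      if (x %in% sel) next            # masked: own row stays e_x
      if (!is.na(si[x])) {
        own <- B[x, ]                  # keep the identity entry if candidate
        B[x, ] <- 0.5 * B[si[x], ] + 0.5 * B[di[x], ]
        B[x, ] <- B[x, ] + own
      }
    }
    colMeans(B[ref_idx, , drop = FALSE])
  }
  explained_fraction <- function(sel) {
    alpha <- numeric(n)
    for (x in seq_len(n)) {
      if (x %in% sel) { alpha[x] <- 1; next }
      if (!is.na(si[x])) alpha[x] <- 0.5 * alpha[si[x]] + 0.5 * alpha[di[x]]
    }
    alpha
  }

  remaining <- cand
  while (length(remaining) > 0) {
    cc <- contrib_masked(selected)
    alpha <- explained_fraction(selected)
    p <- cc * (1 - alpha[cand])
    p[match(selected, cand)] <- -Inf
    best <- which.max(p)               # ties: earliest topological order
    if (p[best] < tol) break
    selected <- c(selected, cand[best])
    marginal <- c(marginal, p[best])
  }
  names(marginal) <- ped$id[selected]
  fa <- 1 / sum(marginal^2)
  csum <- cumsum(marginal)
  n50 <- if (any(csum >= 0.5)) unname(which(csum >= 0.5)[1]) else NA_integer_
  list(fa = fa, marginal = marginal, n50 = n50)
}

#' Founder genome equivalents
#'
#' The number of equally contributing founders with no allele loss that
#' would give the observed diversity of the reference population.
#'
#' Method `"coancestry"` (deterministic): `fg = 1 / (2 * fbar)` with `fbar`
#' the mean co-ancestry over all reference pairs, self pairs included.
#'
#' Method `"genedrop"` (Monte Carlo): two unique alleles per founder are
#' segregated through the pedigree `replicates` times. The primary `fg` is
#' the unbiased estimator `1 / (2 * mean founder-allele homozygosity)`,
#' whose expectation is exactly the co-ancestry form; the per-founder
#' allele retention `r_j` and the classical retention approximation
#' `fg_retention = 1 / sum(p_j^2 / r_j)` are also returned.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @param method `"coancestry"` or `"genedrop"`.
#' @param replicates number of gene-drop replicates (default 10000).
#' @param seed optional integer seed; a fixed seed makes the gene-drop
#'   result reproducible bit for bit.
#' @return For `"coancestry"`, a list with `fg` and `mean_coancestry`. For
#'   `"genedrop"`, a list with `fg`, `fg_retention`, `retention` (named
#'   vector over founders), `replicates`.
#' @export
founder_genome_equivalents <- function(ped, ids = NULL,
                                       method = c("coancestry", "genedrop"),
                                       replicates = 10000, seed = NULL) {
  method <- match.arg(method)
  ids <- .default_ref(ped, ids)
  if (method == "coancestry") {
    ks <- relationship_matrix(ped, ids)
    fbar <- mean(ks$A) / 2
    return(list(fg = 1 / (2 * fbar), mean_coancestry = fbar))
  }
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  founders <- founder_ids(ped)
  f <- length(founders)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  fi <- match(founders, ped$id)
  R <- as.integer(replicates)
  # allele codes: founder j carries 2j-1 and 2j
  M1 <- matrix(0L, n, R)
  M2 <- matrix(0L, n, R)
  M1[fi, ] <- (2L * seq_len(f) - 1L)
  M2[fi, ] <- (2L * seq_len(f))
  for (x in seq_len(n)) {
    if (is.na(si[x])) next
    from_s <- ifelse(runif(R) < 0.5, M1[si[x], ], M2[si[x], ])
    from_d <- ifelse(runif(R) < 0.5, M1[di[x], ], M2[di[x], ])
    M1[x, ] <- from_s
    M2[x, ] <- from_d
  }
  ref_idx <- match(ids, ped$id)
  pool <- rbind(M1[ref_idx, , drop = FALSE], M2[ref_idx, , drop = FALSE])
  copies <- nrow(pool)
  hom <- numeric(R)          # founder-allele homozygosity per replicate
  surv <- matrix(0, f, R)    # distinct surviving alleles per founder
  for (r in seq_len(R)) {
    cnt <- tabulate(pool[, r], nbins = 2L * f)
    hom[r] <- sum((cnt / copies)^2)
    present <- cnt > 0
    surv[, r] <- present[c(TRUE, FALSE)] + present[c(FALSE, TRUE)]
  }
  retention <- rowMeans(surv) / 2
  names(retention) <- founders
  q <- founder_contributions(ped, ids)
  ok <- q > 0
  if (any(retention[ok] == 0)) {
    warning("founder(s) with positive expected contribution but zero ",
            "observed retention excluded from the retention form")
    ok <- ok & retention > 0
  }
  list(fg = 1 / (2 * mean(hom)),
       fg_retention = 1 / sum(q[ok]^2 / retention[ok]),
       retention = retention, replicates = R)
}

#' Partition of genetic diversity loss
#'
#' `GD = 1 - 1/(2 fg)` is the diversity retained accounting for drift and
#' bottlenecks; `GD* = 1 - 1/(2 fe)` accounts for unequal founder
#' contributions only. The total loss `1 - GD` decomposes exactly into the
#' founder-imbalance loss `1 - GD*` plus the drift loss `GD* - GD`.
#'
#' @param fe effective number of founders.
#' @param fg founder genome equivalents.
#' @return List with `GD`, `GDstar`, `loss_total`, `loss_founder`,
#'   `loss_drift`.
#' @export
diversity_loss <- function(fe, fg) {
  stopifnot(fe > 0, fg > 0)
  GD <- 1 - 1 / (2 * fg)
  GDstar <- 1 - 1 / (2 * fe)
  list(GD = GD, GDstar = GDstar,
       loss_total = 1 - GD, loss_founder = 1 - GDstar,
       loss_drift = GDstar - GD)
}

#' Full gene-origin report
#'
#' Assembles founder contributions, `fe`, ancestor marginals with `fa` and
#' `n50`, founder genome equivalents (both methods) and the diversity-loss
#' partition for one reference set.
#'
#' @inheritParams founder_genome_equivalents
#' @return A `gene_origin_report` object (list); its `f` counts the
#'   founders with a non-zero expected contribution to the reference.
#' @export
gene_origin_report <- function(ped, ids = NULL, replicates = 10000, seed = NULL) {
  ids <- .default_ref(ped, ids)
  q <- founder_contributions(ped, ids)
  fe <- effective_founders(q)
  ea <- effective_ancestors(ped, ids)
  fg_co <- founder_genome_equivalents(ped, ids, "coancestry")
  fg_gd <- founder_genome_equivalents(ped, ids, "genedrop",
                                      replicates = replicates, seed = seed)
  structure(list(n_ref = length(ids), f = sum(q > 0), q_founder = q,
                 fe = fe, marginal = ea$marginal, fa = ea$fa, n50 = ea$n50,
                 fg_coancestry = fg_co$fg, fg_genedrop = fg_gd$fg,
                 fg_retention = fg_gd$fg_retention,
                 retention = fg_gd$retention,
                 loss = diversity_loss(fe, fg_co$fg)),
            class = "gene_origin_report")
}

#' @export
print.gene_origin_report <- function(x, ...) {
  cat(sprintf("Gene-origin report: n = %d, f = %d\n", x$n_ref, x$f))
  cat(sprintf("  fe = %.2f   fa = %.2f   n50 = %d\n", x$fe, x$fa, x$n50))
  cat(sprintf("  fg = %.2f (co-ancestry), %.2f (gene drop)\n",
              x$fg_coancestry, x$fg_genedrop))
  cat(sprintf("  diversity loss: total %.2f%% = founder %.2f%% + drift %.2f%%\n",
              100 * x$loss$loss_total, 100 * x$loss$loss_founder,
              100 * x$loss$loss_drift))
  invisible(x)
}
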