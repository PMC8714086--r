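# Subpopulation structure: mean co-ancestry partition, pairwise pedigree
# FST, UPGMA dendrograms and relationship-matrix PCA.

#' Mean co-ancestries within and between subpopulations
#'
#' `f_ij` is the mean co-ancestry over all pairs (x in group i, y in group
#' j); within a group the self pairs are included, with self co-ancestry
#' `(1 + F_x)/2`, so singleton groups are well defined.
#'
#' @param ped a `pedigree`.
#' @param groups named character/factor vector mapping animal ids (names)
#'   to group labels, or `NULL` to group the reference animals (or all
#'   animals when none are flagged) by their `location` column.
#' @return A `subpop_coancestry` object: list with the symmetric matrix `f`
#'   and the `groups` list (label -> ids). Empty groups are dropped with a
#'   warning.
#' @export
subpop_coancestry <- function(ped, groups = NULL) {
  stopifnot(is_pedigree(ped))
  if (is.null(groups)) {
    ids <- .default_ref(ped, NULL)
    loc <- ped$location[match(ids, ped$id)]
    keep <- !is.na(loc)
    if (!all(keep)) warning("animals without a location were dropped")
    groups <- stats::setNames(loc[keep], ids[keep])
  }
  if (is.null(names(groups))) stop("'groups' must be named by animal id")
  if (!all(names(groups) %in% ped$id)) stop("unknown id(s) in grouping")
  glist <- split(names(groups), as.character(groups))
  glist <- glist[vapply(glist, length, 0L) > 0]
  if (length(glist) == 0) stop("no non-empty group")
  ks <- relationship_matrix(ped, names(groups))
  s <- length(glist)
  f <- matrix(0, s, s, dimnames = list(names(glist), names(glist)))
  for (i in seq_len(s)) for (j in i:s) {
    f[i, j] <- f[j, i] <- mean(ks$A[glist[[i]], glist[[j]], drop = FALSE]) / 2
  }
  structure(list(f = f, groups = glist), class = "subpop_coancestry")
}

#' Pairwise pedigree FST between subpopulations
#'
#' Nei minimum-distance form on mean co-ancestries:
#' `D_ij = (f_ii + f_jj)/2 - f_ij` and `FST_ij = D_ij / (1 - (f_ii +
#' f_jj)/2)`, clamped to `[0, 1]`. FST is 0 for identical subpopulations
#' and 1 for fully differentiated ones; a pair with mean self co-ancestry
#' of 1 is undefined and reported as `NA`.
#'
#' @param coancestry a `subpop_coancestry` object or its `f` matrix.
#' @return Symmetric FST matrix with zero diagonal.
#' @export
pairwise_fst <- function(coancestry) {
  f <- if (inherits(coancestry, "subpop_coancestry")) coancestry$f else coancestry
  s <- nrow(f)
  fst <- matrix(0, s, s, dimnames = dimnames(f))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (i == j) next
    selfbar <- (f[i, i] + f[j, j]) / 2
    if (selfbar >= 1) { fst[i, j] <- NA_real_; next }
    fst[i, j] <- min(max((selfbar - f[i, j]) / (1 - selfbar), 0), 1)
  }
  fst
}

#' UPGMA dendrogram of subpopulations from an FST matrix
#'
#' Average-linkage hierarchical clustering of the FST matrix; ties are
#' resolved deterministically by label order. The tree is returned both as
#' an `hclust` object and as a rooted `ape::phylo`/Newick string, with
#' ultrametric heights non-decreasing from leaves to root.
#'
#' @param fst symmetric FST matrix (`>= 2` groups, no missing entries).
#' @return List with `hclust`, `phylo` and `newick`.
#' @export
fst_dendrogram <- function(fst) {
  if (nrow(fst) < 2) stop("need at least two groups")
  if (anyNA(fst)) {
    bad <- which(is.na(fst), arr.ind = TRUE)
    stop("missing FST for pair(s): ",
         paste(rownames(fst)[bad[, 1]], colnames(fst)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(fst), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}

#' PCA of the relationship matrix
#'
#' Eigen-decomposition of the double-centered relationship matrix of the
#' reference animals (treated as a similarity); coordinates are the
#' eigenvectors scaled by the square root of their eigenvalues, so they
#' embed genetic distance. Identical relatives map to identical points and
#' unrelated families separate with opposite signs on the leading axis.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @param k number of components returned (default 2; truncated with a
#'   warning if larger than the reference size).
#' @return List with `coords` (ids x k), `var_explained` (fractions over
#'   all components, summing to 1) and `eigenvalues`.
#' @export
relationship_pca <- function(ped, ids = NULL, k = 2) {
  ids <- .default_ref(ped, ids)
  if (length(ids) < 2) stop("need at least two animals")
  if (k < 1) stop("k must be >= 1")
  if (k > length(ids)) {
    warning("k larger than the reference size; truncated")
    k <- length(ids)
  }
  ks <- relationship_matrix(ped, ids)
  n <- length(ids)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% ks$A %*% C
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  dimnames(coords) <- list(ids, paste0("PC", seq_len(k)))
  list(coords = coords,
       var_explained = if (sum(ev) > 0) ev / sum(ev) else ev,
       eigenvalues = eig$values)
}

#' Relationship heatmap matrix with dendrogram leaf ordering
#'
#' The pairwise relationship submatrix of the reference animals, with rows
#' and columns permuted to the leaf order of an average-linkage clustering
#' on co-ancestry distance (1 - c), so related family blocks are
#' contiguous. Values are exported; rendering is left to the caller.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @return List with `matrix` (ordered relationship submatrix) and
#'   `ordering` (a permutation of the reference ids).
#' @export
ar_heatmap_matrix <- function(ped, ids = NULL) {
  ids <- .default_ref(ped, ids)
  if (length(ids) < 2) stop("need at least two animals")
  ks <- relationship_matrix(ped, ids)
  d <- stats::as.dist(1 - ks$A / 2)
  hc <- stats::hclust(d, method = "average")
  ord <- ids[hc$order]
  list(matrix = ks$A[ord, ord], ordering = ord)
}

#' Full structure report
#'
#' Subpopulation co-ancestry means, pairwise FST, UPGMA dendrogram, PCA of
#' the relationship matrix and the ordered heatmap matrix in one object.
#'
#' @param ped a `pedigree`.
#' @param ids reference set (default: flagged reference animals, or all).
#' @param groups optional named grouping vector (default: `location`).
#' @param k PCA components.
#' @return A `structure_report` list.
#' @export
structure_report <- function(ped, ids = NULL, groups = NULL, k = 2) {
  ids <- .default_ref(ped, ids)
  co <- if (is.null(groups)) {
    loc <- ped$location[match(ids, ped$id)]
    keep <- !is.na(loc)
    subpop_coancestry(ped, stats::setNames(loc[keep], ids[keep]))
  } else subpop_coancestry(ped, groups)
  fst <- pairwise_fst(co)
  dend <- if (nrow(fst) >= 2) fst_dendrogram(fst) else NULL
  structure(list(coancestry = co, fst = fst, dendrogram = dend,
                 pca = relationship_pca(ped, ids, k),
                 heatmap = ar_heatmap_matrix(ped, ids),
                 estimator = "Nei minimum distance on mean co-ancestries"),
            class = "structure_report")
}
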