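# Pedigree completeness measures.
#
# "Known" throughout means a recorded, non-phantom animal: phantom founders
# stand for missing parent slots and therefore count as unknown ancestors.

.ped_indices <- function(ped) {
  list(si = match(ped$sire, ped$id), di = match(ped$dam, ped$id),
       known = !ped$phantom)
}

# Count of known ancestors of each animal at each generation 0..(d-1),
# counting the animal itself as generation 0 of its own line. Slot
# multiplicity is preserved: an ancestor reachable twice is counted twice.
.known_counts <- function(ped, d) {
  ix <- .ped_indices(ped)
  n <- nrow(ped)
  K <- matrix(0, n, d)
  for (x in seq_len(n)) {
    if (!ix$known[x]) next
    K[x, 1] <- 1
    if (d > 1) {
      s <- ix$si[x]; dm <- ix$di[x]
      if (!is.na(s)) K[x, 2:d] <- K[x, 2:d] + K[s, 1:(d - 1)]
      if (!is.na(dm)) K[x, 2:d] <- K[x, 2:d] + K[dm, 1:(d - 1)]
    }
  }
  K
}

#' Maximum number of generations traced
#'
#' The number of generations separating an animal from its furthest known
#' ancestor; founders (and animals with only phantom parents) are 0.
#'
#' @param ped a `pedigree`.
#' @param ids animal ids (default: all non-phantom animals).
#' @return Named integer vector.
#' @export
max_generations <- function(ped, ids = NULL) {
  stopifnot(is_pedigree(ped))
  ix <- .ped_indices(ped)
  n <- nrow(ped)
  g <- integer(n)
  for (x in seq_len(n)) {
    s <- ix$si[x]; d <- ix$di[x]
    vals <- c(if (!is.na(s) && ix$known[s]) 1L + g[s],
              if (!is.na(d) && ix$known[d]) 1L + g[d])
    g[x] <- if (length(vals) > 0) max(vals) else 0L
  }
  .pick_ids(ped, g, ids)
}

#' Number of fully traced generations
#'
#' The largest `g` such that every one of the `2^g` ancestor slots in
#' generations 1..g is filled by a known (non-phantom) animal.
#'
#' @inheritParams max_generations
#' @return Named integer vector.
#' @export
full_generations <- function(ped, ids = NULL) {
  stopifnot(is_pedigree(ped))
  ix <- .ped_indices(ped)
  n <- nrow(ped)
  g <- integer(n)
  for (x in seq_len(n)) {
    s <- ix$si[x]; d <- ix$di[x]
    g[x] <- if (!is.na(s) && ix$known[s] && !is.na(d) && ix$known[d])
      1L + min(g[s], g[d]) else 0L
  }
  .pick_ids(ped, g, ids)
}

#' Equivalent complete generations
#'
#' Sum over all known ancestors of (1/2)^n, with n the generation distance;
#' an ancestor reachable along several paths contributes once per path.
#' Computed by the linear-time recursion
#' `t(x) = sum over known parents of (1/2) (1 + t(parent))`, which equals
#' the path sum.
#'
#' @inheritParams max_generations
#' @return Named numeric vector.
#' @export
equivalent_generations <- function(ped, ids = NULL) {
  stopifnot(is_pedigree(ped))
  ix <- .ped_indices(ped)
  n <- nrow(ped)
  t <- numeric(n)
  for (x in seq_len(n)) {
    s <- ix$si[x]; d <- ix$di[x]
    v <- 0
    if (!is.na(s) && ix$known[s]) v <- v + 0.5 * (1 + t[s])
    if (!is.na(d) && ix$known[d]) v <- v + 0.5 * (1 + t[d])
    t[x] <- v
  }
  .pick_ids(ped, t, ids)
}

.pick_ids <- function(ped, values, ids) {
  names(values) <- ped$id
  if (is.null(ids)) return(values[!ped$phantom])
  if (!all(ids %in% ped$id)) stop("unknown id(s): ",
                                  paste(setdiff(ids, ped$id), collapse = ", "))
  values[ids]
}

#' Pedigree completeness index
#'
#' MacCluer's index: per parental line, the mean over generations 1..d of
#' the proportion of known ancestors in that generation; the index is the
#' harmonic mean of the paternal and maternal line values,
#' `PCI = 2 Cp Cm / (Cp + Cm)`, and 0 when either line is entirely unknown.
#'
#' @param ped a `pedigree`.
#' @param ids animal ids (default: all non-phantom animals).
#' @param depth number of generations counted, `d >= 1` (default 5).
#' @return Named numeric vector in `[0, 1]`.
#' @export
pci <- function(ped, ids = NULL, depth = 5) {
  stopifnot(is_pedigree(ped))
  if (depth < 1) stop("depth must be >= 1")
  ix <- .ped_indices(ped)
  K <- .known_counts(ped, depth)
  slots <- 2^(seq_len(depth) - 1)
  line_c <- function(p) {
    if (is.na(p) || !ix$known[p]) return(0)
    mean(K[p, ] / slots)
  }
  n <- nrow(ped)
  out <- numeric(n)
  for (x in seq_len(n)) {
    cp <- line_c(ix$si[x]); cm <- line_c(ix$di[x])
    out[x] <- if (cp + cm == 0) 0 else 2 * cp * cm / (cp + cm)
  }
  .pick_ids(ped, out, ids)
}

#' Per-generation completeness profile
#'
#' For each ancestor generation 1..`max_depth`, the mean (over the focal
#' animals) proportion of the `2^g` ancestor slots filled with known
#' animals — the familiar declining completeness curve of studbook
#' pedigrees.
#'
#' @param ped a `pedigree`.
#' @param ids focal animals (default: all non-phantom animals).
#' @param max_depth deepest generation profiled.
#' @return Data frame with columns `generation` and `prop_known`.
#' @export
completeness_profile <- function(ped, ids = NULL, max_depth = 7) {
  stopifnot(is_pedigree(ped))
  if (is.null(ids)) ids <- ped$id[!ped$phantom]
  if (length(ids) == 0) stop("empty id set")
  if (!all(ids %in% ped$id)) stop("unknown id(s)")
  ix <- .ped_indices(ped)
  K <- .known_counts(ped, max_depth)
  xi <- match(ids, ped$id)
  si <- ix$si[xi]; di <- ix$di[xi]
  counts <- matrix(0, length(ids), max_depth)
  ok_s <- !is.na(si); ok_d <- !is.na(di)
  counts[ok_s, ] <- counts[ok_s, , drop = FALSE] + K[si[ok_s], , drop = FALSE]
  counts[ok_d, ] <- counts[ok_d, , drop = FALSE] + K[di[ok_d], , drop = FALSE]
  prop <- sweep(counts, 2, 2^seq_len(max_depth), "/")
  data.frame(generation = seq_len(max_depth), prop_known = colMeans(prop))
}

#' Per-animal completeness table
#'
#' @param ped a `pedigree`.
#' @param ids animal ids (default: all non-phantom animals).
#' @param depth PCI depth (default 5, the conventional window).
#' @return Data frame with columns `id`, `max_gen`, `full_gen`,
#'   `equiv_gen`, `pci`.
#' @export
completeness <- function(ped, ids = NULL, depth = 5) {
  mg <- max_generations(ped, ids)
  data.frame(id = names(mg), max_gen = unname(mg),
             full_gen = unname(full_generations(ped, ids)),
             equiv_gen = unname(equivalent_generations(ped, ids)),
             pci = unname(pci(ped, ids, depth)),
             stringsAsFactors = FALSE)
}
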