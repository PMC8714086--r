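# AR-threshold mating groups and minimum-kinship pair recommendation.

#' Classify candidates into mating groups by average relatedness
#'
#' Three groups: group 1 (`AR < low`) are the animals most suitable for
#' reproduction schemes; group 2 (`low <= AR <= high`, boundary values
#' inclusive) may supplement a plan when their AR is close to the lower
#' threshold; group 3 (`AR > high`) should be avoided. Default thresholds
#' 4% and 12.5%.
#'
#' @param ar named numeric vector of AR values.
#' @param low,high thresholds with `0 < low < high < 1`.
#' @return A `mating_groups` object: list of id vectors `group1`,
#'   `group2`, `group3` plus `thresholds`.
#' @export
classify_by_ar <- function(ar, low = 0.04, high = 0.125) {
  if (!(low > 0 && low < high && high < 1)) stop("need 0 < low < high < 1")
  structure(list(group1 = names(ar)[ar < low],
                 group2 = names(ar)[ar >= low & ar <= high],
                 group3 = names(ar)[ar > high],
                 thresholds = c(low = low, high = high)),
            class = "mating_groups")
}

#' @export
print.mating_groups <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Mating groups (AR < %.3g | %.3g-%.3g | > %.3g): %d / %d / %d animals\n",
              th["low"], th["low"], th["high"], th["high"],
              length(x$group1), length(x$group2), length(x$group3)))
  invisible(x)
}

# exact matching maximizing pair count first, then minimizing total
# kinship; dynamic programming over a bitmask of females, so only used for
# small instances (<= 10 females).
.exact_matching <- function(K, feasible) {
  nm <- nrow(K); nf <- ncol(K)
  memo <- new.env(hash = TRUE)
  solve <- function(m, mask) {
    if (m > nm) return(list(count = 0L, sum = 0, pairs = list()))
    key <- paste(m, mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- solve(m + 1L, mask)            # leave male m unpaired
    for (f in seq_len(nf)) {
      bit <- bitwShiftL(1L, f - 1L)
      if (feasible[m, f] && !bitwAnd(mask, bit)) {
        sub <- solve(m + 1L, bitwOr(mask, bit))
        cand <- list(count = sub$count + 1L, sum = sub$sum + K[m, f],
                     pairs = c(list(c(m, f)), sub$pairs))
        if (cand$count > best$count ||
            (cand$count == best$count && cand$sum < best$sum - 1e-12))
          best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  res <- solve(1L, 0L)
  if (res$count == 0L) NULL else do.call(rbind, res$pairs)
}

#' Recommend minimum-kinship breeding pairs
#'
#' Builds the male x female kinship (co-ancestry) matrix of the candidate
#' animals and selects pairs with small kinship: the predicted inbreeding
#' coefficient of a pair's offspring equals the pair kinship exactly.
#' Default candidates are the reference animals in mating group 1
#' (`AR < low`). Constraints: a kinship ceiling (default 0.0625, the first
#' cousin level), a per-animal use limit, and an optional same-location
#' preference. The default `"greedy"` method scans feasible pairs in
#' ascending kinship (ties by male then female id); `"exact"` enumerates
#' matchings on small instances (at most 10 females), maximizing the
#' number of pairs and then minimizing total kinship.
#'
#' @param ped a `pedigree`.
#' @param candidates candidate ids; default group 1 of the reference
#'   population by [classify_by_ar()].
#' @param max_kinship pair kinship ceiling (pairs at or above it are
#'   infeasible).
#' @param max_uses maximum number of recommended pairs per animal.
#' @param method `"greedy"` or `"exact"`.
#' @param same_location_only restrict to pairs housed at the same location.
#' @param ar_low AR threshold used when `candidates` is `NULL`.
#' @return A `pair_recommendation` data frame with columns `male`,
#'   `female`, `kinship`, `predicted_F`, sorted by ascending kinship;
#'   attribute `excluded` tabulates infeasible-pair reasons.
#' @export
recommend_pairs <- function(ped, candidates = NULL, max_kinship = 0.0625,
                            max_uses = 1, method = c("greedy", "exact"),
                            same_location_only = FALSE, ar_low = 0.04) {
  stopifnot(is_pedigree(ped))
  method <- match.arg(method)
  if (is.null(candidates)) {
    ids <- .default_ref(ped, NULL)
    ar <- average_relatedness(ped)[ids]
    candidates <- classify_by_ar(ar, low = ar_low)$group1
  }
  sex <- ped$sex[match(candidates, ped$id)]
  males <- sort(candidates[sex == "male"])
  females <- sort(candidates[sex == "female"])
  empty <- data.frame(male = character(0), female = character(0),
                      kinship = numeric(0), predicted_F = numeric(0))
  if (length(males) == 0 || length(females) == 0) {
    return(structure(empty, excluded = c(no_candidates = 1L),
                     class = c("pair_recommendation", "data.frame")))
  }
  ks <- relationship_matrix(ped, c(males, females))
  K <- ks$A[males, females, drop = FALSE] / 2
  feasible <- K < max_kinship
  excluded <- c(kinship_ceiling = sum(!feasible))
  if (same_location_only) {
    locm <- ped$location[match(males, ped$id)]
    locf <- ped$location[match(females, ped$id)]
    same <- outer(locm, locf, function(a, b) !is.na(a) & !is.na(b) & a == b)
    excluded <- c(excluded, different_location = sum(feasible & !same))
    feasible <- feasible & same
  }

  pairs <- NULL
  if (method == "exact" && length(females) <= 10 && max_uses == 1) {
    pairs <- .exact_matching(K, feasible)
  } else if (method == "exact") {
    warning("exact mode limited to <= 10 females and max_uses = 1; using greedy")
    method <- "greedy"
  }
  if (is.null(pairs) && method == "greedy") {
    idx <- which(feasible, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(K[idx], males[idx[, 1]], females[idx[, 2]])
      idx <- idx[ord, , drop = FALSE]
      uses_m <- stats::setNames(integer(length(males)), males)
      uses_f <- stats::setNames(integer(length(females)), females)
      keep <- logical(nrow(idx))
      for (r in seq_len(nrow(idx))) {
        m <- males[idx[r, 1]]; f <- females[idx[r, 2]]
        if (uses_m[m] < max_uses && uses_f[f] < max_uses) {
          keep[r] <- TRUE
          uses_m[m] <- uses_m[m] + 1L
          uses_f[f] <- uses_f[f] + 1L
        }
      }
      pairs <- idx[keep, , drop = FALSE]
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(structure(empty, excluded = excluded,
                     class = c("pair_recommendation", "data.frame")))
  }
  out <- data.frame(male = males[pairs[, 1]], female = females[pairs[, 2]],
                    kinship = K[pairs], stringsAsFactors = FALSE)
  out$predicted_F <- out$kinship
  out <- out[order(out$kinship, out$male, out$female), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("pair_recommendation", "data.frame"))
}

#' @export
print.pair_recommendation <- function(x, ...) {
  cat(sprintf("Recommended pairs: %d\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(as.data.frame(x))
  ex <- attr(x, "excluded")
  if (!is.null(ex) && sum(ex) > 0)
    cat("excluded pairs:", paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
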