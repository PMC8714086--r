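# Fixtures built in code plus independent oracles (explicit path
# enumeration / brute force) used to cross-check the recursive
# implementations.

full_sib_ped <- function() {
  pedigree(id = c("A", "B", "C", "D", "E"),
           sire = c(NA, NA, "A", "A", "C"),
           dam = c(NA, NA, "B", "B", "D"),
           sex = c("male", "female", "male", "female", "male"))
}

half_sib_ped <- function() {
  # C and D share the sire A only; E is their offspring
  pedigree(id = c("A", "B", "B2", "C", "D", "E"),
           sire = c(NA, NA, NA, "A", "A", "C"),
           dam = c(NA, NA, NA, "B", "B2", "D"),
           sex = c("male", "female", "female", "male", "female", "male"))
}

parent_offspring_ped <- function() {
  # D is the offspring of A and his own daughter C
  pedigree(id = c("A", "B", "C", "D"),
           sire = c(NA, NA, "A", "A"),
           dam = c(NA, NA, "B", "C"),
           sex = c("male", "female", "female", "female"))
}

bottleneck_ped <- function() {
  # deep founders P,Q,R,S; couple X,Y; all reference animals descend from X,Y
  pedigree(id = c("P", "Q", "R", "S", "X", "Y", "U", "V", "W"),
           sire = c(NA, NA, NA, NA, "P", "R", "X", "X", "X"),
           dam = c(NA, NA, NA, NA, "Q", "S", "Y", "Y", "Y"),
           sex = c("male", "female", "male", "female",
                   "male", "female", "male", "female", "female"),
           is_reference = c(rep(FALSE, 6), TRUE, TRUE, TRUE))
}

two_family_ped <- function() {
  # two unrelated full-sib families
  pedigree(id = c("A", "B", "C", "D", "E", "F", "G", "H"),
           sire = c(NA, NA, NA, NA, "A", "A", "C", "C"),
           dam = c(NA, NA, NA, NA, "B", "B", "D", "D"),
           sex = c("male", "female", "male", "female",
                   "male", "female", "male", "female"))
}

# Random small pedigree using the current RNG stream; guarantees at least
# one male and one female founder so parents can always be drawn.
rand_ped <- function(n, p_parent = 0.8) {
  id <- sprintf("X%02d", seq_len(n))
  sex <- c("male", "female", sample(c("male", "female"), n - 2, replace = TRUE))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) > 0 && length(females) > 0 && runif(1) < p_parent) {
      sire[i] <- id[males[sample.int(length(males), 1)]]
      dam[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  pedigree(id = id, sire = sire, dam = dam, sex = sex)
}

# ---- independent oracles -------------------------------------------------

.parent_map <- function(ped) {
  known <- !ped$phantom
  list(sire = stats::setNames(ped$sire, ped$id),
       dam = stats::setNames(ped$dam, ped$id),
       known = stats::setNames(known, ped$id))
}

# all upward paths from x through known (non-phantom) animals; each path is
# the vector of visited ids ending at some ancestor
.all_paths <- function(pm, x) {
  out <- list()
  for (p in c(pm$sire[[x]], pm$dam[[x]])) {
    if (is.na(p) || !pm$known[[p]]) next
    out <- c(out, list(p), lapply(.all_paths(pm, p), function(q) c(p, q)))
  }
  out
}

# Wright path-counting inbreeding coefficient with the (1 + F_a) correction
# for inbred common ancestors; fully independent of the tabular method.
oracle_inbreeding <- function(ped) {
  pm <- .parent_map(ped)
  # here phantoms count as ordinary founders (they carry no relatedness),
  # so paths may pass through them
  pm$known[] <- TRUE
  Fo <- stats::setNames(numeric(nrow(ped)), ped$id)
  for (x in ped$id) {  # topological order
    s <- pm$sire[[x]]; d <- pm$dam[[x]]
    if (is.na(s) || is.na(d)) next
    ps <- c(list(s), lapply(.all_paths(pm, s), function(q) c(s, q)))
    pd <- c(list(d), lapply(.all_paths(pm, d), function(q) c(d, q)))
    val <- 0
    for (a in ps) for (b in pd) {
      if (a[length(a)] != b[length(b)]) next       # same common ancestor
      if (length(intersect(a, b)) != 1) next       # node-disjoint except it
      anc <- a[length(a)]
      val <- val + 0.5^(length(a) - 1 + length(b) - 1 + 1) * (1 + Fo[[anc]])
    }
    Fo[[x]] <- val
  }
  Fo[!ped$phantom]
}

# path-sum form of equivalent complete generations: every path to a known
# ancestor contributes (1/2)^length
oracle_equiv_gen <- function(ped) {
  pm <- .parent_map(ped)
  vapply(stats::setNames(ped$id[!ped$phantom], ped$id[!ped$phantom]),
         function(x) sum(vapply(.all_paths(pm, x),
                                function(p) 0.5^length(p), 0)),
         0)
}

# ancestor closure by plain graph traversal
oracle_closure <- function(ped, ids) {
  pm <- .parent_map(ped)
  seen <- character(0)
  visit <- function(x) {
    if (x %in% seen) return(invisible())
    seen <<- c(seen, x)
    for (p in c(pm$sire[[x]], pm$dam[[x]])) if (!is.na(p)) visit(p)
  }
  for (x in ids) visit(x)
  sort(seen)
}

# exhaustive minimum-sum matching over all complete assignments (n x n)
oracle_matching_sum <- function(K, max_kinship) {
  n <- nrow(K)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- list(count = -1L, sum = Inf)
  for (p in perms(seq_len(n))) {
    ok <- K[cbind(seq_len(n), p)] < max_kinship
    cnt <- sum(ok)
    s <- sum(K[cbind(seq_len(n), p)][ok])
    if (cnt > best$count || (cnt == best$count && s < best$sum))
      best <- list(count = cnt, sum = s)
  }
  best
}

write_ped_file <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
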