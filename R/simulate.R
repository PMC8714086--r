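# Synthetic studbook generator with known ground truth. Emulates the data
# shape of small captive populations (a few hundred animals, shallow
# pedigrees, heavy missing-parent censoring in the older cohorts, a living
# reference subset spread over a dozen locations) so every estimator can be
# validated without external data.

#' Simulation configuration
#'
#' @param n_founders number of founders (generation 0), split between the
#'   sexes.
#' @param n_generations number of offspring generations simulated.
#' @param offspring_mean mean litter-sum per dam per generation (Poisson).
#' @param sex_ratio probability that an offspring is male.
#' @param mating `"random"`, `"full_sib_bias"` (dams mate a full brother
#'   when one exists) or `"min_kinship"` (each dam takes the least related
#'   sire).
#' @param constant_size when set, ideal-population mode: discrete
#'   generations of exactly this size with random union of gametes and
#'   balanced sexes, the regime in which the inbreeding rate is expected to
#'   be `1/(2N)` per generation.
#' @param n_locations number of location labels.
#' @param transfer_prob probability an offspring is transferred away from
#'   its dam's location.
#' @param missing_schedule per-backward-cohort parent-link deletion
#'   probabilities applied after ground truth is recorded (see [censor()]);
#'   empty for no censoring.
#' @param reference_generations the living reference population is drawn
#'   from this many of the youngest cohorts.
#' @param reference_fraction fraction of those cohorts flagged as the
#'   reference population.
#' @param mean_parental_age,sd_parental_age parental age at offspring birth
#'   (years; normal, truncated at 2).
#' @param founder_year birth year around which founders are placed.
#' @param seed integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 60, n_generations = 7,
                       offspring_mean = 2, sex_ratio = 0.5,
                       mating = c("random", "full_sib_bias", "min_kinship"),
                       constant_size = NULL,
                       n_locations = 12, transfer_prob = 0.15,
                       missing_schedule = numeric(0),
                       reference_generations = 2, reference_fraction = 0.9,
                       mean_parental_age = 6.5, sd_parental_age = 2.5,
                       founder_year = 1970, seed = 1) {
  mating <- match.arg(mating)
  stopifnot(n_founders >= 2, n_generations >= 1,
            sex_ratio > 0, sex_ratio < 1,
            all(missing_schedule >= 0 & missing_schedule <= 1),
            transfer_prob >= 0, transfer_prob <= 1,
            reference_fraction > 0, reference_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Preset emulating the shape of a small captive lion studbook
#'
#' Roughly 450 animals over 7 ancestor generations, about a fifth flagged
#' as the living reference population, a dozen locations with transfers,
#' and a censoring schedule under which completeness falls from about 73%
#' in the first ancestor generation to near zero by the fifth. A shape
#' preset for smoke tests; it does not claim to reproduce any real
#' studbook.
#'
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
paper_shape_config <- function(seed = 1) {
  sim_config(n_founders = 48, n_generations = 7, offspring_mean = 2.15,
             mating = "random", n_locations = 12, transfer_prob = 0.15,
             missing_schedule = c(0.25, 0.35, 0.55, 0.75, 0.9, 1, 1, 1),
             reference_generations = 2, reference_fraction = 0.7,
             seed = seed)
}

.date_from_years <- function(years) {
  as.Date("1900-01-01") + round(years * 365.25)
}

#' Simulate a studbook pedigree with ground truth
#'
#' Generates founders and `n_generations` offspring cohorts under the
#' configured mating policy, assigns sexes, birth dates and locations,
#' flags a reference population, records the ground truth (cohorts,
#' uncensored inbreeding, true founder contributions to the reference) and
#' only then applies the censoring schedule.
#'
#' @param config a [sim_config()].
#' @return List with `pedigree` (a `pedigree`, censored when the config
#'   says so; cohorts kept in its `generation` attribute) and `truth`
#'   (list: `generation`, `F_true`, `founder_contributions`,
#'   `mean_F_by_generation`, `config`).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ideal <- !is.null(config$constant_size)

  n0 <- if (ideal) config$constant_size else config$n_founders
  id <- sprintf("F%03d", seq_len(n0))
  sire <- rep(NA_character_, n0)
  dam <- rep(NA_character_, n0)
  sex <- rep(c("male", "female"), length.out = n0)
  gen <- rep(0L, n0)
  locs <- sprintf("LOC%02d", seq_len(config$n_locations))
  loc <- sample(locs, n0, replace = TRUE)
  birth <- config$founder_year - 1900 + runif(n0, 0, 3)

  for (g in seq_len(config$n_generations)) {
    prev <- which(gen == g - 1L)
    sires_avail <- prev[sex[prev] == "male"]
    dams_avail <- prev[sex[prev] == "female"]
    if (length(sires_avail) == 0 || length(dams_avail) == 0)
      stop("population extinct at generation ", g)

    if (ideal) {
      N <- config$constant_size
      s_idx <- sample(sires_avail, N, replace = TRUE)
      d_idx <- sample(dams_avail, N, replace = TRUE)
      off_sex <- sample(rep(c("male", "female"), length.out = N))
    } else {
      noff <- rpois(length(dams_avail), config$offspring_mean)
      d_idx <- rep(dams_avail, noff)
      if (length(d_idx) == 0)
        stop("population extinct at generation ", g)
      s_idx <- .pick_sires(d_idx, sires_avail, config$mating,
                           id, sire, dam)
      off_sex <- ifelse(runif(length(d_idx)) < config$sex_ratio,
                        "male", "female")
    }
    k <- length(d_idx)
    off_id <- sprintf("G%d-%03d", g, seq_len(k))
    age_s <- pmax(2, rnorm(k, config$mean_parental_age, config$sd_parental_age))
    off_birth <- pmax(birth[s_idx], birth[d_idx]) + age_s
    off_loc <- loc[d_idx]
    moved <- runif(k) < config$transfer_prob
    if (any(moved) && length(locs) > 1) {
      off_loc[moved] <- vapply(off_loc[moved],
                               function(l) sample(setdiff(locs, l), 1), "")
    }
    id <- c(id, off_id); sire <- c(sire, id[s_idx]); dam <- c(dam, id[d_idx])
    sex <- c(sex, off_sex); gen <- c(gen, rep(g, k))
    loc <- c(loc, off_loc); birth <- c(birth, off_birth)
  }

  last_gens <- gen > config$n_generations - config$reference_generations
  pool <- which(last_gens)
  n_ref <- max(1L, round(config$reference_fraction * length(pool)))
  ref <- sort(sample(pool, n_ref))
  is_ref <- seq_along(id) %in% ref

  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   birth_date = format(.date_from_years(birth), "%Y-%m-%d"),
                   location = loc, is_reference = is_ref,
                   stringsAsFactors = FALSE)
  ped <- as_pedigree(df)
  attr(ped, "generation") <- stats::setNames(gen, id)

  F_true <- inbreeding(ped)
  truth <- list(
    generation = stats::setNames(gen, id),
    F_true = F_true,
    founder_contributions = founder_contributions(ped, id[is_ref]),
    mean_F_by_generation = vapply(0:config$n_generations,
                                  function(g) mean(F_true[id[gen == g]]), 0),
    config = config)

  if (length(config$missing_schedule) > 0) {
    ped <- censor(ped, config$missing_schedule)
    attr(ped, "generation") <- stats::setNames(gen, id)
  }
  list(pedigree = ped, truth = truth)
}

.pick_sires <- function(d_idx, sires_avail, mating, id, sire, dam) {
  k <- length(d_idx)
  if (mating == "random" || length(sires_avail) == 1)
    return(sample(sires_avail, k, replace = TRUE))
  if (mating == "full_sib_bias") {
    out <- integer(k)
    for (i in seq_len(k)) {
      d <- d_idx[i]
      sibs <- sires_avail[!is.na(sire[sires_avail]) & !is.na(sire[d]) &
                            sire[sires_avail] == sire[d] &
                            dam[sires_avail] == dam[d]]
      out[i] <- if (length(sibs) > 0 && runif(1) < 0.8)
        sibs[sample.int(length(sibs), 1)]
      else sample(sires_avail, 1)
    }
    return(out)
  }
  # min_kinship: each dam takes the least related available sire
  tmp <- suppressWarnings(
    pedigree(id = id, sire = sire, dam = dam))
  A <- .amatrix_all(tmp)
  out <- integer(k)
  for (i in seq_len(k)) {
    kin <- A[id[d_idx[i]], id[sires_avail]] / 2
    out[i] <- sires_avail[which.min(kin)]
  }
  out
}

#' Censor parent records on a per-cohort schedule
#'
#' Deletes parent links independently: a parent link of an animal in
#' backward birth cohort `b` (the youngest cohort is `b = 1`) is removed
#' with probability `schedule[b]` (the last entry applies beyond the
#' schedule's length). For the youngest animals the backward cohort
#' coincides with ancestor generation depth, so a schedule rising with `b`
#' reproduces the declining completeness curves of real studbooks; the
#' expected proportion of known ancestors at depth `g` is the product of
#' `1 - schedule[b]` over `b = 1..g`. Deleted parents become missing and
#' are replaced by phantom founders on reconstruction.
#'
#' @param ped a `pedigree`; cohorts are taken from its `generation`
#'   attribute when present, otherwise from topological depth.
#' @param schedule vector of deletion probabilities in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A censored `pedigree`.
#' @export
censor <- function(ped, schedule, seed = NULL) {
  stopifnot(is_pedigree(ped), all(schedule >= 0 & schedule <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (length(schedule) == 0) return(ped)
  gen <- attr(ped, "generation")
  if (is.null(gen)) {
    gen <- stats::setNames(.topo_depth(ped$id, ped$sire, ped$dam), ped$id)
  }
  real <- ped[!ped$phantom, , drop = FALSE]
  phantom_ids <- ped$id[ped$phantom]
  real$sire[real$sire %in% phantom_ids] <- NA_character_
  real$dam[real$dam %in% phantom_ids] <- NA_character_
  g <- gen[real$id]
  b <- max(g, na.rm = TRUE) - g + 1L
  p <- schedule[pmin(b, length(schedule))]
  drop_s <- runif(nrow(real)) < p
  drop_d <- runif(nrow(real)) < p
  real$sire[drop_s] <- NA_character_
  real$dam[drop_d] <- NA_character_
  real$birth_date <- format(real$birth_date, "%Y-%m-%d")
  real <- as.data.frame(real)[, .PED_COLS]
  out <- suppressWarnings(as_pedigree(real))
  attr(out, "generation") <- gen
  out
}
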