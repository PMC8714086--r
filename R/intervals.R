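# Generation intervals: mean parental age at offspring birth along the four
# parent-offspring pathways.

.PATHWAYS <- c("father-son", "father-daughter", "mother-son", "mother-daughter")

#' Generation intervals along the four pathways
#'
#' Mean age (years) of parents at the birth of their offspring, separately
#' for father-son, father-daughter, mother-son and mother-daughter pairs.
#' In `"reproducers"` mode only offspring that themselves have at least one
#' offspring in the pedigree (those reared for reproduction) are counted;
#' `"all"` keeps every offspring. Pairs with a missing parent, missing
#' dates or unknown offspring sex are excluded and counted; negative ages
#' (data errors) are excluded with a warning rather than clamped, because
#' validation owns the error.
#'
#' @param ped a `pedigree`.
#' @param mode `"reproducers"` or `"all"`.
#' @param ids restrict offspring to this id set (e.g. the reference
#'   population); default all non-phantom animals.
#' @return An `interval_table`: data frame with columns `pathway`, `n`,
#'   `mean`, `sd` (sample SD, years), one row per pathway plus `total`;
#'   attributes `mode` and `exclusions`.
#' @export
generation_intervals <- function(ped, mode = c("reproducers", "all"), ids = NULL) {
  stopifnot(is_pedigree(ped))
  mode <- match.arg(mode)
  if (is.null(ids)) ids <- ped$id[!ped$phantom]
  off <- ped[ped$id %in% ids & !ped$phantom, , drop = FALSE]

  if (mode == "reproducers") {
    parents <- unique(c(ped$sire, ped$dam))
    off <- off[off$id %in% parents, , drop = FALSE]
  }

  phantom_ids <- ped$id[ped$phantom]
  rows <- list()
  excl <- c(missing_dates = 0L, unknown_sex = 0L, negative_age = 0L)
  for (side in c("sire", "dam")) {
    par_id <- off[[side]]
    ok_par <- !is.na(par_id) & !(par_id %in% phantom_ids)
    sub <- off[ok_par, , drop = FALSE]
    par_birth <- ped$birth_date[match(sub[[side]], ped$id)]
    have_dates <- !is.na(par_birth) & !is.na(sub$birth_date)
    excl["missing_dates"] <- excl["missing_dates"] + sum(!have_dates)
    sub <- sub[have_dates, , drop = FALSE]
    par_birth <- par_birth[have_dates]
    known_sex <- sub$sex %in% c("male", "female")
    excl["unknown_sex"] <- excl["unknown_sex"] + sum(!known_sex)
    sub <- sub[known_sex, , drop = FALSE]
    par_birth <- par_birth[known_sex]
    age <- as.numeric(sub$birth_date - par_birth) / 365.25
    neg <- age <= 0
    if (any(neg)) {
      warning(sprintf("%d parent-offspring pair(s) with non-positive age excluded",
                      sum(neg)), call. = FALSE)
      excl["negative_age"] <- excl["negative_age"] + sum(neg)
      sub <- sub[!neg, , drop = FALSE]
      age <- age[!neg]
    }
    if (nrow(sub) > 0) {
      pw <- paste0(if (side == "sire") "father-" else "mother-",
                   ifelse(sub$sex == "male", "son", "daughter"))
      rows[[side]] <- data.frame(pathway = pw, age = age,
                                 stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows)
           else data.frame(pathway = character(0), age = numeric(0))

  stat <- function(a) c(n = length(a),
                        mean = if (length(a) > 0) mean(a) else NA_real_,
                        sd = if (length(a) > 1) stats::sd(a) else NA_real_)
  tab <- t(vapply(.PATHWAYS, function(p) stat(pairs$age[pairs$pathway == p]),
                  c(n = 0, mean = 0, sd = 0)))
  tab <- rbind(tab, total = stat(pairs$age))
  out <- data.frame(pathway = rownames(tab), n = as.integer(tab[, "n"]),
                    mean = tab[, "mean"], sd = tab[, "sd"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, mode = mode, exclusions = excl, pairs = pairs,
            class = c("interval_table", "data.frame"))
}

#' @export
print.interval_table <- function(x, ...) {
  cat(sprintf("Generation intervals (%s mode), years:\n", attr(x, "mode")))
  print.data.frame(transform(as.data.frame(x),
                             mean = round(mean, 2), sd = round(sd, 2)))
  ex <- attr(x, "exclusions")
  if (sum(ex) > 0)
    cat("excluded pairs:", paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
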