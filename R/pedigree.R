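#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd setNames rnorm runif rpois as.dist hclust
#' @importFrom utils read.table write.table head
NULL

.SEXES <- c("male", "female", "unknown")
.PED_COLS <- c("id", "sire", "dam", "sex", "birth_date", "location", "is_reference")
.DEFAULT_MISSING <- c("0", "", "NA", "NULL")

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1", "s", "sire")] <- "male"
  out[x %in% c("f", "female", "2", "d", "dam")] <- "female"
  out
}

.normalize_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y")
}

# Studbooks often record only a birth year; such dates resolve to July 1
# (the midpoint of the year) so that age arithmetic stays unbiased.
.parse_dates <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  year_only <- !is.na(x) & grepl("^\\d{4}$", x)
  if (any(year_only)) {
    warning(sprintf("%d year-only birth date(s) resolved to July 1", sum(year_only)),
            call. = FALSE)
    x[year_only] <- paste0(x[year_only], "-07-01")
  }
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x)
  if (any(ok)) {
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      warning(sprintf("%d unparseable birth date(s) set to missing", sum(is.na(parsed))),
              call. = FALSE)
    }
    out[ok] <- parsed
  }
  out
}

# Topological depth of every animal (founders at 0); returns NULL on a cycle.
.topo_depth <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  depth <- rep(0L, n)
  for (iter in seq_len(n + 1L)) {
    nd <- pmax(ifelse(is.na(si), -1L, depth[si]),
               ifelse(is.na(di), -1L, depth[di])) + 1L
    nd <- pmax(nd, 0L)
    if (all(nd == depth)) return(depth)
    depth <- nd
  }
  NULL
}

#' Construct a pedigree from a data frame
#'
#' Normalizes missing-value codes, creates one unique phantom founder per
#' single missing parent slot, adds founder records for parents referenced
#' but never defined as rows, and places the records in topological order
#' (every parent before all of its offspring).
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `birth_date`, `location`, `is_reference`.
#' @param missing_codes character vector of tokens treated as a missing
#'   parent / value.
#' @return An object of class `pedigree`: a data frame in topological order
#'   with columns `id`, `sire`, `dam`, `sex`, `birth_date`, `location`,
#'   `is_reference`, `phantom`, plus attributes `input_order` and `cyclic`.
#' @export
as_pedigree <- function(df, missing_codes = .DEFAULT_MISSING) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  unknown <- setdiff(names(df), .PED_COLS)
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         "; accepted columns are: ", paste(.PED_COLS, collapse = ", "))
  }
  for (col in c("id", "sire", "dam")) {
    if (!col %in% names(df)) {
      if (col == "id") stop("required column 'id' is missing")
      df[[col]] <- NA_character_
    }
    df[[col]] <- trimws(as.character(df[[col]]))
  }
  df$sire[df$sire %in% missing_codes] <- NA_character_
  df$dam[df$dam %in% missing_codes] <- NA_character_
  if (any(df$id %in% missing_codes) || any(is.na(df$id)) || any(df$id == ""))
    stop("animal ids must be non-empty and distinct from missing codes")
  if (anyDuplicated(df$id))
    stop("duplicate animal id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))

  sex <- if ("sex" %in% names(df)) .normalize_sex(df$sex) else rep("unknown", nrow(df))
  birth <- if ("birth_date" %in% names(df)) .parse_dates(df$birth_date)
           else as.Date(rep(NA_character_, nrow(df)))
  loc <- if ("location" %in% names(df)) {
    l <- trimws(as.character(df$location)); l[l %in% missing_codes] <- NA_character_; l
  } else rep(NA_character_, nrow(df))
  refflag <- if ("is_reference" %in% names(df)) .normalize_logical(df$is_reference)
             else rep(FALSE, nrow(df))

  ped <- data.frame(id = df$id, sire = df$sire, dam = df$dam, sex = sex,
                    birth_date = birth, location = loc, is_reference = refflag,
                    phantom = FALSE, stringsAsFactors = FALSE)
  input_order <- ped$id

  # Parents referenced but never defined become founder records: an ancestor
  # with unknown parents is a founder by convention.
  undef_sires <- setdiff(ped$sire[!is.na(ped$sire)], ped$id)
  undef_dams <- setdiff(ped$dam[!is.na(ped$dam)], ped$id)
  if (length(undef_sires) + length(undef_dams) > 0) {
    warning(sprintf("%d parent id(s) never defined as rows; added as founder records",
                    length(undef_sires) + length(undef_dams)), call. = FALSE)
    add <- data.frame(
      id = c(undef_sires, undef_dams),
      sire = NA_character_, dam = NA_character_,
      sex = c(rep("male", length(undef_sires)), rep("female", length(undef_dams))),
      birth_date = as.Date(NA), location = NA_character_,
      is_reference = FALSE, phantom = FALSE, stringsAsFactors = FALSE)
    ped <- rbind(ped, add)
  }

  # One unique phantom founder per single missing parent slot; phantoms are
  # never shared so they carry no relatedness.
  one_miss_s <- which(is.na(ped$sire) & !is.na(ped$dam))
  one_miss_d <- which(is.na(ped$dam) & !is.na(ped$sire))
  if (length(one_miss_s) + length(one_miss_d) > 0) {
    pid_s <- if (length(one_miss_s)) paste0("~S:", ped$id[one_miss_s]) else character(0)
    pid_d <- if (length(one_miss_d)) paste0("~D:", ped$id[one_miss_d]) else character(0)
    ped$sire[one_miss_s] <- pid_s
    ped$dam[one_miss_d] <- pid_d
    add <- data.frame(
      id = c(pid_s, pid_d),
      sire = NA_character_, dam = NA_character_,
      sex = c(rep("male", length(pid_s)), rep("female", length(pid_d))),
      birth_date = as.Date(NA), location = NA_character_,
      is_reference = FALSE, phantom = TRUE, stringsAsFactors = FALSE)
    ped <- rbind(ped, add)
  }

  depth <- .topo_depth(ped$id, ped$sire, ped$dam)
  cyclic <- is.null(depth)
  if (!cyclic) {
    ord <- order(depth, match(ped$id, c(input_order, sort(setdiff(ped$id, input_order)))))
    ped <- ped[ord, , drop = FALSE]
  }
  rownames(ped) <- NULL
  structure(ped, input_order = input_order, cyclic = cyclic,
            class = c("pedigree", "data.frame"))
}

#' Build a pedigree from vectors
#'
#' Convenience constructor, mainly for examples and tests.
#'
#' @param id,sire,dam,sex,birth_date,location,is_reference record fields;
#'   parent vectors may use `NA` or any accepted missing code.
#' @param ... passed to [as_pedigree()].
#' @return A `pedigree` object.
#' @examples
#' pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"), dam = c(NA, NA, "B"))
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = NULL, birth_date = NULL,
                     location = NULL, is_reference = NULL, ...) {
  df <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(birth_date)) df$birth_date <- as.character(birth_date)
  if (!is.null(location)) df$location <- location
  if (!is.null(is_reference)) df$is_reference <- is_reference
  as_pedigree(df, ...)
}

#' Read a studbook pedigree file
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) with columns `id`, `sire`, `dam` and optionally `sex`,
#' `birth_date`, `location`, `is_reference`.
#'
#' @param path file path.
#' @param missing_codes tokens treated as missing (default `"0"`, `""`,
#'   `"NA"`, `"NULL"`).
#' @param sep field separator; `NULL` autodetects.
#' @return A `pedigree` object; the file's row order is kept in the
#'   `input_order` attribute.
#' @export
read_pedigree <- function(path, missing_codes = .DEFAULT_MISSING, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", na.strings = character(0),
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_pedigree(df, missing_codes = missing_codes)
}

#' Write a pedigree back to delimited text
#'
#' Writes the non-phantom records in the original input order; phantom
#' parents are encoded as the missing code so that a parse/write/parse
#' round trip reproduces the pedigree exactly.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @param sep field separator.
#' @param missing_code token written for a missing parent.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, sep = ",", missing_code = "0") {
  stopifnot(is_pedigree(ped))
  out <- ped[!ped$phantom, .PED_COLS, drop = FALSE]
  ord <- match(attr(ped, "input_order"), out$id)
  ord <- c(ord[!is.na(ord)], setdiff(seq_len(nrow(out)), ord))
  out <- out[ord, , drop = FALSE]
  out$sire[out$sire %in% ped$id[ped$phantom]] <- NA_character_
  out$dam[out$dam %in% ped$id[ped$phantom]] <- NA_character_
  out$sire[is.na(out$sire)] <- missing_code
  out$dam[is.na(out$dam)] <- missing_code
  out$birth_date <- ifelse(is.na(out$birth_date), "",
                           format(out$birth_date, "%Y-%m-%d"))
  out$location[is.na(out$location)] <- ""
  out$is_reference <- ifelse(out$is_reference, "TRUE", "FALSE")
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  n <- sum(!x$phantom)
  cat(sprintf("Pedigree: %d animals (%d phantom founders), %d founders, %d reference\n",
              n, sum(x$phantom), length(founder_ids(x)), sum(x$is_reference)))
  if (isTRUE(attr(x, "cyclic"))) cat("WARNING: ancestry graph contains a cycle\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Test for the pedigree class
#' @param x object.
#' @return `TRUE` if `x` is a `pedigree`.
#' @export
is_pedigree <- function(x) inherits(x, "pedigree")

#' Founder ids of a pedigree
#'
#' Founders are the animals with both parents unrecorded, including phantom
#' founders created for single missing parent slots.
#'
#' @param ped a `pedigree`.
#' @param phantoms include phantom founders (default `TRUE`).
#' @return Character vector of ids.
#' @export
founder_ids <- function(ped, phantoms = TRUE) {
  stopifnot(is_pedigree(ped))
  f <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  if (!phantoms) f <- setdiff(f, ped$id[ped$phantom])
  f
}

#' Reference population ids
#' @param ped a `pedigree`.
#' @return Character vector of flagged ids.
#' @export
reference_ids <- function(ped) {
  stopifnot(is_pedigree(ped))
  ped$id[ped$is_reference]
}

#' Ancestor closure of a set of animals
#'
#' @param ped a `pedigree`.
#' @param ids focal animal ids.
#' @param include_self keep the focal ids in the result (default `TRUE`).
#' @return Character vector: `ids` together with every ancestor (phantoms
#'   included). Closing the closure again changes nothing.
#' @export
ancestor_closure <- function(ped, ids, include_self = TRUE) {
  stopifnot(is_pedigree(ped))
  if (!all(ids %in% ped$id)) stop("unknown id(s): ",
                                  paste(setdiff(ids, ped$id), collapse = ", "))
  seen <- unique(ids)
  frontier <- seen
  while (length(frontier) > 0) {
    i <- match(frontier, ped$id)
    parents <- unique(c(ped$sire[i], ped$dam[i]))
    parents <- parents[!is.na(parents)]
    frontier <- setdiff(parents, seen)
    seen <- c(seen, frontier)
  }
  if (!include_self) seen <- setdiff(seen, ids)
  ped$id[ped$id %in% seen]  # pedigree (topological) order
}

#' Extract the reference population with its ancestor closure
#'
#' Returns the subset of the pedigree needed to analyse the reference
#' population: the flagged animals plus every ancestor (phantoms included).
#' All diversity functions accept either the full pedigree or this view.
#'
#' @param ped a `pedigree` with at least one `is_reference` flag set (or
#'   explicit `ids`).
#' @param ids optional explicit focal id set overriding the flags.
#' @return A `pedigree` restricted to the closure, in topological order.
#' @export
extract_reference <- function(ped, ids = NULL) {
  stopifnot(is_pedigree(ped))
  if (is.null(ids)) ids <- reference_ids(ped)
  if (length(ids) == 0) stop("reference set is empty")
  keep <- ancestor_closure(ped, ids)
  out <- ped[ped$id %in% keep, , drop = FALSE]
  out$is_reference <- out$id %in% ids
  rownames(out) <- NULL
  structure(out,
            input_order = intersect(attr(ped, "input_order"), out$id),
            cyclic = isTRUE(attr(ped, "cyclic")), view = TRUE,
            class = c("pedigree", "data.frame"))
}

#' Validate a pedigree
#'
#' Checks acyclicity, self-parentage, sex-role consistency (no id used both
#' as sire and dam; recorded sex matching the parental role) and birth-date
#' ordering (offspring born after both parents when dates are known).
#' Permissive mode (the default, since studbooks are rarely fully
#' consistent) downgrades sex and date violations to warnings.
#'
#' @param ped a `pedigree`.
#' @param mode `"permissive"` or `"strict"`.
#' @return A `validation_report`: list with `errors` and `warnings`, each a
#'   list of `(rule, ids)` entries. The pedigree is accepted iff `errors`
#'   is empty.
#' @export
validate_pedigree <- function(ped, mode = c("permissive", "strict")) {
  stopifnot(is_pedigree(ped))
  mode <- match.arg(mode)
  errors <- list()
  warnings <- list()
  add <- function(pool, rule, ids) c(pool, list(list(rule = rule, ids = ids)))

  self <- ped$id[!is.na(ped$sire) & ped$id == ped$sire |
                 !is.na(ped$dam) & ped$id == ped$dam]
  if (length(self) > 0) errors <- add(errors, "self-parentage", self)

  if (isTRUE(attr(ped, "cyclic")))
    errors <- add(errors, "ancestry cycle", character(0))

  real <- ped[!ped$phantom, ]
  as_sire <- unique(real$sire[!is.na(real$sire)])
  as_dam <- unique(real$dam[!is.na(real$dam)])
  both_roles <- setdiff(intersect(as_sire, as_dam), ped$id[ped$phantom])
  sex_bad <- c(ped$id[ped$id %in% as_sire & ped$sex == "female" & !ped$phantom],
               ped$id[ped$id %in% as_dam & ped$sex == "male" & !ped$phantom])
  sex_viol <- unique(c(both_roles, sex_bad))
  if (length(sex_viol) > 0) {
    if (mode == "strict") errors <- add(errors, "sex-role inconsistency", sex_viol)
    else warnings <- add(warnings, "sex-role inconsistency", sex_viol)
  }

  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  bad_date <- !is.na(ped$birth_date) &
    ((!is.na(si) & !is.na(ped$birth_date[si]) & ped$birth_date <= ped$birth_date[si]) |
     (!is.na(di) & !is.na(ped$birth_date[di]) & ped$birth_date <= ped$birth_date[di]))
  if (any(bad_date)) {
    if (mode == "strict") errors <- add(errors, "birth before parent", ped$id[bad_date])
    else warnings <- add(warnings, "birth before parent", ped$id[bad_date])
  }

  structure(list(errors = errors, warnings = warnings, mode = mode),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Pedigree validation (%s mode): %s\n", x$mode,
              if (length(x$errors) == 0) "ACCEPTED" else "REJECTED"))
  for (e in x$errors)
    cat("  error:", e$rule, "-", paste(e$ids, collapse = ", "), "\n")
  for (w in x$warnings)
    cat("  warning:", w$rule, "-", paste(w$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  j <- jsonlite::toJSON(list(accepted = length(report$errors) == 0,
                             mode = report$mode,
                             errors = report$errors, warnings = report$warnings),
                        auto_unbox = TRUE, null = "null")
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}
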