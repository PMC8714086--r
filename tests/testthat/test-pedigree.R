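test_that("parsing a minimal file yields founders and preserved records", {
  path <- write_ped_file(data.frame(id = c("A", "B", "C"),
                                    sire = c("0", "0", "A"),
                                    dam = c("0", "0", "B")))
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_setequal(founder_ids(ped), c("A", "B"))
  expect_false(any(ped$phantom))
})

test_that("undefined parents become founder records with a warning", {
  path <- write_ped_file(data.frame(id = c("A", "B", "C"),
                                    sire = c("0", "0", "X"),
                                    dam = c("0", "0", "B")))
  expect_warning(ped <- read_pedigree(path), "never defined")
  expect_equal(nrow(ped), 4)
  expect_true("X" %in% founder_ids(ped))
  expect_equal(ped$sex[ped$id == "X"], "male")
})

test_that("a single missing parent gets a unique unshared phantom founder", {
  ped <- pedigree(id = c("A", "C", "D"), sire = c(NA, "A", "A"),
                  dam = c(NA, NA, NA))
  phantoms <- ped$id[ped$phantom]
  expect_length(phantoms, 2)           # one per missing slot, never shared
  expect_setequal(ped$dam[ped$id %in% c("C", "D")], phantoms)
  expect_setequal(founder_ids(ped), c("A", phantoms))
  expect_setequal(founder_ids(ped, phantoms = FALSE), "A")
})

test_that("rows listed before their parents are topologically reordered", {
  path <- write_ped_file(data.frame(id = c("C", "A", "B"),
                                    sire = c("A", "0", "0"),
                                    dam = c("B", "0", "0")))
  ped <- read_pedigree(path)
  expect_true(which(ped$id == "A") < which(ped$id == "C"))
  expect_true(which(ped$id == "B") < which(ped$id == "C"))
  expect_equal(attr(ped, "input_order"), c("C", "A", "B"))
})

test_that("duplicate ids and unknown columns are hard errors", {
  expect_error(pedigree(id = c("A", "A"), sire = NA, dam = NA), "duplicate")
  path <- write_ped_file(data.frame(id = "A", sire = "0", dam = "0",
                                    colour = "golden"))
  expect_error(read_pedigree(path), "unknown column.*accepted")
})

test_that("parse -> write -> parse round trip is the identity", {
  df <- data.frame(id = c("A", "B", "C", "D"),
                   sire = c("0", "0", "A", "A"),
                   dam = c("0", "0", "B", "0"),
                   sex = c("male", "female", "female", "male"),
                   birth_date = c("2000-01-01", "2001-07-02", "2005-03-04", ""),
                   location = c("ZooA", "ZooB", "ZooA", ""),
                   is_reference = c("FALSE", "FALSE", "TRUE", "TRUE"))
  ped1 <- as_pedigree(df)
  out <- tempfile(fileext = ".csv")
  write_pedigree(ped1, out)
  ped2 <- read_pedigree(out)
  expect_equal(as.data.frame(ped1), as.data.frame(ped2))
  expect_equal(attr(ped1, "input_order"), attr(ped2, "input_order"))
})

test_that("year-only dates resolve to July 1 with a warning", {
  expect_warning(
    ped <- pedigree(id = c("A", "B"), sire = NA, dam = NA,
                    birth_date = c("1995", "1995-02-03")),
    "July 1")
  expect_equal(ped$birth_date[ped$id == "A"], as.Date("1995-07-01"))
})

test_that("validation flags cycles, dates and sex-role inconsistencies", {
  cyc <- pedigree(id = c("A", "B"), sire = c("B", "A"), dam = c(NA, NA))
  rep <- validate_pedigree(cyc)
  expect_true(any(vapply(rep$errors, function(e) e$rule, "") == "ancestry cycle"))

  # offspring born before its dam: warning permissive, error strict
  bad <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                  dam = c(NA, NA, "B"), sex = c("male", "female", "male"),
                  birth_date = c("2000-01-01", "2010-01-01", "2005-01-01"))
  expect_length(validate_pedigree(bad, "permissive")$errors, 0)
  expect_true(length(validate_pedigree(bad, "permissive")$warnings) > 0)
  expect_true(length(validate_pedigree(bad, "strict")$errors) > 0)

  # same id used as sire and dam
  mix <- pedigree(id = c("P", "C1", "C2"), sire = c(NA, "P", NA),
                  dam = c(NA, NA, "P"))
  expect_true(length(validate_pedigree(mix, "permissive")$warnings) > 0)
  expect_true(length(validate_pedigree(mix, "strict")$errors) > 0)

  clean <- full_sib_ped()
  repc <- validate_pedigree(clean)
  expect_length(repc$errors, 0)
  expect_length(repc$warnings, 0)
})

test_that("reference extraction closes over ancestors, phantoms included", {
  ped <- full_sib_ped()
  ped$is_reference <- ped$id == "E"
  view <- extract_reference(ped)
  expect_setequal(view$id, c("A", "B", "C", "D", "E"))

  # reference animal with a phantom parent: the phantom is in the closure
  ped2 <- pedigree(id = c("A", "C"), sire = c(NA, "A"), dam = c(NA, NA),
                   is_reference = c(FALSE, TRUE))
  view2 <- extract_reference(ped2)
  expect_equal(sort(view2$id), oracle_closure(ped2, "C"))
  expect_true(any(view2$phantom))

  # all flagged: view has the same animals as the pedigree
  ped3 <- full_sib_ped(); ped3$is_reference <- TRUE
  expect_setequal(extract_reference(ped3)$id, ped3$id)
  expect_error(extract_reference(full_sib_ped()), "empty")
})

test_that("ancestor closure matches graph traversal and is a fixed point", {
  set.seed(42)
  for (i in 1:10) {
    ped <- rand_ped(10)
    ids <- sample(ped$id[!ped$phantom], 2)
    cl <- ancestor_closure(ped, ids)
    expect_setequal(cl, oracle_closure(ped, ids))
    expect_equal(ancestor_closure(ped, cl), cl)
  }
})

test_that("topological order exists exactly when validation finds no cycle", {
  set.seed(7)
  for (i in 1:10) {
    ped <- rand_ped(8)
    expect_false(isTRUE(attr(ped, "cyclic")))
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
    pos <- seq_len(nrow(ped))
    expect_true(all(is.na(si) | pos[si] < pos))
    expect_true(all(is.na(di) | pos[di] < pos))
  }
  expect_true(isTRUE(attr(pedigree(id = c("A", "B"), sire = c("B", "A"),
                                   dam = c(NA, NA)), "cyclic")))
})
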