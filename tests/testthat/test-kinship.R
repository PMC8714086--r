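test_that("classic inbreeding values are reproduced exactly", {
  expect_equal(unname(inbreeding(full_sib_ped())["E"]), 0.25)
  expect_equal(unname(inbreeding(half_sib_ped())["E"]), 0.125)
  expect_equal(unname(inbreeding(parent_offspring_ped())["D"]), 0.25)
})

test_that("tabular relationships match the fixture hand values", {
  ks <- relationship_matrix(full_sib_ped())
  expect_equal(ks$A["C", "A"], 0.5)
  expect_equal(ks$A["C", "D"], 0.5)
  expect_equal(ks$A["E", "E"], 1.25)
  expect_true(isSymmetric(ks$A))
  expect_equal(relationship_matrix(pedigree(id = c("A", "B"), sire = NA,
                                            dam = NA))$A, diag(2),
               ignore_attr = "dimnames")
})

test_that("tabular F equals Wright path counting on random small pedigrees", {
  set.seed(101)
  for (i in 1:40) {
    ped <- rand_ped(sample(6:12, 1))
    expect_equal(inbreeding(ped), oracle_inbreeding(ped), tolerance = 1e-12)
  }
})

test_that("F of an animal equals the co-ancestry of its parents", {
  set.seed(23)
  for (i in 1:10) {
    ped <- rand_ped(10)
    ks <- relationship_matrix(ped)
    kids <- ped$id[!is.na(ped$sire) & !ped$phantom]
    for (x in kids) {
      s <- ped$sire[ped$id == x]; d <- ped$dam[ped$id == x]
      if (ped$phantom[ped$id == s] || ped$phantom[ped$id == d]) next
      expect_equal(ks$F[[x]], ks$A[s, d] / 2)
    }
  }
})

test_that("average relatedness matches direct row means of A", {
  # single founder alone: only the self term
  expect_equal(unname(average_relatedness(pedigree("A", NA, NA))), 0.5)
  ped <- pedigree(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                  dam = c(NA, NA, "B"))
  ar <- average_relatedness(ped)
  expect_equal(unname(ar["A"]), (1 + 0 + 0.5) / 6)
  expect_equal(unname(ar["C"]), (0.5 + 0.5 + 1) / 6)
  # mean AR over all animals = mean of A / 2
  set.seed(31)
  ped2 <- rand_ped(12)
  ks <- relationship_matrix(ped2)
  expect_equal(mean(ks$AR), mean(ks$A) / 2)
})

test_that("relationship matrices stay positive semi-definite", {
  set.seed(37)
  for (i in 1:10) {
    ped <- rand_ped(12)
    ev <- eigen(relationship_matrix(ped)$A, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(min(ev) >= -1e-8)
  }
})

test_that("individual increase in inbreeding follows its closed form", {
  ped <- full_sib_ped()
  dF <- delta_f_individual(ped)
  t_E <- equivalent_generations(ped)[["E"]]
  expect_equal(unname(dF["E"]), 1 - (1 - 0.25)^(1 / (t_E - 1)))
  expect_true(all(is.na(dF[c("A", "B")])))      # t <= 1: undefined
  expect_equal(unname(dF["C"]), NA_real_)       # t = 1 exactly
})

test_that("generation-mean rate of inbreeding matches the ratio form", {
  ped <- full_sib_ped()
  res <- delta_f_generations(ped,
                             generations = setNames(c(0, 0, 1, 1, 2), ped$id))
  # cohort means (0, 0, 0.25): rates 0 and 0.25
  expect_equal(res$table$mean_F, c(0, 0, 0.25))
  expect_equal(res$table$dF[-1], c(0, 0.25))
  # non-inbred base generation: rate equals the raw difference
  expect_equal((0.1 - 0) / (1 - 0), 0.1)
})

test_that("Ne from mean increases behaves as 1/(2 dF) with exclusions", {
  # every animal with dF = 0 -> infinite Ne, flagged not crashed
  ped <- full_sib_ped()
  expect_equal(ne_from_delta_f(ped, "E")$ne,
               1 / (2 * delta_f_individual(ped)[["E"]]))
  expect_error(ne_from_delta_f(pedigree(c("A", "B"), NA, NA)), "no animal")

  # co-ancestry pair form: c = 0.25 at mean generation 2
  ped2 <- full_sib_ped()
  ne2 <- ne_from_coancestry(ped2, c("C", "D"))
  dc <- 1 - (1 - 0.25)^(1 / 1)   # g_C = g_D = 1
  expect_equal(ne2$ne, 1 / (2 * dc))
  expect_equal(ne2$n_used, 1L)
  # unrelated non-founder pair: zero increase, infinite Ne
  expect_equal(ne_from_coancestry(two_family_ped(), c("E", "G"))$ne, Inf)
  # founder-only pairs have no usable generations
  expect_error(ne_from_coancestry(ped2, c("A", "B")), "no usable pair")
})

test_that("Ne estimators are invariant to relabeling and row order", {
  set.seed(43)
  ped <- rand_ped(12)
  df <- as.data.frame(ped[!ped$phantom, c("id", "sire", "dam", "sex")])
  relabel <- setNames(sprintf("Z%02d", seq_len(nrow(df))), df$id)
  df2 <- data.frame(id = relabel[df$id],
                    sire = ifelse(is.na(df$sire), NA, relabel[df$sire]),
                    dam = ifelse(is.na(df$dam), NA, relabel[df$dam]),
                    sex = df$sex)
  df2 <- df2[rev(seq_len(nrow(df2))), ]
  ped2 <- as_pedigree(df2)
  ids1 <- df$id[!is.na(df$sire)]
  ids2 <- unname(relabel[ids1])
  expect_equal(ne_from_delta_f(ped, ids1)$ne, ne_from_delta_f(ped2, ids2)$ne)
  expect_equal(ne_from_coancestry(ped, ids1)$ne,
               ne_from_coancestry(ped2, ids2)$ne)
})

test_that("inbreeding classes partition animals by level and sex", {
  f <- c(a = 0, b = 0.05, c = 0.25)
  sex <- c(a = "male", b = "female", c = "male")
  tab <- inbreeding_classes(f, sex)
  expect_equal(tab$total, c(1L, 1L, 1L))
  expect_equal(tab$male, c(1L, 0L, 1L))
  expect_equal(tab$female, c(0L, 1L, 0L))
  # founders only: everything in the first class
  tab2 <- inbreeding_classes(c(x = 0, y = 0))
  expect_equal(tab2$total, c(2L, 0L, 0L))
  # boundary: F = 0.13 goes to the top class, F = 1 stays inside
  tab3 <- inbreeding_classes(c(x = 0.13, y = 1))
  expect_equal(tab3$total, c(0L, 0L, 2L))
  expect_error(inbreeding_classes(f, bounds = c(0.5, 0.2)), "increasing")
})
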