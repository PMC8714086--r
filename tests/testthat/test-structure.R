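test_that("subpopulation co-ancestry means match direct averaging", {
  # two singleton groups of unrelated non-inbred founders
  two <- pedigree(id = c("A", "B"), sire = NA, dam = NA,
                  sex = c("male", "female"))
  co <- subpop_coancestry(two, setNames(c("g1", "g2"), c("A", "B")))
  expect_equal(co$f, matrix(c(0.5, 0, 0, 0.5), 2, 2,
                            dimnames = list(c("g1", "g2"), c("g1", "g2"))))

  # one set of animals duplicated under two labels: all means equal
  ped <- full_sib_ped()
  grp <- setNames(c("x", "x", "y", "y"), c("C", "D", "C", "D"))
  co2 <- subpop_coancestry(ped, setNames(rep(c("x", "y"), each = 2),
                                         rep(c("C", "D"), 2)))
  expect_equal(co2$f["x", "x"], co2$f["y", "y"])
  expect_equal(co2$f["x", "y"], co2$f["x", "x"])

  # hand-computed mean over the 2x2 block C,D vs E
  ks <- relationship_matrix(ped)
  co3 <- subpop_coancestry(ped, setNames(c("cd", "cd", "e"),
                                         c("C", "D", "E")))
  expect_equal(co3$f["cd", "e"], mean(ks$A[c("C", "D"), "E"]) / 2)
  expect_equal(co3$f["cd", "cd"], mean(ks$A[c("C", "D"), c("C", "D")]) / 2)
})

test_that("pairwise FST spans its theoretical range", {
  # identical subpopulations: 0
  ped <- full_sib_ped()
  co <- subpop_coancestry(ped, setNames(rep(c("x", "y"), each = 2),
                                        rep(c("C", "D"), 2)))
  fst <- pairwise_fst(co)
  expect_equal(fst["x", "y"], 0)
  # unrelated non-inbred singletons: D = 0.5, FST = 1
  two <- pedigree(id = c("A", "B"), sire = NA, dam = NA)
  fst2 <- pairwise_fst(subpop_coancestry(two, setNames(c("g1", "g2"),
                                                       c("A", "B"))))
  expect_equal(fst2["g1", "g2"], 1)
  expect_equal(unname(diag(fst2)), c(0, 0))
  # FST decreases monotonically as between-group co-ancestry rises
  f <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  vals <- vapply(seq(0, 0.5, by = 0.1), function(b) {
    f[1, 2] <- f[2, 1] <- b
    pairwise_fst(f)[1, 2]
  }, 0)
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[length(vals)], 0)
})

test_that("FST is robust to duplicating every animal within groups", {
  ped <- two_family_ped()
  g1 <- setNames(c("f1", "f1", "f2", "f2"), c("E", "F", "G", "H"))
  g2 <- setNames(c("f1", "f1", "f1", "f1", "f2", "f2", "f2", "f2"),
                 c("E", "F", "E", "F", "G", "H", "G", "H"))
  f1 <- pairwise_fst(subpop_coancestry(ped, g1))
  # duplication at the mean level: grouping vector lists each animal twice
  co2 <- subpop_coancestry(ped, g2)
  expect_equal(pairwise_fst(co2), f1)
})

test_that("UPGMA joins the closest pair first and yields valid Newick", {
  fst <- matrix(c(0, 0.02, 0.3,
                  0.02, 0, 0.3,
                  0.3, 0.3, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- fst_dendrogram(fst)
  expect_equal(dend$hclust$merge[1, ], c(-1, -2))  # A and B join first
  expect_equal(dend$hclust$height[1], 0.02)
  expect_equal(dend$hclust$height[2], 0.3)
  expect_true(!is.unsorted(dend$hclust$height))    # ultrametric heights
  phy <- ape::read.tree(text = dend$newick)
  expect_setequal(phy$tip.label, c("A", "B", "C"))

  # permuting group order yields an isomorphic tree
  perm <- c("C", "A", "B")
  dend2 <- fst_dendrogram(fst[perm, perm])
  expect_true(ape::all.equal.phylo(ape::read.tree(text = dend2$newick),
                                   phy, use.edge.length = FALSE))

  # star case: all distances zero
  z <- matrix(0, 3, 3, dimnames = dimnames(fst))
  expect_equal(fst_dendrogram(z)$hclust$height, c(0, 0))
  fst_na <- fst; fst_na[1, 3] <- fst_na[3, 1] <- NA
  expect_error(fst_dendrogram(fst_na), "missing FST")
})

test_that("relationship PCA embeds families and reconstructs the matrix", {
  ped <- two_family_ped()
  ids <- c("E", "F", "G", "H")
  p <- relationship_pca(ped, ids, k = 2)
  # PC1 separates the two unrelated families with opposite signs
  expect_true(prod(sign(p$coords[c("E", "G"), 1])) < 0)
  expect_equal(sign(p$coords["E", 1]), sign(p$coords["F", 1]))
  expect_equal(sum(p$var_explained), 1)
  expect_true(all(p$var_explained >= 0))

  # full eigen reconstruction of the centered matrix
  ks <- relationship_matrix(ped, ids)
  n <- length(ids)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% ks$A %*% C
  full <- relationship_pca(ped, ids, k = n)
  recon <- full$coords %*% t(full$coords)
  expect_lt(max(abs(recon - G)), 1e-8)

  # full sibs coincide on the family axis and mirror on the sib axis
  expect_equal(p$coords["E", 1], p$coords["F", 1])
  expect_equal(abs(p$coords["E", 2]), abs(p$coords["F", 2]))
  expect_warning(relationship_pca(ped, ids, k = 10), "truncated")
})

test_that("heatmap matrix is the reordered relationship submatrix", {
  ped <- two_family_ped()
  ids <- c("E", "G", "F", "H")
  hm <- ar_heatmap_matrix(ped, ids)
  expect_setequal(hm$ordering, ids)
  ks <- relationship_matrix(ped, ids)
  expect_equal(hm$matrix, ks$A[hm$ordering, hm$ordering])
  # family members end up adjacent in the leaf order
  pos <- match(c("E", "F", "G", "H"), hm$ordering)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)
})
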