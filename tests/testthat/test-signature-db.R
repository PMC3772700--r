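test_that("signature building applies the >=2-leaf filter and LCA placement", {
  tr <- toyTree()
  base <- list(A = strrep("G", 40), B = strrep("H", 40),
               C = strrep("I", 40), D = strrep("S", 40))
  plant <- function(refs, leaves, pep) {
    for (l in leaves) refs[[l]] <- c(refs[[l]], paste0(strrep("W", 10), pep))
    refs
  }
  ## present in A and B -> placed at their parent clade
  refs <- plant(base, c("A", "B"), "ACDEFGHIKL")
  db <- buildSignatureDB(refs, tr)
  expect_equal(unname(nodeAssignments(db)["ACDEFGHIKL"]), nodeId(tr, "N1"))
  ## present twice in A only (paralogs) -> discarded
  refs2 <- base
  refs2$A <- c(refs2$A, "QACDEFGHIKLQ", "WACDEFGHIKLW")
  db2 <- buildSignatureDB(refs2, tr)
  expect_false("ACDEFGHIKL" %in% peptides(db2))
  ## present in all four leaves -> root
  refs3 <- plant(base, c("A", "B", "C", "D"), "ACDEFGHIKL")
  db3 <- buildSignatureDB(refs3, tr)
  expect_equal(unname(nodeAssignments(db3)["ACDEFGHIKL"]), treeRoot(tr))
  ## unknown leaf is a configuration error naming the leaf
  expect_error(buildSignatureDB(list(Z = "ACDEFGHIKLM"), tr), "Z")
})

test_that("signature building equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (rep in 1:4) {
    ntips <- sample(4:8, 1)
    phy <- ape::rtree(ntips)
    tr <- signatureTreeFromPhylo(phy)
    k <- 4L  # short k so random leaves genuinely share k-mers
    refs <- lapply(setNames(nm = names(treeLeaves(tr))), function(l)
      randomProteins(3, 60))
    db <- buildSignatureDB(refs, tr, k = k)
    oracle <- oracleSignatures(refs, tr, k)
    expect_equal(peptides(db), oracle$peptide)
    expect_equal(unname(nodeAssignments(db)), oracle$node)
    ## every stored peptide is an internal-node assignment backed by >= 2 leaves
    expect_true(all(lengths(db@coverage) >= 2L))
    expect_true(all(!isLeaf(tr, unname(nodeAssignments(db)))))
  }
})

test_that("adding a leaf moves signatures only rootward (LCA monotonicity)", {
  set.seed(32)
  phy <- ape::rtree(6)
  tr <- signatureTreeFromPhylo(phy)
  leaves <- names(treeLeaves(tr))
  refs <- lapply(setNames(nm = leaves), function(l) randomProteins(3, 80))
  k <- 4L
  dbSmall <- buildSignatureDB(refs[leaves[-1]], tr, k = k)
  dbFull <- buildSignatureDB(refs, tr, k = k)
  common <- intersect(peptides(dbSmall), peptides(dbFull))
  expect_gt(length(common), 0L)
  for (p in common) {
    old <- nodeAssignments(dbSmall)[[p]]
    new <- nodeAssignments(dbFull)[[p]]
    ## new placement is an ancestor-or-self of the old one
    expect_true(new %in% oracleAncestors(tr, old))
  }
})

test_that("genus grouping can relax the distinct-leaf criterion", {
  tr <- readSignatureTree("((Ecoli1,Ecoli2)N1,(C,D)N2)R;")
  refs <- list(Ecoli1 = paste0("WW", "ACDEFGHIKL"),
               Ecoli2 = paste0("ACDEFGHIKL", "WW"),
               C = strrep("G", 30), D = strrep("H", 30))
  ## two leaves, one genus: kept under the leaf reading, dropped under genus
  genus <- c(Ecoli1 = "Escherichia", Ecoli2 = "Escherichia",
             C = "Cgen", D = "Dgen")
  dbLeaf <- buildSignatureDB(refs, tr)
  expect_true("ACDEFGHIKL" %in% peptides(dbLeaf))
  dbGenus <- buildSignatureDB(refs, tr, genusLabels = genus)
  expect_false("ACDEFGHIKL" %in% peptides(dbGenus))
})

test_that("functional annotation attaches all matching subsystems", {
  fx <- plantedFixture()
  db <- buildSignatureDB(fx$refs, fx$tree)
  db <- annotateSignatureFunctions(db, fx$annotated)
  ss <- subsystemSets(db)
  expect_equal(ss[["ACDEFGHIKL"]], c("S1", "S2"))
  expect_equal(ss[["MNPQRSTVWY"]], "S3")
  ## signatures absent from annotated gene sets keep an empty set
  dbNone <- annotateSignatureFunctions(db, list(S9 = strrep("W", 30)))
  expect_true(all(lengths(subsystemSets(dbNone)) == 0L))
  ## two overlapping signatures from one annotated gene share its subsystem
  tr <- toyTree()
  refs <- list(A = paste0("WW", "ACDEFGHIKLM"), B = paste0("ACDEFGHIKLM", "WW"),
               C = strrep("G", 30), D = strrep("H", 30))
  db2 <- buildSignatureDB(refs, tr)
  expect_setequal(peptides(db2), c("ACDEFGHIKL", "CDEFGHIKLM"))
  db2 <- annotateSignatureFunctions(db2, list(S1 = "QQACDEFGHIKLMQQ"))
  expect_equal(unname(lengths(subsystemSets(db2))), c(1L, 1L))
})

test_that("database TSV round-trips and malformed lines raise parse errors", {
  fx <- plantedFixture()
  db <- annotateSignatureFunctions(buildSignatureDB(fx$refs, fx$tree),
                                   fx$annotated)
  f <- tempfile(fileext = ".tsv")
  writeSignatureDB(db, f)
  db2 <- readSignatureDB(f, fx$tree)
  expect_equal(peptides(db2), peptides(db))
  expect_equal(nodeAssignments(db2), nodeAssignments(db))
  expect_equal(subsystemSets(db2), subsystemSets(db))
  expect_equal(dbK(db2), dbK(db))
  ## three valid lines parse to three entries
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("#k=10", "AAAAAAAAAA\t1", "CCCCCCCCCC\t2\tS1,S2",
               "DDDDDDDDDD\t3"), f2)
  expect_length(readSignatureDB(f2), 3L)
  ## short peptide, bad node id, and out-of-tree node are line errors
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("#k=10", "AAAAAAAAA\t1"), f3)
  expect_error(readSignatureDB(f3), "line 2")
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("#k=10", "AAAAAAAAAA\tx"), f4)
  expect_error(readSignatureDB(f4), "not an integer")
  f5 <- tempfile(fileext = ".tsv")
  writeLines(c("#k=10", "AAAAAAAAAA\t99"), f5)
  expect_error(readSignatureDB(f5, fx$tree), "not in tree")
})

test_that("shared k-mer prevalence tracks the random-match model", {
  ## random leaves share few k-mers; near-copy leaves share many
  tr <- toyTree()
  set.seed(33)
  refsRandom <- lapply(setNames(nm = names(treeLeaves(tr))), function(l)
    randomProteins(2, 500))
  k <- 4L
  dbRandom <- buildSignatureDB(refsRandom, tr, k = k)
  total4mers <- 4 * 2 * (500 - k + 1)
  ## expected shared pairs between two 1000-residue proteomes at k=4
  expPair <- expectedRandomMatches(1000, 1000, k)
  ## 6 leaf pairs; retained fraction must be small, near the model scale
  expect_lt(length(dbRandom) / total4mers, 0.2)
  expect_lt(length(dbRandom), 6 * expPair * 5)
  protein <- randomProteins(1, 500)
  refsCopy <- lapply(setNames(nm = names(treeLeaves(tr))), function(l) protein)
  dbCopy <- buildSignatureDB(refsCopy, tr, k = k)
  expect_gt(length(dbCopy) / (500 - k + 1), 0.9)
})
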