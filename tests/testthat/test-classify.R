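## Reads are built by embedding reverse-translated signature peptides in
## random DNA so each worked example controls exactly which signatures a
## read contains.

readWith <- function(..., pad = 30L, seed = 1L) {
  set.seed(seed)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  ## join peptide-coding stretches in one frame, stop-free, with DNA padding
  ## at the outside only so the fragment stays >= 15 residues
  core <- reverseTranslate(paste0(...))
  paste0(bg(pad), core, bg(pad))
}

fixtureDB <- function() {
  fx <- plantedFixture()
  db <- annotateSignatureFunctions(buildSignatureDB(fx$refs, fx$tree),
                                   fx$annotated)
  list(fx = fx, db = db, tree = fx$tree)
}

test_that("single-node, monophyletic and polyphyletic evidence classify correctly", {
  env <- fixtureDB()
  tr <- env$tree
  pepN1 <- "ACDEFGHIKL"   # planted in A,B -> node N1
  pepN2 <- "MNPQRSTVWY"   # planted in C,D -> node N2
  pepR <- "LKIHGFEDCA"    # planted in all leaves -> root
  expect_equal(unname(nodeAssignments(env$db)[c(pepN1, pepN2, pepR)]),
               c(nodeId(tr, "N1"), nodeId(tr, "N2"), treeRoot(tr)))
  ## one signature at N1 -> that node, single-node evidence
  r1 <- classifyRead(readWith(pepN1, "AAAAA"), env$db, tr)
  expect_equal(r1$nodeId, nodeId(tr, "N1"))
  expect_equal(r1$evidence, "single-node")
  ## signatures at R and N1 -> deepest on the path, monophyletic
  r2 <- classifyRead(readWith(pepR, "GG", pepN1), env$db, tr)
  expect_equal(r2$nodeId, nodeId(tr, "N1"))
  expect_equal(r2$evidence, "monophyletic")
  ## signatures at N1 and N2 -> branch point (root), polyphyletic
  r3 <- classifyRead(readWith(pepN1, "GG", pepN2), env$db, tr)
  expect_equal(r3$nodeId, treeRoot(tr))
  expect_equal(r3$evidence, "polyphyletic")
  ## no signature -> unassigned
  r4 <- classifyRead(readWith("WWWWWWWWWWWWWWWW"), env$db, tr)
  expect_equal(r4$evidence, "none")
  expect_true(is.na(r4$nodeId))
})

test_that("classification is strand-invariant", {
  env <- fixtureDB()
  reads <- c(
    readWith("ACDEFGHIKL", "AAAAA", seed = 2),
    readWith("LKIHGFEDCA", "GG", "ACDEFGHIKL", seed = 3),
    readWith("ACDEFGHIKL", "GG", "MNPQRSTVWY", seed = 4),
    simulateReads(encodeGenome(env$fx$refs$A), 150, 10, seed = 5))
  for (r in reads) {
    fwd <- classifyRead(r, env$db, env$tree)
    rev <- classifyRead(revcomp(r), env$db, env$tree)
    expect_equal(fwd$nodeId, rev$nodeId)
    expect_equal(fwd$evidence, rev$evidence)
    expect_equal(fwd$nSignatures, rev$nSignatures)
  }
})

test_that("batch profiles conserve counts and flag skipped reads", {
  env <- fixtureDB()
  reads <- c(
    a = readWith("ACDEFGHIKL", seed = 6),
    b = readWith("MNPQRSTVWY", seed = 7),
    c = readWith("WWWWWWWWWWWWWWWW", seed = 8))
  res <- classifyReads(reads, env$db, env$tree)
  expect_equal(totalReads(res$profile), 3L)
  expect_equal(assignedReads(res$profile), 2L)
  expect_equal(sum(profileCounts(res$profile)), 2L)
  expect_equal(nrow(res$placements), 3L)
  ## empty input -> empty profile
  res0 <- classifyReads(character(0), env$db, env$tree)
  expect_equal(totalReads(res0$profile), 0L)
  expect_equal(assignedReads(res0$profile), 0L)
  ## invalid nucleotides: read skipped and counted, not fatal
  expect_warning(
    resBad <- classifyReads(c(ok = readWith("ACDEFGHIKL", seed = 9),
                              bad = "ACGT77ACGT"),
                            env$db, env$tree),
    "skipped")
  expect_equal(resBad$profile@skippedReads, 1L)
  expect_equal(totalReads(resBad$profile), 2L)
})

test_that("reads from a reference leaf always land on that leaf's root path", {
  env <- fixtureDB()
  tr <- env$tree
  pathA <- nodeAncestors(tr, treeLeaves(tr)[["A"]])
  genome <- encodeGenome(env$fx$refs$A)
  reads <- simulateReads(genome, 200, 120, seed = 10)
  res <- classifyReads(reads, env$db, tr)
  assigned <- res$placements$nodeId[!is.na(res$placements$nodeId)]
  expect_gt(length(assigned), 0L)
  expect_true(all(assigned %in% pathA))
})

test_that("assigned fraction grows with read length on a sparse fixture", {
  env <- fixtureDB()
  genome <- encodeGenome(env$fx$refs$A)
  frac <- sapply(c(60L, 150L, 400L), function(len) {
    reads <- simulateReads(genome, len, 150, seed = 12)
    res <- classifyReads(reads, env$db, env$tree)
    assignedReads(res$profile) / totalReads(res$profile)
  })
  expect_true(all(diff(frac) > 0))
})

test_that("functional assignment follows the per-frame intersection / union rule", {
  env <- fixtureDB()
  ## one forward frame carries signatures with sets {S1,S2} and {S1}
  ## (intersection {S1}); a reverse frame carries {S3}; the union has
  ## n = 2 members, each allotted 1/2
  fwd <- readWith("ACDEFGHIKL", "GG", "LKIHGFEDCA", seed = 13)
  r <- paste0(fwd, revcomp(readWith("MNPQRSTVWY", seed = 14)))
  fa2 <- functionalAssign(r, env$db)
  expect_equal(fa2[sort(names(fa2))], c(S1 = 0.5, S3 = 0.5))
  ## single signature with one subsystem -> weight 1
  fa3 <- functionalAssign(readWith("MNPQRSTVWY", seed = 15), env$db)
  expect_equal(fa3, c(S3 = 1))
  ## signatures without annotations yield no functional assignment
  dbBare <- buildSignatureDB(env$fx$refs, env$tree)
  fa4 <- functionalAssign(readWith("ACDEFGHIKL", seed = 16), dbBare)
  expect_length(fa4, 0L)
  ## per-read weights always sum to 1 when non-empty
  expect_equal(sum(fa2), 1)
})

test_that("within one frame annotated subsystem sets are intersected", {
  tr <- toyTree()
  ## two overlapping signatures from one gene: one labelled {S1,S2}, the
  ## other {S1}; sharing a frame they intersect to {S1}
  gene <- "ACDEFGHIKLM"
  refs <- list(A = paste0("WW", gene), B = paste0(gene, "WW"),
               C = strrep("G", 30), D = strrep("H", 30))
  db <- buildSignatureDB(refs, tr)
  db <- annotateSignatureFunctions(db, list(
    S1 = paste0("QQ", gene, "QQ"),           # contains both 10-mers
    S2 = paste0("QQ", "ACDEFGHIKL", "QQ")))  # contains only the first
  fa <- functionalAssign(readWith(gene, seed = 17), db)
  expect_equal(fa, c(S1 = 1))
})

test_that("functional profiles conserve the 1/n fractional counts exactly", {
  env <- fixtureDB()
  reads <- c(
    r1 = paste0(readWith("ACDEFGHIKL", seed = 18),
                revcomp(readWith("MNPQRSTVWY", seed = 19))),
    r2 = paste0(readWith("ACDEFGHIKL", seed = 20),
                revcomp(readWith("MNPQRSTVWY", seed = 21))),
    r3 = readWith("WWWWWWWWWWWWWWWW", seed = 22))
  fp <- functionalProfile(reads, env$db)
  expect_equal(assignedReads(fp), 2L)
  expect_equal(sum(profileCounts(fp)), 2)
  ## each read unions {S1,S2} (forward frame) with {S3} (reverse frame),
  ## so n = 3 and S1 accumulates 2 * 1/3
  expect_equal(profileCounts(fp)[["S1"]], 2 / 3)
  ## no annotations -> zero profile
  fp0 <- functionalProfile(reads, buildSignatureDB(env$fx$refs, env$tree))
  expect_equal(assignedReads(fp0), 0L)
  expect_equal(sum(profileCounts(fp0)), 0)
  ## random fixture reads: conservation holds for every batch
  reads2 <- simulateReads(encodeGenome(env$fx$refs$B), 180, 60, seed = 23)
  fp2 <- functionalProfile(reads2, env$db)
  expect_equal(sum(profileCounts(fp2)), assignedReads(fp2))
})

test_that("signature survival under mutation matches (1-e)^(3k) per signature", {
  env <- fixtureDB()
  ## reads carrying exactly one signature, the Met/Trp-only 10-mer whose
  ## 30 coding bases tolerate no synonymous substitution, inside a
  ## Met-flanked stop-free fragment (>= 15 residues even after splits)
  n <- 300L
  reads <- vapply(seq_len(n), function(i)
    readWith("MMMMM", "MWMWMWMWMW", "MMMMM", pad = 24L, seed = 1000L + i),
    character(1))
  rate <- 0.02
  mreads <- mutateReads(reads, rate, seed = 99)
  surv <- vapply(seq_len(n), function(i) {
    pr <- classifyRead(mreads[[i]], env$db, env$tree)
    pr$evidence != "none"
  }, logical(1))
  p <- (1 - rate)^30
  expect_lt(abs(mean(surv) - p), 3 * sqrt(p * (1 - p) / n))
  ## rate 0 keeps every signature
  expect_true(all(vapply(seq_len(20), function(i) {
    pr <- classifyRead(reads[[i]], env$db, env$tree)
    pr$evidence != "none"
  }, logical(1))))
})
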