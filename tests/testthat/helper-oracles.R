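## Brute-force oracles, independent of the algorithms they check: LCA by
## intersecting full ancestor lists, GCD by explicit antichain search,
## signature building by exhaustive k-mer enumeration, maximal matches by
## quadratic position-pair extension.

toyTree <- function() readSignatureTree("((A,B)N1,(C,D)N2)R;")

## full ancestor list (self..root) via repeated parent lookups
oracleAncestors <- function(tree, id) {
  out <- id
  while (!is.na(nodeParent(tree, id))) {
    id <- nodeParent(tree, id)
    out <- c(out, id)
  }
  out
}

oracleLCA <- function(tree, nodes) {
  common <- Reduce(intersect, lapply(nodes, oracleAncestors, tree = tree))
  common[which.max(nodeDepth(tree, common))]
}

oracleGCD <- function(tree, nodes) {
  nodes <- unique(nodes)
  isProperAnc <- function(a, b) a != b && a %in% oracleAncestors(tree, b)
  M <- Filter(function(a) !any(vapply(nodes, function(b) isProperAnc(a, b),
                                      logical(1))), nodes)
  if (length(M) == 1L) M[[1L]] else oracleLCA(tree, M)
}

## exhaustive signature building: every k-mer of every leaf, explicit
## coverage sets, >= 2 distinct leaves, oracle LCA
oracleSignatures <- function(refs, tree, k) {
  cov <- list()
  for (leaf in names(refs)) {
    for (seq in refs[[leaf]]) {
      n <- nchar(seq)
      if (n < k) next
      for (i in seq_len(n - k + 1L)) {
        km <- substr(seq, i, i + k - 1L)
        if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", km)) next
        cov[[km]] <- union(cov[[km]], leaf)
      }
    }
  }
  cov <- cov[lengths(cov) >= 2L]
  if (!length(cov))
    return(data.frame(peptide = character(0), node = integer(0)))
  out <- data.frame(
    peptide = names(cov),
    node = vapply(cov, function(ls)
      oracleLCA(tree, unname(treeLeaves(tree)[ls])), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$peptide), ]
  rownames(out) <- NULL
  out
}

## quadratic maximal-match scan: every position pair, explicit extension;
## residues match iff equal and in the 20-letter alphabet
oracleMaximalMatches <- function(protsA, protsB, minK) {
  idsA <- names(protsA); idsB <- names(protsB)
  if (is.null(idsA)) idsA <- as.character(seq_along(protsA))
  if (is.null(idsB)) idsB <- as.character(seq_along(protsB))
  aaSet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  eq <- function(x, y) x == y && x %in% aaSet
  rows <- list()
  for (ia in seq_along(protsA)) for (ib in seq_along(protsB)) {
    a <- strsplit(toupper(protsA[[ia]]), "")[[1L]]
    b <- strsplit(toupper(protsB[[ib]]), "")[[1L]]
    for (i in seq_along(a)) for (j in seq_along(b)) {
      if (!eq(a[i], b[j])) next
      ## run start: previous pair must not match
      if (i > 1L && j > 1L && eq(a[i - 1L], b[j - 1L])) next
      len <- 0L
      while (i + len <= length(a) && j + len <= length(b) &&
             eq(a[i + len], b[j + len])) len <- len + 1L
      if (len >= minK)
        rows[[length(rows) + 1L]] <- data.frame(
          seqA = idsA[ia], posA = i - 1L, seqB = idsB[ib], posB = j - 1L,
          length = len, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seqA = character(0), posA = integer(0),
                      seqB = character(0), posB = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  out[order(out$seqA, out$seqB, out$posA, out$posB), ]
}

sortMatches <- function(m) {
  m <- m[order(m$seqA, m$seqB, m$posA, m$posB), ]
  rownames(m) <- NULL
  m
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## standard planted fixture used across classification tests
plantedFixture <- function(seed = 11L) {
  makeToyReference(
    "((A,B)N1,(C,D)N2)R;",
    proteinsPerLeaf = 4L, proteinLength = 100L,
    planted = list(
      list(peptide = "ACDEFGHIKL", leaves = c("A", "B"),
           subsystems = c("S1", "S2")),
      list(peptide = "MNPQRSTVWY", leaves = c("C", "D"),
           subsystems = "S3"),
      list(peptide = "LKIHGFEDCA", leaves = c("A", "B", "C", "D"),
           subsystems = "S1"),
      ## Met/Trp-only signature: every single-base substitution in its 30
      ## coding bases changes the peptide (no synonymous codons), so its
      ## survival under mutation is exactly (1-e)^30
      list(peptide = "MWMWMWMWMW", leaves = c("A", "B"))),
    seed = seed)
}
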