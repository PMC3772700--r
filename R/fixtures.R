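## Generators for toy reference sets with planted signature peptides,
## deterministic reverse translation, and simulated error-free
## fixed-length shotgun reads with an optional per-base substitution
## model.  Everything is seeded so fixtures are byte-reproducible.

#' Random background proteins
#'
#' i.i.d. residues over the 20-letter alphabet (uniform by default), the
#' simplest null consistent with the analytic random-match model.
#'
#' @param n number of proteins.
#' @param len protein length in residues.
#' @param freqs residue frequency vector over the 20-letter alphabet
#'   (default uniform).
#' @return Character vector of protein sequences.
#' @export
randomProteins <- function(n, len, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  vapply(seq_len(n), function(i)
    paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = ""),
    character(1))
}

#' Build a toy reference set with planted signature peptides
#'
#' Generates random background proteins for every leaf of the tree and
#' overwrites a random window of a random protein with each planted
#' peptide in each of its designated leaves.  The expected database entry
#' for each planted peptide - the least common ancestor of its leaves -
#' is returned as ground truth.
#'
#' @param tree a [SignatureTree-class] or Newick string.
#' @param proteinsPerLeaf,proteinLength background proteome shape
#'   (defaults 5 proteins of 120 residues).
#' @param planted list of plant specifications, each a list with
#'   `peptide` (length-`k` amino-acid text), `leaves` (character vector
#'   of leaf labels, length >= 1) and optional `subsystems` (character
#'   vector).
#' @param k signature peptide length the fixture is built for
#'   (default 10); planted peptides must have exactly this length.
#' @param seed integer seed fixing all randomness.
#' @param freqs background residue frequencies (default uniform).
#' @return A list with `refs` (named list leaf -> protein character
#'   vector), `tree` (the [SignatureTree-class]), `truth` (data.frame
#'   `peptide`, `node` with the expected LCA placements), and
#'   `annotated` (named list subsystem -> member sequences, built from
#'   the planted proteins that carry subsystem labels).
#' @export
makeToyReference <- function(tree, proteinsPerLeaf = 5L,
                             proteinLength = 120L, planted = list(),
                             k = 10L, seed = 1L, freqs = NULL) {
  if (is.character(tree)) tree <- readSignatureTree(tree)
  for (p in planted) {
    if (nchar(p$peptide) != k)
      stop("planted peptide '", p$peptide, "' does not have length k = ", k)
    if (grepl(.nonstandard_re, p$peptide))
      stop("planted peptide must use the 20-letter alphabet")
    if (nchar(p$peptide) > proteinLength)
      stop("planted peptide longer than protein length")
    bad <- setdiff(p$leaves, names(tree@leafIds))
    if (length(bad))
      stop("planted leaf not in tree: ", paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  leaves <- names(tree@leafIds)
  refs <- lapply(leaves, function(l)
    randomProteins(proteinsPerLeaf, proteinLength, freqs))
  names(refs) <- leaves
  annotated <- list()
  for (p in planted) {
    for (leaf in p$leaves) {
      pi <- sample.int(proteinsPerLeaf, 1L)
      pos <- sample.int(proteinLength - nchar(p$peptide) + 1L, 1L)
      prot <- refs[[leaf]][pi]
      substr(prot, pos, pos + nchar(p$peptide) - 1L) <- p$peptide
      refs[[leaf]][pi] <- prot
      for (ss in p$subsystems %||% character(0))
        annotated[[ss]] <- c(annotated[[ss]], prot)
    }
  }
  truth <- if (length(planted)) data.frame(
    peptide = vapply(planted, `[[`, character(1), "peptide"),
    node = vapply(planted, function(p)
      lcaNode(tree, tree@leafIds[p$leaves]), integer(1)),
    stringsAsFactors = FALSE)
  else data.frame(peptide = character(0), node = integer(0))
  list(refs = refs, tree = tree, truth = truth, annotated = annotated)
}

## First codon (in standard genetic-code table order) for each amino acid.
.aaToCodon <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      tab <- Biostrings::GENETIC_CODE
      gc <<- setNames(names(tab)[match(AA20, tab)], AA20)
    }
    gc
  }
})

#' Deterministic reverse translation of a peptide
#'
#' Each amino acid maps to the first codon listed for it in the standard
#' genetic-code table, so the DNA encoding of a fixture protein is unique
#' and reproducible.
#'
#' @param peptide amino-acid text over the 20-letter alphabet.
#' @return DNA text of length `3 * nchar(peptide)`.
#' @export
reverseTranslate <- function(peptide) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  codons <- .aaToCodon()[aas]
  if (anyNA(codons))
    stop("cannot reverse-translate residue(s): ",
         paste(unique(aas[is.na(codons)]), collapse = ", "))
  paste(codons, collapse = "")
}

#' Encode a proteome as a single DNA genome
#'
#' Reverse-translates each protein deterministically, appends a stop
#' codon, and concatenates - a minimal coding genome for read
#' simulation.
#'
#' @param proteins character vector of protein sequences.
#' @return DNA text.
#' @export
encodeGenome <- function(proteins) {
  paste(vapply(proteins, function(p) paste0(reverseTranslate(p), "TAA"),
               character(1)),
        collapse = "")
}

#' Simulate error-free fixed-length shotgun reads
#'
#' Each read is an exact substring of the genome or its reverse
#' complement: start positions uniform, strand by fair coin, all reads of
#' the stated length - no error model, no paired ends.
#'
#' @param genome DNA text.
#' @param readLength read length (must not exceed the genome length).
#' @param n number of reads.
#' @param seed integer seed.
#' @return Named character vector of reads (`read_1`, ...).
#' @export
simulateReads <- function(genome, readLength, n, seed = 1L) {
  genome <- toupper(as.character(genome))
  L <- nchar(genome)
  if (readLength > L) stop("read length exceeds genome length")
  set.seed(as.integer(seed))
  if (n == 0L) return(setNames(character(0), character(0)))
  starts <- sample.int(L - readLength + 1L, n, replace = TRUE)
  rc <- runif(n) < 0.5
  reads <- substring(genome, starts, starts + readLength - 1L)
  if (any(rc))
    reads[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[rc])))
  setNames(reads, paste0("read_", seq_len(n)))
}

#' Apply independent per-base substitutions to reads
#'
#' Every base is replaced, independently with probability `rate`, by one
#' of the three other nucleotides chosen uniformly.
#'
#' @param reads character vector of reads.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return Character vector of mutated reads (names preserved).
#' @export
mutateReads <- function(reads, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("'rate' must be in [0, 1]")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  out <- vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
  setNames(out, names(reads))
}

#' Write a named set of sequences as FASTA
#'
#' @param seqs named character vector (or list) of sequences.
#' @param file output path.
#' @param type `"AA"` or `"DNA"`.
#' @return Invisibly, the file path.
#' @export
writeFasta <- function(seqs, file, type = c("AA", "DNA")) {
  type <- match.arg(type)
  seqs <- unlist(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
       else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
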