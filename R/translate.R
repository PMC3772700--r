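## Six-frame translation of DNA reads and extraction of putative peptide
## fragments (stop-free, ambiguity-free, minimum 15 residues) and their
## overlapping k-mers.

#' Translate a DNA sequence in all six reading frames
#'
#' Frames +1..+3 translate the forward strand starting at offsets 0..2;
#' frames -1..-3 translate the reverse complement at offsets 0..2 (so frame
#' -1 starts at the last base of the forward strand).  The standard genetic
#' code is used by default; trailing partial codons are dropped and any
#' codon containing an ambiguous nucleotide translates to `X`.
#'
#' @param dna a DNA string (character scalar or [Biostrings::DNAString]),
#'   IUPAC alphabet, case-insensitive.
#' @param geneticCode a genetic code table as returned by
#'   [Biostrings::getGeneticCode()]; defaults to the standard code.  The
#'   bacterial code (table 11) differs only in start-codon handling, which
#'   this method never uses.
#' @return Named character vector of six translations
#'   (`F1,F2,F3,R1,R2,R3`).
#' @examples
#' sixFrameTranslate("ATGGCC")
#' @export
sixFrameTranslate <- function(dna, geneticCode = Biostrings::GENETIC_CODE) {
  s <- toupper(as.character(dna))
  if (length(s) != 1L) stop("'dna' must be a single sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", s))
    stop("invalid nucleotide characters in read (IUPAC DNA expected)",
         call. = FALSE)
  r <- .revcompChr(s)
  ## direct codon-table lookup; any codon containing an ambiguity letter
  ## is absent from the table and translates to X
  trans1 <- function(x) {
    n <- nchar(x) %/% 3L * 3L
    if (n == 0L) return("")
    aa <- geneticCode[substring(x, seq(1L, n, 3L), seq(3L, n, 3L))]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  out <- c(trans1(s), trans1(substring(s, 2L)), trans1(substring(s, 3L)),
           trans1(r), trans1(substring(r, 2L)), trans1(substring(r, 3L)))
  names(out) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  out
}

.rcTable <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y",
              Y = "R", S = "S", W = "W", K = "M", M = "K", B = "V",
              V = "B", D = "H", H = "D")

## reverse complement of an upper-case IUPAC DNA character scalar
.revcompChr <- function(s) {
  if (!nzchar(s)) return(s)
  paste(rev(.rcTable[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

## frame name -> signed frame integer
.frameNum <- c(F1 = 1L, F2 = 2L, F3 = 3L, R1 = -1L, R2 = -2L, R3 = -3L)

#' Extract putative peptide fragments from a translated frame
#'
#' Splits a translation at every stop symbol and every residue outside the
#' closed 20-letter alphabet (ambiguity residues are treated like stops)
#' and keeps segments of at least `minFragmentLength` residues, recording
#' each segment's 0-based offset within the frame.
#'
#' @param translation amino-acid text for one frame (may contain `*`/`X`).
#' @param minFragmentLength minimum fragment length (default 15).
#' @param frame signed frame number for bookkeeping (default `NA`).
#' @param readId read identifier for bookkeeping (default `NA`).
#' @return A data.frame with columns `readId`, `frame`, `offset`,
#'   `sequence` (possibly zero rows).
#' @examples
#' extractFragments(paste0(strrep("M", 20), "*", strrep("K", 10)))
#' @export
extractFragments <- function(translation, minFragmentLength = 15L,
                             frame = NA_integer_, readId = NA_character_) {
  empty <- data.frame(readId = character(0), frame = integer(0),
                      offset = integer(0), sequence = character(0))
  m <- gregexpr("[ACDEFGHIKLMNPQRSTVWY]+", translation)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= minFragmentLength
  if (!any(keep)) return(empty)
  data.frame(
    readId = rep(readId, sum(keep)),
    frame = rep(as.integer(frame), sum(keep)),
    offset = starts[keep] - 1L,
    sequence = substring(translation, starts[keep],
                         starts[keep] + lens[keep] - 1L),
    stringsAsFactors = FALSE)
}

#' Overlapping k-mers of a peptide fragment
#'
#' Returns all length-`k` substrings at offsets `0..len-k`; a fragment of
#' length L yields `max(0, L - k + 1)` k-mers, so a match of length 50
#' corresponds to 41 overlapping 10-mers.
#'
#' @param x amino-acid text (character scalar).
#' @param k k-mer length (default 10).
#' @return Character vector of k-mers in order (possibly empty).
#' @examples
#' length(tokenizeKmers(strrep("A", 50), 10))  # 41
#' @export
tokenizeKmers <- function(x, k = 10L) {
  n <- nchar(x)
  if (k < 1L) stop("'k' must be >= 1")
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Read DNA reads from FASTA or FASTQ
#'
#' Format is detected from the extension (`.fq`/`.fastq`, optionally
#' `.gz`-free) or, failing that, from the first character of the file.
#' Qualities are ignored.
#'
#' @param path input file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readReads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq"
         else if (grepl("\\.(fa|fasta|fna|ffn)$", path, ignore.case = TRUE)) "fasta"
         else if (startsWith(readLines(path, n = 1L), "@")) "fastq"
         else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Normalize a protein sequence to the closed alphabet
#'
#' Upper-cases and replaces every residue outside the 20-letter alphabet
#' (U, O, B, Z, J, X, stops, gaps) with `X`, which downstream acts as a
#' fragment breaker and disqualifies overlapping k-mers: exact matching
#' requires a closed alphabet.
#'
#' @param x character vector of amino-acid sequences.
#' @return Character vector of the same length.
#' @export
normalizeProtein <- function(x) {
  gsub(.nonstandard_re, "X", toupper(x))
}
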