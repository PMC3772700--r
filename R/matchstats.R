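## Maximal exact-match enumeration between proteome pairs, run-length
## histograms, exponential-falloff fits, and analytic random-match
## expectations.

## kmer occurrence table of a set of sequences: data.frame(kmer, seq, pos)
## with 0-based positions; sequences are normalized and k-mers containing
## X are excluded so runs break at non-standard residues.
.kmerTable <- function(seqs, k) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  seqs <- normalizeProtein(as.character(seqs))
  kms <- lapply(seqs, tokenizeKmers, k = k)
  out <- data.frame(
    kmer = unlist(kms, use.names = FALSE),
    seq = rep(ids, lengths(kms)),
    pos = unlist(lapply(lengths(kms), function(n) seq_len(n) - 1L),
                 use.names = FALSE),
    stringsAsFactors = FALSE)
  out[!grepl("X", out$kmer, fixed = TRUE), , drop = FALSE]
}

#' Enumerate maximal exact matches between two proteomes
#'
#' Finds every maximal run of identical amino acids of length at least
#' `minK` between any protein of `protsA` and any protein of `protsB`.
#' Each run is reported once, at its maximal extension: a shared run of
#' length 12 with `minK = 10` yields one length-12 match, not three
#' length-10 matches.  Matches never cross protein boundaries, and the
#' same peptide occurring at several position pairs yields one match per
#' position pair.
#'
#' @param protsA,protsB character vectors (or [Biostrings::AAStringSet])
#'   of protein sequences; names are used as sequence ids.
#' @param minK minimum run length to report (default 10).
#' @return A data.frame with columns `seqA`, `posA`, `seqB`, `posB`
#'   (0-based residue positions) and `length`.
#' @examples
#' maximalMatches(c(a = "MMMMACDEFGHIKLMMMM"),
#'                c(b = "WWWWACDEFGHIKLWWWW"), minK = 10)
#' @export
maximalMatches <- function(protsA, protsB, minK = 10L) {
  minK <- as.integer(minK)
  if (minK < 1L) stop("'minK' must be >= 1")
  ta <- .kmerTable(protsA, minK)
  tb <- .kmerTable(protsB, minK)
  empty <- data.frame(seqA = character(0), posA = integer(0),
                      seqB = character(0), posB = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (!nrow(ta) || !nrow(tb)) return(empty)
  hits <- merge(ta, tb, by = "kmer", suffixes = c("A", "B"))
  if (!nrow(hits)) return(empty)
  ## seed hits on one diagonal of one sequence pair belong to one run
  diag <- hits$posA - hits$posB
  key <- paste(hits$seqA, hits$seqB, diag, sep = "\r")
  ord <- order(key, hits$posA)
  key <- key[ord]; hits <- hits[ord, , drop = FALSE]
  newrun <- c(TRUE, key[-1L] != key[-length(key)] |
                    diff(hits$posA) != 1L)
  runid <- cumsum(newrun)
  starts <- which(newrun)
  nseeds <- tabulate(runid)
  data.frame(
    seqA = hits$seqA[starts],
    posA = hits$posA[starts],
    seqB = hits$seqB[starts],
    posB = hits$posB[starts],
    length = nseeds + minK - 1L,
    stringsAsFactors = FALSE)
}

#' Run-length histogram of maximal matches
#'
#' @param matches a data.frame from [maximalMatches()], or an integer
#'   vector of match lengths.
#' @return Named integer vector: match length -> number of maximal
#'   matches (empty for no matches).
#' @export
runLengthHistogram <- function(matches) {
  lens <- if (is.data.frame(matches)) matches$length else as.integer(matches)
  if (!length(lens)) return(setNames(integer(0), character(0)))
  tab <- table(lens)
  setNames(as.integer(tab), names(tab))
}

#' Expected number of chance k-mer matches between two proteomes
#'
#' Under an i.i.d. residue model, the expected number of shared k-mer
#' position pairs between proteomes of `n1` and `n2` residues is
#' `n1 * n2 * (sum(f^2))^k`, which for uniform frequencies over an
#' alphabet of size `s` reduces to `n1 * n2 * s^-k`.  For two typical
#' bacterial proteomes of 1e6 residues at k = 10 this is about 0.1 - the
#' chance-match level that motivates 10-mers as signatures.
#'
#' @param n1,n2 proteome sizes in residues.
#' @param k match length.
#' @param freqs optional residue frequency vector (must sum to 1);
#'   default uniform over `alphabetSize` letters.
#' @param alphabetSize alphabet size for the uniform default (20).
#' @return Expected number of chance matches (real).
#' @examples
#' expectedRandomMatches(1e6, 1e6, k = 10)   # ~0.098
#' @export
expectedRandomMatches <- function(n1, n2, k, freqs = NULL,
                                  alphabetSize = 20L) {
  if (k < 1L) stop("'k' must be >= 1")
  if (is.null(freqs)) freqs <- rep(1 / alphabetSize, alphabetSize)
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("'freqs' must sum to 1")
  n1 * n2 * sum(freqs^2)^k
}

#' Per-unit fold reduction of a run-length histogram
#'
#' Fits an exponential to the run-length counts over `[kLo, kHi]` by
#' unweighted least squares on log counts and returns the fold reduction
#' in match count per unit increase of run length (`exp(-slope)`).  Under
#' a uniform random model over 20 letters the expected value is 20; real
#' proteome pairs fall off more slowly (about 16-fold) because gene
#' matches mix in.
#'
#' @param hist named integer vector from [runLengthHistogram()].
#' @param kLo,kHi fit range (defaults 3 and 7, the random-dominated
#'   regime).
#' @return The per-unit fold reduction (real > 0).
#' @export
fitFalloff <- function(hist, kLo = 3L, kHi = 7L) {
  ks <- kLo:kHi
  counts <- hist[as.character(ks)]
  ok <- !is.na(counts) & counts > 0
  if (sum(ok) < 2L)
    stop("need at least two positive counts in [", kLo, ",", kHi,
         "] to fit the falloff")
  fit <- lm(log(as.numeric(counts[ok])) ~ ks[ok])
  exp(-unname(coef(fit)[2L]))
}

#' Per-position match track across a genomic window
#'
#' Projects residue-level matches onto genomic coordinates: each matched
#' residue of a gene of proteome A contributes the genomic position of its
#' codon start, tagged with the partner sequence of the match.  This is
#' the data behind per-genome match maps along a reference genome.
#'
#' @param matches a data.frame from [maximalMatches()] computed against
#'   proteome A.
#' @param geneCoords data.frame with columns `gene` (matching `seqA`),
#'   `start`, `end` (0-based half-open genomic interval) and `strand`
#'   (`"+"`/`"-"`).
#' @param window numeric length-2 genomic interval `[start, end)`;
#'   default spans all supplied genes.
#' @return A data.frame with columns `pos` (genomic codon-start position)
#'   and `partner` (the matched `seqB`), one row per covered residue and
#'   partner, sorted and de-duplicated.  The number of matches whose gene
#'   had no coordinates is attached as attribute `"skipped"`.
#' @export
matchMap <- function(matches, geneCoords, window = NULL) {
  required <- c("gene", "start", "end", "strand")
  if (!all(required %in% names(geneCoords)))
    stop("'geneCoords' needs columns gene, start, end, strand")
  if (is.null(window))
    window <- c(min(geneCoords$start), max(geneCoords$end))
  idx <- match(matches$seqA, geneCoords$gene)
  skipped <- sum(is.na(idx))
  if (skipped)
    warning(skipped, " match(es) referenced genes without coordinates")
  keep <- which(!is.na(idx))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    g <- idx[i]
    r <- matches$posA[i] + seq_len(matches$length[i]) - 1L  # residues
    pos <- if (geneCoords$strand[g] == "+")
      geneCoords$start[g] + 3L * r
    else
      geneCoords$end[g] - 3L * (r + 1L)
    pos <- pos[pos >= window[1L] & pos < window[2L]]
    if (length(pos))
      rows[[j]] <- data.frame(pos = pos, partner = matches$seqB[i],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pos = integer(0), partner = character(0),
                      stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$pos, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
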