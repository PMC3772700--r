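#' @import methods
#' @importFrom stats lm coef runif setNames prop.test fisher.test p.adjust
#' @importFrom utils read.table write.table
NULL

## The closed 20-letter amino-acid alphabet used for signature peptides.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Regular expression matching any residue outside the closed alphabet
## (stops, X, U/O/B/Z/J, gaps).  Such residues break putative fragments
## and disqualify reference k-mers.
.nonstandard_re <- "[^ACDEFGHIKLMNPQRSTVWY]"

## 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
## Used to fingerprint trees and input files in database headers and run
## logs; stability matters more than cryptographic strength.  The running
## hash is kept as a double < 2^32 and the multiplication is split into
## 16-bit halves so every intermediate stays below 2^53.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    ## xor on values < 2^32 via 16-bit halves (bitwXor needs < 2^31)
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- hi * 65536 + lo
    ## h * 16777619 mod 2^32
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (hi * 65536 + lo) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Fingerprint a file's contents (text mode).
fileChecksum <- function(path) {
  fnv1a32(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
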