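## Profile roll-ups and similarity metrics between samples.

#' Extract a plain profile vector
#'
#' @param x a [PhyloProfile-class], [FunctionProfile-class], or named
#'   numeric vector (returned as-is).
#' @return Named numeric vector.
#' @export
profileVector <- function(x) {
  if (is(x, "PhyloProfile") || is(x, "FunctionProfile"))
    return(as.numeric(profileCounts(x)) |> setNames(names(profileCounts(x))))
  if (is.numeric(x)) {
    if (length(x) && is.null(names(x))) stop("profile vector must be named")
    return(x)
  }
  stop("cannot interpret object of class ", class(x)[1L], " as a profile")
}

.alignProfiles <- function(a, b, excludeRoot, root) {
  va <- profileVector(a)
  vb <- profileVector(b)
  if (!setequal(names(va), names(vb)))
    stop("profiles have mismatched label sets")
  vb <- vb[names(va)]
  if (isTRUE(excludeRoot)) {
    root <- as.character(root %||% if (is(a, "PhyloProfile")) "1" else NULL)
    if (is.null(root) || !root %in% names(va))
      stop("excludeRoot = TRUE but no root label available")
    keep <- names(va) != root
    va <- va[keep]; vb <- vb[keep]
  }
  list(a = va, b = vb)
}

#' Normalized dot product between two profiles
#'
#' `a . b / (|a| |b|)` over the retained labels, in `[0, 1]` for
#' non-negative profiles; 0 when either vector is all zero after
#' exclusion.  For phylogenetic profiles the root node is excluded by
#' default, since root-level counts pool highly conserved and ambiguous
#' evidence and would inflate similarity between unrelated samples.
#'
#' @param a,b profiles with identical label sets ([PhyloProfile-class],
#'   [FunctionProfile-class], or named numeric vectors).
#' @param excludeRoot drop the root label before computing; defaults to
#'   `TRUE` when `a` is a [PhyloProfile-class], otherwise `FALSE`.
#' @param root the root label (default `"1"` for phylogenetic profiles).
#' @return Similarity in `[0, 1]`.
#' @examples
#' normalizedDot(c(a = 1, b = 0, c = 1), c(a = 1, b = 1, c = 0))  # 0.5
#' @export
normalizedDot <- function(a, b, excludeRoot = is(a, "PhyloProfile"),
                          root = NULL) {
  v <- .alignProfiles(a, b, excludeRoot, root)
  na <- sqrt(sum(v$a^2)); nb <- sqrt(sum(v$b^2))
  if (na == 0 || nb == 0) return(0)
  sum(v$a * v$b) / (na * nb)
}

#' Profile distance: one minus the normalized dot product
#'
#' @inheritParams normalizedDot
#' @return Distance in `[0, 1]`.
#' @export
profileDistance <- function(a, b, excludeRoot = is(a, "PhyloProfile"),
                            root = NULL) {
  1 - normalizedDot(a, b, excludeRoot = excludeRoot, root = root)
}

#' Roll a profile up into higher-level groups
#'
#' Group value = sum of member values; labels absent from the grouping go
#' to an `"other"` bucket, so the total is conserved exactly.
#'
#' @param profile a profile (see [profileVector()]).
#' @param grouping named character vector mapping label -> group.
#' @param other bucket name for ungrouped labels (default `"other"`).
#' @return Named numeric vector over groups.
#' @export
rollupProfile <- function(profile, grouping, other = "other") {
  v <- profileVector(profile)
  if (!length(v)) return(setNames(numeric(0), character(0)))
  grp <- grouping[names(v)]
  grp[is.na(grp)] <- other
  out <- tapply(v, grp, sum)
  setNames(as.numeric(out), names(out))
}

#' Per-node differential test between two phylogenetic profiles
#'
#' For each tree node, compares the proportion of assigned reads recruited
#' to that node between two samples with a two-proportion z-test
#' (chi-square without continuity correction), falling back to Fisher's
#' exact test when any expected cell count is below 5.  Nodes with zero
#' counts in both samples are skipped.  Raw p-values are reported by
#' default; Benjamini-Hochberg adjustment is opt-in.
#'
#' @param a,b [PhyloProfile-class] objects over the same tree, or named
#'   count vectors (then `totalA`/`totalB` are required).
#' @param totalA,totalB assigned-read totals when `a`/`b` are plain
#'   vectors.
#' @param adjust apply Benjamini-Hochberg adjustment (default `FALSE`).
#' @return A data.frame with columns `node`, `countA`, `countB`,
#'   `direction` (sign of the proportion difference, a minus b), `p`,
#'   `method`, and `padj` when `adjust = TRUE`.
#' @export
nodeDifferential <- function(a, b, totalA = NULL, totalB = NULL,
                             adjust = FALSE) {
  va <- profileVector(a); vb <- profileVector(b)
  if (!setequal(names(va), names(vb)))
    stop("profiles have mismatched label sets")
  vb <- vb[names(va)]
  nA <- if (is(a, "PhyloProfile")) assignedReads(a) else totalA
  nB <- if (is(b, "PhyloProfile")) assignedReads(b) else totalB
  if (is.null(nA) || is.null(nB))
    stop("totals are required for plain count vectors")
  if (is(a, "PhyloProfile") && is(b, "PhyloProfile") &&
      !identical(a@treeHash, b@treeHash))
    stop("profiles come from different trees")
  if (nA == 0 || nB == 0)
    stop("both samples must have assigned reads")
  keep <- which(va + vb > 0)
  rows <- lapply(keep, function(i) {
    xa <- va[i]; xb <- vb[i]
    tabl <- rbind(c(xa, nA - xa), c(xb, nB - xb))
    expected <- outer(rowSums(tabl), colSums(tabl)) / sum(tabl)
    if (any(expected < 5)) {
      p <- fisher.test(round(tabl))$p.value
      method <- "fisher"
    } else {
      p <- suppressWarnings(
        prop.test(c(xa, xb), c(nA, nB), correct = FALSE)$p.value)
      method <- "z"
    }
    data.frame(node = names(va)[i], countA = unname(xa),
               countB = unname(xb),
               direction = sign(xa / nA - xb / nB),
               p = p, method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = character(0), countA = numeric(0),
                      countB = numeric(0), direction = numeric(0),
                      p = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust) out$padj <- p.adjust(out$p, method = "BH")
  out
}

#' Write / read a profile as two-column TSV
#'
#' Lines beginning `#` carry metadata (profile kind, totals, tree
#' fingerprint) and are restored on read where applicable.
#'
#' @param profile a [PhyloProfile-class], [FunctionProfile-class] or
#'   named numeric vector.
#' @param file path.
#' @return `writeProfile`: invisibly the path; `readProfile`: a named
#'   numeric vector with attributes `kind`, `totalReads`,
#'   `assignedReads` when present in the header.
#' @export
writeProfile <- function(profile, file) {
  hdr <- character(0)
  if (is(profile, "PhyloProfile"))
    hdr <- c(sprintf("#kind=phylogeny"),
             sprintf("#totalReads=%d", profile@totalReads),
             sprintf("#assignedReads=%d", profile@assignedReads),
             sprintf("#tree=%s", profile@treeHash))
  else if (is(profile, "FunctionProfile"))
    hdr <- c(sprintf("#kind=function"),
             sprintf("#assignedReads=%d", profile@assignedReads))
  v <- profileVector(profile)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(v), format(v, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(file)
}

#' @rdname writeProfile
#' @export
readProfile <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed profile line in ", file)
  v <- setNames(as.numeric(vapply(parts, `[`, character(1), 2L)),
                vapply(parts, `[`, character(1), 1L))
  getH <- function(key) {
    x <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(x)) sub(paste0("^#", key, "="), "", x[1L]) else NULL
  }
  attr(v, "kind") <- getH("kind")
  tr <- getH("totalReads"); ar <- getH("assignedReads")
  if (!is.null(tr)) attr(v, "totalReads") <- as.integer(tr)
  if (!is.null(ar)) attr(v, "assignedReads") <- as.integer(ar)
  v
}
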