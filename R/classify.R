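## Per-read phylogenetic and functional assignment, and batch profiling.

## Translate one read, extract fragments and look up signature k-mers.
## Returns NULL when the read has invalid characters; otherwise a list
## with per-frame integer vectors of matched db indices (names F1..R3)
## and the distinct matched peptide strings.
.readSignatureHits <- function(dna, db, minFragmentLength = 15L) {
  frames <- tryCatch(sixFrameTranslate(dna), error = function(e) NULL)
  if (is.null(frames)) return(NULL)
  perFrame <- lapply(names(frames), function(fn) {
    fr <- extractFragments(frames[[fn]],
                           minFragmentLength = minFragmentLength,
                           frame = .frameNum[[fn]])
    if (!nrow(fr)) return(integer(0))
    km <- unlist(lapply(fr$sequence, tokenizeKmers, k = db@k),
                 use.names = FALSE)
    idx <- match(unique(km), db@peptide)
    idx[!is.na(idx)]
  })
  names(perFrame) <- names(frames)
  hits <- unique(unlist(perFrame, use.names = FALSE))
  list(perFrame = perFrame, hits = hits)
}

#' Classify a single read on the reference tree
#'
#' Translates the read in six frames, extracts putative peptide fragments
#' (minimum 15 residues, stop- and ambiguity-free), looks up all
#' overlapping k-mers in the signature database, and assigns the read by
#' the greatest-common-descendant rule over the matched signatures'
#' nodes.  Evidence is classified as `none` (no signature), `single-node`
#' (all signatures at one node), `monophyletic` (nodes on one root-to-leaf
#' path; read assigned to the deepest) or `polyphyletic` (conflicting
#' nodes; read assigned to the branch point).
#'
#' @param dna the read (character scalar or [Biostrings::DNAString]).
#' @param db a [SignatureDB-class].
#' @param tree the [SignatureTree-class] the database was built against.
#' @param readId read identifier for bookkeeping.
#' @param minFragmentLength minimum putative-fragment length (default 15).
#' @return A list with elements `readId`, `nodeId` (`NA` when
#'   unassigned), `evidence`, `nSignatures` (distinct matched peptides)
#'   and `nodes` (the matched node set), or `NULL` when the read contains
#'   invalid nucleotide characters.
#' @export
classifyRead <- function(dna, db, tree, readId = "read",
                         minFragmentLength = 15L) {
  hs <- .readSignatureHits(dna, db, minFragmentLength)
  if (is.null(hs)) return(NULL)
  if (!length(hs$hits))
    return(list(readId = readId, nodeId = NA_integer_, evidence = "none",
                nSignatures = 0L, nodes = integer(0)))
  nodes <- sort(unique(db@node[hs$hits]))
  evidence <- if (length(nodes) == 1L) "single-node"
              else if (isMonophyleticPath(tree, nodes)) "monophyletic"
              else "polyphyletic"
  list(readId = readId, nodeId = gcdAssign(tree, nodes),
       evidence = evidence, nSignatures = length(hs$hits), nodes = nodes)
}

#' Classify a batch of reads and tally a phylogenetic profile
#'
#' @param reads a [Biostrings::DNAStringSet] or named character vector of
#'   reads.
#' @inheritParams classifyRead
#' @return A list with `profile` (a [PhyloProfile-class] whose counts
#'   span every tree node) and `placements` (a data.frame with one row
#'   per successfully translated read: `readId`, `nodeId`, `evidence`,
#'   `nSignatures`, `nodes` as comma-joined text).  Reads with invalid
#'   characters are skipped, counted in the profile's `skippedReads` and
#'   in `totalReads`.
#' @export
classifyReads <- function(reads, db, tree, minFragmentLength = 15L) {
  reads <- as.character(reads)
  ids <- names(reads) %||% paste0("read_", seq_along(reads))
  counts <- setNames(integer(nNodes(tree)), seq_len(nNodes(tree)))
  rows <- vector("list", length(reads))
  skipped <- 0L
  for (i in seq_along(reads)) {
    pr <- classifyRead(reads[[i]], db, tree, readId = ids[i],
                       minFragmentLength = minFragmentLength)
    if (is.null(pr)) {
      skipped <- skipped + 1L
      warning("read '", ids[i], "' skipped: invalid nucleotide characters")
      next
    }
    if (!is.na(pr$nodeId))
      counts[pr$nodeId] <- counts[pr$nodeId] + 1L
    rows[[i]] <- data.frame(
      readId = pr$readId,
      nodeId = pr$nodeId,
      evidence = pr$evidence,
      nSignatures = pr$nSignatures,
      nodes = paste(pr$nodes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, rows)
  if (is.null(placements))
    placements <- data.frame(readId = character(0), nodeId = integer(0),
                             evidence = character(0),
                             nSignatures = integer(0), nodes = character(0),
                             stringsAsFactors = FALSE)
  profile <- new("PhyloProfile",
                 counts = counts,
                 totalReads = length(reads),
                 assignedReads = sum(counts),
                 skippedReads = skipped,
                 treeHash = tree@hash)
  list(profile = profile, placements = placements)
}

#' Functional assignment of a single read
#'
#' For each reading frame in which at least one function-annotated
#' signature was found, the subsystem sets of those signatures are
#' intersected; the per-frame sets are then unioned across frames into a
#' set of n subsystems, each allotted 1/n counts.  Frames whose matched
#' signatures all lack annotations contribute nothing (they do not
#' annihilate the union), and a read whose union is empty gets no
#' functional assignment.
#'
#' @inheritParams classifyRead
#' @return Named numeric vector of fractional counts summing to 1
#'   (empty when no functional assignment, `NULL` for untranslatable
#'   reads).
#' @export
functionalAssign <- function(dna, db, minFragmentLength = 15L) {
  hs <- .readSignatureHits(dna, db, minFragmentLength)
  if (is.null(hs)) return(NULL)
  frameSets <- lapply(hs$perFrame, function(idx) {
    sets <- db@subsystems[idx]
    sets <- sets[lengths(sets) > 0L]
    if (!length(sets)) return(character(0))
    Reduce(intersect, sets)
  })
  u <- sort(unique(unlist(frameSets, use.names = FALSE)))
  if (!length(u)) return(setNames(numeric(0), character(0)))
  setNames(rep(1 / length(u), length(u)), u)
}

#' Functional profile of a batch of reads
#'
#' Sums per-read fractional subsystem counts; the profile total equals
#' the number of functionally assigned reads exactly.
#'
#' @inheritParams classifyReads
#' @return A [FunctionProfile-class] over every subsystem known to the
#'   database (plus any observed), zeros included.
#' @export
functionalProfile <- function(reads, db, minFragmentLength = 15L) {
  reads <- as.character(reads)
  universe <- sort(unique(unlist(db@subsystems, use.names = FALSE)))
  counts <- setNames(numeric(length(universe)), universe)
  assigned <- 0L
  for (i in seq_along(reads)) {
    fa <- functionalAssign(reads[[i]], db, minFragmentLength)
    if (is.null(fa) || !length(fa)) next
    assigned <- assigned + 1L
    miss <- setdiff(names(fa), names(counts))
    if (length(miss))
      counts <- c(counts, setNames(numeric(length(miss)), miss))
    counts[names(fa)] <- counts[names(fa)] + fa
  }
  new("FunctionProfile", counts = counts, assignedReads = assigned)
}

#' Profile accessors
#'
#' @param x a [PhyloProfile-class] or [FunctionProfile-class].
#' @return `profileCounts`: the named count vector; `assignedReads` /
#'   `totalReads`: the respective read tallies.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname profile-accessors
#' @export
setMethod("profileCounts", "PhyloProfile", function(x) x@counts)

#' @rdname profile-accessors
#' @export
setMethod("profileCounts", "FunctionProfile", function(x) x@counts)

#' @rdname profile-accessors
#' @export
setGeneric("assignedReads", function(x) standardGeneric("assignedReads"))

#' @rdname profile-accessors
#' @export
setMethod("assignedReads", "PhyloProfile", function(x) x@assignedReads)

#' @rdname profile-accessors
#' @export
setMethod("assignedReads", "FunctionProfile", function(x) x@assignedReads)

#' @rdname profile-accessors
#' @export
totalReads <- function(x) x@totalReads

setMethod("show", "PhyloProfile", function(object) {
  cat(sprintf("PhyloProfile: %d/%d reads assigned (%d skipped) over %d nodes, tree %s\n",
              object@assignedReads, object@totalReads, object@skippedReads,
              length(object@counts), object@treeHash))
})

setMethod("show", "FunctionProfile", function(object) {
  cat(sprintf("FunctionProfile: %d reads over %d subsystems (total %.3f)\n",
              object@assignedReads, length(object@counts),
              sum(object@counts)))
})
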