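#' Rooted reference phylogeny with integer node identifiers
#'
#' A rooted tree whose nodes carry stable integer identifiers assigned by a
#' deterministic preorder traversal of the input Newick (root = 1, then each
#' clade in the order written).  Leaves correspond to reference genomes;
#' internal nodes are the possible placements for signature peptides and
#' reads.  Branch lengths are deliberately not stored: placement uses only
#' the connectivity of the tree.
#'
#' @slot parent integer vector indexed by node id; `NA` for the root.
#' @slot children list of integer vectors of child ids (empty for leaves).
#' @slot depth integer vector of edge distances from the root (root = 0).
#' @slot label character vector of node labels; leaves keep their Newick
#'   tip labels, unlabeled internal nodes get `"N<id>"`.
#' @slot root integer id of the root node.
#' @slot leafIds named integer vector mapping leaf label to node id.
#' @slot hash character; fingerprint of the canonical Newick, used to check
#'   that a signature database and a tree belong together.
#'
#' @seealso [readSignatureTree()], [lcaNode()], [gcdAssign()]
#' @export
setClass("SignatureTree",
  representation(
    parent = "integer",
    children = "list",
    depth = "integer",
    label = "character",
    root = "integer",
    leafIds = "integer",
    hash = "character"
  )
)

setValidity("SignatureTree", function(object) {
  n <- length(object@parent)
  msgs <- character(0)
  if (length(object@children) != n || length(object@depth) != n ||
      length(object@label) != n)
    msgs <- c(msgs, "parent, children, depth and label must have equal length")
  roots <- which(is.na(object@parent))
  if (length(roots) != 1L || roots != object@root)
    msgs <- c(msgs, "exactly one root (parent NA) matching @root is required")
  ## parent/child mutual consistency
  for (id in seq_len(n)) {
    for (ch in object@children[[id]]) {
      if (ch < 1L || ch > n || !identical(object@parent[ch], id))
        msgs <- c(msgs, sprintf("child link %d -> %d not mirrored by parent", id, ch))
    }
  }
  kids <- lengths(object@children)
  if (!all(object@leafIds >= 1L & object@leafIds <= n) ||
      any(kids[object@leafIds] > 0L))
    msgs <- c(msgs, "leafIds must point to childless nodes")
  if (anyDuplicated(names(object@leafIds)))
    msgs <- c(msgs, "leaf labels must be unique")
  ## connectivity: every node reaches the root
  if (n > 0L) {
    reached <- vapply(seq_len(n), function(id) {
      steps <- 0L
      while (!is.na(object@parent[id]) && steps <= n) {
        id <- object@parent[id]
        steps <- steps + 1L
      }
      identical(id, object@root) && steps <= n
    }, logical(1))
    if (!all(reached))
      msgs <- c(msgs, "graph is not a single connected tree")
  }
  if (length(msgs)) msgs else TRUE
})

#' Signature peptide database
#'
#' Maps each signature peptide (an amino-acid k-mer found in at least two
#' distinct leaves of the reference set) to the tree node that is the least
#' common ancestor of the leaves containing it, plus an optional set of
#' functional subsystem identifiers per peptide.
#'
#' @slot k integer peptide length.
#' @slot peptide character vector of signature peptides (sorted, unique,
#'   all of length `k` over the 20-letter alphabet).
#' @slot node integer vector of assigned tree node ids, parallel to
#'   `peptide`.
#' @slot subsystems list of character vectors, parallel to `peptide`;
#'   empty vector when the peptide matched no annotated gene.
#' @slot coverage list of character vectors of covering leaf labels
#'   (diagnostic; may be an empty list when not retained).
#' @slot treeHash character fingerprint of the tree the node ids refer to.
#'
#' @seealso [buildSignatureDB()], [annotateSignatureFunctions()],
#'   [writeSignatureDB()]
#' @export
setClass("SignatureDB",
  representation(
    k = "integer",
    peptide = "character",
    node = "integer",
    subsystems = "list",
    coverage = "list",
    treeHash = "character"
  )
)

setValidity("SignatureDB", function(object) {
  msgs <- character(0)
  n <- length(object@peptide)
  if (length(object@node) != n || length(object@subsystems) != n)
    msgs <- c(msgs, "peptide, node and subsystems must be parallel")
  if (n > 0L) {
    if (!all(nchar(object@peptide) == object@k))
      msgs <- c(msgs, sprintf("all peptides must have length k = %d", object@k))
    if (any(grepl(.nonstandard_re, object@peptide)))
      msgs <- c(msgs, "peptides must use the closed 20-letter alphabet")
    if (anyDuplicated(object@peptide))
      msgs <- c(msgs, "peptides must be unique")
    if (is.unsorted(object@peptide))
      msgs <- c(msgs, "peptides must be sorted")
    if (any(is.na(object@node)) || any(object@node < 1L))
      msgs <- c(msgs, "node ids must be positive integers")
  }
  if (length(object@coverage) && length(object@coverage) != n)
    msgs <- c(msgs, "coverage, when kept, must be parallel to peptide")
  if (length(msgs)) msgs else TRUE
})

#' Phylogenetic profile of a read sample
#'
#' Read counts per tree node for one sample.  The counts vector spans every
#' node of the reference tree (named by node id) so profiles from the same
#' tree are directly comparable.
#'
#' @slot counts named integer vector over all tree node ids.
#' @slot totalReads integer; reads seen, including unassigned and skipped.
#' @slot assignedReads integer; reads placed on a node (root included).
#' @slot skippedReads integer; reads dropped for invalid characters.
#' @slot treeHash character fingerprint of the tree.
#' @export
setClass("PhyloProfile",
  representation(
    counts = "integer",
    totalReads = "integer",
    assignedReads = "integer",
    skippedReads = "integer",
    treeHash = "character"
  )
)

setValidity("PhyloProfile", function(object) {
  msgs <- character(0)
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (sum(object@counts) != object@assignedReads)
    msgs <- c(msgs, "sum(counts) must equal assignedReads")
  if (object@assignedReads > object@totalReads)
    msgs <- c(msgs, "assignedReads cannot exceed totalReads")
  if (is.null(names(object@counts)) && length(object@counts))
    msgs <- c(msgs, "counts must be named by node id")
  if (length(msgs)) msgs else TRUE
})

#' Functional profile of a read sample
#'
#' Fractional read counts per subsystem.  A read assigned to n subsystems
#' contributes 1/n to each, so the column total equals the number of
#' functionally assigned reads exactly.
#'
#' @slot counts named numeric vector over subsystem ids.
#' @slot assignedReads integer; reads with a non-empty functional
#'   assignment.
#' @export
setClass("FunctionProfile",
  representation(
    counts = "numeric",
    assignedReads = "integer"
  )
)

setValidity("FunctionProfile", function(object) {
  msgs <- character(0)
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (abs(sum(object@counts) - object@assignedReads) > 1e-8)
    msgs <- c(msgs, "sum(counts) must equal assignedReads (1/n conservation)")
  if (length(object@counts) && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by subsystem id")
  if (length(msgs)) msgs else TRUE
})
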