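## Rooted-tree data model and the two placement algorithms: least common
## ancestor (signature placement) and greatest common descendant (read
## placement).  Only connectivity is used; branch lengths are discarded.

#' Read a rooted reference phylogeny from Newick
#'
#' Parses a Newick string or file and assigns integer node ids by a
#' deterministic preorder traversal (root = 1, then each clade in writing
#' order).  The published node numbering of any particular reference tree
#' is not derivable from the Newick alone, so numbering is tool-defined but
#' reproducible: the same Newick always yields the same ids, which keeps
#' profiles comparable across runs.
#'
#' @param x path to a Newick file, or a Newick string (must contain "(").
#' @return A [SignatureTree-class] object.
#' @examples
#' tr <- readSignatureTree("((A,B)N1,(C,D)N2)R;")
#' nNodes(tr)
#' @export
readSignatureTree <- function(x) {
  if (length(x) != 1L || !is.character(x))
    stop("'x' must be a single Newick string or file path")
  phy <- if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
         else ape::read.tree(x)
  if (is.null(phy)) stop("could not parse Newick input")
  signatureTreeFromPhylo(phy)
}

#' Build a SignatureTree from an ape phylo object
#'
#' @param phy a rooted `ape::phylo` object.
#' @return A [SignatureTree-class] object.
#' @export
signatureTreeFromPhylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (!ape::is.rooted(phy)) stop("the reference tree must be rooted")
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  phy <- stats::reorder(phy, "cladewise") # edges in preorder
  aperoot <- ntip + 1L
  ## preorder ids: root first, then children in edge (writing) order
  newid <- integer(n)
  newid[aperoot] <- 1L
  nxt <- 2L
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2L]
    newid[child] <- nxt
    nxt <- nxt + 1L
  }
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- newid[phy$edge[i, 1L]]
    c <- newid[phy$edge[i, 2L]]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  depth <- integer(n)
  ## preorder ids guarantee parents precede children
  ord <- order(newid)
  for (id in seq_len(n)[-1L]) depth[id] <- depth[parent[id]] + 1L
  label <- character(n)
  label[newid[seq_len(ntip)]] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    intlab <- phy$node.label
    intlab[is.na(intlab) | intlab == ""] <- ""
    label[newid[ntip + seq_len(phy$Nnode)]] <- intlab
  }
  unlabeled <- which(label == "")
  label[unlabeled] <- paste0("N", unlabeled)
  leafIds <- setNames(newid[seq_len(ntip)], phy$tip.label)
  leafIds <- leafIds[order(names(leafIds))]
  tr <- new("SignatureTree",
    parent = parent, children = children, depth = depth,
    label = label, root = 1L, leafIds = leafIds, hash = "")
  tr@hash <- fnv1a32(treeNewick(tr))
  validObject(tr)
  tr
}

#' Canonical Newick of a SignatureTree
#'
#' Emits the tree with the assigned integer node ids as internal labels, so
#' downstream profile files (keyed by node id) stay interpretable.
#'
#' @param tree a [SignatureTree-class].
#' @return A Newick string.
#' @export
treeNewick <- function(tree) {
  rec <- function(id) {
    kids <- tree@children[[id]]
    if (!length(kids)) return(tree@label[id])
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", id)
  }
  paste0(rec(tree@root), ";")
}

#' Write a SignatureTree to a Newick file
#'
#' @param tree a [SignatureTree-class].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeSignatureTree <- function(tree, file) {
  writeLines(treeNewick(tree), file)
  invisible(file)
}

#' Tree accessors
#'
#' @param x,tree a [SignatureTree-class].
#' @param id an integer node id.
#' @return `nNodes`: node count; `treeRoot`: root id; `treeLeaves`: named
#'   integer vector label -> leaf id; the per-node accessors return the
#'   requested attribute for `id`.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname tree-accessors
#' @export
setMethod("nNodes", "SignatureTree", function(x) length(x@parent))

#' @rdname tree-accessors
#' @export
treeRoot <- function(tree) tree@root

#' @rdname tree-accessors
#' @export
treeLeaves <- function(tree) tree@leafIds

#' @rdname tree-accessors
#' @export
nodeLabel <- function(tree, id) tree@label[id]

#' @rdname tree-accessors
#' @export
nodeDepth <- function(tree, id) tree@depth[id]

#' @rdname tree-accessors
#' @export
nodeParent <- function(tree, id) tree@parent[id]

#' @rdname tree-accessors
#' @export
nodeChildren <- function(tree, id) tree@children[[id]]

#' @rdname tree-accessors
#' @export
isLeaf <- function(tree, id) lengths(tree@children[id]) == 0L

#' Look up a node id by its label
#'
#' @param tree a [SignatureTree-class].
#' @param label node label(s).
#' @return Integer node id(s); errors on unknown labels.
#' @export
nodeId <- function(tree, label) {
  id <- match(label, tree@label)
  if (anyNA(id))
    stop("unknown node label(s): ", paste(label[is.na(id)], collapse = ", "))
  id
}

setMethod("show", "SignatureTree", function(object) {
  cat(sprintf("SignatureTree: %d nodes (%d leaves), root id %d, hash %s\n",
              nNodes(object), length(object@leafIds), object@root,
              object@hash))
  lv <- names(object@leafIds)
  cat("  leaves: ", paste(utils::head(lv, 6), collapse = ", "),
      if (length(lv) > 6) ", ..." else "", "\n", sep = "")
})

.checkNodes <- function(tree, nodes) {
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L || anyNA(nodes))
    stop("node set must be non-empty with no NA")
  if (any(nodes < 1L | nodes > nNodes(tree)))
    stop("node id(s) not in tree: ",
         paste(nodes[nodes < 1L | nodes > nNodes(tree)], collapse = ", "))
  nodes
}

## TRUE iff a is an ancestor of b or a == b
.ancestorOrSelf <- function(tree, a, b) {
  while (tree@depth[b] > tree@depth[a]) b <- tree@parent[b]
  b == a
}

.pairLCA <- function(tree, a, b) {
  while (tree@depth[a] > tree@depth[b]) a <- tree@parent[a]
  while (tree@depth[b] > tree@depth[a]) b <- tree@parent[b]
  while (a != b) {
    a <- tree@parent[a]
    b <- tree@parent[b]
  }
  a
}

#' Least common ancestor of a node set
#'
#' The deepest node that is an ancestor-or-self of every node in the set.
#' This is the placement rule for signature peptides: a signature seen in a
#' set of reference leaves is assigned to the most specific node covering
#' all of them.
#'
#' @param tree a [SignatureTree-class].
#' @param nodes integer node ids (non-empty).
#' @return A single node id.
#' @examples
#' tr <- readSignatureTree("((A,B)N1,(C,D)N2)R;")
#' lcaNode(tr, treeLeaves(tr)[c("A", "B")])   # the (A,B) clade
#' @export
lcaNode <- function(tree, nodes) {
  nodes <- .checkNodes(tree, nodes)
  Reduce(function(a, b) .pairLCA(tree, a, b), nodes)
}

#' Are the nodes totally ordered by ancestry?
#'
#' TRUE iff all nodes lie on a single root-to-leaf path, i.e. the evidence
#' is monophyletic.
#'
#' @inheritParams lcaNode
#' @return Logical scalar.
#' @export
isMonophyleticPath <- function(tree, nodes) {
  nodes <- unique(.checkNodes(tree, nodes))
  if (length(nodes) == 1L) return(TRUE)
  nodes <- nodes[order(tree@depth[nodes])]
  for (i in seq_len(length(nodes) - 1L)) {
    if (!.ancestorOrSelf(tree, nodes[i], nodes[i + 1L])) return(FALSE)
  }
  TRUE
}

#' Greatest-common-descendant assignment for a read
#'
#' Given the set of nodes whose signatures were seen in a read, returns the
#' most specific node consistent with all of them: the deepest node when
#' the set lies on one root-to-leaf path, otherwise the least common
#' ancestor of the deepest conflicting nodes (the branch point).  Formally,
#' let M be the nodes with no proper descendant also in the set (the
#' maximal antichain); the result is M's single element, or lca(M).
#'
#' @inheritParams lcaNode
#' @return A single node id.
#' @examples
#' tr <- readSignatureTree("((A,B)N1,(C,D)N2)R;")
#' a <- nodeId(tr, "A")
#' gcdAssign(tr, c(treeRoot(tr), nodeId(tr, "N1"), a)) == a  # deepest on path
#' @export
gcdAssign <- function(tree, nodes) {
  nodes <- unique(.checkNodes(tree, nodes))
  if (length(nodes) == 1L) return(nodes)
  ## maximal antichain: drop nodes that are proper ancestors of another
  isAnc <- vapply(nodes, function(a) {
    any(vapply(nodes, function(b) b != a && .ancestorOrSelf(tree, a, b),
               logical(1)))
  }, logical(1))
  M <- nodes[!isAnc]
  if (length(M) == 1L) M else lcaNode(tree, M)
}

#' All ancestors of a node, including itself
#'
#' @inheritParams lcaNode
#' @param id a single node id.
#' @return Integer vector from the node up to the root.
#' @export
nodeAncestors <- function(tree, id) {
  id <- .checkNodes(tree, id)[1L]
  out <- id
  while (!is.na(tree@parent[id])) {
    id <- tree@parent[id]
    out <- c(out, id)
  }
  out
}

#' Leaf ids under a node (including the node when it is a leaf)
#'
#' @inheritParams nodeAncestors
#' @return Integer vector of leaf node ids.
#' @export
leafDescendants <- function(tree, id) {
  id <- .checkNodes(tree, id)[1L]
  stack <- id
  out <- integer(0)
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    kids <- tree@children[[cur]]
    if (!length(kids)) out <- c(out, cur) else stack <- c(kids, stack)
  }
  out
}
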