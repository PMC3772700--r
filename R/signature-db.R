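## Building the orthogenomic signature database: enumerate reference
## k-mers, keep those present in >= 2 distinct leaves (or genera), place
## each survivor at the least common ancestor of its covering leaves, and
## optionally attach functional subsystem labels.

## Unique clean k-mers of a set of protein sequences (one leaf).
.leafKmers <- function(seqs, k) {
  seqs <- normalizeProtein(as.character(seqs))
  km <- unlist(lapply(seqs, tokenizeKmers, k = k), use.names = FALSE)
  if (!length(km)) return(character(0))
  km <- km[!grepl("X", km, fixed = TRUE)]
  unique(km)
}

#' Build a signature peptide database from reference proteomes
#'
#' Enumerates every amino-acid k-mer of every reference proteome, discards
#' k-mers present in fewer than two distinct leaves (within-leaf paralogs
#' count once), and assigns each survivor to the tree node that is the
#' least common ancestor of the leaves containing it.  K-mers touching a
#' residue outside the closed 20-letter alphabet are excluded.
#'
#' With `genusLabels`, the >= 2 filter counts distinct genera instead of
#' distinct leaves, for trees carrying several leaves per genus; on a
#' genus-deduplicated reference set the two readings coincide.
#'
#' @param refs named list mapping leaf label to a character vector (or
#'   [Biostrings::AAStringSet]) of protein sequences.
#' @param tree a [SignatureTree-class]; every name of `refs` must be a leaf
#'   label of the tree.
#' @param k signature peptide length (default 10).
#' @param genusLabels optional named character vector mapping leaf label to
#'   genus; default treats each leaf as its own genus.
#' @param keepCoverage keep the covering-leaf sets for diagnostics
#'   (default `TRUE`; at genome scale set `FALSE`).
#' @return A [SignatureDB-class].
#' @examples
#' tr <- readSignatureTree("((A,B)N1,(C,D)N2)R;")
#' refs <- list(A = "ACDEFGHIKLMNP", B = "WACDEFGHIKLW",
#'              C = "MMMMMMMMMMMMMM", D = "PPPPPPPPPPPPPP")
#' db <- buildSignatureDB(refs, tr, k = 10)
#' peptides(db)
#' @export
buildSignatureDB <- function(refs, tree, k = 10L, genusLabels = NULL,
                             keepCoverage = TRUE) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  leaves <- names(refs)
  if (is.null(leaves) || any(leaves == ""))
    stop("'refs' must be a named list of per-leaf protein sets")
  missing <- setdiff(leaves, names(tree@leafIds))
  if (length(missing))
    stop("reference leaf not present in tree: ",
         paste(missing, collapse = ", "))
  genus <- if (is.null(genusLabels)) setNames(leaves, leaves)
           else genusLabels
  perLeaf <- lapply(refs, .leafKmers, k = k)
  kl <- data.frame(
    kmer = unlist(perLeaf, use.names = FALSE),
    leaf = rep(leaves, lengths(perLeaf)),
    stringsAsFactors = FALSE)
  if (!nrow(kl)) {
    return(new("SignatureDB", k = k, peptide = character(0),
               node = integer(0), subsystems = list(), coverage = list(),
               treeHash = tree@hash))
  }
  cov <- split(kl$leaf, kl$kmer)                 # sorted by kmer
  ngen <- vapply(cov, function(ls) length(unique(genus[ls])), integer(1))
  cov <- cov[ngen >= 2L]
  if (!length(cov)) {
    return(new("SignatureDB", k = k, peptide = character(0),
               node = integer(0), subsystems = list(), coverage = list(),
               treeHash = tree@hash))
  }
  ## LCA per distinct coverage set (memoized: many peptides share one set)
  keys <- vapply(cov, function(ls) paste(sort(ls), collapse = "\r"),
                 character(1))
  uk <- unique(keys)
  lcaByKey <- vapply(uk, function(key) {
    ls <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    lcaNode(tree, tree@leafIds[ls])
  }, integer(1))
  node <- unname(lcaByKey[match(keys, uk)])
  new("SignatureDB",
      k = k,
      peptide = names(cov),
      node = node,
      subsystems = rep(list(character(0)), length(cov)),
      coverage = if (keepCoverage) unname(lapply(cov, sort)) else list(),
      treeHash = tree@hash)
}

#' Attach functional subsystem labels to signatures
#'
#' For every signature peptide, records the set of subsystems in which the
#' exact k-mer occurs in any annotated member sequence.  Signatures
#' matching no annotated sequence keep an empty set; a signature occurring
#' in several subsystems is assigned to all of them.
#'
#' @param db a [SignatureDB-class].
#' @param annotated named list mapping subsystem id to a character vector
#'   (or [Biostrings::AAStringSet]) of member protein sequences.
#' @return A new [SignatureDB-class] with updated subsystem sets.
#' @export
annotateSignatureFunctions <- function(db, annotated) {
  if (is.null(names(annotated)) && length(annotated))
    stop("'annotated' must be named by subsystem id")
  subs <- rep(list(character(0)), length(db@peptide))
  for (ss in names(annotated)) {
    km <- .leafKmers(annotated[[ss]], db@k)
    hit <- which(db@peptide %in% km)
    for (i in hit) subs[[i]] <- c(subs[[i]], ss)
  }
  db@subsystems <- lapply(subs, function(s) sort(unique(s)))
  validObject(db)
  db
}

#' Signature database accessors
#'
#' @param db a [SignatureDB-class].
#' @return `peptides`: character vector of signature peptides;
#'   `nodeAssignments`: named integer vector peptide -> node id;
#'   `subsystemSets`: named list peptide -> subsystem ids; `dbK`: the
#'   peptide length.
#' @name db-accessors
NULL

#' @rdname db-accessors
#' @export
peptides <- function(db) db@peptide

#' @rdname db-accessors
#' @export
nodeAssignments <- function(db) setNames(db@node, db@peptide)

#' @rdname db-accessors
#' @export
subsystemSets <- function(db) setNames(db@subsystems, db@peptide)

#' @rdname db-accessors
#' @export
dbK <- function(db) db@k

setMethod("show", "SignatureDB", function(object) {
  nfun <- sum(lengths(object@subsystems) > 0L)
  cat(sprintf("SignatureDB: %d signature %d-mers (%d with function labels), tree %s\n",
              length(object@peptide), object@k, nfun, object@treeHash))
})

setMethod("length", "SignatureDB", function(x) length(x@peptide))

#' Write a signature database as sorted tab-separated text
#'
#' Format: `#` header lines carrying `k` and the tree fingerprint, then one
#' line per signature: `peptide<TAB>node_id<TAB>comma-joined subsystem
#' ids` (third field empty when unannotated).  Portable, diff-able and
#' streamable.
#'
#' @param db a [SignatureDB-class].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeSignatureDB <- function(db, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#k=%d", db@k), sprintf("#tree=%s", db@treeHash)),
             con)
  if (length(db@peptide)) {
    ss <- vapply(db@subsystems, paste, character(1), collapse = ",")
    writeLines(paste(db@peptide, db@node, ss, sep = "\t"), con)
  }
  invisible(file)
}

#' Read a signature database from tab-separated text
#'
#' Round-trips [writeSignatureDB()] output.  Malformed lines (wrong field
#' count, peptide length not matching the header `k`, non-integer or
#' out-of-tree node id) raise a parse error naming the line number.
#'
#' @param file input path.
#' @param tree optional [SignatureTree-class]; when given, node ids are
#'   range-checked and the tree fingerprint is compared to the header.
#' @return A [SignatureDB-class].
#' @export
readSignatureDB <- function(file, tree = NULL) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  kline <- grep("^#k=", hdr, value = TRUE)
  if (!length(kline)) stop("missing '#k=' header in ", file)
  k <- as.integer(sub("^#k=", "", kline[1L]))
  tline <- grep("^#tree=", hdr, value = TRUE)
  treeHash <- if (length(tline)) sub("^#tree=", "", tline[1L]) else ""
  if (!is.null(tree) && nzchar(treeHash) && !identical(treeHash, tree@hash))
    warning("signature database was built against a different tree (",
            treeHash, " vs ", tree@hash, ")")
  body <- which(!grepl("^#", lines) & nzchar(lines))
  pep <- character(length(body)); node <- integer(length(body))
  subs <- vector("list", length(body))
  for (j in seq_along(body)) {
    i <- body[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L || length(f) > 3L)
      stop(sprintf("line %d: expected 2-3 tab-separated fields", i))
    if (nchar(f[1L]) != k)
      stop(sprintf("line %d: peptide length %d does not match k=%d",
                   i, nchar(f[1L]), k))
    nd <- suppressWarnings(as.integer(f[2L]))
    if (is.na(nd))
      stop(sprintf("line %d: node id '%s' is not an integer", i, f[2L]))
    if (!is.null(tree) && (nd < 1L || nd > nNodes(tree)))
      stop(sprintf("line %d: node id %d not in tree", i, nd))
    pep[j] <- f[1L]; node[j] <- nd
    subs[[j]] <- if (length(f) == 3L && nzchar(f[3L]))
      strsplit(f[3L], ",", fixed = TRUE)[[1L]] else character(0)
  }
  ord <- order(pep)
  db <- new("SignatureDB", k = k, peptide = pep[ord], node = node[ord],
            subsystems = subs[ord], coverage = list(),
            treeHash = if (!is.null(tree)) tree@hash else treeHash)
  validObject(db)
  db
}

#' Read per-leaf proteomes from a directory of FASTA files
#'
#' Each `*.fa/*.faa/*.fasta` file supplies one leaf, named by the file
#' stem.
#'
#' @param dir directory of protein FASTA files.
#' @return Named list of character vectors of protein sequences.
#' @export
readProteomeDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", dir)
  refs <- lapply(files, function(f)
    as.character(Biostrings::readAAStringSet(f)))
  names(refs) <- sub("\\.(fa|faa|fasta)$", "", basename(files))
  refs
}
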