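#' Read and write Newick trees
#'
#' Thin, validating wrappers around ape's Newick I/O. Internal node
#' labels (used downstream for `"BRP|TBE"` support annotations) are
#' preserved. Duplicate tip labels and unparsable strings are format
#' errors rather than silent `NULL`s.
#'
#' @param path File path (or, for `readNewickTree`, a literal Newick
#'   string containing ";").
#' @return An ape `phylo` object.
#' @export
readNewickTree <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) .stopf("tree file not found: %s", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) .stopf("malformed Newick in %s", path)
  if (anyDuplicated(tr$tip.label))
    .stopf("duplicate tip labels: %s",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname readNewickTree
#' @param tree An ape `phylo`.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# ---- bipartition machinery -------------------------------------------------

# Tip indices (tree order) below every node; list indexed by node id.
.tipsBelow <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# Canonical split: indices into sort(tip.label) of the side NOT containing
# the alphabetically first tip. Returns NULL for trivial splits.
.canonicalSplit <- function(tipIdx, rank, n) {
  side <- sort(rank[tipIdx])
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  if (length(side) < 2L || length(side) > n - 2L) return(NULL)
  side
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal branch of an unrooted tree splits the tips in two; the
#' split is stored canonically as the (sorted) side not containing the
#' alphabetically first tip. Trivial splits (single tips) are excluded.
#' A fully resolved unrooted tree with n tips has exactly n-3 of them.
#'
#' @param tree An ape `phylo` (rooted trees are treated as unrooted).
#' @return List with `labels` (sorted tip labels), `sets` (list of
#'   integer index vectors into `labels`), `key` (character keys),
#'   `p` (smaller-side sizes), `node` (child node of the branch) and
#'   `length` (branch length, or NA).
#' @examples
#' tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
#' length(bipartitions(tr)$key)  # 1
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  labels <- sort(tree$tip.label)
  rank <- match(tree$tip.label, labels)
  below <- .tipsBelow(tree)
  root <- n + 1L
  sets <- list(); nodes <- integer(0); lens <- numeric(0)
  haveLen <- !is.null(tree$edge.length)
  childLen <- if (haveLen)
    stats::setNames(tree$edge.length, tree$edge[, 2L]) else NULL
  internal <- setdiff(seq_len(tree$Nnode) + n, root)
  for (v in internal) {
    side <- .canonicalSplit(below[[v]], rank, n)
    if (is.null(side)) next
    sets[[length(sets) + 1L]] <- side
    nodes <- c(nodes, v)
    lens <- c(lens, if (haveLen) unname(childLen[as.character(v)]) else NA_real_)
  }
  # a rooted binary tree stored in phylo has one redundant basal clade
  key <- vapply(sets, function(s) paste(labels[s], collapse = ","),
                character(1))
  dup <- duplicated(key)
  list(labels = labels, sets = sets[!dup], key = key[!dup],
       p = vapply(sets[!dup], function(s) min(length(s), n - length(s)),
                  integer(1)),
       node = nodes[!dup], length = lens[!dup])
}

.checkSameTips <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label)))
    .stopf("trees are on different tip sets")
}

# ---- consensus + BRP -------------------------------------------------------

#' Majority-rule consensus with branch recovery proportions and TBE
#'
#' Combines replicate trees (same tip set) into the majority-rule
#' consensus: exactly the bipartitions occurring in strictly more than
#' half of the trees (such splits are guaranteed mutually compatible)
#' are retained; splits failing the threshold collapse into polytomies.
#' Each consensus branch carries its branch recovery proportion
#' (BRP, occurrence fraction across replicate trees) and its transfer
#' bootstrap expectation (TBE, see [tbe()]). Branch lengths are the
#' mean over the trees containing the split (tip branches over all
#' trees) when all inputs have lengths.
#'
#' @param trees List of `phylo` objects (or `multiPhylo`), >= 2,
#'   identical tip sets.
#' @return A [SupportedTree-class]. The consensus `phylo` carries
#'   `"BRP|TBE"` internal node labels.
#' @export
majorityRuleConsensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) < 2L) .stopf("need at least 2 replicate trees")
  for (t in trees[-1L]) .checkSameTips(trees[[1L]], t)
  k <- length(trees)
  labels <- sort(trees[[1L]]$tip.label)
  n <- length(labels)
  bp <- lapply(trees, bipartitions)
  counts <- table(unlist(lapply(bp, `[[`, "key")))
  keep <- if (length(counts)) names(counts)[counts / k > 0.5] else character(0)
  brp <- as.numeric(counts[keep]) / k
  sets <- lapply(strsplit(keep, ",", fixed = TRUE),
                 function(nm) match(nm, labels))
  p <- vapply(sets, function(s) min(length(s), n - length(s)), integer(1))
  tbeVal <- vapply(seq_along(sets), function(i)
    tbe(labels[sets[[i]]], trees), numeric(1))

  # mean branch lengths (consensus splits over trees containing them)
  haveLen <- all(vapply(trees, function(t) !is.null(t$edge.length), logical(1)))
  splitLen <- tipLen <- NULL
  if (haveLen) {
    splitLen <- stats::setNames(numeric(length(keep)), keep)
    splitCnt <- stats::setNames(numeric(length(keep)), keep)
    tipLenM <- matrix(0, nrow = n, ncol = 0)
    tipAcc <- stats::setNames(numeric(n), labels)
    for (j in seq_len(k)) {
      hit <- match(bp[[j]]$key, keep)
      ok <- !is.na(hit)
      splitLen[hit[ok]] <- splitLen[hit[ok]] + bp[[j]]$length[ok]
      splitCnt[hit[ok]] <- splitCnt[hit[ok]] + 1
      tr <- trees[[j]]
      tl <- stats::setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                                 tr$edge[, 2L])],
                            tr$tip.label)
      tipAcc <- tipAcc + tl[labels]
    }
    splitLen <- splitLen / pmax(splitCnt, 1)
    tipLen <- tipAcc / k
  }

  # build the consensus topology from the laminar family of kept splits
  ord <- order(lengths(sets))
  children <- list()           # node -> list of members (tip idx or group id)
  parentOf <- rep(NA_integer_, length(sets))
  tipParent <- rep(0L, n)      # 0 = attached at the root
  for (i in ord) {
    s <- sets[[i]]
    inside <- tipParent[s]
    # members directly inside this split: groups whose parent is still
    # unset and whose tips are covered, plus uncovered tips
    grpIds <- setdiff(unique(inside), 0L)
    direct <- grpIds[vapply(grpIds, function(g) is.na(parentOf[g]), logical(1))]
    freeTips <- s[inside == 0L]
    children[[as.character(i)]] <- list(tips = freeTips, groups = direct)
    parentOf[direct] <- i
    tipParent[s] <- i
  }
  fmtLab <- function(i) sprintf("%.6g|%.6g", brp[i], tbeVal[i])
  emit <- function(i) {
    ch <- children[[as.character(i)]]
    parts <- c(
      vapply(ch$tips, function(tI) {
        if (haveLen) sprintf("%s:%.10g", labels[tI], tipLen[tI]) else labels[tI]
      }, character(1)),
      vapply(ch$groups, function(g) emit(g), character(1))
    )
    lab <- fmtLab(i)
    br <- if (haveLen) sprintf(":%.10g", splitLen[keep[i]]) else ""
    paste0("(", paste(parts, collapse = ","), ")", lab, br)
  }
  topGroups <- which(is.na(parentOf))
  topTips <- which(tipParent == 0L)
  parts <- c(
    vapply(topTips, function(tI) {
      if (haveLen) sprintf("%s:%.10g", labels[tI], tipLen[tI]) else labels[tI]
    }, character(1)),
    vapply(topGroups, function(g) emit(g), character(1))
  )
  nwk <- paste0("(", paste(parts, collapse = ","), ");")
  cons <- ape::read.tree(text = nwk)

  # map consensus splits back to consensus node ids
  consBp <- if (length(sets)) bipartitions(cons) else list(key = character(0))
  nodeOf <- consBp$node[match(keep, consBp$key)]
  smallSide <- vapply(sets, function(s) {
    if (length(s) <= n - length(s)) paste(labels[s], collapse = ",")
    else paste(labels[-s], collapse = ",")
  }, character(1))
  support <- data.frame(
    node = if (length(keep)) nodeOf else integer(0),
    tips = smallSide,
    p = p, brp = brp, tbe = tbeVal, stringsAsFactors = FALSE)
  new("SupportedTree", tree = cons, support = support, nTrees = as.integer(k))
}

#' @describeIn majorityRuleConsensus Accessor for the consensus `phylo`.
#' @param x A [SupportedTree-class].
#' @export
consensusTree <- function(x) { stopifnot(is(x, "SupportedTree")); x@tree }

#' @describeIn majorityRuleConsensus Accessor for the per-branch support table.
#' @export
branchSupport <- function(x) { stopifnot(is(x, "SupportedTree")); x@support }

setMethod("show", "SupportedTree", function(object) {
  s <- object@support
  cat("SupportedTree: majority-rule consensus of", object@nTrees,
      "replicate trees\n")
  cat("  ", length(object@tree$tip.label), "tips,", nrow(s),
      "supported branches\n")
  if (nrow(s))
    cat(sprintf("  BRP: %.2f-%.2f  TBE: %.2f-%.2f\n",
                min(s$brp), max(s$brp), min(s$tbe), max(s$tbe)))
})

# ---- transfer index / TBE --------------------------------------------------

#' Transfer index of a bipartition with respect to a tree
#'
#' The minimum, over all branches of the tree (trivial tip branches
#' included), of the transfer distance between the branch's bipartition
#' and the query bipartition: the number of tips that must be moved to
#' turn one into the other. Zero iff the bipartition occurs in the tree;
#' never exceeds p-1, where p is the query's smaller-side size.
#'
#' @param side Character vector: the tips on one side of the query
#'   bipartition (the other side is the complement).
#' @param tree An ape `phylo` on the same tip set.
#' @return Integer transfer index.
#' @export
transferIndex <- function(side, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  n <- length(tips)
  if (!all(side %in% tips)) .stopf("bipartition references unknown tips")
  if (length(side) == 0L || length(side) >= n)
    .stopf("bipartition side must be a proper non-empty subset of the tips")
  A <- tips %in% side  # indicator over tree tip order
  below <- .tipsBelow(tree)
  root <- n + 1L
  best <- n
  for (v in seq_len(n + tree$Nnode)) {
    if (v == root) next
    B <- logical(n); B[below[[v]]] <- TRUE
    h <- sum(A != B)
    best <- min(best, h, n - h)
    if (best == 0L) break
  }
  as.integer(best)
}

#' Transfer bootstrap expectation of a branch over replicate trees
#'
#' For each replicate tree the transfer index delta of the branch is
#' computed ([transferIndex()]) and scored as `1 - delta/(p-1)`, where p
#' is the branch's smaller-side size; the TBE is the mean score. For
#' p = 2 the score reduces to presence/absence. Always in \[0,1\] and
#' never below the branch's BRP on the same replicate set.
#'
#' @param side Character vector: tips on one side of the branch.
#' @param trees List of `phylo` objects on the same tip set.
#' @return Numeric TBE in \[0,1\].
#' @export
tbe <- function(side, trees) {
  trees <- unclass(trees)
  if (!length(trees)) .stopf("no replicate trees given")
  tips <- sort(trees[[1L]]$tip.label)
  p <- min(length(side), length(tips) - length(side))
  if (p < 2L) .stopf("TBE is undefined for trivial branches (p = %d)", p)
  scores <- vapply(trees, function(t) {
    d <- transferIndex(side, t)
    1 - d / (p - 1)
  }, numeric(1))
  mean(scores)
}

# ---- Robinson-Foulds -------------------------------------------------------

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of the two trees' non-trivial bipartition
#' sets, divided by the maximum attainable for their resolutions
#' (the total number of bipartitions in both trees): 0 for topologically
#' identical trees, 1 for completely contradictory ones.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return Numeric in \[0,1\].
#' @export
rfNormalized <- function(t1, t2) {
  .checkSameTips(t1, t2)
  k1 <- bipartitions(t1)$key
  k2 <- bipartitions(t2)$key
  denom <- length(k1) + length(k2)
  if (denom == 0L) return(0)
  (denom - 2L * length(intersect(k1, k2))) / denom
}

#' Branch-length-weighted Robinson-Foulds distance
#'
#' Over the union of the two trees' non-trivial bipartitions, sums
#' `|l1 - l2|` (an absent split contributes length 0) and divides by
#' `sum(l1 + l2)`. Identical topologies and lengths give 0; disjoint
#' split sets give 1. Reduces to [rfNormalized()] when all internal
#' lengths are equal and shared-split lengths match.
#'
#' @param t1,t2 `phylo` objects on the same tip set, with branch lengths.
#' @return Numeric in \[0,1\].
#' @export
rfWeighted <- function(t1, t2) {
  .checkSameTips(t1, t2)
  if (is.null(t1$edge.length) || is.null(t2$edge.length))
    .stopf("both trees must have branch lengths")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  u <- union(b1$key, b2$key)
  l1 <- stats::setNames(rep(0, length(u)), u)
  l2 <- l1
  l1[b1$key] <- b1$length
  l2[b2$key] <- b2$length
  denom <- sum(l1 + l2)
  if (denom == 0) return(0)
  sum(abs(l1 - l2)) / denom
}

#' Pairwise Pearson concordance of replicate branch-length vectors
#'
#' @param length_vectors List (or matrix columns) of equal-length numeric
#'   vectors: branch lengths of one fixed topology estimated from each
#'   replicate alignment. Zero-variance vectors yield `NA` (undefined),
#'   never 0.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
branchLengthConcordance <- function(length_vectors) {
  if (is.matrix(length_vectors))
    length_vectors <- lapply(seq_len(ncol(length_vectors)),
                             function(j) length_vectors[, j])
  m <- length(length_vectors)
  if (m < 2L) .stopf("need at least 2 branch-length vectors")
  len <- unique(lengths(length_vectors))
  if (length(len) != 1L) .stopf("vectors must have equal length")
  if (len < 3L) .stopf("vectors must have length >= 3")
  out <- diag(1, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    x <- length_vectors[[i]]; y <- length_vectors[[j]]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    out[i, j] <- out[j, i] <- r
  }
  nms <- names(length_vectors)
  if (!is.null(nms)) dimnames(out) <- list(nms, nms)
  out
}

# ---- NJ fallback -----------------------------------------------------------

#' Missing-aware p-distance matrix
#'
#' Per pair of rows, the proportion of mismatches over the columns where
#' both sequences are non-missing (gap/ambiguous columns excluded
#' pairwise). A pair with zero comparable sites is an error.
#'
#' @param aln A [ModuleAlignment-class].
#' @return A symmetric numeric distance matrix.
#' @export
pDistance <- function(aln) {
  stopifnot(is(aln, "ModuleAlignment"))
  m <- .alnMatrix(aln)
  miss <- matrix(.isMissingChar(m), nrow = nrow(m))
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- !miss[i, ] & !miss[j, ]
    if (!any(ok))
      .stopf("sequences '%s' and '%s' share no comparable sites",
             rownames(m)[i], rownames(m)[j])
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree from an alignment (pipeline fallback)
#'
#' Builds an unrooted tree via neighbor joining on missing-aware
#' p-distances, for end-to-end runs when externally estimated ML trees
#' are not supplied. Negative branch lengths are clamped to 0.
#'
#' @param aln A [ModuleAlignment-class] with >= 4 sequences.
#' @return An ape `phylo`.
#' @export
njTree <- function(aln) {
  stopifnot(is(aln, "ModuleAlignment"))
  if (length(alignedSeqs(aln)) < 4L) .stopf("NJ needs at least 4 sequences")
  d <- pDistance(aln)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
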