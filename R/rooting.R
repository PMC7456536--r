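# Canonical name key of a split: the smaller side, ties broken by the
# lexicographically smaller comma-joined string.
.canonicalSideKey <- function(sideNames, allLabels) {
  a <- sort(sideNames)
  b <- sort(setdiff(allLabels, a))
  ka <- paste(a, collapse = ","); kb <- paste(b, collapse = ",")
  if (length(a) < length(b)) ka
  else if (length(b) < length(a)) kb
  else if (ka < kb) ka else kb
}

# Root an unrooted tree at a point on the edge above `child`, at distance
# `distFromChild` from the child end. Degenerate positions are nudged by
# a hair so the new root edge is never exactly zero-length.
.rootAtEdgePoint <- function(tree, child, distFromChild) {
  row <- which(tree$edge[, 2L] == child)
  l <- tree$edge.length[row]
  eps <- max(l * 1e-9, 1e-12)
  d <- min(max(distFromChild, eps), max(l - eps, eps))
  phytools::reroot(tree, node.number = child, position = l - d)
}

# Deviation statistics of rooting on the edge above `child`.
# D: full node-distance matrix; below: tip indices under each node.
# Returns list(rho, dev) with rho measured from the child end.
.madEdgeObjective <- function(tree, D, below, child, parent, l, nTips) {
  B <- below[[child]]                      # child side
  A <- setdiff(seq_len(nTips), B)          # parent side
  ssConst <- 0; sab <- 0; sbb <- 0; nPairs <- 0L; nSkip <- 0L
  # same-side pairs: ancestor = point on the b..c path nearest the edge
  sameSide <- function(side, anchor) {
    k <- length(side)
    if (k < 2L) return()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      b <- side[i]; c <- side[j]
      dbc <- D[b, c]
      if (dbc == 0) { nSkip <<- nSkip + 1L; next }
      dab <- (dbc + D[anchor, b] - D[anchor, c]) / 2
      ssConst <<- ssConst + (2 * dab / dbc - 1)^2
      nPairs <<- nPairs + 1L
    }
  }
  sameSide(B, child)
  sameSide(A, parent)
  # spanning pairs: ancestor is the candidate root itself
  for (b in B) for (c in A) {
    dbc <- D[b, c]
    if (dbc == 0) { nSkip <- nSkip + 1L; next }
    a0 <- (2 * D[child, b] - dbc) / dbc
    b0 <- 2 * l / dbc
    sab <- sab + a0 * b0
    sbb <- sbb + b0 * b0
    nPairs <- nPairs + 1L
    ssConst <- ssConst + a0 * a0       # constant part; linear handled below
  }
  # SS(rho) = ssConst + 2*sab*rho + sbb*rho^2  (spanning quadratic)
  rho <- if (sbb > 0) min(max(-sab / sbb, 0), 1) else 0.5
  ss <- ssConst + 2 * sab * rho + sbb * rho^2
  dev <- if (nPairs > 0L) sqrt(max(ss, 0) / nPairs) else NA_real_
  list(rho = rho, dev = dev, skipped = nSkip)
}

#' Root a tree by Minimal Ancestor Deviation (MAD)
#'
#' For every branch, finds the position rho (relative, measured from the
#' child end) minimizing the root-mean-square over all tip pairs (b, c)
#' of `|2 d(anc, b)/d(b, c) - 1|`, where the ancestor is the candidate
#' root point for pairs spanning the branch and the ordinary path
#' ancestor for same-side pairs. The per-branch optimum is the
#' closed-form minimizer of the quadratic in rho, clamped to \[0,1\].
#' The branch with the globally minimal deviation is selected; ties
#' within 1e-12 are all reported, and the winner is the branch whose
#' smaller-side tip set is lexicographically smallest. Tip pairs at
#' zero distance are skipped (and counted): their relative deviation is
#' undefined.
#'
#' @param tree An ape `phylo`, >= 2 tips, non-negative branch lengths,
#'   at least one positive. Rooted input is unrooted first.
#' @return List with `tree` (the MAD-rooted `phylo`), `best` (one-row
#'   `data.frame`: `node`, `tips`, `rho`, `deviation`), `candidates`
#'   (the full per-branch table) and `skipped_pairs`.
#' @export
madRoot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stopf("MAD rooting needs branch lengths")
  if (any(tree$edge.length < 0)) .stopf("negative branch lengths")
  if (all(tree$edge.length == 0)) .stopf("all branch lengths are zero")
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n == 2L) {
    l <- sum(tree$edge.length)
    rooted <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                            tree$tip.label[1L], l / 2,
                                            tree$tip.label[2L], l / 2))
    best <- data.frame(node = NA_integer_,
                       tips = sort(tree$tip.label)[1L],
                       rho = 0.5, deviation = 0, stringsAsFactors = FALSE)
    return(list(tree = rooted, best = best, candidates = best,
                skipped_pairs = 0L))
  }
  D <- ape::dist.nodes(tree)
  below <- .tipsBelow(tree)
  res <- lapply(seq_len(nrow(tree$edge)), function(k) {
    parent <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
    l <- tree$edge.length[k]
    ob <- .madEdgeObjective(tree, D, below, child, parent, l, n)
    data.frame(node = child,
               tips = .canonicalSideKey(tree$tip.label[below[[child]]],
                                        tree$tip.label),
               rho = ob$rho, deviation = ob$dev,
               skipped = ob$skipped, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, res)
  skipped <- cand$skipped[1L]
  cand$skipped <- NULL
  dmin <- min(cand$deviation)
  tied <- which(cand$deviation <= dmin + 1e-12)
  winner <- tied[order(cand$tips[tied])][1L]
  child <- cand$node[winner]
  l <- tree$edge.length[tree$edge[, 2L] == child]
  rooted <- .rootAtEdgePoint(tree, child, cand$rho[winner] * l)
  if (skipped > 0L)
    warning(sprintf("%d zero-distance tip pair(s) skipped in MAD deviation",
                    skipped), call. = FALSE)
  list(tree = rooted, best = cand[winner, , drop = FALSE],
       candidates = cand[order(cand$deviation), , drop = FALSE],
       skipped_pairs = as.integer(skipped))
}

#' Root a tree at the phylogenetic midpoint
#'
#' Places the root halfway along the longest tip-to-tip path. Ties on
#' the longest path are broken by the lexicographically smallest tip
#' name pair.
#'
#' @inheritParams madRoot
#' @return List with `tree` (rooted `phylo`), `node` (child end of the
#'   root branch), `tips` (canonical smaller-side tip set of the root
#'   branch, comma-joined) and `diameter` (the longest path length).
#' @export
midpointRoot <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stopf("midpoint rooting needs branch lengths")
  if (all(tree$edge.length == 0)) .stopf("all branch lengths are zero")
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  dt <- D[seq_len(n), seq_len(n), drop = FALSE]
  mx <- max(dt)
  pairs <- which(dt == mx, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
  nm <- cbind(tree$tip.label[pairs[, 1L]], tree$tip.label[pairs[, 2L]])
  o <- order(pmin(nm[, 1L], nm[, 2L]), pmax(nm[, 1L], nm[, 2L]))[1L]
  i <- pairs[o, 1L]; j <- pairs[o, 2L]
  path <- ape::nodepath(tree, i, j)
  steps <- vapply(seq_len(length(path) - 1L), function(k)
    D[path[k], path[k + 1L]], numeric(1))
  cum <- c(0, cumsum(steps))
  half <- mx / 2
  k <- max(which(cum <= half + 1e-12))
  k <- min(k, length(steps))
  a <- path[k]; b <- path[k + 1L]
  row <- which((tree$edge[, 1L] == a & tree$edge[, 2L] == b) |
               (tree$edge[, 1L] == b & tree$edge[, 2L] == a))
  child <- tree$edge[row, 2L]
  distFromChild <- if (child == b) cum[k + 1L] - half else half - cum[k]
  rooted <- .rootAtEdgePoint(tree, child, distFromChild)
  below <- .tipsBelow(tree)
  list(tree = rooted, node = child,
       tips = .canonicalSideKey(tree$tip.label[below[[child]]],
                                tree$tip.label),
       diameter = mx)
}

#' Compare MAD and midpoint root placements
#'
#' Runs both rootings and reports whether they select the same branch;
#' rate-accelerated clades typically pull the midpoint away from the
#' MAD root.
#'
#' @inheritParams madRoot
#' @return List with `mad_branch`, `midpoint_branch` (canonical
#'   smaller-side tip sets), `same` (logical), `mad_deviation`.
#' @export
rootComparison <- function(tree) {
  m <- madRoot(tree)
  p <- midpointRoot(tree)
  list(mad_branch = m$best$tips, midpoint_branch = p$tips,
       same = identical(m$best$tips, p$tips),
       mad_deviation = m$best$deviation)
}

#' Canonical split of the root branch of a rooted tree
#'
#' The bipartition induced by the root: tips under the root's first
#' child, canonicalized to the smaller side (ties: the side with the
#' alphabetically first tip of the two is resolved by size then
#' lexicographic order). Useful for checking root-branch recovery.
#'
#' @param tree A rooted `phylo`.
#' @return Comma-joined sorted tip names of the canonical root split side.
#' @export
rootBranchSplit <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) .stopf("tree is not rooted")
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  below <- .tipsBelow(tree)
  .canonicalSideKey(tree$tip.label[below[[kids[1L]]]], tree$tip.label)
}
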