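# Independent oracles used to cross-check the package's algorithms.
# Everything here recomputes quantities from first principles (grid
# search, exhaustive enumeration, direct set comparison) and must stay
# free of the code paths it checks.

# --- split utilities --------------------------------------------------------

# all non-trivial splits of a tree as canonical comma-joined name keys,
# computed via ape::prop.part (independent of zpmod's bipartitions)
oracleSplitKeys <- function(tr) {
  pp <- ape::prop.part(tr)
  n <- length(tr$tip.label)
  first <- sort(tr$tip.label)[1L]
  keys <- vapply(pp, function(idx) {
    side <- tr$tip.label[idx]
    if (first %in% side) side <- setdiff(tr$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = ",")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# transfer distance of a query side to a tree, by explicitly scoring the
# 2-coloring induced by every branch (tip branches included)
oracleTransferIndex <- function(side, tr) {
  tips <- tr$tip.label
  n <- length(tips)
  A <- tips %in% side
  pp <- ape::prop.part(tr)
  clades <- lapply(pp, function(idx) tips[idx])
  # add tip branches and clade complements
  clades <- c(clades, as.list(tips))
  best <- n
  for (cl in clades) {
    B <- tips %in% cl
    h <- sum(A != B)
    best <- min(best, h, n - h)
  }
  best
}

# exhaustive small parsimony: minimum changes over all internal labelings
oracleParsimony <- function(tr, tipStates) {
  states <- sort(unique(unname(tipStates)))
  n <- length(tr$tip.label)
  nI <- tr$Nnode
  combos <- expand.grid(rep(list(states), nI), stringsAsFactors = FALSE)
  tipLab <- unname(tipStates[tr$tip.label])
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(tipLab, unlist(combos[r, ], use.names = FALSE))
    ch <- sum(lab[tr$edge[, 1L]] != lab[tr$edge[, 2L]])
    if (ch < best) best <- ch
  }
  best
}

# grid-search MAD: evaluates the deviation definition directly on a rho
# grid for every branch; returns the global best
oracleMadGrid <- function(tr, step = 1e-3) {
  n <- length(tr$tip.label)
  D <- ape::dist.nodes(tr)
  po <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(po$edge)))
    below[[po$edge[k, 1L]]] <- c(below[[po$edge[k, 1L]]],
                                 below[[po$edge[k, 2L]]])
  rhos <- seq(0, 1, by = step)
  best <- list(dev = Inf, rho = NA, node = NA)
  for (k in seq_len(nrow(tr$edge))) {
    u <- tr$edge[k, 1L]; v <- tr$edge[k, 2L]; l <- tr$edge.length[k]
    B <- below[[v]]
    d0 <- c(); slope <- c(); dbc <- c()
    for (b in seq_len(n - 1L)) for (c2 in (b + 1L):n) {
      dd <- D[b, c2]
      if (dd == 0) next
      inB <- c(b %in% B, c2 %in% B)
      if (xor(inB[1L], inB[2L])) {
        bb <- if (inB[1L]) b else c2
        d0 <- c(d0, D[v, bb]); slope <- c(slope, l)
      } else {
        anchor <- if (inB[1L]) v else u
        d0 <- c(d0, (dd + D[anchor, b] - D[anchor, c2]) / 2)
        slope <- c(slope, 0)
      }
      dbc <- c(dbc, dd)
    }
    for (rho in rhos) {
      dev <- sqrt(mean((2 * (d0 + slope * rho) / dbc - 1)^2))
      if (dev < best$dev) best <- list(dev = dev, rho = rho, node = v)
    }
  }
  best
}

# does `tips` form a clade (split side) of the unrooted tree?
isSplitSide <- function(tr, tips) {
  bp <- bipartitions(tr)
  keyA <- paste(sort(tips), collapse = ",")
  keyB <- paste(sort(setdiff(tr$tip.label, tips)), collapse = ",")
  keyA %in% bp$key || keyB %in% bp$key
}

# --- random structures ------------------------------------------------------

randomUnrootedTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  ape::unroot(tr)
}

# clocklike tree with multiplicative branch-length noise (sd as fraction)
noisyClockTree <- function(n, seed, sdFrac = 0.05) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  trueSplit <- rootBranchSplit(tr)
  u <- ape::unroot(tr)
  u$edge.length <- u$edge.length *
    (1 + stats::rnorm(length(u$edge.length), 0, sdFrac))
  u$edge.length[u$edge.length <= 0] <- 1e-8
  list(tree = u, trueSplit = trueSplit)
}

smallSpec <- function(seed = 1L, ...) {
  syntheticSpec(n_subfamilies = 4L, n_species = 4L, n_replicates = 4L,
                seed = seed, ...)
}
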