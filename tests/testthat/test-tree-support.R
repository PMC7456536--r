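test_that("Newick I/O round-trips and rejects malformed input", {
  tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(length(tr$tip.label), 4L)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewickTree(tr, f)
  tr2 <- readNewickTree(f)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))
  expect_error(readNewickTree("((A,B,(C;"), "malformed")
  expect_error(readNewickTree("((A:1,A:1):1,(C:1,D:1):1);"), "duplicate")
})

test_that("bipartition counts are n-3 on resolved trees, 0 on stars", {
  tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(length(bipartitions(tr)$key), 1L)
  star <- readNewickTree("(A:1,B:1,C:1,D:1,E:1);")
  expect_equal(length(bipartitions(star)$key), 0L)
  for (seed in 1:8) {
    n <- sample(4:40, 1)
    tr <- randomUnrootedTree(n, seed)
    expect_equal(length(bipartitions(tr)$key), n - 3L)
  }
})

test_that("bipartition sets agree with an independent split enumeration", {
  for (seed in 1:10) {
    tr <- randomUnrootedTree(sample(5:12, 1), seed + 100)
    keys <- sort(bipartitions(tr)$key)
    expect_equal(keys, sort(oracleSplitKeys(tr)))
  }
})

test_that("majority-rule consensus keeps >50% splits with correct BRP", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  t3 <- readNewickTree("((A:1,C:1):1,(B:1,D:1):1);")
  # identical trees: same topology, all BRP 1
  consSame <- majorityRuleConsensus(list(t1, t1, t1))
  expect_equal(branchSupport(consSame)$brp, 1.0)
  expect_equal(rfNormalized(consensusTree(consSame), t1), 0)
  # 2x AB|CD + 1x AC|BD
  cons <- majorityRuleConsensus(list(t1, t1, t3))
  s <- branchSupport(cons)
  expect_equal(nrow(s), 1L)
  expect_equal(s$tips, "C,D")
  expect_equal(s$brp, 2 / 3)
  # three mutually conflicting 4-tip trees: star
  t2 <- readNewickTree("((A:1,D:1):1,(C:1,B:1):1);")
  consStar <- majorityRuleConsensus(list(t1, t2, t3))
  expect_equal(nrow(branchSupport(consStar)), 0L)
  expect_equal(consensusTree(consStar)$Nnode, 1L)
  # mismatched tip sets are hard errors
  t4 <- readNewickTree("((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(majorityRuleConsensus(list(t1, t4)), "tip")
})

test_that("consensus is idempotent", {
  set.seed(9)
  trees <- lapply(1:5, function(i) {
    tr <- ape::rtree(8)
    tr$tip.label <- paste0("t", match(tr$tip.label, sort(tr$tip.label)))
    ape::unroot(tr)
  })
  cons <- majorityRuleConsensus(trees)
  again <- majorityRuleConsensus(list(consensusTree(cons),
                                      consensusTree(cons)))
  expect_equal(rfNormalized(consensusTree(cons), consensusTree(again)), 0)
})

test_that("transfer index matches the exhaustive per-branch oracle", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(transferIndex(c("A", "B"), t1), 0L)
  # absent cherry: delta must be exactly 1
  expect_equal(transferIndex(c("A", "C"), t1), 1L)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    tr <- ape::unroot(ape::rtree(n))
    refTr <- ape::unroot(ape::rtree(n))
    refTr$tip.label <- sample(tr$tip.label)
    splits <- bipartitions(refTr)
    if (!length(splits$key)) next
    j <- sample(length(splits$key), 1)
    side <- splits$labels[splits$sets[[j]]]
    d <- transferIndex(side, tr)
    expect_equal(d, oracleTransferIndex(side, tr))
    expect_lte(d, min(length(side), n - length(side)) - 1L)
  }
})

test_that("TBE floors at 0, equals 1 for omnipresent branches, errors on trivial", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(tbe(c("A", "B"), list(t1, t1, t1)), 1.0)
  # p=4 branch at maximal transfer distance in a single tree scores 0
  cat8 <- readNewickTree("(((((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1):1,G:1):1,H:1);")
  side <- c("A", "C", "E", "G")
  d <- oracleTransferIndex(side, cat8)
  expect_equal(d, 3)                       # worst case for p = 4
  expect_equal(tbe(side, list(cat8)), 0)   # floors at delta = p - 1
  expect_error(tbe("A", list(t1)), "trivial")
})

test_that("TBE is never below BRP across random replicate sets", {
  set.seed(77)
  for (trial in 1:60) {
    n <- sample(6:9, 1)
    base <- ape::rtree(n)
    trees <- lapply(1:4, function(i) {
      tr <- if (i <= 2) base else ape::rtree(n)
      tr$tip.label <- paste0("t", match(tr$tip.label, sort(tr$tip.label)))
      ape::unroot(tr)
    })
    cons <- majorityRuleConsensus(trees)
    s <- branchSupport(cons)
    if (nrow(s)) expect_true(all(s$tbe >= s$brp - 1e-12))
  }
})

test_that("normalized RF matches brute-force split comparison and is a metric", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  t3 <- readNewickTree("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rfNormalized(t1, t1), 0)
  expect_equal(rfNormalized(t1, t3), 1.0)
  set.seed(31)
  mk <- function() {
    tr <- ape::unroot(ape::rtree(8))
    tr$tip.label <- paste0("t", match(tr$tip.label, sort(tr$tip.label)))
    tr
  }
  for (i in 1:20) {
    a <- mk(); b <- mk()
    ka <- oracleSplitKeys(a); kb <- oracleSplitKeys(b)
    expected <- (length(ka) + length(kb) - 2 * length(intersect(ka, kb))) /
      (length(ka) + length(kb))
    expect_equal(rfNormalized(a, b), expected)
  }
  # metric properties on random triples
  for (i in 1:10) {
    a <- mk(); b <- mk(); c <- mk()
    expect_equal(rfNormalized(a, b), rfNormalized(b, a))
    expect_gte(rfNormalized(a, b) + rfNormalized(b, c),
               rfNormalized(a, c) - 1e-12)
  }
})

test_that("weighted RF has the stated boundary behavior and matches a union sum", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  t3 <- readNewickTree("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rfWeighted(t1, t1), 0)
  expect_equal(rfWeighted(t1, t3), 1.0)
  set.seed(41)
  for (i in 1:20) {
    a <- ape::unroot(ape::rtree(8)); b <- ape::unroot(ape::rtree(8))
    a$tip.label <- paste0("t", match(a$tip.label, sort(a$tip.label)))
    b$tip.label <- paste0("t", match(b$tip.label, sort(b$tip.label)))
    ba <- bipartitions(a); bb <- bipartitions(b)
    u <- union(ba$key, bb$key)
    la <- stats::setNames(rep(0, length(u)), u); lb <- la
    la[ba$key] <- ba$length; lb[bb$key] <- bb$length
    expect_equal(rfWeighted(a, b), sum(abs(la - lb)) / sum(la + lb))
  }
  noLen <- ape::rtree(6); noLen$edge.length <- NULL
  expect_error(rfWeighted(noLen, noLen), "lengths")
})

test_that("branch-length concordance is Pearson r with NA for zero variance", {
  v <- c(0.1, 0.5, 0.9, 1.3)
  m <- branchLengthConcordance(list(a = v, b = 2 * v))
  expect_equal(m["a", "b"], 1.0)
  set.seed(51)
  x <- runif(10); y <- runif(10)
  m2 <- branchLengthConcordance(list(x = x, y = y))
  expect_equal(m2["x", "y"],
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  m3 <- branchLengthConcordance(list(a = v, flat = rep(1, 4)))
  expect_true(is.na(m3["a", "flat"]))
  expect_equal(diag(m3), c(a = 1, flat = 1))
})

test_that("NJ fallback recovers additive topologies and handles ties deterministically", {
  # 4 sequences engineered so p-distances are additive with AB|CD structure
  seqs <- c(A = "AAAAAAAAAACCCCC",
            B = "AAAAAAAAAAGGGGG",
            C = "TTTTTTTTTTCCCCC",
            D = "TTTTTTTTTTGGGGG")
  tr <- njTree(moduleAlignment(seqs))
  expect_equal(sort(bipartitions(tr)$key), "C,D")
  expect_true(all(tr$edge.length >= 0))
  # identical sequences: all lengths zero
  same <- stats::setNames(rep("ACDEACDEACDE", 4), c("a", "b", "c", "d"))
  tr0 <- njTree(moduleAlignment(same))
  expect_true(all(tr0$edge.length == 0))
  # deterministic
  expect_equal(ape::write.tree(njTree(moduleAlignment(seqs))),
               ape::write.tree(njTree(moduleAlignment(seqs))))
  # pair with no comparable sites
  bad <- c(a = "AC--", b = "AC--", c = "--AG", d = "ACAG")
  expect_error(njTree(moduleAlignment(bad)), "comparable")
})

test_that("missing-aware p-distance excludes pairwise-missing sites", {
  aln <- moduleAlignment(c(a = "ACDE-X", b = "ACDFGG", c = "ACDEGG"))
  d <- pDistance(aln)
  expect_equal(d["a", "b"], 1 / 4)   # comparable: cols 1-4
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "c"], 1 / 6)
  expect_equal(d, t(d))
})
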