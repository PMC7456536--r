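test_that("family trees have the requested shape and are deterministic", {
  s1 <- syntheticSpec(n_subfamilies = 1L, n_species = 3L, seed = 3L)
  t1 <- simulateFamilyTree(s1)
  expect_equal(length(t1$tip.label), 3L)
  expect_equal(length(bipartitions(t1)$key), 0L)

  s2 <- syntheticSpec(n_subfamilies = 4L, n_species = 5L, seed = 3L)
  t2 <- simulateFamilyTree(s2)
  expect_equal(length(t2$tip.label), 20L)
  expect_equal(length(bipartitions(t2)$key), 17L)  # n - 3
  # every subfamily is a clade
  for (sf in paste0("SF", 1:4)) {
    tips <- grep(sf, t2$tip.label, value = TRUE)
    expect_true(isSplitSide(t2, tips))
  }
  # determinism
  expect_identical(ape::write.tree(simulateFamilyTree(s2)),
                   ape::write.tree(simulateFamilyTree(s2)))
  expect_error(syntheticSpec(n_subfamilies = 0L), "positive")
})

test_that("backbone branches are much longer than within-subfamily branches", {
  spec <- syntheticSpec(seed = 8L)
  tr <- simulateFamilyTree(spec)
  bp <- bipartitions(tr)
  sf <- sub("_SP.*$", "", bp$labels)
  isBackbone <- vapply(bp$sets, function(s) {
    inSide <- unique(sf[s]); outSide <- unique(sf[-s])
    length(intersect(inSide, outSide)) == 0L && length(inSide) >= 1L &&
      (length(inSide) > 1L || length(s) == sum(sf == inSide))
  }, logical(1))
  expect_gt(mean(bp$length[isBackbone]), 3 * mean(bp$length[!isBackbone]))
})

test_that("sequence evolution respects the planted cysteine layouts", {
  spec <- syntheticSpec(seed = 5L)
  tr <- simulateFamilyTree(spec)
  reg <- defaultRegistry()
  seqs <- evolveSequences(tr, spec, reg)
  expect_equal(sort(names(seqs)), sort(tr$tip.label))
  expect_true(all(nchar(seqs) == 240L))
  ch3 <- strsplit(seqs[["SF5_SP1"]], "")[[1]]  # SF5 is Type 3
  expect_equal(ch3[c(105, 134, 140)], c("C", "C", "C"))
  expect_false(ch3[206] == "C")
  ch1 <- strsplit(seqs[["SF1_SP1"]], "")[[1]]  # SF1 is Type 1
  expect_equal(ch1[c(146, 164, 201, 206, 210)], rep("C", 5))
  expect_false(any(ch1[c(105, 134, 140)] == "C"))
  # zero rate: all tips identical to each other (and to the root)
  spec0 <- syntheticSpec(subs_rate = 0, seed = 5L,
                         type_assignments = c(SF1 = "Type1", SF2 = "Type1",
                                              SF3 = "Type1", SF4 = "Type1",
                                              SF5 = "Type1", SF6 = "Type1"))
  seqs0 <- evolveSequences(simulateFamilyTree(spec0), spec0, reg)
  expect_equal(length(unique(unname(seqs0))), 1L)
})

test_that("variable-column fraction tracks the Poisson expectation", {
  reg <- defaultRegistry()
  obs <- exp <- numeric(0)
  for (seed in 1:10) {
    spec <- syntheticSpec(n_subfamilies = 1L, n_species = 4L,
                          subs_rate = 0.25, seed = seed)
    tr <- simulateFamilyTree(spec)
    seqs <- evolveSequences(tr, spec, reg)
    bg <- setdiff(seq_len(240), unlist(registrySites(reg)$columns))
    m <- do.call(rbind, strsplit(unname(seqs), ""))
    variable <- vapply(bg, function(j) length(unique(m[, j])) > 1L,
                       logical(1))
    obs <- c(obs, mean(variable))
    # P(any substitution event on the tree) for one site
    exp <- c(exp, 1 - exp(-sum(tr$edge.length)))
  }
  expect_lt(abs(mean(obs) - mean(exp)), 0.05)
})

test_that("planted domain loss realizes the target gap regime", {
  set.seed(1)
  L <- 240L
  seqs <- stats::setNames(
    replicate(100, paste(sample(c("A", "D", "E"), L, replace = TRUE),
                         collapse = "")), paste0("tip", 1:100))
  out <- plantDomainLoss(seqs, names(seqs), c(1, 80), noise = TRUE, seed = 2L)
  gaps <- vapply(out, function(s)
    mean(strsplit(substr(s, 1, 80), "")[[1]] == "-"), numeric(1))
  expect_true(all(gaps >= 0.80 & gaps <= 0.99))
  # noise off: complete loss
  one <- plantDomainLoss(seqs[1], names(seqs)[1], c(1, 80), noise = FALSE)
  expect_equal(mean(strsplit(substr(one[[1]], 1, 80), "")[[1]] == "-"), 1.0)
  # non-loss tips untouched
  part <- plantDomainLoss(seqs, "tip1", c(1, 80), seed = 2L)
  expect_identical(unname(part["tip2"]), unname(seqs["tip2"]))
  expect_error(plantDomainLoss(seqs, "tip1", c(80, 1)), "interval")
})

test_that("replicate alignments jitter gaps mildly and keep the name set", {
  spec <- smallSpec(seed = 4L)
  b <- makeFixtureBundle(spec, dir = withr::local_tempdir())
  reps <- b$replicates
  expect_equal(length(reps), 4L)
  nms <- seqNames(reps[[1]])
  for (r in reps) expect_equal(sort(seqNames(r)), sort(nms))
  # zero jitter + fixed flanks impossible; but sd=0 keeps gap columns fixed
  spec0 <- smallSpec(seed = 4L, gap_jitter_sd = 0)
  seqs <- b$sequences
  reps0 <- emitReplicateAlignments(seqs, spec0)
  base <- alignedSeqs(reps0[[1]])
  for (k in 2:length(reps0)) {
    rk <- alignedSeqs(reps0[[k]])
    # flank trim aside, interior gap structure is untouched
    expect_true(all(vapply(nms, function(nm)
      grepl(rk[[nm]], base[[nm]], fixed = TRUE), logical(1))))
  }
  # per-sequence domain gap proportions stay within 0.15 of replicate 0
  for (seed in 1:10) {
    bb <- makeFixtureBundle(smallSpec(seed = seed),
                            dir = withr::local_tempdir(), structures = character(0))
    profs <- lapply(bb$replicates, function(aln) {
      a <- locateAnchors(aln)
      dm <- demarcateDomains(a, n_cols = nCols(aln))
      vapply(seqNames(aln), function(nm)
        gapProportion(aln, nm, c(dm$start[2], dm$end[2])), numeric(1))
    })
    base <- profs[[1]]
    for (k in 2:length(profs))
      expect_true(all(abs(profs[[k]] - base) < 0.15))
  }
})

test_that("synthesized coordinates realize planted and decoy geometry", {
  seq1 <- paste(c(rep("A", 100), "C", rep("A", 30), "C", rep("A", 50), "C",
                  rep("A", 40), "C", rep("A", 16)), collapse = "")
  cysCols <- which(strsplit(seq1, "")[[1]] == "C")
  expect_equal(length(cysCols), 4L)
  planted <- matrix(cysCols[1:2], ncol = 2)
  m <- synthesizeCoordinates(seq1, planted, seed = 11L)
  d <- pairDistance(m, planted[1], planted[2])
  expect_gte(d, 2.0); expect_lte(d, 6.0)
  # all non-planted pairs at least 10 apart
  for (i in 1:3) for (j in (i + 1):4) {
    if (i == 1 && j == 2) next
    expect_gte(pairDistance(m, cysCols[i], cysCols[j]), 10)
  }
  # no planted pairs: every pair distant
  m0 <- synthesizeCoordinates(seq1, NULL, seed = 11L)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gte(pairDistance(m0, cysCols[i], cysCols[j]), 10)
  expect_error(synthesizeCoordinates("----", NULL), "empty")
  expect_error(synthesizeCoordinates(seq1, matrix(c(1L, 2L), ncol = 2)),
               "cysteine")
})

test_that("planted geometry survives a file round-trip", {
  seq1 <- paste(c(rep("A", 104), "C", rep("A", 28), "C", rep("A", 107)),
                collapse = "")
  m <- synthesizeCoordinates(seq1, matrix(c(105L, 134L), ncol = 2), seed = 3L)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  map <- withr::local_tempfile(fileext = ".tsv")
  writeStructure(m, pdb, map)
  m2 <- readStructure(pdb, map)
  expect_equal(nResidues(m2), nResidues(m))
  d <- pairDistance(m2, 105L, 134L)
  expect_gte(d, 2.0); expect_lte(d, 6.0)
  expect_equal(d, pairDistance(m, 105L, 134L), tolerance = 1e-3)
})

test_that("fixture bundles are complete, self-consistent and reproducible", {
  spec <- smallSpec(seed = 6L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- makeFixtureBundle(spec, dir = d1, structures = character(0))
  b2 <- makeFixtureBundle(spec, dir = d2, structures = character(0))
  expect_equal(length(list.files(d1, pattern = "rep[0-9]+\\.fasta$")),
               spec@nReplicates)
  # identical (spec, seed): byte-identical truth records
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  # truth loss tips == tips under the loss subfamily clades of the tree
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  tr <- readNewickTree(file.path(d1, "true_tree.nwk"))
  lossSf <- unique(sub("_SP.*$", "", unlist(truth$loss_tips)))
  expected <- sort(tr$tip.label[sub("_SP.*$", "", tr$tip.label) %in% lossSf])
  expect_equal(sort(unlist(truth$loss_tips)), expected)
  for (sf in lossSf)
    expect_true(isSplitSide(tr, grep(sf, tr$tip.label, value = TRUE)))
})

test_that("bundle gap regime matches the intended background/loss separation", {
  spec <- syntheticSpec(seed = 10L)
  b <- makeFixtureBundle(spec, dir = withr::local_tempdir(),
                         structures = character(0))
  isLoss <- names(b$sequences) %in% b$truth@lossTips
  # overall missing fraction of background (non-loss) sequences: 6-8% +/- 2pp
  bgFrac <- vapply(b$sequences[!isLoss], function(s)
    mean(strsplit(s, "")[[1]] == "-"), numeric(1))
  expect_gte(mean(bgFrac), 0.04)
  expect_lte(mean(bgFrac), 0.10)
  # loss tips: ZP-N gap at least 0.80 - 2pp in every case
  prof <- meanGapProfiles(b$replicates)
  lossZPN <- prof$gap_fraction[prof$domain == "ZP-N" &
                               prof$name %in% b$truth@lossTips]
  expect_true(all(lossZPN >= 0.78))
})
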