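test_that("structure reading validates the residue-column map", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  CYS A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  CYS A   2       3.800   1.500   0.000  1.00  0.00           C",
    "ATOM      4  SG  CYS A   2       3.800   3.300   0.000  1.00  0.00           S",
    "ATOM      5  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  writeLines(c("residue_number\talignment_column", "1\t10", "2\t11", "3\t12"),
             map)
  m <- readStructure(pdb, map)
  expect_s4_class(m, "StructureModel")
  expect_equal(nResidues(m), 3L)
  # map row referencing an absent residue
  writeLines(c("residue_number\talignment_column", "1\t10", "99\t11"), map)
  expect_error(readStructure(pdb, map), "absent")
})

test_that("cysteine centroids average CB and SG, with CA fallback", {
  atoms <- data.frame(
    resno = c(1L, 1L, 1L, 2L),
    resname = c("CYS", "CYS", "CYS", "CYS"),
    atom = c("CA", "CB", "SG", "CA"),
    x = c(-1, 0, 2, 5), y = c(0, 0, 0, 5), z = c(0, 0, 0, 5))
  m <- new("StructureModel", atoms = atoms,
           map = stats::setNames(c(7L, 9L), c("1", "2")), chain = "A")
  expect_equal(cysCentroid(m, 7L), c(x = 1, y = 0, z = 0))
  expect_warning(c2 <- cysCentroid(m, 9L), "CA")
  expect_equal(unname(c2), c(5, 5, 5))
  expect_error(cysCentroid(m, 99L), "unmapped")
  atoms$resname[4] <- "ALA"
  mBad <- new("StructureModel", atoms = atoms,
              map = stats::setNames(c(7L, 9L), c("1", "2")), chain = "A")
  expect_error(cysCentroid(mBad, 9L), "not a cysteine")
})

test_that("pair distances are Euclidean, symmetric and match planted truth", {
  atoms <- data.frame(
    resno = c(1L, 1L, 2L, 2L),
    resname = "CYS",
    atom = c("CB", "SG", "CB", "SG"),
    x = c(0, 0, 3, 3), y = c(0, 0, 4, 4), z = c(0, 0, 0, 0))
  m <- new("StructureModel", atoms = atoms,
           map = stats::setNames(c(1L, 2L), c("1", "2")), chain = "A")
  expect_equal(pairDistance(m, 1L, 2L), 5)
  expect_equal(pairDistance(m, 2L, 1L), pairDistance(m, 1L, 2L))
})

test_that("greedy disulfide calling builds a matching and honors thresholds", {
  mk <- function(coords) {
    rows <- do.call(rbind, lapply(seq_along(coords), function(i)
      data.frame(resno = i, resname = "CYS", atom = c("CB", "SG"),
                 x = coords[[i]][1], y = coords[[i]][2],
                 z = coords[[i]][3])))
    new("StructureModel", atoms = rows,
        map = stats::setNames(seq_along(coords) * 10L,
                              as.character(seq_along(coords))), chain = "A")
  }
  # A-B at 5, B-C at 6, A-C at 12 (1D): greedy pairs A-B only
  m <- mk(list(c(0, 0, 0), c(5, 0, 0), c(11, 0, 0)))
  calls <- callDisulfides(m, c(10L, 20L, 30L))
  called <- calls[calls$status == "called", ]
  expect_equal(nrow(called), 1L)
  expect_equal(c(called$colA, called$colB), c(10L, 20L))
  # B consumed, so B-C is not called even though it is below threshold
  expect_false(any(calls$status == "called" & calls$colA == 20L &
                   calls$colB == 30L))
  # no cysteine occurs in two called pairs (matching property)
  m4 <- mk(list(c(0, 0, 0), c(3, 0, 0), c(4, 0, 0), c(7, 0, 0)))
  calls4 <- callDisulfides(m4, c(10L, 20L, 30L, 40L))
  usedCys <- c(calls4$colA[calls4$status == "called"],
               calls4$colB[calls4$status == "called"])
  expect_equal(anyDuplicated(usedCys), 0L)
  # distance > proximal: not called
  far <- mk(list(c(0, 0, 0), c(12, 0, 0)))
  expect_equal(callDisulfides(far, c(10L, 20L))$status, "not_called")
  close2 <- mk(list(c(0, 0, 0), c(2.05, 0, 0)))
  expect_equal(callDisulfides(close2, c(10L, 20L))$status, "called")
})

test_that("presence vectors use the tolerance window and alternative columns", {
  reg <- defaultRegistry()
  base <- rep("A", 240)
  s <- base; s[146] <- "C"
  pv <- presenceVector(paste(s, collapse = ""), reg)
  expect_true(pv[["Cys5"]])
  expect_false(pv[["Cys7"]])
  # C at 216 matches Cys8 via the 215/218 alternatives with window 2
  s2 <- base; s2[216] <- "C"
  expect_true(presenceVector(paste(s2, collapse = ""), reg)[["Cys8"]])
  # K at 146 / A at 201 (no nearby C): Cys5 and Cys7 absent
  s3 <- base; s3[146] <- "K"; s3[201] <- "A"
  pv3 <- presenceVector(paste(s3, collapse = ""), reg)
  expect_false(pv3[["Cys5"]]); expect_false(pv3[["Cys7"]])
})

test_that("type classification implements the Type 1/2/3 rules and flags", {
  reg <- defaultRegistry()
  mkPresence <- function(present) {
    nm <- registrySites(reg)$name
    stats::setNames(nm %in% present, nm)
  }
  core <- c("Cys1", "Cys2", "Cys3", "Cys4", "Cys5", "Cys6", "Cys7", "Cys8")
  t1 <- classifyType(mkPresence(c(core, "CysA", "CysB")))
  expect_equal(t1$type, "Type1")
  expect_equal(t1$flags, character(0))
  t2 <- classifyType(mkPresence(c(core, "CysA", "CysB", "IHP_A", "IHP_B")))
  expect_equal(t2$type, "Type2")
  t3 <- classifyType(mkPresence(c(core, "CysB", "IHP_A", "IHP_B",
                                  "T3_partner")))
  expect_equal(t3$type, "Type3")
  # single IHP cysteine fits no rule
  odd <- classifyType(mkPresence(c(core, "CysA", "CysB", "IHP_A")))
  expect_equal(odd$type, "atypical")
  # flags: Cys5-Cys7 loss (lysine/alanine replacement) and CysA-CysB loss
  c57 <- classifyType(mkPresence(c("Cys6", "Cys8", "CysA", "CysB")))
  expect_true("Cys5-Cys7 loss" %in% c57$flags)
  cab <- classifyType(mkPresence(core))
  expect_true("CysA-CysB loss" %in% cab$flags)
})

test_that("classification is a pure function over presence patterns", {
  reg <- defaultRegistry()
  nm <- registrySites(reg)$name
  key <- c("IHP_A", "IHP_B", "CysA", "T3_partner")
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), 4))
  for (r in seq_len(nrow(combos))) {
    pres <- stats::setNames(rep(TRUE, length(nm)), nm)
    pres[key] <- unlist(combos[r, ])
    out1 <- classifyType(pres)
    out2 <- classifyType(pres)
    expect_identical(out1, out2)
    expect_true(out1$type %in% c("Type1", "Type2", "Type3", "atypical"))
    # the Type3 rule is the Type2 rule with CysA swapped for the partner
    if (out1$type == "Type3") {
      expect_true(pres[["IHP_A"]] && pres[["IHP_B"]])
      expect_false(pres[["CysA"]])
      expect_true(pres[["T3_partner"]])
    }
  }
})

test_that("Fitch parsimony matches exhaustive minimization and tie-breaks", {
  tf <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  same <- stats::setNames(rep("Type1", 4), LETTERS[1:4])
  expect_equal(fitchParsimony(tf, same)$changes, 0L)
  half <- c(A = "Type1", B = "Type1", C = "Type2", D = "Type2")
  expect_equal(fitchParsimony(tf, half)$changes, 1L)
  set.seed(61)
  for (i in 1:12) {
    tr <- ape::rtree(8)
    tr$tip.label <- LETTERS[1:8]
    states <- sample(c("Type1", "Type2", "Type3"), 8, replace = TRUE)
    names(states) <- tr$tip.label
    f <- fitchParsimony(tr, states)
    expect_equal(f$changes, oracleParsimony(tr, states))
    # returned labeling achieves the reported count
    realized <- sum(f$labels[tr$edge[, 1]] != f$labels[tr$edge[, 2]])
    expect_equal(realized, f$changes)
  }
  expect_error(fitchParsimony(tf, half[-1]), "unlabeled")
})
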