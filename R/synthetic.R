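#' Specify a synthetic ZP-module family
#'
#' Constructor for [SyntheticSpec-class]. The defaults are the
#' generator's study conditions: an ancient gene family of 6 paralogous
#' subfamilies across 5 species, 240-column trimmed alignments, ~1
#' expected substitution/site root-to-tip, 10 replicate alignments with
#' 1-column gap jitter, ZP-N loss planted in two subfamilies (one Type 2,
#' one Type 3, mirroring the standalone ZP-C subfamilies), and
#' connectivity types covering Type 1/2/3.
#'
#' @param n_subfamilies,n_species Tip grid (`SF<i>_SP<j>` naming).
#' @param seq_length Alignment columns (>= 220).
#' @param subs_rate Expected substitutions/site root-to-tip.
#' @param gap_jitter_sd SD (columns) of replicate gap-block jitter.
#' @param n_replicates Number of replicate alignments (>= 2).
#' @param loss_subfamilies `data.frame(subfamily, domain)` of planted
#'   domain losses.
#' @param type_assignments Named character vector subfamily -> type.
#' @param seed Integer master seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(n_subfamilies = 6L, n_species = 5L,
                          seq_length = 240L, subs_rate = 1.0,
                          gap_jitter_sd = 1.0, n_replicates = 10L,
                          loss_subfamilies = data.frame(
                            subfamily = c("SF2", "SF5"),
                            domain = c("ZP-N", "ZP-N"),
                            stringsAsFactors = FALSE),
                          type_assignments = c(
                            SF1 = "Type1", SF2 = "Type2", SF3 = "Type2",
                            SF4 = "Type1", SF5 = "Type3", SF6 = "Type3"),
                          seed = 1L) {
  if (n_subfamilies < 1L || n_species < 1L)
    .stopf("subfamily and species counts must be positive")
  keep <- names(type_assignments) %in% paste0("SF", seq_len(n_subfamilies))
  type_assignments <- type_assignments[keep]
  if (nrow(loss_subfamilies))
    loss_subfamilies <- loss_subfamilies[
      loss_subfamilies$subfamily %in% paste0("SF", seq_len(n_subfamilies)), ,
      drop = FALSE]
  new("SyntheticSpec",
      nSubfamilies = as.integer(n_subfamilies),
      nSpecies = as.integer(n_species),
      seqLength = as.integer(seq_length),
      subsRate = as.numeric(subs_rate),
      gapJitterSd = as.numeric(gap_jitter_sd),
      nReplicates = as.integer(n_replicates),
      lossSubfamilies = loss_subfamilies,
      typeAssignments = type_assignments,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nSubfamilies, "subfamilies x",
      object@nSpecies, "species;", object@seqLength, "columns;",
      object@nReplicates, "replicates; seed", object@seed, "\n")
  if (nrow(object@lossSubfamilies))
    cat("  planted loss:",
        paste(object@lossSubfamilies$subfamily, collapse = ", "),
        "(", unique(object@lossSubfamilies$domain), ")\n")
})

# type of a tip's subfamily under a spec (unassigned -> Type1)
.tipType <- function(spec, subfamily) {
  t <- spec@typeAssignments[subfamily]
  ifelse(is.na(t), "Type1", unname(t))
}

# coalescent-style random join of items (newick fragments with heights)
.randomJoin <- function(texts, heights, incRange) {
  while (length(texts) > 1L) {
    pick <- sample.int(length(texts), 2L)
    h <- max(heights[pick]) + stats::runif(1, incRange[1L], incRange[2L])
    nw <- sprintf("(%s:%.10g,%s:%.10g)",
                  texts[pick[1L]], h - heights[pick[1L]],
                  texts[pick[2L]], h - heights[pick[2L]])
    texts <- c(texts[-pick], nw)
    heights <- c(heights[-pick], h)
  }
  list(text = texts, height = heights)
}

#' Simulate the true family tree
#'
#' Builds an unrooted binary tree with `n_subfamilies * n_species` tips
#' named `SF<i>_SP<j>`. Each subfamily forms a clade; the backbone
#' branches connecting subfamilies are drawn ~5x longer than
#' within-subfamily branches (ancient paralogous origins). The tree is
#' generated clocklike, mild branch-wise rate noise is applied, and all
#' lengths are scaled so the mean root-to-tip path equals `subs_rate`.
#' Deterministic given the spec's seed.
#'
#' @param spec A [SyntheticSpec-class].
#' @return An ape `phylo` (unrooted when > 3 tips allow it).
#' @export
simulateFamilyTree <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nSubfamilies < 1L || spec@nSpecies < 3L)
    .stopf("need n_subfamilies >= 1 and n_species >= 3")
  .withSeed(spec@seed, 1L, {
    subTexts <- character(0); subHeights <- numeric(0)
    for (i in seq_len(spec@nSubfamilies)) {
      tips <- paste0("SF", i, "_SP", seq_len(spec@nSpecies))
      j <- .randomJoin(tips, rep(0, length(tips)), c(0.2, 0.6))
      subTexts <- c(subTexts, j$text)
      subHeights <- c(subHeights, j$height)
    }
    top <- .randomJoin(subTexts, subHeights, c(1.5, 3.0))
    tr <- ape::read.tree(text = paste0(top$text, ";"))
    # mild branch-wise rate noise, then calibrate depth to subs_rate
    tr$edge.length <- tr$edge.length * stats::runif(length(tr$edge.length),
                                                    0.85, 1.15)
    depth <- mean(ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)])
    if (depth > 0) tr$edge.length <- tr$edge.length * spec@subsRate / depth
    ape::unroot(tr)
  })
}

#' Evolve aligned (gap-free) sequences along the family tree
#'
#' The root sequence carries random non-cysteine residues at background
#' columns; substitutions are placed site-wise by a Poisson process along
#' each branch (an event always changes the residue, drawn uniformly
#' from the other non-cysteine residues). Registry cysteine columns are
#' held invariant and then set per tip according to the subfamily's
#' connectivity type: required sites carry C at their primary column,
#' non-required registry columns carry an invariant non-cysteine residue
#' (mirroring the lysine/alanine replacements seen at lost sites).
#' Background columns never carry cysteine, so presence calls are a pure
#' function of the planted layout. Deterministic given the spec's seed.
#'
#' @param tree The family tree from [simulateFamilyTree()].
#' @param spec A [SyntheticSpec-class].
#' @param registry A [CysteineRegistry-class].
#' @return Named character vector: one aligned residue string per tip.
#' @export
evolveSequences <- function(tree, spec, registry = defaultRegistry()) {
  stopifnot(inherits(tree, "phylo"), is(spec, "SyntheticSpec"))
  L <- spec@seqLength
  regCols <- .allRegistryColumns(registry)
  if (max(regCols) > L)
    .stopf("registry column %d exceeds seq_length %d", max(regCols), L)
  bg <- setdiff(seq_len(L), regCols)
  AA <- setdiff(.AA20, "C")
  .withSeed(spec@seed, 2L, {
    root <- sample(AA, L, replace = TRUE)
    n <- length(tree$tip.label)
    po <- ape::reorder.phylo(tree, "postorder")
    pre <- rev(seq_len(nrow(po$edge)))
    seqs <- vector("list", n + tree$Nnode)
    seqs[[n + 1L]] <- root
    for (k in pre) {
      p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]; b <- po$edge.length[k]
      s <- seqs[[p]]
      hit <- bg[stats::runif(length(bg)) < 1 - exp(-b)]
      for (site in hit) {
        s[site] <- sample(setdiff(AA, s[site]), 1L)
      }
      seqs[[ch]] <- s
    }
    out <- stats::setNames(character(n), tree$tip.label)
    primCols <- stats::setNames(
      lapply(registrySites(registry)$name,
             function(nm) registryColumn(registry, nm)),
      registrySites(registry)$name)
    for (i in seq_len(n)) {
      s <- seqs[[i]]
      sf <- sub("_SP.*$", "", tree$tip.label[i])
      required <- .typeLayout(.tipType(spec, sf))
      for (nm in names(primCols)) {
        col <- primCols[[nm]]
        s[col] <- if (nm %in% required) "C" else root[col]
      }
      out[i] <- paste(s, collapse = "")
    }
    out
  })
}

# Inject short background gap runs (~5-9% of columns per sequence),
# avoiding the +/- window neighborhood of every registry column so gap
# noise never erases a planted cysteine signal.
.addBackgroundGaps <- function(seqs, registry, seed) {
  L <- nchar(seqs[[1L]])
  w <- registryWindow(registry)
  protected <- unique(unlist(lapply(.allRegistryColumns(registry),
                                    function(c) (c - w):(c + w))))
  protected <- protected[protected >= 1 & protected <= L]
  .withSeed(seed, 4L, {
    for (i in seq_along(seqs)) {
      x <- .chars(seqs[[i]])
      target <- round(stats::runif(1, 0.05, 0.09) * L)
      placed <- 0L; attempts <- 0L
      while (placed < target && attempts < 500L) {
        attempts <- attempts + 1L
        len <- sample(3:9, 1L)
        len <- min(len, target - placed + 2L)
        start <- sample.int(L - len + 1L, 1L)
        run <- start:(start + len - 1L)
        if (any(run %in% protected) || any(x[run] == "-")) next
        x[run] <- "-"
        placed <- placed + len
      }
      seqs[[i]] <- paste(x, collapse = "")
    }
    seqs
  })
}

#' Plant domain loss into synthetic sequences
#'
#' For every loss tip, residues within the closed column interval are
#' replaced by gaps; per-tip retention noise keeps a random handful of
#' residues so the realized gap proportion is drawn uniformly from
#' \[0.80, 0.99\] (the regime observed for standalone ZP-C subfamilies).
#' With `noise = FALSE` the interval is gapped completely. Non-loss tips
#' are untouched.
#'
#' @param sequences Named character vector of aligned sequences.
#' @param truth A [SyntheticTruth-class], or a character vector of loss
#'   tip names.
#' @param domain_interval Closed 1-based column interval `c(start, end)`.
#' @param noise Apply per-tip retention noise (default TRUE).
#' @param seed Integer seed for the retention noise.
#' @return The sequences with loss planted.
#' @export
plantDomainLoss <- function(sequences, truth, domain_interval,
                            noise = TRUE, seed = 1L) {
  lossTips <- if (is(truth, "SyntheticTruth")) truth@lossTips else
    as.character(truth)
  iv <- as.integer(domain_interval)
  L <- nchar(sequences[[1L]])
  if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L] ||
      iv[1L] < 1L || iv[2L] > L)
    .stopf("invalid or empty domain interval")
  missing <- setdiff(lossTips, names(sequences))
  if (length(missing))
    .stopf("loss tips absent from sequences: %s",
           paste(missing, collapse = ", "))
  cols <- iv[1L]:iv[2L]
  .withSeed(seed, 5L, {
    for (tip in lossTips) {
      x <- .chars(sequences[[tip]])
      if (noise) {
        g <- stats::runif(1, 0.80, 0.99)
        k <- round(g * length(cols))
        # retention noise spares only non-cysteine residues: the lost
        # domain's disulfide network goes with the domain
        nonC <- cols[x[cols] != "C"]
        retained <- if (length(nonC)) sample(nonC, min(length(cols) - k,
                                                       length(nonC)))
                    else integer(0)
        gapped <- setdiff(cols, retained)
      } else gapped <- cols
      x[gapped] <- "-"
      sequences[[tip]] <- paste(x, collapse = "")
    }
    sequences
  })
}

# shift the gap runs of one row by discretized normal offsets, within the
# free space between adjacent runs (rows keep their length and residue order)
.jitterRow <- function(x, sd) {
  isGap <- x == "-"
  if (!any(isGap) || sd <= 0) return(x)
  r <- rle(isGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gapIdx <- which(r$values)
  for (gi in gapIdx) {
    s <- starts[gi]; e <- ends[gi]
    leftSpace <- if (gi == 1L) s - 1L else s - ends[gi - 1L] - 1L
    rightSpace <- if (gi == length(r$lengths)) length(x) - e else
      starts[gi + 1L] - e - 1L
    delta <- round(stats::rnorm(1, 0, sd))
    delta <- min(max(delta, -leftSpace), rightSpace)
    if (delta == 0L) next
    if (delta > 0L) {
      block <- x[(e + 1L):(e + delta)]
      x[s:(s + delta - 1L)] <- block
      x[(s + delta):(e + delta)] <- "-"
    } else {
      d <- -delta
      block <- x[(s - d):(s - 1L)]
      x[(e - d + 1L):e] <- block
      x[(s - d):(e - d)] <- "-"
    }
  }
  x
}

#' Emit replicate alignments with stochastic gap/flank jitter
#'
#' Replicate 0 is the unperturbed alignment. Each further replicate
#' independently shifts every gap block by a discretized
#' `Normal(0, gap_jitter_sd)` offset within the free space between
#' adjacent blocks, and re-trims 0-3 columns from each flank (so
#' replicate alignments vary slightly in length, as replicate trimming
#' does in practice). All replicates share the sequence name set.
#' Deterministic given the spec's seed.
#'
#' @param sequences Named character vector of aligned sequences.
#' @param spec A [SyntheticSpec-class].
#' @return List of [ModuleAlignment-class], `rep0` first.
#' @export
emitReplicateAlignments <- function(sequences, spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@nReplicates < 1L) .stopf("n_replicates must be >= 1")
  out <- vector("list", spec@nReplicates)
  out[[1L]] <- moduleAlignment(sequences, "rep0")
  if (spec@nReplicates == 1L) return(out)
  L <- nchar(sequences[[1L]])
  for (k in seq_len(spec@nReplicates - 1L)) {
    repSeqs <- .withSeed(spec@seed, 100L + k, {
      rs <- vapply(sequences, function(s)
        paste(.jitterRow(.chars(s), spec@gapJitterSd), collapse = ""),
        character(1))
      kL <- sample(0:3, 1L); kR <- sample(0:3, 1L)
      stats::setNames(substring(rs, 1L + kL, L - kR), names(rs))
    })
    out[[k + 1L]] <- moduleAlignment(repSeqs, paste0("rep", k))
  }
  out
}

.aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

#' Synthesize residue coordinates with planted disulfide geometry
#'
#' Places one 3D point set per (non-gap) residue of an aligned sequence:
#' CA for every residue, plus CB and SG for cysteines. Residues planted
#' as disulfide partners are moved so their side-chain centroid (mean of
#' CB and SG) distances are drawn uniformly from \[2.0, 6.0\] Angstrom,
#' while every non-planted cysteine pair stays >= 10 Angstrom apart;
#' placement is retried up to 1,000 times before a generation error.
#'
#' @param sequence One aligned residue string (gaps allowed; gapped
#'   columns get no residue).
#' @param planted_pairs Integer matrix with 2 columns: alignment-column
#'   pairs to plant (each column must hold a cysteine). May have 0 rows.
#' @param seed Integer seed.
#' @return A [StructureModel-class] whose map covers every residue.
#' @export
synthesizeCoordinates <- function(sequence, planted_pairs = NULL, seed = 1L) {
  ch <- .chars(sequence)
  resCols <- which(!.isMissingChar(ch))
  if (!length(resCols)) .stopf("empty sequence: no residues to place")
  m <- length(resCols)
  resAA <- ch[resCols]
  if (is.null(planted_pairs)) planted_pairs <- matrix(integer(0), ncol = 2L)
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2L)
  colOf <- stats::setNames(resCols, seq_len(m))      # resno -> column
  resnoOf <- stats::setNames(seq_len(m), resCols)    # column -> resno
  for (c in as.vector(planted_pairs)) {
    i <- resnoOf[as.character(c)]
    if (is.na(i) || resAA[i] != "C")
      .stopf("planted pair references column %d which is not a cysteine", c)
  }
  if (anyDuplicated(as.vector(planted_pairs)))
    .stopf("a cysteine column may occur in at most one planted pair")

  base <- function() {
    ca <- cbind(3.8 * seq_len(m),
                1.2 * sin(0.6 * seq_len(m)),
                1.2 * cos(0.6 * seq_len(m)))
    list(ca = ca,
         cb = ca + matrix(rep(c(0.3, 1.4, 0.2), each = m), ncol = 3L),
         sg = ca + matrix(rep(c(0.7, 3.0, 0.5), each = m), ncol = 3L))
  }
  cysRes <- which(resAA == "C")
  plantedRes <- matrix(resnoOf[as.character(planted_pairs)],
                       ncol = 2L)
  plantedKey <- if (nrow(plantedRes))
    apply(plantedRes, 1L, function(p) paste(sort(p), collapse = "-")) else
    character(0)

  .withSeed(seed, 6L, {
    for (attempt in seq_len(1000L)) {
      g <- base()
      if (nrow(plantedRes)) for (r in seq_len(nrow(plantedRes))) {
        a <- plantedRes[r, 1L]; b <- plantedRes[r, 2L]
        u <- stats::runif(1, 2.0, 6.0)
        v <- stats::rnorm(3); v <- v / sqrt(sum(v * v))
        centA <- (g$cb[a, ] + g$sg[a, ]) / 2
        centBold <- (g$cb[b, ] + g$sg[b, ]) / 2
        shift <- centA + u * v - centBold
        g$ca[b, ] <- g$ca[b, ] + shift
        g$cb[b, ] <- g$cb[b, ] + shift
        g$sg[b, ] <- g$sg[b, ] + shift
      }
      ok <- TRUE
      if (length(cysRes) > 1L) {
        cent <- (g$cb[cysRes, , drop = FALSE] +
                 g$sg[cysRes, , drop = FALSE]) / 2
        dd <- as.matrix(stats::dist(cent))
        for (i in seq_along(cysRes)) for (j in seq_along(cysRes)) {
          if (i >= j) next
          key <- paste(sort(c(cysRes[i], cysRes[j])), collapse = "-")
          if (key %in% plantedKey) next
          if (dd[i, j] < 10) { ok <- FALSE; break }
        }
      }
      if (ok) {
        rows <- list()
        for (i in seq_len(m)) {
          rn <- .aa3[resAA[i]]
          if (is.na(rn)) rn <- "UNK"
          rows[[length(rows) + 1L]] <- data.frame(
            resno = i, resname = rn, atom = "CA",
            x = g$ca[i, 1L], y = g$ca[i, 2L], z = g$ca[i, 3L],
            stringsAsFactors = FALSE)
          if (resAA[i] == "C") {
            rows[[length(rows) + 1L]] <- data.frame(
              resno = i, resname = rn, atom = "CB",
              x = g$cb[i, 1L], y = g$cb[i, 2L], z = g$cb[i, 3L],
              stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
              resno = i, resname = rn, atom = "SG",
              x = g$sg[i, 1L], y = g$sg[i, 2L], z = g$sg[i, 3L],
              stringsAsFactors = FALSE)
          }
        }
        atoms <- do.call(rbind, rows)
        map <- stats::setNames(as.integer(resCols),
                               as.character(seq_len(m)))
        return(new("StructureModel", atoms = atoms, map = map, chain = "A"))
      }
    }
    .stopf("infeasible disulfide geometry after 1000 placement attempts")
  })
}

#' Write a StructureModel as a minimal PDB plus residue-column map
#'
#' Emits single-chain ATOM records (1-based residue numbering) and a
#' sidecar TSV with columns `residue_number`, `alignment_column`.
#'
#' @param model A [StructureModel-class].
#' @param pdb_path,map_path Output paths.
#' @export
writeStructure <- function(model, pdb_path, map_path) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$atom[i], a$resname[i], model@chain, a$resno[i],
            a$x[i], a$y[i], a$z[i], substr(a$atom[i], 1L, 1L))
  }, character(1))
  writeLines(c(lines, "END"), pdb_path)
  map <- data.frame(residue_number = as.integer(names(model@map)),
                    alignment_column = unname(model@map))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(pdb_path)
}

# minimum number of type changes on the tree, by exhaustive enumeration
# over the subfamily backbone (every subfamily is a uniformly labeled
# clade, so the full-tree minimum equals the backbone minimum)
.plantedSwitchCount <- function(tree, tipTypes) {
  sfOf <- sub("_SP.*$", "", names(tipTypes))
  reps <- names(tipTypes)[!duplicated(sfOf)]
  if (length(reps) < 2L) return(0L)
  bb <- ape::keep.tip(tree, reps)
  if (!ape::is.rooted(bb)) bb <- ape::root(bb, outgroup = reps[1L],
                                           resolve.root = TRUE)
  states <- unique(unname(tipTypes[reps]))
  if (length(states) == 1L) return(0L)
  nT <- length(bb$tip.label)
  nI <- bb$Nnode
  tipState <- unname(tipTypes[bb$tip.label])
  grids <- rep(list(states), nI)
  combos <- as.matrix(expand.grid(grids, stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(tipState, combos[r, ])
    changes <- sum(lab[bb$edge[, 1L]] != lab[bb$edge[, 2L]])
    if (changes < best) best <- changes
  }
  as.integer(best)
}

#' Generate a complete synthetic fixture bundle
#'
#' Runs the whole generator: family tree, evolved sequences, background
#' gaps, planted ZP-N loss, replicate alignments, per-tip coordinate
#' files with planted disulfides, a per-sequence feature table, and a
#' truth record. Everything is written under `dir` (replicate FASTAs
#' `alignment_rep<k>.fasta`, `true_tree.nwk`, `structures/<tip>.pdb` +
#' `<tip>_map.tsv`, `features.tsv`, `truth.json`); the bundle is
#' byte-identical for identical (spec, seed).
#'
#' @param spec A [SyntheticSpec-class].
#' @param dir Output directory (created if needed).
#' @param registry A [CysteineRegistry-class].
#' @param structures Which tips get coordinate files: `"all"` or a
#'   character vector of tip names (default all).
#' @return Invisibly, a list with `dir`, `spec`, `truth`
#'   ([SyntheticTruth-class]), `tree`, `replicates` (list of
#'   [ModuleAlignment-class]) and `files`.
#' @export
makeFixtureBundle <- function(spec, dir = tempfile("bundle"),
                              registry = defaultRegistry(),
                              structures = "all") {
  stopifnot(is(spec, "SyntheticSpec"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) .stopf("cannot create bundle directory %s", dir)
  tree <- simulateFamilyTree(spec)
  tipTypes <- stats::setNames(
    .tipType(spec, sub("_SP.*$", "", tree$tip.label)), tree$tip.label)
  lossSf <- spec@lossSubfamilies$subfamily
  lossTips <- tree$tip.label[sub("_SP.*$", "", tree$tip.label) %in% lossSf]
  lossDomain <- if (nrow(spec@lossSubfamilies))
    unique(spec@lossSubfamilies$domain) else character(0)

  seqs <- evolveSequences(tree, spec, registry)
  seqs <- .addBackgroundGaps(seqs, registry, spec@seed)
  zpn <- demarcateDomains()[1L, ]
  if (length(lossTips))
    seqs <- plantDomainLoss(seqs, lossTips, c(zpn$start, zpn$end),
                            noise = TRUE, seed = spec@seed)
  replicates <- emitReplicateAlignments(seqs, spec)

  planted <- lapply(tree$tip.label, function(tip) {
    pairs <- .typeDisulfidePairs(registry, tipTypes[[tip]])
    # keep only pairs whose cysteines survived in the planted sequence
    ch <- .chars(seqs[[tip]])
    keep <- apply(pairs, 1L, function(p) all(ch[p] == "C"))
    pairs[keep, , drop = FALSE]
  })
  names(planted) <- tree$tip.label

  truth <- new("SyntheticTruth", tree = tree, tipTypes = tipTypes,
               lossTips = lossTips,
               lossDomain = if (length(lossDomain)) lossDomain else "ZP-N",
               plantedDisulfides = planted,
               switchCount = .plantedSwitchCount(tree, tipTypes))

  files <- character(0)
  for (k in seq_along(replicates)) {
    f <- file.path(dir, sprintf("alignment_rep%d.fasta", k - 1L))
    writeAlignment(replicates[[k]], f)
    files <- c(files, f)
  }
  treeFile <- file.path(dir, "true_tree.nwk")
  writeNewickTree(tree, treeFile)
  files <- c(files, treeFile)

  structDir <- file.path(dir, "structures")
  dir.create(structDir, showWarnings = FALSE)
  structTips <- if (identical(structures, "all")) tree$tip.label else
    structures
  for (tip in structTips) {
    model <- synthesizeCoordinates(seqs[[tip]], planted[[tip]],
                                   seed = .deriveSeed(spec@seed,
                                                      match(tip, tree$tip.label)))
    pf <- file.path(structDir, paste0(tip, ".pdb"))
    mf <- file.path(structDir, paste0(tip, "_map.tsv"))
    writeStructure(model, pf, mf)
    files <- c(files, pf, mf)
  }

  feats <- .withSeed(spec@seed, 7L, {
    sf <- sub("_SP.*$", "", tree$tip.label)
    isLoss <- sf %in% lossSf
    gpiSf <- if (length(lossSf)) lossSf[1L] else NA_character_
    data.frame(
      name = tree$tip.label,
      subfamily = sf,
      signal_peptide = stats::runif(length(sf)) <
        ifelse(isLoss, 0.79, 0.66),
      rk_cleavage_site = stats::runif(length(sf)) <
        ifelse(isLoss, 0.10, 0.66),
      gpi_anchor = stats::runif(length(sf)) <
        ifelse(sf == gpiSf & !is.na(gpiSf), 0.57, 0.05),
      stringsAsFactors = FALSE)
  })
  featFile <- file.path(dir, "features.tsv")
  utils::write.table(feats, featFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, featFile)

  truthFile <- file.path(dir, "truth.json")
  truthList <- list(
    tree = ape::write.tree(tree, digits = 10),
    tip_types = as.list(tipTypes),
    loss_tips = as.list(lossTips),
    loss_domain = truth@lossDomain,
    planted_disulfides = lapply(planted, function(p)
      lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))),
    switch_count = truth@switchCount,
    spec = list(n_subfamilies = spec@nSubfamilies,
                n_species = spec@nSpecies,
                seq_length = spec@seqLength,
                subs_rate = spec@subsRate,
                gap_jitter_sd = spec@gapJitterSd,
                n_replicates = spec@nReplicates,
                seed = spec@seed))
  jsonlite::write_json(truthList, truthFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, truthFile)

  invisible(list(dir = dir, spec = spec, truth = truth, tree = tree,
                 sequences = seqs, replicates = replicates,
                 features = feats, files = files))
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@tree$tip.label), "tips;",
      length(object@lossTips), "loss tips (", object@lossDomain, ");",
      "min type changes:", object@switchCount, "\n")
})
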