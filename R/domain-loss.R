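#' Annotate tree tips with per-domain gap values
#'
#' Attaches the per-domain mean gap fractions to a tree. Every tip must
#' have a profile for every domain; a missing profile is an error naming
#' the tip, never a silent default.
#'
#' @param tree An ape `phylo`.
#' @param gap_profiles `data.frame` with columns `name`, `domain`,
#'   `gap_fraction` (e.g. from [meanGapProfiles()]).
#' @return List with `tree` and `gap` (numeric matrix, tips x domains).
#' @export
annotateTips <- function(tree, gap_profiles) {
  stopifnot(inherits(tree, "phylo"))
  need <- c("name", "domain", "gap_fraction")
  if (!all(need %in% names(gap_profiles)))
    .stopf("gap_profiles needs columns: %s", paste(need, collapse = ", "))
  doms <- unique(gap_profiles$domain)
  gap <- matrix(NA_real_, nrow = length(tree$tip.label), ncol = length(doms),
                dimnames = list(tree$tip.label, doms))
  for (r in seq_len(nrow(gap_profiles)))
    if (gap_profiles$name[r] %in% tree$tip.label)
      gap[gap_profiles$name[r], gap_profiles$domain[r]] <-
        gap_profiles$gap_fraction[r]
  bad <- rownames(gap)[apply(gap, 1L, anyNA)]
  if (length(bad))
    .stopf("tip(s) without a complete gap profile: %s",
           paste(bad, collapse = ", "))
  list(tree = tree, gap = gap)
}

#' Write/read a tip-annotated tree with Newick comment fields
#'
#' Serializes per-tip annotations as `[&key=value,...]` comments after
#' the tip label, and parses them back, so annotated trees round-trip
#' through plain text.
#'
#' @param annotated List from [annotateTips()].
#' @param path Output file.
#' @export
writeAnnotatedTree <- function(annotated, path) {
  tree <- annotated$tree; gap <- annotated$gap
  nwk <- ape::write.tree(tree, digits = 10)
  for (tip in rownames(gap)) {
    ann <- paste0("[&", paste0(colnames(gap), "=",
                               sprintf("%.10g", gap[tip, ]),
                               collapse = ","), "]")
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", tip, "(?=[:,)])"),
               paste0(tip, ann), nwk, perl = TRUE)
  }
  writeLines(nwk, path)
  invisible(path)
}

#' @rdname writeAnnotatedTree
#' @return `readAnnotatedTree`: a list as returned by [annotateTips()].
#' @export
readAnnotatedTree <- function(path) {
  nwk <- paste(readLines(path, warn = FALSE), collapse = "")
  m <- gregexpr("([A-Za-z0-9_.|-]+)\\[&([^]]*)\\]", nwk)
  hits <- regmatches(nwk, m)[[1L]]
  ann <- list()
  for (h in hits) {
    tip <- sub("\\[.*$", "", h)
    body <- sub("^.*\\[&", "", sub("\\]$", "", h))
    kv <- strsplit(strsplit(body, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- vapply(kv, function(x) as.numeric(x[2L]), numeric(1))
    names(vals) <- vapply(kv, `[[`, character(1), 1L)
    ann[[tip]] <- vals
  }
  clean <- gsub("\\[&[^]]*\\]", "", nwk)
  tree <- readNewickTree(clean)
  doms <- unique(unlist(lapply(ann, names)))
  gap <- matrix(NA_real_, nrow = length(tree$tip.label), ncol = length(doms),
                dimnames = list(tree$tip.label, doms))
  for (tip in names(ann)) gap[tip, names(ann[[tip]])] <- ann[[tip]]
  list(tree = tree, gap = gap)
}

#' Detect clades with domain-specific sequence loss
#'
#' Scans all clades of a rooted tree (the tree is MAD-rooted first, with
#' a message, if given unrooted) and flags the maximal clades whose
#' tip-median gap fraction for the target domain is at least `tau_high`
#' while the tip-median for every other domain stays at or below
#' `tau_low`, with at least `min_tips` tips. To qualify, a clade must be
#' loss-conforming throughout: every multi-tip child subtree must itself
#' have a target-domain tip-median of at least `tau_high` (recursively),
#' so a clade cannot be carried over the threshold by one dense loss
#' subclade while harboring a clean subfamily; single tips are exempt,
#' preserving the median's resistance to isolated aberrant tips.
#' High-gap tips that fall outside every flagged clade are reported
#' separately as outliers — isolated truncations, not loss clades.
#'
#' @param annotated List from [annotateTips()] (tree + gap matrix).
#' @param domain_id Target domain, e.g. `"ZP-N"`.
#' @param tau_high Clade-median gap threshold for the lost domain
#'   (default 0.70).
#' @param tau_low Ceiling on the other domains' clade medians
#'   (default 0.30).
#' @param min_tips Minimum clade size (default 4).
#' @return List with `calls` (`data.frame`: `node`, `tips`, `n_tips`,
#'   `clade_median_gap`, `other_domain_median_gap`) and `outliers`
#'   (`data.frame`: `name`, `gap_fraction`).
#' @export
detectLossClades <- function(annotated, domain_id, tau_high = 0.70,
                             tau_low = 0.30, min_tips = 4L) {
  tree <- annotated$tree; gap <- annotated$gap
  if (!(tau_high > 0 && tau_high < 1 && tau_low > 0 && tau_low < 1 &&
        tau_low < tau_high))
    .stopf("thresholds must satisfy 0 < tau_low < tau_high < 1")
  if (!domain_id %in% colnames(gap))
    .stopf("unknown domain '%s'", domain_id)
  if (!ape::is.rooted(tree)) {
    message("input tree is unrooted; applying MAD rooting")
    tree <- madRoot(tree)$tree
    gap <- gap[tree$tip.label, , drop = FALSE]
  }
  n <- length(tree$tip.label)
  below <- .tipsBelow(tree)
  others <- setdiff(colnames(gap), domain_id)
  internal <- seq_len(tree$Nnode) + n
  medTarget <- rep(NA_real_, n + tree$Nnode)
  for (v in c(seq_len(n), internal))
    medTarget[v] <- stats::median(gap[tree$tip.label[below[[v]]], domain_id])
  # loss-conforming: clade median high, and recursively so for every
  # child subtree with more than one tip
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  conforming <- rep(NA, n + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in unique(po$edge[, 1L])) {
    ch <- kids[[as.character(v)]]
    chOk <- vapply(ch, function(c2) {
      if (length(below[[c2]]) < 2L) TRUE else conforming[c2]
    }, logical(1))
    conforming[v] <- medTarget[v] >= tau_high && all(chOk)
  }
  flagged <- list()
  for (v in internal) {
    tipIdx <- below[[v]]
    if (length(tipIdx) < min_tips) next
    if (!isTRUE(conforming[v])) next
    tips <- tree$tip.label[tipIdx]
    medOther <- if (length(others))
      max(vapply(others, function(d) stats::median(gap[tips, d]),
                 numeric(1))) else 0
    if (medOther <= tau_low)
      flagged[[length(flagged) + 1L]] <- list(
        node = v, tips = tips, med = medTarget[v], medOther = medOther)
  }
  # keep maximal clades only
  keep <- rep(TRUE, length(flagged))
  if (length(flagged) > 1L) {
    for (i in seq_along(flagged)) for (j in seq_along(flagged)) {
      if (i == j) next
      if (all(flagged[[i]]$tips %in% flagged[[j]]$tips) &&
          length(flagged[[i]]$tips) < length(flagged[[j]]$tips))
        keep[i] <- FALSE
    }
  }
  flagged <- flagged[keep]
  calls <- if (length(flagged)) data.frame(
    node = vapply(flagged, `[[`, numeric(1), "node"),
    tips = vapply(flagged, function(f)
      paste(sort(f$tips), collapse = ","), character(1)),
    n_tips = vapply(flagged, function(f) length(f$tips), integer(1)),
    clade_median_gap = vapply(flagged, `[[`, numeric(1), "med"),
    other_domain_median_gap = vapply(flagged, `[[`, numeric(1), "medOther"),
    stringsAsFactors = FALSE
  ) else data.frame(node = numeric(0), tips = character(0),
                    n_tips = integer(0), clade_median_gap = numeric(0),
                    other_domain_median_gap = numeric(0))
  called <- unlist(lapply(flagged, `[[`, "tips"))
  hi <- rownames(gap)[gap[, domain_id] >= tau_high]
  outNames <- setdiff(hi, called)
  outliers <- data.frame(name = outNames,
                         gap_fraction = gap[outNames, domain_id],
                         stringsAsFactors = FALSE)
  rownames(outliers) <- NULL
  list(calls = calls, outliers = outliers,
       thresholds = c(tau_high = tau_high, tau_low = tau_low,
                      min_tips = min_tips))
}

#' Per-subfamily per-domain gap summaries across replicates
#'
#' For each subfamily and domain: the mean gap fraction over member
#' sequences is computed within every replicate, then the min, max and
#' mean of those per-replicate means are reported (the
#' "depending on alignment replicate" ranges).
#'
#' @param subfamily_map Named character vector: sequence -> subfamily.
#'   Every sequence in the replicates must be assigned.
#' @param replicates List of [ModuleAlignment-class] objects.
#' @param anchor_cols Nominal domain anchors.
#' @return `data.frame` with columns `subfamily`, `domain`, `min`,
#'   `max`, `mean`.
#' @export
subfamilySummary <- function(subfamily_map, replicates,
                             anchor_cols = c(1L, 80L, 105L, 218L)) {
  if (!length(replicates)) .stopf("no replicate alignments given")
  nms <- seqNames(replicates[[1L]])
  unassigned <- setdiff(nms, names(subfamily_map))
  if (length(unassigned))
    .stopf("sequence(s) without a subfamily: %s",
           paste(unassigned, collapse = ", "))
  doms <- c("ZP-N", "ZP-C")
  perRep <- lapply(replicates, function(aln) {
    a <- locateAnchors(aln, anchor_cols)
    dm <- demarcateDomains(a, n_cols = nCols(aln))
    sapply(doms, function(d) {
      i <- match(d, dm$domain)
      vapply(nms, function(nm)
        gapProportion(aln, nm, c(dm$start[i], dm$end[i])), numeric(1))
    })
  })
  sfs <- sort(unique(subfamily_map[nms]))
  rows <- list()
  for (sf in sfs) {
    members <- nms[subfamily_map[nms] == sf]
    for (d in doms) {
      repMeans <- vapply(perRep, function(x)
        mean(x[members, d]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subfamily = sf, domain = d,
        min = min(repMeans), max = max(repMeans), mean = mean(repMeans),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
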