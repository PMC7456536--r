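#' Read a structure model (PDB + residue-column map)
#'
#' Parses single-chain ATOM records via bio3d and attaches the sidecar
#' TSV mapping residue numbers to alignment columns. Map rows that
#' reference residues absent from the coordinate set are input errors;
#' unmapped residues are retained but cannot be queried by column.
#'
#' @param pdb_path PDB file (ATOM records, single chain).
#' @param map_path TSV with columns `residue_number`, `alignment_column`.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(pdb_path, map_path) {
  if (!file.exists(pdb_path)) .stopf("PDB file not found: %s", pdb_path)
  if (!file.exists(map_path)) .stopf("map file not found: %s", map_path)
  pdb <- tryCatch(bio3d::read.pdb(pdb_path),
                  error = function(e) .stopf("cannot parse PDB %s (%s)",
                                             pdb_path, conditionMessage(e)))
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) .stopf("no ATOM records in %s", pdb_path)
  if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
    .stopf("non-numeric coordinates in %s", pdb_path)
  chain <- unique(a$chain)
  if (length(chain) > 1L) .stopf("expected a single chain, found: %s",
                                 paste(chain, collapse = ", "))
  atoms <- data.frame(resno = a$resno, resname = a$resid, atom = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  mp <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("residue_number", "alignment_column") %in% names(mp)))
    .stopf("map file must have columns residue_number, alignment_column")
  absent <- setdiff(mp$residue_number, atoms$resno)
  if (length(absent))
    .stopf("map references residue(s) absent from PDB: %s",
           paste(absent, collapse = ", "))
  map <- stats::setNames(as.integer(mp$alignment_column),
                         as.character(mp$residue_number))
  new("StructureModel", atoms = atoms, map = map,
      chain = if (length(chain)) chain else "A")
}

#' @describeIn readStructure Number of residues in the coordinate set.
#' @param model A [StructureModel-class].
#' @export
nResidues <- function(model) {
  stopifnot(is(model, "StructureModel"))
  length(unique(model@atoms$resno))
}

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel: chain", object@chain, "with", nResidues(object),
      "residues (", length(object@map), "mapped to alignment columns )\n")
})

# residue number mapped to an alignment column, or NA
.resnoForColumn <- function(model, column) {
  hit <- names(model@map)[model@map == column]
  if (length(hit)) as.integer(hit[1L]) else NA_integer_
}

#' Side-chain centroid of a cysteine at an alignment column
#'
#' The centroid is the mean of the side-chain heavy atoms (CB, SG) when
#' present; if only CA is available it is returned with a warning.
#'
#' @param model A [StructureModel-class].
#' @param column Alignment column mapping to a cysteine residue.
#' @return Numeric xyz vector (Angstrom).
#' @export
cysCentroid <- function(model, column) {
  stopifnot(is(model, "StructureModel"))
  resno <- .resnoForColumn(model, column)
  if (is.na(resno)) .stopf("alignment column %d is unmapped", column)
  a <- model@atoms[model@atoms$resno == resno, , drop = FALSE]
  if (!identical(unique(a$resname), "CYS"))
    .stopf("residue %d at column %d is %s, not a cysteine",
           resno, column, paste(unique(a$resname), collapse = "/"))
  side <- a[a$atom %in% c("CB", "SG"), , drop = FALSE]
  if (nrow(side)) return(colMeans(as.matrix(side[, c("x", "y", "z")])))
  ca <- a[a$atom == "CA", , drop = FALSE]
  if (!nrow(ca)) .stopf("residue %d has no CA/CB/SG atoms", resno)
  warning(sprintf("residue %d: no side-chain atoms; using CA as centroid",
                  resno), call. = FALSE)
  as.numeric(ca[1L, c("x", "y", "z")])
}

#' Centroid distance between two cysteine columns
#'
#' @param model A [StructureModel-class].
#' @param colA,colB Alignment columns, both mapping to cysteines.
#' @return Euclidean distance in Angstrom (symmetric in its arguments).
#' @export
pairDistance <- function(model, colA, colB) {
  a <- cysCentroid(model, colA)
  b <- cysCentroid(model, colB)
  sqrt(sum((a - b)^2))
}

#' Call plausible disulfide bonds from centroid geometry
#'
#' Greedy non-overlapping pairing: the closest remaining cysteine pair
#' with centroid distance <= `call_thresh` is called, its members are
#' consumed, and the process repeats, so each cysteine joins at most one
#' called pair. Remaining pairs within `proximal_thresh` are reported as
#' `"proximal"`, all others as `"not_called"`.
#'
#' @param model A [StructureModel-class].
#' @param cys_columns Alignment columns of the cysteines to consider.
#' @param call_thresh Call threshold in Angstrom (default 8.0).
#' @param proximal_thresh Proximal threshold in Angstrom (default 10.0),
#'   must be >= `call_thresh`.
#' @return `data.frame` with columns `colA`, `colB`, `distance`,
#'   `status`, sorted called pairs first.
#' @export
callDisulfides <- function(model, cys_columns, call_thresh = 8.0,
                           proximal_thresh = 10.0) {
  stopifnot(is(model, "StructureModel"))
  if (call_thresh <= 0 || proximal_thresh < call_thresh)
    .stopf("need 0 < call_thresh <= proximal_thresh")
  cols <- sort(unique(as.integer(cys_columns)))
  if (length(cols) < 2L)
    return(data.frame(colA = integer(0), colB = integer(0),
                      distance = numeric(0), status = character(0)))
  cent <- lapply(cols, function(c) cysCentroid(model, c))
  k <- length(cols)
  pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(i)
    do.call(rbind, lapply((i + 1L):k, function(j)
      data.frame(colA = cols[i], colB = cols[j],
                 distance = sqrt(sum((cent[[i]] - cent[[j]])^2)))))))
  pairs <- pairs[order(pairs$distance, pairs$colA, pairs$colB), ,
                 drop = FALSE]
  used <- integer(0)
  status <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$colA[r]; b <- pairs$colB[r]; d <- pairs$distance[r]
    if (d <= call_thresh && !(a %in% used) && !(b %in% used)) {
      status[r] <- "called"
      used <- c(used, a, b)
    } else if (d <= proximal_thresh) {
      status[r] <- "proximal"
    } else status[r] <- "not_called"
  }
  pairs$status <- status
  rownames(pairs) <- NULL
  pairs[order(match(pairs$status, c("called", "proximal", "not_called")),
              pairs$distance), , drop = FALSE]
}

#' Registry-site presence vector of an aligned sequence
#'
#' A site is present iff a cysteine occurs within `+/- window` columns
#' of any of its registry columns (sites with alternatives, like Cys8 at
#' 215/218, are present if either matches).
#'
#' @param aligned_sequence One aligned residue string.
#' @param registry A [CysteineRegistry-class].
#' @return Named logical vector over registry site names.
#' @export
presenceVector <- function(aligned_sequence, registry = defaultRegistry()) {
  stopifnot(is(registry, "CysteineRegistry"))
  ch <- .chars(aligned_sequence)
  L <- length(ch)
  if (L < max(.allRegistryColumns(registry)))
    .stopf("sequence length %d below the largest registry column %d",
           L, max(.allRegistryColumns(registry)))
  w <- registryWindow(registry)
  s <- registrySites(registry)
  pres <- vapply(seq_len(nrow(s)), function(i) {
    any(vapply(s$columns[[i]], function(col) {
      lo <- max(1L, col - w); hi <- min(L, col + w)
      any(ch[lo:hi] == "C")
    }, logical(1)))
  }, logical(1))
  stats::setNames(pres, s$name)
}

#' Classify cysteine connectivity type from a presence vector
#'
#' Type 1: the IHP pair (105/134) is absent. Type 2: the IHP pair is
#' present with CysA retained. Type 3: the IHP pair is present, CysA is
#' absent and the betaC partner (140) is present — the reshuffled
#' CysA-CysB bond. A presence vector with exactly one IHP cysteine fits
#' no rule and is `"atypical"`. Flags record Cys5-Cys7 loss (either
#' member absent) and CysA-CysB loss (both absent).
#'
#' @param presence Named logical vector from [presenceVector()].
#' @return List with `type` (`"Type1"`, `"Type2"`, `"Type3"` or
#'   `"atypical"`) and `flags` (character vector).
#' @export
classifyType <- function(presence) {
  need <- c("IHP_A", "IHP_B", "CysA", "CysB", "T3_partner", "Cys5", "Cys7")
  if (!all(need %in% names(presence)))
    .stopf("presence vector is missing sites: %s",
           paste(setdiff(need, names(presence)), collapse = ", "))
  ihpA <- presence[["IHP_A"]]; ihpB <- presence[["IHP_B"]]
  type <- if (ihpA && ihpB) {
    if (!presence[["CysA"]] && presence[["T3_partner"]]) "Type3" else "Type2"
  } else if (!ihpA && !ihpB) "Type1" else "atypical"
  flags <- character(0)
  if (!presence[["Cys5"]] || !presence[["Cys7"]])
    flags <- c(flags, "Cys5-Cys7 loss")
  if (!presence[["CysA"]] && !presence[["CysB"]])
    flags <- c(flags, "CysA-CysB loss")
  list(type = type, flags = flags)
}

#' Fitch small parsimony on a rooted binary tree
#'
#' Standard two-pass Fitch: the bottom-up pass counts the minimum number
#' of state changes; the top-down pass produces one optimal internal
#' labeling, breaking ties by preferring the parent's state and
#' otherwise taking the lexicographically smallest state.
#'
#' @param tree A rooted, fully bifurcating `phylo`.
#' @param tip_labels Named character vector: state of every tip.
#' @return List with `changes` (integer) and `labels` (named character
#'   vector over all nodes: tips then internals, in node-id order).
#' @export
fitchParsimony <- function(tree, tip_labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) .stopf("Fitch parsimony needs a rooted tree")
  if (!ape::is.binary(tree))
    .stopf("tree has polytomies; resolve them (e.g. ape::multi2di) first")
  n <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(tip_labels))
  if (length(missing))
    .stopf("unlabeled tip(s): %s", paste(missing, collapse = ", "))
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- unname(tip_labels[tree$tip.label[i]])
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (v in unique(po$edge[, 1L])) {        # postorder visits parents in order
    ch <- kids[[as.character(v)]]
    inter <- Reduce(intersect, sets[ch])
    if (length(inter)) sets[[v]] <- inter
    else {
      sets[[v]] <- sort(Reduce(union, sets[ch]))
      changes <- changes + 1L
    }
  }
  labels <- character(n + tree$Nnode)
  labels[seq_len(n)] <- unname(tip_labels[tree$tip.label])
  root <- n + 1L
  labels[root] <- sort(sets[[root]])[1L]
  pre <- rev(seq_len(nrow(po$edge)))
  for (k in pre) {
    p <- po$edge[k, 1L]; v <- po$edge[k, 2L]
    if (v <= n) next
    labels[v] <- if (labels[p] %in% sets[[v]]) labels[p] else
      sort(sets[[v]])[1L]
  }
  names(labels) <- c(tree$tip.label,
                     paste0("node", seq_len(tree$Nnode) + n))
  list(changes = changes, labels = labels)
}
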