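#' @import methods
NULL

setOldClass("phylo")
setOldClass("multiPhylo")

#' Replicate protein alignment
#'
#' A rectangular, gap-aware protein alignment with a replicate identity.
#' Rows are stored as a named character vector of equal-length residue
#' strings; gaps are "-" and ambiguous residues are "X"/"?".
#'
#' @slot seqs Named character vector; one aligned residue string per sequence.
#' @slot replicateId Single character label identifying the replicate
#'   (e.g. `"rep0"`), or `"mean"` for averaged profiles downstream.
#' @export
setClass("ModuleAlignment",
  representation(seqs = "character", replicateId = "character"),
  prototype(seqs = character(0), replicateId = "rep0")
)

setValidity("ModuleAlignment", function(object) {
  msg <- character(0)
  if (length(object@replicateId) != 1L)
    msg <- c(msg, "replicateId must be a single label")
  if (length(object@seqs)) {
    if (is.null(names(object@seqs)) || anyNA(names(object@seqs)) ||
        any(names(object@seqs) == ""))
      msg <- c(msg, "all sequences must be named")
    if (anyDuplicated(names(object@seqs)))
      msg <- c(msg, "sequence names must be unique")
    if (length(unique(nchar(object@seqs))) > 1L)
      msg <- c(msg, "all rows must have identical length (ragged alignment)")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus tree with replicate branch support
#'
#' Majority-rule consensus of replicate trees, with per-branch branch
#' recovery proportions (BRP; the fraction of replicate trees containing
#' the bipartition) and transfer bootstrap expectations (TBE).
#'
#' @slot tree The consensus topology as an ape `phylo` object. Internal
#'   node labels carry `"BRP|TBE"` annotations.
#' @slot support `data.frame` with one row per consensus bipartition:
#'   `node` (consensus node id), `tips` (smaller-side tip set,
#'   comma-joined), `p` (smaller-side size), `brp`, `tbe`.
#' @slot nTrees Number of replicate trees combined.
#' @export
setClass("SupportedTree",
  representation(tree = "phylo", support = "data.frame", nTrees = "integer")
)

setValidity("SupportedTree", function(object) {
  msg <- character(0)
  s <- object@support
  need <- c("node", "tips", "p", "brp", "tbe")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("support must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(s$brp <= 0.5 | s$brp > 1))
      msg <- c(msg, "every consensus branch must have BRP in (0.5, 1]")
    if (any(s$tbe < s$brp - 1e-9))
      msg <- c(msg, "TBE must be >= BRP on every consensus branch")
  }
  if (length(msg)) msg else TRUE
})

#' Registry of homologous cysteine alignment columns
#'
#' Named cysteine sites of the ZP module in trimmed-alignment coordinates:
#' the core ZP-N pairs (Cys1-Cys4, Cys2-Cys3), the canonical ZP-C set
#' (Cys5-Cys8, CysA, CysB) and the novel sites involved in connectivity
#' changes (the IHP pair, the Type-3 partner, the AB-loop pair, the
#' FBN-1 partner). A site may list alternative columns (Cys8 maps to
#' either 215 or 218 depending on replicate).
#'
#' @slot sites `data.frame` with columns `name`, `columns` (list of
#'   integer vectors), `domain` ("ZP-N"/"ZP-C"), `role` ("core"/"novel").
#' @slot window Integer tolerance (columns) used when matching a cysteine
#'   to a registry column; absorbs replicate-alignment jitter.
#' @export
setClass("CysteineRegistry",
  representation(sites = "data.frame", window = "integer")
)

setValidity("CysteineRegistry", function(object) {
  msg <- character(0)
  s <- object@sites
  if (!all(c("name", "columns", "domain", "role") %in% names(s)))
    msg <- c(msg, "sites needs columns name, columns, domain, role")
  else {
    if (anyDuplicated(s$name)) msg <- c(msg, "site names must be unique")
    cols <- unlist(s$columns)
    if (any(cols < 1L)) msg <- c(msg, "registry columns must be positive")
  }
  if (length(object@window) != 1L || object@window < 0L)
    msg <- c(msg, "window must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Structure model: residue coordinates mapped to alignment columns
#'
#' Per-residue heavy-atom coordinates for one chain, plus the
#' residue-number to alignment-column map used to query cysteine sites.
#'
#' @slot atoms `data.frame` with columns `resno`, `resname`, `atom`,
#'   `x`, `y`, `z` (coordinates in Angstrom).
#' @slot map Named integer vector: names are residue numbers (as
#'   character), values are 1-based alignment columns. Injective.
#' @slot chain Single chain identifier.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", map = "integer", chain = "character")
)

setValidity("StructureModel", function(object) {
  msg <- character(0)
  a <- object@atoms
  need <- c("resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (length(object@map)) {
    if (is.null(names(object@map)))
      msg <- c(msg, "map must be named by residue number")
    if (anyDuplicated(object@map))
      msg <- c(msg, "residue->column map must be injective")
    if (all(need %in% names(a)) &&
        !all(names(object@map) %in% as.character(a$resno)))
      msg <- c(msg, "map references residues absent from the coordinate set")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic ZP-module family
#'
#' Parameters of the synthetic fixture generator: an ancient paralogous
#' gene family (`n_subfamilies` clades, each with one module per species),
#' replicate alignments with stochastic gap/flank jitter, planted ZP-N
#' domain loss in selected subfamilies, and per-subfamily connectivity
#' types. Defaults are the generator's study conditions (see the methods
#' vignette).
#'
#' @slot nSubfamilies,nSpecies Counts defining the tip set.
#' @slot seqLength Alignment columns (>= 220 so all registry columns fit).
#' @slot subsRate Expected substitutions/site root-to-tip on the family tree.
#' @slot gapJitterSd SD (columns) of the replicate gap-block jitter.
#' @slot nReplicates Number of replicate alignments (>= 2).
#' @slot lossSubfamilies `data.frame` with columns `subfamily`, `domain`.
#' @slot typeAssignments Named character vector subfamily -> Type1/2/3.
#' @slot seed Integer master seed; all randomness derives from it.
#' @export
setClass("SyntheticSpec",
  representation(
    nSubfamilies = "integer", nSpecies = "integer", seqLength = "integer",
    subsRate = "numeric", gapJitterSd = "numeric", nReplicates = "integer",
    lossSubfamilies = "data.frame", typeAssignments = "character",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (object@nSubfamilies < 1L) msg <- c(msg, "n_subfamilies must be >= 1")
  if (object@nSpecies < 3L) msg <- c(msg, "n_species must be >= 3")
  if (object@nReplicates < 2L) msg <- c(msg, "n_replicates must be >= 2")
  if (object@seqLength < 220L)
    msg <- c(msg, "seq_length must be >= 220 (registry columns reach 218)")
  if (object@subsRate < 0) msg <- c(msg, "subs_rate must be non-negative")
  if (object@gapJitterSd < 0) msg <- c(msg, "gap_jitter_sd must be non-negative")
  sf <- paste0("SF", seq_len(object@nSubfamilies))
  if (nrow(object@lossSubfamilies) &&
      !all(object@lossSubfamilies$subfamily %in% sf))
    msg <- c(msg, "loss_subfamilies references unknown subfamily ids")
  if (!all(names(object@typeAssignments) %in% sf))
    msg <- c(msg, "type_assignments references unknown subfamily ids")
  if (!all(object@typeAssignments %in% c("Type1", "Type2", "Type3")))
    msg <- c(msg, "type_assignments values must be Type1/Type2/Type3")
  if (length(msg)) msg else TRUE
})

#' Planted truth of a synthetic bundle
#'
#' Everything a recovery test needs: the true family tree with subfamily
#' clades, the planted connectivity type of every tip, the tips whose
#' ZP-N domain was deleted, the planted disulfide column pairs per tip,
#' and the minimum number of type changes on the true tree (computed at
#' generation time by exhaustive enumeration over the subfamily backbone,
#' independently of the package's Fitch implementation).
#'
#' @slot tree The true `phylo` tree (unrooted, binary).
#' @slot tipTypes Named character vector tip -> Type1/2/3.
#' @slot lossTips Character vector of tips lacking the ZP-N domain.
#' @slot lossDomain Domain id of the planted loss (e.g. "ZP-N").
#' @slot plantedDisulfides Named list: tip -> integer matrix (2 columns)
#'   of alignment-column pairs planted as spatially close.
#' @slot switchCount Minimum number of type changes on the true tree.
#' @export
setClass("SyntheticTruth",
  representation(
    tree = "phylo", tipTypes = "character", lossTips = "character",
    lossDomain = "character", plantedDisulfides = "list",
    switchCount = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  tips <- object@tree$tip.label
  if (!all(names(object@tipTypes) %in% tips))
    msg <- c(msg, "tipTypes names must be tree tips")
  if (!all(object@lossTips %in% tips))
    msg <- c(msg, "lossTips must be tree tips")
  if (length(msg)) msg else TRUE
})
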