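#' Read a similarity-search hit table
#'
#' TSV with (at least) named columns `query`, `subject`, `e_value`,
#' `query_coverage` (coverage as a fraction in \[0,1\]). Malformed rows
#' (non-numeric e-value or coverage, coverage outside \[0,1\]) are
#' row-level errors reported with their line numbers.
#'
#' @param path TSV file path.
#' @return `data.frame` of hit records.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) .stopf("hit table not found: %s", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query", "subject", "e_value", "query_coverage")
  if (!all(need %in% names(tb)))
    .stopf("hit table must have columns: %s", paste(need, collapse = ", "))
  ev <- suppressWarnings(as.numeric(tb$e_value))
  cv <- suppressWarnings(as.numeric(tb$query_coverage))
  bad <- which(is.na(ev) | is.na(cv) | ev < 0 | cv < 0 | cv > 1)
  if (length(bad))
    .stopf("malformed hit row(s) at line(s): %s",
           paste(bad + 1L, collapse = ", "))
  tb$e_value <- ev
  tb$query_coverage <- cv
  tb
}

#' Filter similarity-search hits by E-value and query coverage
#'
#' Retains records with `e_value` strictly below `e_max` ("lower than")
#' and `query_coverage` at or above `cov_min` ("at least"). A record at
#' exactly the E-value cutoff is dropped; one at exactly the coverage
#' cutoff is kept. Input order is preserved.
#'
#' @param records `data.frame` with columns `e_value`, `query_coverage`.
#' @param e_max E-value cutoff, exclusive (default 1e-10).
#' @param cov_min Coverage cutoff, inclusive (default 0.75).
#' @return The retained rows.
#' @export
filterHits <- function(records, e_max = 1e-10, cov_min = 0.75) {
  if (!all(c("e_value", "query_coverage") %in% names(records)))
    .stopf("records need columns e_value and query_coverage")
  keep <- records$e_value < e_max & records$query_coverage >= cov_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the longest isoform per gene
#'
#' Groups sequences whose names end in an isoform suffix (default:
#' trailing `.t<k>` or `t<k>`) by the suffix-stripped gene id and keeps
#' the isoform with the greatest ungapped length; ties go to the
#' lexicographically smallest name. Sequences whose names do not match
#' the pattern pass through untouched (isoform filtering is only
#' possible where suffixes identify isoforms).
#'
#' @param sequences Named character vector of (possibly gapped)
#'   sequences.
#' @param suffix_pattern Regular expression for the isoform suffix.
#' @return The filtered named character vector, input order preserved.
#' @export
selectLongestIsoform <- function(sequences,
                                 suffix_pattern = "\\.?t[0-9]+$") {
  nms <- names(sequences)
  if (is.null(nms)) .stopf("sequences must be named")
  hasSuffix <- grepl(suffix_pattern, nms)
  gene <- ifelse(hasSuffix, sub(suffix_pattern, "", nms), nms)
  ungapped <- nchar(gsub("[-.?]|X", "", sequences))
  keep <- logical(length(sequences))
  keep[!hasSuffix] <- TRUE
  for (g in unique(gene[hasSuffix])) {
    idx <- which(hasSuffix & gene == g)
    best <- idx[order(-ungapped[idx], nms[idx])][1L]
    keep[best] <- TRUE
  }
  sequences[keep]
}

#' Feature prevalence per subfamily and for the rest of the data set
#'
#' For each focal subfamily, and for the complement group
#' `"rest_of_data_set"`, reports the fraction of sequences with each
#' predicted feature (signal peptide, R/K cleavage site, GPI anchor)
#' together with the group size. Empty groups yield `NA` prevalences.
#'
#' @param feature_table `data.frame` with columns `subfamily`,
#'   `signal_peptide`, `rk_cleavage_site`, `gpi_anchor` (logicals).
#' @param focal_subfamilies Character vector of subfamily ids.
#' @return `data.frame` with one row per group.
#' @export
summarizeFeatures <- function(feature_table, focal_subfamilies) {
  need <- c("subfamily", "signal_peptide", "rk_cleavage_site", "gpi_anchor")
  if (!all(need %in% names(feature_table)))
    .stopf("feature table needs columns: %s", paste(need, collapse = ", "))
  if (!nrow(feature_table)) .stopf("empty feature table")
  groups <- c(as.list(focal_subfamilies), list("rest_of_data_set"))
  rows <- lapply(groups, function(g) {
    rowsIn <- if (identical(g, "rest_of_data_set"))
      !(feature_table$subfamily %in% focal_subfamilies) else
      feature_table$subfamily == g
    sub <- feature_table[rowsIn, , drop = FALSE]
    frac <- function(x) if (nrow(sub)) mean(x) else NA_real_
    data.frame(group = if (identical(g, "rest_of_data_set")) g else g,
               n = nrow(sub),
               signal_peptide = frac(sub$signal_peptide),
               rk_cleavage_site = frac(sub$rk_cleavage_site),
               gpi_anchor = frac(sub$gpi_anchor),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    .stopf("[stage: %s] %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline from a config
#'
#' Executes the stages in order: synthesize (if requested) -> gap
#' profiles -> trees (read, or NJ fallback per replicate) -> consensus
#' with BRP/TBE -> MAD + midpoint rooting -> loss-clade scan ->
#' connectivity typing + Fitch parsimony -> subfamily/feature summaries.
#' Writes a single JSON report recording every threshold and seed, plus
#' TSV side tables. Nothing is written unless every stage succeeds
#' (failed runs leave no partial report), and reruns with the same
#' config and seed produce byte-identical reports.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent
#'   named list. Recognized entries: `synthetic` (list of
#'   [syntheticSpec()] arguments), `alignments` (FASTA paths),
#'   `trees` (Newick paths), `thresholds` (named list overriding
#'   `tau_high`, `tau_low`, `min_tips`, `call_thresh`,
#'   `proximal_thresh`), `seed`.
#' @param out_dir Output directory.
#' @param seed Seed overriding the config's.
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(config, out_dir = tempfile("zpmod_run"),
                        seed = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  th <- utils::modifyList(list(tau_high = 0.70, tau_low = 0.30,
                               min_tips = 4L, call_thresh = 8.0,
                               proximal_thresh = 10.0),
                          as.list(cfg$thresholds))
  report <- list(config = list(seed = cfg$seed, thresholds = th),
                 version = as.character(utils::packageVersion("zpmod")))
  sideTables <- list()

  bundle <- NULL
  if (!is.null(cfg$synthetic)) {
    bundle <- .pipelineStage("synthesize", {
      args <- as.list(cfg$synthetic)
      args$seed <- cfg$seed
      spec <- do.call(syntheticSpec, args)
      makeFixtureBundle(spec, dir = file.path(out_dir, "bundle"))
    })
    replicates <- bundle$replicates
  } else {
    replicates <- .pipelineStage("read-alignments", {
      if (is.null(cfg$alignments)) .stopf("no alignments and no synthetic spec")
      lapply(cfg$alignments, readAlignment)
    })
  }
  report$n_replicates <- length(replicates)
  report$n_sequences <- length(seqNames(replicates[[1L]]))

  profiles <- .pipelineStage("profiles", meanGapProfiles(replicates))
  sideTables$gap_profiles <- profiles

  trees <- .pipelineStage("trees", {
    if (!is.null(cfg$trees)) lapply(cfg$trees, readNewickTree)
    else lapply(replicates, njTree)
  })
  report$tree_source <- if (!is.null(cfg$trees)) "input" else "nj_fallback"

  if (length(trees) >= 2L) {
    cons <- .pipelineStage("consensus", majorityRuleConsensus(trees))
    report$consensus <- list(
      n_branches = nrow(branchSupport(cons)),
      brp_range = range(branchSupport(cons)$brp),
      tbe_range = range(branchSupport(cons)$tbe))
    sideTables$branch_support <- branchSupport(cons)
  } else {
    report$consensus <- "skipped: fewer than 2 replicate trees"
  }

  rfPairs <- .pipelineStage("rf", {
    if (length(trees) >= 2L) {
      idx <- utils::combn(min(length(trees), 5L), 2L)
      vapply(seq_len(ncol(idx)), function(j)
        rfNormalized(trees[[idx[1L, j]]], trees[[idx[2L, j]]]), numeric(1))
    } else numeric(0)
  })
  if (length(rfPairs)) report$rf_normalized_range <- range(rfPairs)

  mainTree <- trees[[1L]]
  rooting <- .pipelineStage("rooting", rootComparison(mainTree))
  report$rooting <- rooting
  rooted <- .pipelineStage("rooting", madRoot(mainTree)$tree)

  ann <- .pipelineStage("loss-scan", annotateTips(rooted, profiles))
  scan <- .pipelineStage("loss-scan",
    detectLossClades(ann, "ZP-N", tau_high = th$tau_high,
                     tau_low = th$tau_low, min_tips = th$min_tips))
  report$loss_calls <- nrow(scan$calls)
  report$loss_outliers <- nrow(scan$outliers)
  sideTables$loss_calls <- scan$calls

  typing <- .pipelineStage("connectivity", {
    rep0 <- replicates[[1L]]
    reg <- defaultRegistry()
    types <- vapply(seqNames(rep0), function(nm) {
      classifyType(presenceVector(alignedSeqs(rep0)[[nm]], reg))$type
    }, character(1))
    types
  })
  report$type_counts <- as.list(table(typing))
  sideTables$types <- data.frame(name = names(typing), type = unname(typing),
                                 stringsAsFactors = FALSE)

  fitch <- .pipelineStage("parsimony", {
    tr <- rooted
    if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
    fitchParsimony(tr, typing)
  })
  report$type_changes <- fitch$changes

  if (!is.null(bundle)) {
    report$subfamily_summary_file <- "subfamily_summary.tsv"
    sfMap <- stats::setNames(sub("_SP.*$", "", seqNames(replicates[[1L]])),
                             seqNames(replicates[[1L]]))
    sideTables$subfamily_summary <-
      .pipelineStage("summaries", subfamilySummary(sfMap, replicates))
    lossSf <- unique(sub("_SP.*$", "", bundle$truth@lossTips))
    sideTables$feature_prevalence <-
      .pipelineStage("summaries",
                     summarizeFeatures(bundle$features, lossSf))
  }

  # all stages succeeded: write outputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sideTables))
    utils::write.table(sideTables[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
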