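#' Construct a ModuleAlignment from residue strings
#'
#' @param seqs Named character vector of equal-length aligned residue
#'   strings. Residues are upper-cased; "." is normalized to "-".
#' @param replicateId Replicate label (default `"rep0"`).
#' @return A [ModuleAlignment-class].
#' @export
moduleAlignment <- function(seqs, replicateId = "rep0") {
  if (!length(seqs)) .stopf("alignment has no sequences")
  s <- toupper(seqs)
  s <- gsub(".", "-", s, fixed = TRUE)
  new("ModuleAlignment", seqs = s, replicateId = as.character(replicateId))
}

#' Read an aligned FASTA file
#'
#' Reads an aligned protein FASTA into a [ModuleAlignment-class].
#' Residues are upper-cased and "." gaps normalized to "-". Ragged rows,
#' duplicate names and empty files are format errors.
#'
#' @param path FASTA file path.
#' @param replicateId Replicate label; defaults to a `_rep<k>` suffix
#'   parsed from the file name, else the base file name.
#' @return A [ModuleAlignment-class].
#' @export
readAlignment <- function(path, replicateId = NULL) {
  if (!file.exists(path)) .stopf("alignment file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("not a readable FASTA file: %s (%s)",
                                             path, conditionMessage(e)))
  if (!length(set)) .stopf("empty alignment file: %s", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    .stopf("duplicate sequence names in %s", path)
  if (length(unique(nchar(seqs))) > 1L)
    .stopf("ragged alignment (unequal row lengths) in %s", path)
  if (is.null(replicateId)) {
    m <- regmatches(basename(path), regexpr("rep[0-9]+", basename(path)))
    replicateId <- if (length(m)) m else sub("\\.[^.]*$", "", basename(path))
  }
  moduleAlignment(seqs, replicateId)
}

#' Write an alignment as FASTA
#' @param aln A [ModuleAlignment-class].
#' @param path Output path.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "ModuleAlignment"))
  set <- Biostrings::BStringSet(aln@seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @describeIn moduleAlignment Number of alignment columns.
#' @param aln A [ModuleAlignment-class].
#' @export
nCols <- function(aln) {
  stopifnot(is(aln, "ModuleAlignment"))
  if (!length(aln@seqs)) 0L else nchar(aln@seqs[[1L]])
}

#' @describeIn moduleAlignment Sequence names.
#' @export
seqNames <- function(aln) names(aln@seqs)

#' @describeIn moduleAlignment Residue strings (named character vector).
#' @export
alignedSeqs <- function(aln) aln@seqs

#' @describeIn moduleAlignment Replicate label.
#' @export
replicateId <- function(aln) aln@replicateId

setMethod("show", "ModuleAlignment", function(object) {
  cat("ModuleAlignment [", object@replicateId, "]: ",
      length(object@seqs), " sequences x ", nCols(object), " columns\n",
      sep = "")
})

# character matrix view (rows = sequences)
.alnMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, "", fixed = TRUE))
  rownames(m) <- names(aln@seqs)
  m
}

#' Residue frequencies of one alignment column
#'
#' Gaps ("-") and ambiguous residues ("X", "?") count toward the missing
#' fraction; residue frequencies are computed over the remaining rows and
#' sum to 1 whenever any non-missing residue exists.
#'
#' @param aln A [ModuleAlignment-class].
#' @param col 1-based column index.
#' @return List with `col`, `residue_freqs` (named numeric) and
#'   `missing_frac`.
#' @export
columnProfile <- function(aln, col) {
  stopifnot(is(aln, "ModuleAlignment"))
  col <- as.integer(col)
  if (length(col) != 1L || is.na(col) || col < 1L || col > nCols(aln))
    .stopf("column %s out of range 1..%d", col, nCols(aln))
  ch <- substring(aln@seqs, col, col)
  miss <- .isMissingChar(ch)
  freqs <- if (any(!miss)) {
    tb <- table(ch[!miss])
    stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  } else stats::setNames(numeric(0), character(0))
  list(col = col, residue_freqs = freqs,
       missing_frac = mean(miss))
}

#' Majority-rule consensus sequence
#'
#' For each column, emits the residue whose frequency among non-missing
#' rows strictly exceeds `threshold`; otherwise "-". A 50/50 tie at the
#' default threshold therefore yields "-" (strict majority, order
#' independent).
#'
#' @param aln A [ModuleAlignment-class].
#' @param threshold Majority threshold in (0,1); default 0.5.
#' @return List with `consensus` (residue string of length `nCols`) and
#'   `n_cys` (cysteine count of the consensus).
#' @export
consensusSequence <- function(aln, threshold = 0.5) {
  stopifnot(is(aln, "ModuleAlignment"))
  if (!(threshold > 0 && threshold < 1)) .stopf("threshold must be in (0,1)")
  m <- .alnMatrix(aln)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    ch <- m[, j]
    ch <- ch[!.isMissingChar(ch)]
    if (!length(ch)) return("-")
    tb <- table(ch)
    best <- which.max(tb)
    if (tb[best] / length(ch) > threshold) names(tb)[best] else "-"
  }, character(1))
  consensus <- paste(cons, collapse = "")
  list(consensus = consensus, n_cys = sum(cons == "C"))
}

#' Demarcate ZP-N and ZP-C domains from cysteine anchor columns
#'
#' The ZP-N domain is bounded by Cys1 and Cys4, the ZP-C domain by the
#' moderately conserved betaA-strand cysteine and Cys8; the canonical
#' anchors in trimmed-alignment coordinates are columns 1, 80, 105, 218.
#' Intervals are closed and 1-based.
#'
#' @param anchor_cols Four strictly increasing anchor columns
#'   (ZP-N start, ZP-N end, ZP-C start, ZP-C end).
#' @param n_cols Optional alignment width; anchors beyond it are an error.
#' @return `data.frame` with columns `domain`, `start`, `end`.
#' @examples
#' demarcateDomains()
#' @export
demarcateDomains <- function(anchor_cols = c(1L, 80L, 105L, 218L),
                             n_cols = NULL) {
  a <- as.integer(anchor_cols)
  if (length(a) != 4L || anyNA(a)) .stopf("need four anchor columns")
  if (any(diff(a) <= 0L)) .stopf("anchor columns must be strictly increasing")
  if (a[1L] < 1L) .stopf("anchors must be >= 1")
  if (!is.null(n_cols) && a[4L] > n_cols)
    .stopf("anchor %d exceeds alignment width %d", a[4L], n_cols)
  data.frame(domain = c("ZP-N", "ZP-C"),
             start = c(a[1L], a[3L]), end = c(a[2L], a[4L]),
             stringsAsFactors = FALSE)
}

#' Relocate domain anchors within one replicate alignment
#'
#' Replicate alignments jitter columns, so each nominal anchor is moved
#' to the nearest column within `+/- window` whose cysteine frequency
#' among non-missing rows is at least `min_c_freq`; if no such column
#' exists the nominal position is kept (clamped to the alignment).
#'
#' @param aln A [ModuleAlignment-class].
#' @param anchor_cols Nominal anchor columns (default `c(1,80,105,218)`).
#' @param window Search window in columns (default 3).
#' @param min_c_freq Minimum C frequency to accept a column as the
#'   conserved anchor (default 0.5).
#' @return Integer vector of relocated anchors.
#' @export
locateAnchors <- function(aln, anchor_cols = c(1L, 80L, 105L, 218L),
                          window = 3L, min_c_freq = 0.5) {
  stopifnot(is(aln, "ModuleAlignment"))
  nc <- nCols(aln)
  vapply(as.integer(anchor_cols), function(a) {
    lo <- max(1L, a - window); hi <- min(nc, a + window)
    cand <- lo:hi
    cf <- vapply(cand, function(j) {
      p <- columnProfile(aln, j)
      if ("C" %in% names(p$residue_freqs)) p$residue_freqs[["C"]] else 0
    }, numeric(1))
    ok <- cand[cf >= min_c_freq]
    if (!length(ok)) return(min(max(a, 1L), nc))
    ok[which.min(abs(ok - a))]
  }, integer(1))
}

#' Gap proportion of a sequence over a column interval
#'
#' Fraction of positions in the closed interval that are gaps or
#' ambiguous ("-", "X", "?").
#'
#' @param aln A [ModuleAlignment-class].
#' @param seq_name Sequence name.
#' @param interval Length-2 integer vector `c(start, end)`, closed, 1-based.
#' @return Numeric fraction in \[0,1\].
#' @export
gapProportion <- function(aln, seq_name, interval) {
  stopifnot(is(aln, "ModuleAlignment"))
  if (!seq_name %in% names(aln@seqs))
    .stopf("sequence '%s' not present in replicate %s", seq_name, aln@replicateId)
  iv <- as.integer(interval)
  if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L] ||
      iv[1L] < 1L || iv[2L] > nCols(aln))
    .stopf("invalid interval [%s]", paste(interval, collapse = ","))
  ch <- .chars(substring(aln@seqs[[seq_name]], iv[1L], iv[2L]))
  mean(.isMissingChar(ch))
}

#' Per-domain gap profile of one sequence in one replicate
#'
#' @param aln A [ModuleAlignment-class].
#' @param seq_name Sequence name.
#' @param domain_map `data.frame` from [demarcateDomains()].
#' @return `data.frame` with columns `name`, `replicate`, `domain`,
#'   `gap_fraction`.
#' @export
gapProfile <- function(aln, seq_name, domain_map = demarcateDomains()) {
  gf <- vapply(seq_len(nrow(domain_map)), function(i)
    gapProportion(aln, seq_name, c(domain_map$start[i], domain_map$end[i])),
    numeric(1))
  data.frame(name = seq_name, replicate = aln@replicateId,
             domain = domain_map$domain, gap_fraction = gf,
             stringsAsFactors = FALSE)
}

#' Mean per-domain gap proportion across replicate alignments
#'
#' Computes the gap proportion of one sequence for one domain in every
#' replicate (anchors relocated per replicate via [locateAnchors()]),
#' then averages. Missing the sequence in any replicate is an error.
#'
#' @param replicates List of [ModuleAlignment-class] objects.
#' @param seq_name Sequence name.
#' @param domain_id `"ZP-N"` or `"ZP-C"` (a row of the domain map).
#' @param anchor_cols Nominal anchors passed to [locateAnchors()].
#' @param relocate Relocate anchors per replicate (default TRUE).
#' @return List with `mean`, `per_replicate` (named numeric) and
#'   `domain`.
#' @export
replicateMeanGap <- function(replicates, seq_name, domain_id,
                             anchor_cols = c(1L, 80L, 105L, 218L),
                             relocate = TRUE) {
  if (!length(replicates)) .stopf("no replicate alignments given")
  vals <- vapply(replicates, function(aln) {
    if (!seq_name %in% seqNames(aln))
      .stopf("sequence '%s' missing from replicate %s", seq_name,
             replicateId(aln))
    a <- if (relocate) locateAnchors(aln, anchor_cols) else
      pmin(pmax(as.integer(anchor_cols), 1L), nCols(aln))
    dm <- demarcateDomains(a, n_cols = nCols(aln))
    i <- match(domain_id, dm$domain)
    if (is.na(i)) .stopf("unknown domain '%s'", domain_id)
    gapProportion(aln, seq_name, c(dm$start[i], dm$end[i]))
  }, numeric(1))
  names(vals) <- vapply(replicates, replicateId, character(1))
  list(mean = mean(vals), per_replicate = vals, domain = domain_id)
}

#' Per-domain mean gap profiles for all sequences across replicates
#'
#' Convenience wrapper producing the tip-level table consumed by the
#' domain-loss scan: one row per sequence per domain, averaged over
#' replicates.
#'
#' @inheritParams replicateMeanGap
#' @return `data.frame` with columns `name`, `replicate` (`"mean"`),
#'   `domain`, `gap_fraction`.
#' @export
meanGapProfiles <- function(replicates,
                            anchor_cols = c(1L, 80L, 105L, 218L),
                            relocate = TRUE) {
  if (!length(replicates)) .stopf("no replicate alignments given")
  nms <- seqNames(replicates[[1L]])
  doms <- c("ZP-N", "ZP-C")
  # locate anchors once per replicate, then recount
  out <- list()
  per_rep <- lapply(replicates, function(aln) {
    a <- if (relocate) locateAnchors(aln, anchor_cols) else
      pmin(pmax(as.integer(anchor_cols), 1L), nCols(aln))
    dm <- demarcateDomains(a, n_cols = nCols(aln))
    sapply(doms, function(d) {
      i <- match(d, dm$domain)
      vapply(nms, function(nm)
        gapProportion(aln, nm, c(dm$start[i], dm$end[i])), numeric(1))
    })
  })
  for (d in doms) {
    mat <- vapply(per_rep, function(x) x[, d], numeric(length(nms)))
    out[[d]] <- data.frame(name = nms, replicate = "mean", domain = d,
                           gap_fraction = rowMeans(mat),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Position frequency matrix of an alignment
#'
#' One row per column: residue frequencies among non-missing rows plus
#' the missing fraction — the table behind a sequence-logo rendering.
#'
#' @param aln A [ModuleAlignment-class].
#' @return `data.frame` with columns `col`, `missing_frac`, and one
#'   column per residue observed anywhere in the alignment.
#' @export
logoMatrix <- function(aln) {
  stopifnot(is(aln, "ModuleAlignment"))
  if (!length(aln@seqs)) .stopf("empty alignment")
  m <- .alnMatrix(aln)
  residues <- sort(setdiff(unique(as.vector(m)), .MISSING_CHARS))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    ch <- m[, j]
    miss <- .isMissingChar(ch)
    fr <- stats::setNames(numeric(length(residues)), residues)
    if (any(!miss)) {
      tb <- table(ch[!miss])
      fr[names(tb)] <- as.numeric(tb) / sum(tb)
    }
    c(col = j, missing_frac = mean(miss), fr)
  })
  as.data.frame(do.call(rbind, rows))
}
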