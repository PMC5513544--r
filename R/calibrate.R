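## Mock-community calibration: label MOTUs as selected/non-selected
## against the known references, derive the abundance threshold from
## the least abundant selected MOTU, express and transfer it across
## sequencing depths, compute the expected-MOTU partition of the
## references themselves, and emit the detection table.

## Indel-excluded identity between two ungapped sequences via global
## affine alignment (same metric as clustering distances).
alignment_identity <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 1)
  pc <- str_chars(as.character(Biostrings::pattern(pa)))
  sc <- str_chars(as.character(Biostrings::subject(pa)))
  cmp <- pc != "-" & sc != "-"
  if (!any(cmp)) return(0)
  mean(pc[cmp] == sc[cmp])
}

#' Label MOTUs as selected or non-selected against mock references
#'
#' A MOTU is "selected" when its representative sequence reaches the
#' similarity threshold against at least one mock reference, using the
#' same indel-excluded identity as clustering (a representative
#' exactly at the threshold counts as selected); otherwise
#' "non-selected". The best-matching species is recorded either way.
#'
#' @param motuTable a [MotuTable-class].
#' @param mockRefs a `ReferenceSet`, or a named `DNAStringSet` of
#'   primer-free reference interiors (names = species).
#' @param similarityThreshold 0.97 or 0.99 by default (taken from the
#'   table when NULL).
#' @param rawIdentity use raw alignment-column identity (gaps counted
#'   as differences) instead of the indel-excluded metric.
#' @return `DataFrame` with motu_id, total, selected, best_species,
#'   similarity.
#' @export
classifySelected <- function(motuTable, mockRefs,
                             similarityThreshold = NULL,
                             rawIdentity = FALSE) {
  if (inherits(mockRefs, "ReferenceSet")) {
    refSeqs <- as.character(mockRefs$interiors)
    names(refSeqs) <- unname(mockRefs$species)
  } else {
    refSeqs <- as.character(mockRefs)
  }
  if (length(refSeqs) == 0L) stop("empty mock reference set")
  if (is.null(similarityThreshold))
    similarityThreshold <- similarityThreshold(motuTable)
  reps <- as.character(representatives(motuTable))
  ident <- matrix(NA_real_, length(reps), length(refSeqs))
  for (i in seq_along(reps)) for (j in seq_along(refSeqs))
    ident[i, j] <- if (rawIdentity)
      raw_identity(reps[i], refSeqs[j]) else
      alignment_identity(reps[i], refSeqs[j])
  bestJ <- apply(ident, 1L, function(v)
    order(-v, names(refSeqs))[1L])
  best <- ident[cbind(seq_along(reps), bestJ)]
  S4Vectors::DataFrame(
    motu_id = rownames(motuTable),
    total = SummarizedExperiment::rowData(motuTable)$total,
    selected = best >= similarityThreshold,
    best_species = names(refSeqs)[bestJ],
    similarity = best)
}

raw_identity <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 1)
  pc <- str_chars(as.character(Biostrings::pattern(pa)))
  sc <- str_chars(as.character(Biostrings::subject(pa)))
  mean(pc == sc)
}

#' Minimum read count over selected MOTUs
#'
#' The calibration quantity: the total read count of the least
#' abundant MOTU that derives from a known mock species, with that
#' MOTU's species. Ties are resolved toward the smallest MOTU id.
#'
#' @param labels output of [classifySelected()].
#' @return list(`count`, `species`, `motu_id`).
#' @export
minSelectedAbundance <- function(labels) {
  sel <- labels[labels$selected, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no selected MOTUs")
  i <- order(sel$total, sel$motu_id)[1L]
  list(count = as.integer(sel$total[i]),
       species = sel$best_species[i],
       motu_id = sel$motu_id[i])
}

#' Express an abundance threshold count as a per-sample percentage
#'
#' @param count threshold read count (1 <= count <= depth).
#' @param depth subsampled per-sample read depth.
#' @return the exact percentage `100 * count / depth`, printed rounded
#'   to 3 decimals (class `"motu_pct"`).
#' @export
countToFraction <- function(count, depth) {
  if (depth <= 0) stop("depth must be positive")
  if (count < 1 || count > depth)
    stop("count must lie in [1, depth]")
  structure(100 * count / depth, class = "motu_pct")
}

#' @export
print.motu_pct <- function(x, ...) {
  cat(sprintf("%.3f%%\n", unclass(x)))
  invisible(x)
}

#' @export
format.motu_pct <- function(x, ...) sprintf("%.3f%%", unclass(x))

#' Transfer an abundance threshold to a different depth
#'
#' The smallest integer count at the new depth whose per-sample
#' fraction is at least the calibrated fraction:
#' `ceiling(count * newDepth / depth)`.
#'
#' @param count calibrated threshold count.
#' @param depth depth at which it was calibrated.
#' @param newDepth depth of the target analysis.
#' @return integer threshold count at `newDepth`.
#' @export
transferThreshold <- function(count, depth, newDepth) {
  stopifnot(depth >= 1, newDepth >= 1)
  num <- as.numeric(count) * as.numeric(newDepth)
  c0 <- num %/% depth
  as.integer(if (num %% depth == 0) c0 else c0 + 1)
}

#' Calibrate the abundance threshold from a mock analysis
#'
#' Combines [classifySelected()], [minSelectedAbundance()] and
#' [countToFraction()] into a [CalibrationResult-class].
#'
#' @inheritParams classifySelected
#' @param depth per-sample subsampled depth (default: minimum column
#'   sum of the table).
#' @return a [CalibrationResult-class].
#' @export
calibrateThreshold <- function(motuTable, mockRefs,
                               similarityThreshold = NULL,
                               depth = NULL) {
  labels <- classifySelected(motuTable, mockRefs, similarityThreshold)
  m <- minSelectedAbundance(labels)
  if (is.null(depth)) depth <- min(colSums(motuCounts(motuTable)))
  new("CalibrationResult", labels = labels,
      thresholdCount = m$count, thresholdSpecies = m$species,
      depth = as.integer(depth),
      thresholdPct = unclass(countToFraction(m$count, depth)))
}

#' Expected MOTUs: the reference partition at a clustering cutoff
#'
#' Applies the same average-neighbor clustering (indel-excluded
#' distances) to the reference sequences themselves; genetically
#' related species collapse into one expected MOTU.
#'
#' @param refs a `ReferenceSet` (its true alignment is used).
#' @param cutoff distance cutoff (0.03 or 0.01).
#' @return list of character vectors of species names, one per
#'   expected MOTU, each sorted, the list ordered by first species.
#' @export
expectedMotus <- function(refs, cutoff) {
  rows <- as.character(refs$alignment)
  d <- distanceMatrix(rows)
  parts <- average_neighbor(d, cutoff)
  sp <- unname(refs$species)
  out <- lapply(parts, function(idx) sort(sp[idx]))
  out[order(vapply(out, `[[`, character(1), 1L))]
}

#' Detection table of expected versus observed MOTUs
#'
#' Each selected MOTU is mapped to the expected MOTU containing its
#' best-matching species; per expected MOTU the number of observed
#' MOTUs is tallied (>= 2 marks an overestimate) and undetected
#' expected MOTUs are flagged.
#'
#' @param labels output of [classifySelected()].
#' @param expectedPartition output of [expectedMotus()] at the same
#'   similarity threshold.
#' @return data.frame with one row per expected MOTU: `species`
#'   (collapsed with " + "), `n_motus` observed, `detected`; totals in
#'   `attr(, "totals")` (selected, non_selected, total MOTUs).
#' @export
detectionTable <- function(labels, expectedPartition) {
  expOf <- stats::setNames(
    rep(seq_along(expectedPartition),
        lengths(expectedPartition)),
    unlist(expectedPartition))
  sel <- labels[labels$selected, , drop = FALSE]
  hit <- expOf[sel$best_species]
  nObs <- tabulate(hit[!is.na(hit)], nbins = length(expectedPartition))
  out <- data.frame(
    species = vapply(expectedPartition, paste, character(1),
                     collapse = " + "),
    n_motus = nObs,
    detected = nObs >= 1L,
    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(selected = nrow(sel),
                           non_selected = sum(!labels$selected),
                           total = nrow(labels))
  out
}

#' MOTU counts across a sweep of abundance thresholds
#'
#' For each threshold t, the number of MOTUs with at least t total
#' reads, split into selected and non-selected; non-increasing in t.
#'
#' @param labels output of [classifySelected()].
#' @param thresholds ascending integer thresholds.
#' @return data.frame(threshold, selected, non_selected, total).
#' @export
thresholdSweep <- function(labels, thresholds) {
  if (is.unsorted(thresholds))
    stop("thresholds must be ascending")
  sel <- vapply(thresholds, function(t)
    sum(labels$selected & labels$total >= t), integer(1))
  non <- vapply(thresholds, function(t)
    sum(!labels$selected & labels$total >= t), integer(1))
  data.frame(threshold = thresholds, selected = sel,
             non_selected = non, total = sel + non)
}
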