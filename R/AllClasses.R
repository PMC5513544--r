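## Central S4 containers.

#' MotuTable: MOTU-by-sample count container
#'
#' A `MotuTable` holds the result of average-neighbor clustering: a
#' MOTU x sample matrix of read counts (assay `"counts"`), the
#' representative sequence of each MOTU, and the per-member unique
#' sequence counts. It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so the usual
#' accessors (`assay()`, `rowData()`, `colnames()`, `[`) all work.
#' Rows are kept in a canonical order: decreasing total read count,
#' ties broken by MOTU id, so serialisations are reproducible.
#'
#' @slot similarityThreshold numeric similarity used for clustering
#'   (e.g. 0.97 or 0.99); the distance cutoff was
#'   `1 - similarityThreshold`.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass MotuTable
setClass("MotuTable",
  contains = "SummarizedExperiment",
  representation(similarityThreshold = "numeric")
)

setValidity("MotuTable", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("rep_id", "rep_seq", "total")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must contain %s",
                          paste(need, collapse = ", ")))
  if (length(object@similarityThreshold) != 1L ||
      object@similarityThreshold <= 0 || object@similarityThreshold > 1)
    msg <- c(msg, "similarityThreshold must be a single value in (0, 1]")
  if ("members" %in% colnames(rd) && nrow(rd) > 0) {
    ok <- mapply(function(m, rep) rep %in% names(m),
                 rd$members, rd$rep_id)
    if (!all(ok))
      msg <- c(msg, "each representative must be a member of its MOTU")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MotuTable
#'
#' @param counts integer matrix, MOTUs x samples; rownames are MOTU
#'   ids, colnames sample labels.
#' @param repIds character vector of representative unique-sequence ids,
#'   one per MOTU.
#' @param repSeqs character vector of representative (ungapped)
#'   sequences, one per MOTU.
#' @param members list of named integer vectors: per-MOTU total counts
#'   of each member unique sequence (names are unique-sequence ids).
#' @param similarityThreshold similarity used for clustering.
#' @param lineages optional character vector of assigned lineages
#'   (semicolon-delimited), one per MOTU; `NA` when unassigned.
#' @return a [MotuTable-class] object, rows sorted by decreasing total
#'   count with ties broken by MOTU id.
#' @export
MotuTable <- function(counts, repIds, repSeqs, members = NULL,
                      similarityThreshold, lineages = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    stop("counts must have MOTU ids as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample labels as colnames")
  total <- as.integer(rowSums(counts))
  ord <- order(-total, rownames(counts))
  rd <- S4Vectors::DataFrame(
    rep_id = as.character(repIds),
    rep_seq = as.character(repSeqs),
    total = total,
    row.names = rownames(counts)
  )
  if (!is.null(members)) rd$members <- members
  if (!is.null(lineages)) rd$lineage <- as.character(lineages)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd
  )
  se <- se[ord, ]
  new("MotuTable", se, similarityThreshold = similarityThreshold)
}

#' @describeIn MotuTable MOTU x sample count matrix.
#' @param object,x a `MotuTable`.
#' @export
motuCounts <- function(object) {
  SummarizedExperiment::assay(object, "counts")
}

#' @describeIn MotuTable representative sequences as a named
#'   `DNAStringSet` (names are MOTU ids).
#' @export
representatives <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  out <- Biostrings::DNAStringSet(rd$rep_seq)
  names(out) <- rownames(object)
  out
}

#' @describeIn MotuTable similarity threshold used for clustering.
#' @export
similarityThreshold <- function(object) object@similarityThreshold

#' @describeIn MotuTable per-MOTU member unique-sequence counts.
#' @export
motuMembers <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"members" %in% colnames(rd)) return(NULL)
  stats::setNames(as.list(rd$members), rownames(object))
}

setMethod("show", "MotuTable", function(object) {
  cnt <- motuCounts(object)
  cat(sprintf(
    "MotuTable: %d MOTUs x %d samples (similarity %.2f, %d reads)\n",
    nrow(cnt), ncol(cnt), object@similarityThreshold, sum(cnt)))
  cat("samples:", paste(colnames(cnt), collapse = ", "), "\n")
  k <- min(5L, nrow(cnt))
  if (k > 0) {
    cat(sprintf("top %d MOTUs by total count:\n", k))
    print(utils::head(
      data.frame(total = SummarizedExperiment::rowData(object)$total,
                 row.names = rownames(cnt)), k))
  }
  invisible(NULL)
})

#' ClassifierModel: trained k-mer naive-Bayes taxonomy model
#'
#' Word-presence naive-Bayes model over k-mers, trained per leaf taxon
#' with corpus-prior smoothing `(m + Pi) / (M + 1)` where
#' `Pi = (n + 0.5) / (N + 1)` is the corpus-wide word prior.
#'
#' @slot k word length.
#' @slot ranks names of the taxonomic ranks (constant depth).
#' @slot lineages character matrix, leaf taxa x ranks.
#' @slot leafNames leaf taxon labels (deepest rank).
#' @slot vocab integer ids (1..4^k) of words observed in training.
#' @slot logProb matrix leaves x vocab of log word probabilities.
#' @slot defaultLog per-leaf log probability for words unseen in the
#'   whole corpus.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(k = "integer", ranks = "character",
                 lineages = "matrix", leafNames = "character",
                 vocab = "integer", logProb = "matrix",
                 defaultLog = "numeric")
)

setValidity("ClassifierModel", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (nrow(object@logProb) != length(object@leafNames))
    msg <- c(msg, "logProb rows must match leaf taxa")
  if (ncol(object@logProb) != length(object@vocab))
    msg <- c(msg, "logProb columns must match vocabulary")
  if (any(object@logProb >= 0))
    msg <- c(msg, "log probabilities must be negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: k=%d, %d leaf taxa, %d ranks (%s), %d words\n",
    object@k, length(object@leafNames), length(object@ranks),
    paste(object@ranks, collapse = " > "), length(object@vocab)))
  invisible(NULL)
})

#' CalibrationResult: mock-community abundance threshold
#'
#' Output of [calibrateThreshold()]: per-MOTU selected/non-selected
#' labels against the mock references, the minimum read count over
#' selected MOTUs (the abundance threshold), and that count expressed
#' as a per-sample percentage of the subsampled depth.
#'
#' @slot labels `DataFrame` with columns motu_id, total, selected,
#'   best_species, similarity.
#' @slot thresholdCount minimum read count over selected MOTUs.
#' @slot thresholdSpecies species of the minimum-count selected MOTU.
#' @slot depth subsampled per-sample read depth the percentage refers to.
#' @slot thresholdPct `100 * thresholdCount / depth`.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(labels = "DataFrame", thresholdCount = "integer",
                 thresholdSpecies = "character", depth = "integer",
                 thresholdPct = "numeric")
)

setMethod("show", "CalibrationResult", function(object) {
  lab <- object@labels
  cat(sprintf(
    paste0("CalibrationResult: %d MOTUs (%d selected, %d non-selected)\n",
           "abundance threshold: %d reads (%s%% of depth %d; %s)\n"),
    nrow(lab), sum(lab$selected), sum(!lab$selected),
    object@thresholdCount, formatC(object@thresholdPct, format = "f",
                                   digits = 3),
    object@depth, object@thresholdSpecies))
  invisible(NULL)
})

#' @describeIn CalibrationResult selected/non-selected label table.
#' @param object a `CalibrationResult`.
#' @export
calibrationLabels <- function(object) object@labels

#' @describeIn CalibrationResult the abundance threshold as a read count.
#' @export
thresholdCount <- function(object) object@thresholdCount

#' @describeIn CalibrationResult the threshold as a per-sample
#'   percentage (rounded to 3 decimals for display; exact internally).
#' @export
thresholdPct <- function(object) object@thresholdPct
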