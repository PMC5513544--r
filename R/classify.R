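## k-mer naive-Bayes taxonomic assignment with bootstrap confidence
## (word-presence model with corpus-prior smoothing), used to screen
## reads for the target group before clustering and to re-check for
## contaminants after denoising.

## Distinct k-mer ids (1..4^k) of a sequence by rolling base-4
## encoding; windows containing non-ACGT characters are skipped.
kmer_ids <- function(seq, k) {
  v <- match(str_chars(seq), DNA_BASES4) - 1L
  n <- length(v)
  if (n < k) return(integer(0))
  W <- n - k + 1L
  code <- numeric(W)
  bad <- logical(W)
  for (j in 0:(k - 1L)) {
    x <- v[(1L + j):(W + j)]
    nax <- is.na(x)
    bad <- bad | nax
    x[nax] <- 0L
    code <- code + x * 4^(k - 1L - j)
  }
  unique(as.integer(code[!bad]) + 1L)
}

#' Train the k-mer naive-Bayes classifier
#'
#' Word (k-mer) presence is tallied per leaf taxon; the probability
#' that a leaf contains word w is smoothed with the corpus-wide word
#' prior: `P(w | taxon) = (m + Pi) / (M + 1)` with
#' `Pi = (n + 0.5) / (N + 1)`, where m of the M training sequences of
#' the taxon and n of all N training sequences contain w.
#'
#' @param references named `DNAStringSet` (or character vector) of
#'   training sequences.
#' @param taxonomy a `TaxonomyMap` covering every reference id.
#' @param k word length (default 8).
#' @return a [ClassifierModel-class].
#' @export
trainClassifier <- function(references, taxonomy, k = 8L) {
  if (k < 1L) stop("k must be >= 1")
  seqs <- stats::setNames(as.character(references), names(references))
  ids <- names(seqs)
  if (is.null(ids) || !all(ids %in% rownames(taxonomy)))
    stop("every reference id must have a lineage in the taxonomy")
  short <- nchar(seqs) < k
  if (any(short)) {
    warning("skipping ", sum(short), " reference(s) shorter than k")
    seqs <- seqs[!short]; ids <- ids[!short]
  }
  if (length(seqs) == 0L)
    stop("training error: no reference is at least k bases long")

  linMat <- as.matrix(taxonomy[ids, , drop = FALSE])
  leafLineage <- apply(linMat, 1L, paste0, collapse = ";")
  leaves <- unique(leafLineage)
  leafOf <- match(leafLineage, leaves)

  words <- lapply(seqs, kmer_ids, k = k)
  vocab <- sort(unique(unlist(words)))
  N <- length(seqs)
  nWord <- integer(length(vocab))        # corpus presence counts
  mWord <- matrix(0L, length(leaves), length(vocab))
  for (i in seq_along(words)) {
    idx <- match(words[[i]], vocab)
    nWord[idx] <- nWord[idx] + 1L
    mWord[leafOf[i], idx] <- mWord[leafOf[i], idx] + 1L
  }
  Pi <- (nWord + 0.5) / (N + 1)
  M <- as.integer(table(factor(leafOf, levels = seq_along(leaves))))
  logProb <- log(sweep(sweep(mWord, 2L, Pi, "+"), 1L, M + 1L, "/"))
  defaultLog <- log((0.5 / (N + 1)) / (M + 1))

  lineages <- do.call(rbind, strsplit(leaves, ";", fixed = TRUE))
  new("ClassifierModel", k = as.integer(k),
      ranks = paste0("rank", seq_len(ncol(lineages))),
      lineages = lineages,
      leafNames = lineages[, ncol(lineages)],
      vocab = as.integer(vocab), logProb = logProb,
      defaultLog = defaultLog)
}

## Per-leaf log-probability matrix for a query's words (leaves x W);
## out-of-corpus words take the per-leaf default column.
word_loglik <- function(model, wordIdx) {
  W <- length(wordIdx)
  m <- matrix(model@defaultLog, nrow = nrow(model@logProb), ncol = W)
  known <- !is.na(wordIdx)
  if (any(known))
    m[, known] <- model@logProb[, wordIdx[known], drop = FALSE]
  m
}

score_words <- function(model, wordIdx) {
  rowSums(word_loglik(model, wordIdx))
}

#' Classify a sequence with bootstrap confidence
#'
#' The query's distinct k-mers are scored against every leaf taxon;
#' `nBootstrap` random draws of `ceiling(W/8)` words (W = word count)
#' are then classified the same way, and the per-rank confidence is
#' the fraction of draws agreeing with the full-data winner at that
#' rank. The reported lineage is truncated at the deepest rank whose
#' confidence exceeds `confidenceThreshold` (strict, matching a
#' "> 70\%" rule). Both strands are scored and the better one used.
#'
#' @param seq query sequence (character).
#' @param model a [ClassifierModel-class].
#' @param nBootstrap bootstrap draws (default 100).
#' @param confidenceThreshold strict confidence cutoff (default 0.70).
#' @param seed integer seed for the bootstrap.
#' @return an `Assignment` list: full `lineage`, per-rank `confidence`,
#'   `assigned` lineage truncated at the deepest confident rank
#'   (character(0) when no rank is confident), `orientation`.
#' @export
classifySequence <- function(seq, model, nBootstrap = 100L,
                             confidenceThreshold = 0.70, seed = 1L) {
  if (nchar(seq) < model@k)
    stop("sequence shorter than classifier word length")
  fwdWords <- kmer_ids(seq, model@k)
  revWords <- kmer_ids(revcomp_chr(seq), model@k)
  if (length(fwdWords) == 0L && length(revWords) == 0L) {
    nRanks <- ncol(model@lineages)
    return(list(lineage = rep(NA_character_, nRanks),
                confidence = rep(0, nRanks),
                assigned = character(0), orientation = "forward"))
  }
  fwdIdx <- match(fwdWords, model@vocab)
  revIdx <- match(revWords, model@vocab)
  sFwd <- score_words(model, fwdIdx)
  sRev <- score_words(model, revIdx)
  if (max(sFwd) >= max(sRev)) {
    wordIdx <- fwdIdx; scores <- sFwd; orientation <- "forward"
  } else {
    wordIdx <- revIdx; scores <- sRev; orientation <- "reverse"
  }
  if (all(is.na(wordIdx))) {
    ## no query word occurs anywhere in the corpus: unclassifiable
    nRanks <- ncol(model@lineages)
    return(list(lineage = rep(NA_character_, nRanks),
                confidence = rep(0, nRanks),
                assigned = character(0), orientation = orientation))
  }
  winner <- which.max(scores)
  nRanks <- ncol(model@lineages)
  W <- length(wordIdx)
  draw <- max(1L, ceiling(W / 8))
  ## bootstrap as one multinomial draw matrix and one matrix product
  ll <- word_loglik(model, wordIdx)
  counts <- with_seed(seed,
    stats::rmultinom(nBootstrap, draw, rep(1 / W, W)))
  bs <- ll %*% counts                       # leaves x nBootstrap
  winners <- max.col(t(bs), ties.method = "first")
  ## deepest rank at which each leaf's lineage matches the winner's
  agreeDepth <- apply(
    model@lineages == rep(model@lineages[winner, ],
                          each = nrow(model@lineages)),
    1L, function(z) { d <- which(!z); if (length(d)) d[1L] - 1L else
      nRanks })
  conf <- vapply(seq_len(nRanks),
                 function(r) mean(agreeDepth[winners] >= r), numeric(1))
  deepest <- if (any(conf > confidenceThreshold))
    max(which(conf > confidenceThreshold)) else 0L
  list(lineage = model@lineages[winner, ],
       confidence = conf,
       assigned = if (deepest > 0L)
         model@lineages[winner, seq_len(deepest)] else character(0),
       orientation = orientation)
}

#' Classify many sequences
#'
#' @param seqs named character vector (or `DNAStringSet`).
#' @inheritParams classifySequence
#' @return list of assignments (see [classifySequence()]), named by
#'   sequence id.
#' @export
classifySequences <- function(seqs, model, nBootstrap = 100L,
                              confidenceThreshold = 0.70, seed = 1L) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  for (i in seq_along(seqs))
    out[[i]] <- classifySequence(seqs[i], model, nBootstrap,
                                 confidenceThreshold,
                                 seed = child_seed(seed, i))
  out
}

#' Screen sequences for a target lineage prefix
#'
#' Keeps sequences whose assignment matches `targetPrefix` at every
#' prefix rank with confidence above the threshold at the prefix's
#' deepest rank; applied both before clustering and again after
#' denoising to catch contaminants.
#'
#' @param seqs named character vector (or `DNAStringSet`).
#' @param model a [ClassifierModel-class].
#' @param targetPrefix character vector of leading lineage ranks
#'   (e.g. `"Copepoda"`).
#' @inheritParams classifySequence
#' @return list(`kept`, `discarded`): named character vectors.
#' @export
screenTargetGroup <- function(seqs, model, targetPrefix,
                              nBootstrap = 100L,
                              confidenceThreshold = 0.70, seed = 1L) {
  seqs0 <- stats::setNames(as.character(seqs), names(seqs))
  if (length(seqs0) == 0L)
    return(list(kept = character(0), discarded = character(0)))
  depth <- length(targetPrefix)
  if (depth < 1L || depth > ncol(model@lineages))
    stop("targetPrefix must be a valid lineage prefix")
  ass <- classifySequences(seqs0, model, nBootstrap,
                           confidenceThreshold, seed)
  keep <- vapply(ass, function(a) {
    isTRUE(!any(is.na(a$lineage[seq_len(depth)])) &&
             all(a$lineage[seq_len(depth)] == targetPrefix) &&
             a$confidence[depth] > confidenceThreshold)
  }, logical(1))
  list(kept = seqs0[keep], discarded = seqs0[!keep])
}
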