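## Denoising and MOTU clustering: reference-anchored alignment,
## indel-excluded distances, abundance-greedy single-linkage
## preclustering, singleton removal, a simplified two-parent chimera
## scorer, rarefaction, and agglomerative average-neighbor clustering
## with a deterministic tie rule.

#' Collapse reads to unique sequences with per-sample counts
#'
#' @param seqs named character vector of (primer-stripped) read
#'   sequences.
#' @param samples sample label per read.
#' @return a `UniqueSet` list: `ids` (u000001...), `seqs` (unique
#'   sequences), `counts` (unique x sample integer matrix), `members`
#'   (per unique, ids of the collapsed reads), ordered by decreasing
#'   total count with ties broken lexicographically by sequence.
#' @export
dedupeReads <- function(seqs, samples = rep("sample1", length(seqs))) {
  stopifnot(length(seqs) == length(samples))
  uniq <- sort(unique(unname(seqs)))
  sampleLevels <- sort(unique(samples))
  counts <- table(factor(match(seqs, uniq), levels = seq_along(uniq)),
                  factor(samples, levels = sampleLevels))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(NULL, sampleLevels))
  total <- rowSums(counts)
  ord <- order(-total, uniq)
  uniq <- uniq[ord]
  counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("u%06d", seq_along(uniq))
  rownames(counts) <- ids
  members <- split(names(seqs) %||% as.character(seq_along(seqs)),
                   factor(match(unname(seqs), uniq),
                          levels = seq_along(uniq)))
  names(members) <- ids
  structure(list(ids = ids, seqs = stats::setNames(uniq, ids),
                 counts = counts, members = members),
            class = "UniqueSet")
}

#' Anchor queries into a reference alignment
#'
#' Each query is globally aligned (affine gaps: match +1, mismatch -1,
#' gap open -5, extend -1) to its nearest reference (most shared
#' 6-mers) and threaded into the reference coordinate system;
#' query-specific insertions are counted but projected out so that all
#' rows share the reference column set. Queries below 50\% identity to
#' their nearest reference are flagged unalignable and excluded.
#'
#' @param queries named character vector (or `DNAStringSet`) of
#'   ungapped query sequences.
#' @param referenceAlignment named `DNAStringSet` of equal-width gapped
#'   reference rows.
#' @return an `AlignedSet` list: `rows` (named gapped character
#'   vector, one per alignable query, width = reference columns),
#'   `insertions` (projected-out insertion base counts), `unalignable`
#'   (query names excluded).
#' @export
alignToReference <- function(queries, referenceAlignment) {
  if (length(referenceAlignment) == 0L)
    stop("reference alignment must be non-empty")
  refRows <- as.character(referenceAlignment)
  width <- unique(nchar(refRows))
  if (length(width) != 1L)
    stop("reference alignment rows must have equal width")
  queries <- stats::setNames(as.character(queries), names(queries))
  if (length(queries) == 0L)
    return(structure(list(rows = character(0), insertions = integer(0),
                          unalignable = character(0), width = width),
                     class = "AlignedSet"))
  qnames <- names(queries) %||% sprintf("q%06d", seq_along(queries))
  refSeqs <- degap(refRows)
  ## nearest reference by shared 6-mer presence
  k <- 6L
  presence <- function(s) {
    p <- numeric(4^k)
    p[kmer_ids(s, k)] <- 1
    p
  }
  refK <- t(vapply(refSeqs, presence, numeric(4^k)))
  qK <- t(vapply(queries, presence, numeric(4^k)))
  shared <- qK %*% t(refK)
  nearest <- max.col(shared, ties.method = "first")

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  rows <- character(length(queries))
  insertions <- integer(length(queries))
  ok <- logical(length(queries))
  ## per-reference column maps
  refNonGap <- lapply(refRows, function(r) which(str_chars(r) != "-"))
  for (r in sort(unique(nearest))) {
    idx <- which(nearest == r)
    pas <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(queries[idx]),
      Biostrings::DNAString(refSeqs[r]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1)
    pStr <- as.character(Biostrings::pattern(pas))
    sStr <- as.character(Biostrings::subject(pas))
    for (j in seq_along(idx)) {
      pc <- str_chars(pStr[j]); sc <- str_chars(sStr[j])
      inRef <- sc != "-"
      refPos <- cumsum(inRef)
      qvec <- rep("-", nchar(refSeqs[r]))
      qvec[refPos[inRef]] <- pc[inRef]
      ins <- sum(!inRef & pc != "-")
      ## identity to the anchor, indel-excluded
      cmp <- inRef & pc != "-"
      ident <- if (any(cmp)) mean(pc[cmp] == sc[cmp]) else 0
      i <- idx[j]
      insertions[i] <- ins
      if (ident < 0.5) next
      out <- rep("-", width)
      out[refNonGap[[r]]] <- qvec
      rows[i] <- paste0(out, collapse = "")
      ok[i] <- TRUE
    }
  }
  structure(list(
    rows = stats::setNames(rows[ok], qnames[ok]),
    insertions = stats::setNames(insertions[ok], qnames[ok]),
    unalignable = qnames[!ok],
    width = width), class = "AlignedSet")
}

#' Indel-excluded distance between two aligned rows
#'
#' Distance is mismatches over compared columns, where a column is
#' compared only if both rows carry a base (any gap excludes the
#' column). By convention the distance is 1 when no column is shared,
#' keeping downstream clustering well defined.
#'
#' @param rowA,rowB equal-length gapped sequences.
#' @return distance in [0, 1].
#' @export
pairwiseDistance <- function(rowA, rowB) {
  if (nchar(rowA) != nchar(rowB))
    stop("aligned rows must have equal length")
  d <- row_divergence(rowA, rowB)
  if (is.na(d)) 1.0 else d
}

## Pairwise mismatch and compared-column counts for a set of aligned
## rows, via indicator-matrix cross products.
mismatch_counts <- function(rows) {
  m <- rows_to_matrix(rows)
  n <- nrow(m)
  base <- matrix(0, n, n)
  nongap <- matrix(as.numeric(m != "-"), n)
  for (b in DNA_BASES4) {
    ind <- matrix(as.numeric(m == b), n)
    base <- base + tcrossprod(ind)
  }
  compared <- tcrossprod(nongap)
  list(mismatch = compared - base, compared = compared)
}

#' Indel-excluded distance matrix for aligned rows
#'
#' @param rows named character vector of equal-length gapped rows.
#' @return symmetric matrix of [pairwiseDistance()] values with zero
#'   diagonal.
#' @export
distanceMatrix <- function(rows) {
  mc <- mismatch_counts(rows)
  d <- ifelse(mc$compared > 0, mc$mismatch / pmax(mc$compared, 1), 1)
  diag(d) <- 0
  dimnames(d) <- list(names(rows), names(rows))
  d
}

#' Abundance-greedy single-linkage preclustering
#'
#' Unique sequences are visited in decreasing-count order (ties broken
#' lexicographically by sequence, the `UniqueSet` order); each is
#' absorbed into the cluster of the most abundant earlier sequence
#' within `maxDiffs` indel-excluded mismatches, accumulating counts to
#' that cluster's attractor. Absorbed sequences remain attachment
#' points, giving the single-linkage chaining behaviour.
#'
#' @param uniqueSet a `UniqueSet` (see [dedupeReads()]).
#' @param alignedRows gapped rows for the unique sequences (named by
#'   unique id).
#' @param maxDiffs maximum mismatches for absorption (default 2,
#'   about 0.5\% of a 400 bp marker).
#' @return a `UniqueSet` of attractors with accumulated counts, plus
#'   `rows` (their aligned rows) and `members` mapping each attractor
#'   to its absorbed unique ids.
#' @export
precluster <- function(uniqueSet, alignedRows, maxDiffs = 2L) {
  ids <- uniqueSet$ids
  ids <- ids[ids %in% names(alignedRows)]
  if (length(ids) == 0L)
    return(structure(list(ids = character(0), seqs = character(0),
                          counts = uniqueSet$counts[0, , drop = FALSE],
                          rows = character(0),
                          members = list()), class = "UniqueSet"))
  rows <- alignedRows[ids]
  counts <- uniqueSet$counts[ids, , drop = FALSE]
  total <- rowSums(counts)
  n <- length(ids)
  mism <- mismatch_counts(rows)$mismatch
  root <- seq_len(n)
  find_root <- function(i) { while (root[i] != i) i <- root[i]; i }
  for (i in seq_len(n)[-1L]) {
    cand <- which(mism[i, seq_len(i - 1L)] <= maxDiffs)
    if (length(cand) == 0L) next
    best <- cand[order(-total[cand], cand)][1L]
    root[i] <- find_root(best)
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  keep <- sort(unique(roots))
  newCounts <- rowsum(counts, group = roots, reorder = TRUE)
  rownames(newCounts) <- ids[keep]
  members <- split(ids, factor(roots, levels = keep))
  names(members) <- ids[keep]
  out <- list(ids = ids[keep],
              seqs = uniqueSet$seqs[ids[keep]],
              counts = newCounts,
              rows = rows[keep],
              members = members)
  ## restore canonical order (desc total, ties by sequence)
  ord <- order(-rowSums(out$counts), out$seqs)
  structure(list(ids = out$ids[ord], seqs = out$seqs[ord],
                 counts = out$counts[ord, , drop = FALSE],
                 rows = out$rows[ord], members = out$members[ord]),
            class = "UniqueSet")
}

#' Remove singleton preclusters
#'
#' Preclusters with a total count of 1 are dropped. In pyro mode this
#' is a no-op: singletons were retained in the pyrosequencing-based
#' workflow this reproduces.
#'
#' @param uniqueSet a `UniqueSet` (with `rows` if present).
#' @param mode `"miseq"` (drop singletons) or `"pyro"` (keep).
#' @return the filtered `UniqueSet`.
#' @export
removeSingletons <- function(uniqueSet, mode = c("miseq", "pyro")) {
  mode <- match.arg(mode)
  if (mode == "pyro") return(uniqueSet)
  keep <- rowSums(uniqueSet$counts) > 1L
  subset_unique(uniqueSet, keep)
}

subset_unique <- function(u, keep) {
  out <- list(ids = u$ids[keep], seqs = u$seqs[keep],
              counts = u$counts[keep, , drop = FALSE])
  if (!is.null(u$rows)) out$rows <- u$rows[keep]
  if (!is.null(u$members)) out$members <- u$members[keep]
  structure(out, class = "UniqueSet")
}

## Best single-parent and best two-parent (single breakpoint) identity
## of a query row against a set of parent rows; returns the score gain
## and the two segment identities of the best bimera model.
bimera_score <- function(qChars, parentMat) {
  none <- list(gain = -Inf, idPre = 0, idSuf = 0, model = 0)
  m <- nrow(parentMat)
  if (m < 2L) return(none)
  cmp <- t(t(parentMat != "-") & (qChars != "-"))
  mat <- cmp & t(t(parentMat) == qChars)
  cmpC <- t(apply(cmp, 1L, cumsum))
  matC <- t(apply(mat, 1L, cumsum))
  L <- length(qChars)
  totC <- cmpC[, L]; totM <- matC[, L]
  bestSingle <- max(totM / pmax(totC, 1))
  minSeg <- 10L  # require some evidence in both segments
  bp <- seq_len(L - 1L)
  preC <- cmpC[, bp, drop = FALSE]; preM <- matC[, bp, drop = FALSE]
  sufC <- totC - preC; sufM <- totM - preM
  idPre <- preM / pmax(preC, 1); idPre[preC < minSeg] <- -1
  idSuf <- sufM / pmax(sufC, 1); idSuf[sufC < minSeg] <- -1
  argmax2 <- function(idm) {
    a1 <- max.col(t(idm), ties.method = "first")
    idm2 <- idm
    idm2[cbind(a1, bp)] <- -Inf
    a2 <- max.col(t(idm2), ties.method = "first")
    list(a1 = a1, a2 = a2)
  }
  pre <- argmax2(idPre); suf <- argmax2(idSuf)
  comb_of <- function(a, b)
    (preM[cbind(a, bp)] + sufM[cbind(b, bp)]) /
      pmax(preC[cbind(a, bp)] + sufC[cbind(b, bp)], 1)
  pick <- function(a, b) {
    ok <- idPre[cbind(a, bp)] >= 0 & idSuf[cbind(b, bp)] >= 0
    comb <- comb_of(a, b)
    comb[!ok] <- -Inf
    comb
  }
  ## best distinct prefix/suffix parents: where the two argmaxes
  ## coincide, try the runner-up on either side
  same <- pre$a1 == suf$a1
  combA <- pick(pre$a1, ifelse(same, suf$a2, suf$a1))
  combB <- pick(ifelse(same, pre$a2, pre$a1), suf$a1)
  useA <- combA >= combB
  comb <- pmax(combA, combB)
  if (!any(is.finite(comb))) return(none)
  c0 <- which.max(comb)
  p1 <- if (useA[c0]) pre$a1[c0] else
    if (same[c0]) pre$a2[c0] else pre$a1[c0]
  p2 <- if (useA[c0] && same[c0]) suf$a2[c0] else suf$a1[c0]
  list(gain = comb[c0] - bestSingle,
       idPre = idPre[p1, c0], idSuf = idSuf[p2, c0],
       model = comb[c0])
}

#' Flag likely two-parent chimeras
#'
#' A simplified bimera test: a query is flagged when some single
#' breakpoint, with the prefix taken from one parent and the suffix
#' from another, improves identity over the best single parent by at
#' least `minGain`, both parent segments stay at least
#' `minParentIdentity` identical to the query, and the bimera model as
#' a whole explains at least `minModelIdentity` of the query (keeping
#' genuinely divergent rare species, which no two-parent model can
#' reconstruct, from being flagged). In reference mode
#' parents are the reference rows; in de novo mode parents are other
#' preclusters at least `abundanceSkew` times as abundant as the query
#' (so the most abundant sequence is exempt). The union of both flag
#' sets is reported.
#'
#' @param uniqueSet a `UniqueSet` with aligned `rows`.
#' @param referenceRows gapped reference rows (same width), or NULL to
#'   skip the reference test.
#' @param deNovo also run the abundance-skewed de novo test.
#' @param minGain minimum identity gain of the bimera model.
#' @param minParentIdentity minimum per-segment parent identity.
#' @param minModelIdentity minimum overall identity of the bimera
#'   model to the query.
#' @param abundanceSkew parent/query abundance ratio for de novo.
#' @return named logical vector of chimera flags.
#' @export
detectChimeras <- function(uniqueSet, referenceRows = NULL,
                           deNovo = TRUE, minGain = 0.02,
                           minParentIdentity = 0.80,
                           minModelIdentity = 0.97,
                           abundanceSkew = 2) {
  n <- length(uniqueSet$ids)
  flags <- stats::setNames(rep(FALSE, n), uniqueSet$ids)
  if (n == 0L) return(flags)
  hit <- function(b) {
    is.finite(b$gain) && b$gain >= minGain &&
      b$idPre >= minParentIdentity && b$idSuf >= minParentIdentity &&
      b$model >= minModelIdentity
  }
  qMat <- rows_to_matrix(uniqueSet$rows)
  total <- rowSums(uniqueSet$counts)
  if (!is.null(referenceRows) && length(referenceRows) >= 2L) {
    pMat <- rows_to_matrix(as.character(referenceRows))
    for (i in seq_len(n))
      if (hit(bimera_score(qMat[i, ], pMat))) flags[i] <- TRUE
  }
  if (deNovo && n >= 3L) {
    for (i in seq_len(n)) {
      if (flags[i]) next
      parents <- setdiff(which(total >= abundanceSkew * total[i]), i)
      if (length(parents) < 2L) next
      if (hit(bimera_score(qMat[i, ], qMat[parents, , drop = FALSE])))
        flags[i] <- TRUE
    }
  }
  flags
}

#' Rarefy per-sample counts to a common depth
#'
#' Reads are drawn without replacement (multivariate hypergeometric)
#' within each sample so that every per-sample total equals `depth`
#' exactly.
#'
#' @param counts unique x sample integer matrix.
#' @param depth target depth; default is the minimum per-sample total.
#' @param seed integer seed.
#' @return subsampled counts matrix (same dimensions).
#' @export
subsampleCounts <- function(counts, depth = NULL, seed = 1L) {
  totals <- colSums(counts)
  if (is.null(depth)) depth <- min(totals)
  if (any(depth > totals))
    stop("depth exceeds the total count of sample(s): ",
         paste(colnames(counts)[depth > totals], collapse = ", "))
  out <- counts
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      pool <- rep(seq_len(nrow(counts)), counts[, j])
      drawn <- sample(pool, depth)
      out[, j] <- tabulate(drawn, nbins = nrow(counts))
    }
  })
  out
}

## Agglomerative average-neighbor partition of a distance matrix.
## Merging proceeds while the minimum average cross-pair distance is
## <= cutoff; ties are broken by the smallest (id, id) pair, where a
## cluster's id is its smallest member index. Returns a list of member
## index vectors.
average_neighbor <- function(d, cutoff) {
  n <- nrow(d)
  if (n == 0L) return(list())
  if (!isTRUE(all.equal(d, t(d))))
    stop("distance matrix must be symmetric")
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  size <- rep(1, n)
  eps <- 1e-9  # tie/threshold tolerance for averaged distances
  D <- d
  diag(D) <- Inf
  D[!upper.tri(D)] <- Inf
  while (sum(active) > 1L) {
    mn <- min(D[active, active, drop = FALSE][
      is.finite(D[active, active, drop = FALSE])], Inf)
    if (!is.finite(mn) || mn > cutoff + eps) break
    hit <- which(D <= mn + eps & is.finite(D), arr.ind = TRUE)
    ## tie rule: smallest (min id, max id) pair; slot index == min id
    ids <- cbind(pmin(hit[, 1L], hit[, 2L]), pmax(hit[, 1L], hit[, 2L]))
    pick <- order(ids[, 1L], ids[, 2L])[1L]
    i <- ids[pick, 1L]; j <- ids[pick, 2L]
    ## Lance-Williams update for average linkage
    for (k in which(active)) {
      if (k == i || k == j) next
      dik <- D[min(i, k), max(i, k)]
      djk <- D[min(j, k), max(j, k)]
      D[min(i, k), max(i, k)] <-
        (size[i] * dik + size[j] * djk) / (size[i] + size[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  members[active]
}

#' Representative of a MOTU: most abundant member sequence
#'
#' @param seqs member unique sequences.
#' @param totals member total counts.
#' @return index of the representative: highest total, ties broken by
#'   lexicographically smallest sequence.
#' @export
representativeSequence <- function(seqs, totals) {
  order(-totals, seqs)[1L]
}

#' Average-neighbor MOTU clustering
#'
#' Unique sequences are joined by unweighted-pair average linkage
#' (cluster-to-cluster distance = arithmetic mean over all cross-pairs
#' of unique sequences) while the minimum average distance does not
#' exceed `cutoff` (= 1 - similarity); ties are broken by the smallest
#' pair of cluster ids. Each final cluster is one MOTU; its
#' representative is the most abundant member unique sequence.
#'
#' @param d symmetric indel-excluded distance matrix over the unique
#'   sequences of `uniqueSet` (same order).
#' @param uniqueSet a `UniqueSet` with `counts` and `seqs`.
#' @param cutoff distance cutoff (0.03 for 97\%, 0.01 for 99\%).
#' @return a [MotuTable-class].
#' @export
clusterMotus <- function(d, uniqueSet, cutoff) {
  n <- length(uniqueSet$ids)
  stopifnot(nrow(d) == n, ncol(d) == n)
  parts <- average_neighbor(d, cutoff)
  cnt <- matrix(0L, length(parts), ncol(uniqueSet$counts),
                dimnames = list(NULL, colnames(uniqueSet$counts)))
  repIds <- character(length(parts))
  repSeqs <- character(length(parts))
  members <- vector("list", length(parts))
  for (p in seq_along(parts)) {
    idx <- parts[[p]]
    cnt[p, ] <- colSums(uniqueSet$counts[idx, , drop = FALSE])
    totals <- rowSums(uniqueSet$counts[idx, , drop = FALSE])
    r <- representativeSequence(uniqueSet$seqs[idx], totals)
    repIds[p] <- uniqueSet$ids[idx][r]
    repSeqs[p] <- unname(uniqueSet$seqs[idx][r])
    members[[p]] <- stats::setNames(as.integer(totals),
                                    uniqueSet$ids[idx])
  }
  ord <- order(-rowSums(cnt), repSeqs)
  rownames(cnt) <- sprintf("motu_%03d", order(ord))
  MotuTable(cnt, repIds = repIds, repSeqs = repSeqs, members = members,
            similarityThreshold = 1 - cutoff)
}
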