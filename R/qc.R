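## Read quality control: Trimmomatic-style trimming, quality-aware
## ungapped pair merging, primer finding/stripping, the five
## merged-read filter criteria, and the pyrosequencing average-quality
## filter. Every rejected read carries exactly one reason, and reason
## counts sum to input minus output.

#' Trimming parameters
#'
#' Defaults follow the settings used for 2 x 300 bp paired-end data:
#' CROP:300 MINLEN:100 LEADING:20 TRAILING:20 SLIDINGWINDOW:30:30.
#'
#' @param crop keep at most this many leading bases.
#' @param minLen reject reads shorter than this after trimming.
#' @param leadingQ remove leading bases with quality below this.
#' @param trailingQ remove trailing bases with quality below this.
#' @param windowSize,windowQ sliding-window size and mean-quality
#'   threshold; the read is truncated at the start of the first
#'   window whose mean quality falls below `windowQ`.
#' @return a `TrimParams` list.
#' @export
trimParams <- function(crop = 300L, minLen = 100L, leadingQ = 20L,
                       trailingQ = 20L, windowSize = 30L, windowQ = 30) {
  stopifnot(crop >= 1, minLen >= 0, leadingQ >= 0, trailingQ >= 0,
            windowSize >= 1, windowQ >= 0)
  structure(list(crop = as.integer(crop), minLen = as.integer(minLen),
                 leadingQ = leadingQ, trailingQ = trailingQ,
                 windowSize = as.integer(windowSize), windowQ = windowQ),
            class = "TrimParams")
}

#' Trim a single read
#'
#' Operations are applied in fixed order: crop, leading-quality trim,
#' trailing-quality trim, sliding-window truncation, minimum-length
#' check. Rejection is a reported outcome, not an error.
#'
#' @param seq character sequence.
#' @param qual integer Phred qualities, same length as `seq`.
#' @param params a [trimParams()] list.
#' @return list with `pass`; when passing, trimmed `seq` and `qual`;
#'   when failing, `reason = "trim_min_length"`.
#' @export
trimRead <- function(seq, qual, params = trimParams()) {
  stopifnot(nchar(seq) == length(qual))
  n <- min(nchar(seq), params$crop)
  q <- qual[seq_len(n)]
  from <- 1L; to <- n
  while (from <= to && q[from] < params$leadingQ) from <- from + 1L
  while (to >= from && q[to] < params$trailingQ) to <- to - 1L
  if (from <= to) {
    q2 <- q[from:to]
    len <- length(q2)
    if (len >= params$windowSize) {
      means <- stats::filter(q2, rep(1 / params$windowSize,
                                     params$windowSize),
                             sides = 1)
      ## means[i] is the mean of the window ending at i
      wmeans <- means[params$windowSize:len]
      bad <- which(wmeans < params$windowQ)
      if (length(bad)) to <- from + bad[1L] - 2L  # cut at window start
    }
  }
  if (to - from + 1L < params$minLen || to < from)
    return(list(pass = FALSE, reason = "trim_min_length"))
  list(pass = TRUE,
       seq = substr(seq, from, to),
       qual = qual[from:to])
}

#' Merge a trimmed read pair by best ungapped overlap
#'
#' The reverse mate is reverse-complemented, then every ungapped
#' overlap of at least `minOverlap` bases is scored; the overlap with
#' the fewest mismatches (ties broken toward the longest overlap) is
#' accepted if its mismatch fraction is at most `maxMismatchFrac`.
#' Disagreeing overlap positions take the higher-quality base (ties
#' keep the forward base); agreeing positions take the maximum quality.
#'
#' @param fwdSeq,fwdQual forward mate sequence and integer qualities.
#' @param revSeq,revQual reverse mate (as sequenced; complemented here).
#' @param minOverlap minimum acceptable overlap (default 20).
#' @param maxMismatchFrac maximum mismatch fraction in the overlap.
#' @return list with `pass`; when passing, merged `seq` and `qual` and
#'   the `overlap` used; when failing, `reason = "no_overlap"`.
#' @export
mergePairs <- function(fwdSeq, fwdQual, revSeq, revQual,
                       minOverlap = 20L, maxMismatchFrac = 0.1) {
  fc <- str_chars(fwdSeq)
  rc <- rev(chartr_complement(str_chars(revSeq)))
  rq <- rev(revQual)
  n1 <- length(fc); n2 <- length(rc)
  maxO <- min(n1, n2)
  if (maxO < minOverlap) return(list(pass = FALSE, reason = "no_overlap"))
  best <- NULL
  for (o in minOverlap:maxO) {
    mism <- sum(fc[(n1 - o + 1L):n1] != rc[seq_len(o)])
    if (mism / o <= maxMismatchFrac &&
        (is.null(best) || mism < best$mism ||
         (mism == best$mism && o > best$o)))
      best <- list(o = o, mism = mism)
  }
  if (is.null(best)) return(list(pass = FALSE, reason = "no_overlap"))
  o <- best$o
  fIdx <- (n1 - o + 1L):n1
  rIdx <- seq_len(o)
  fq <- fwdQual[fIdx]; rq2 <- rq[rIdx]
  fb <- fc[fIdx]; rb <- rc[rIdx]
  agree <- fb == rb
  consBase <- ifelse(agree | fq >= rq2, fb, rb)
  consQual <- ifelse(agree, pmax(fq, rq2), ifelse(fq >= rq2, fq, rq2))
  seq <- paste0(c(fc[seq_len(n1 - o)], consBase,
                  rc[(o + 1L):n2][seq_len(max(0L, n2 - o))]),
                collapse = "")
  qual <- c(fwdQual[seq_len(n1 - o)], consQual,
            rq[(o + 1L):n2][seq_len(max(0L, n2 - o))])
  list(pass = TRUE, seq = seq, qual = qual, overlap = o,
       mismatches = best$mism)
}

#' Locate and strip the primer pair from a merged read
#'
#' The forward primer is matched at the 5' end and the
#' reverse-complemented reverse primer at the 3' end, each within a
#' Hamming distance of `maxMismatch`; orientation is auto-detected by
#' trying both strands. Both primer copies are removed.
#'
#' @param seq merged read sequence.
#' @param fwdPrimer,revPrimer primer pair (reverse primer given 5'->3'
#'   on the opposite strand, as published).
#' @param maxMismatch maximum mismatches allowed per primer (default 3).
#' @return list with `pass`; when passing, the `interior` sequence, the
#'   `orientation` (`"forward"`/`"reverse"`), and the interior
#'   coordinates `from`/`to` on the oriented read; when failing,
#'   `reason = "primer_missing"`.
#' @export
findAndStripPrimers <- function(seq, fwdPrimer = FWD_PRIMER,
                                revPrimer = REV_PRIMER,
                                maxMismatch = 3L) {
  fp <- toupper(fwdPrimer)
  rp3 <- revcomp_chr(toupper(revPrimer))
  nf <- nchar(fp); nr <- nchar(rp3)
  try_one <- function(s) {
    if (nchar(s) < nf + nr + 1L) return(NULL)
    if (hamming_chr(substr(s, 1L, nf), fp) > maxMismatch) return(NULL)
    n <- nchar(s)
    if (hamming_chr(substr(s, n - nr + 1L, n), rp3) > maxMismatch)
      return(NULL)
    list(interior = substr(s, nf + 1L, n - nr), from = nf + 1L,
         to = n - nr)
  }
  hit <- try_one(seq)
  if (!is.null(hit))
    return(c(list(pass = TRUE, orientation = "forward"), hit))
  hit <- try_one(revcomp_chr(seq))
  if (!is.null(hit))
    return(c(list(pass = TRUE, orientation = "reverse"), hit))
  list(pass = FALSE, reason = "primer_missing")
}

#' Filter criteria for primer-stripped merged reads
#'
#' @param maxAmbiguous maximum ambiguous bases (N); default 0.
#' @param minLen,maxLen interior length window excluding primers
#'   (default 300-420 bp).
#' @param maxHomopolymer maximum single-base run length (default 5).
#' @return a `FilterCriteria` list.
#' @export
filterCriteria <- function(maxAmbiguous = 0L, minLen = 300L,
                           maxLen = 420L, maxHomopolymer = 5L) {
  stopifnot(minLen > 0, minLen <= maxLen)
  structure(list(maxAmbiguous = maxAmbiguous, minLen = minLen,
                 maxLen = maxLen, maxHomopolymer = maxHomopolymer),
            class = "FilterCriteria")
}

#' Apply the merged-read filter criteria
#'
#' Checked in fixed order: (i) ambiguous bases, (ii) interior length,
#' (iii) maximum homopolymer run; the first violated criterion is
#' reported.
#'
#' @param seq primer-stripped interior sequence.
#' @param criteria a [filterCriteria()] list.
#' @return list(`pass`, `reason`): reason is one of `"ambiguous"`,
#'   `"length"`, `"homopolymer"`, or `NA` when passing.
#' @export
filterMerged <- function(seq, criteria = filterCriteria()) {
  nN <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  if (nN > criteria$maxAmbiguous)
    return(list(pass = FALSE, reason = "ambiguous"))
  n <- nchar(seq)
  if (n < criteria$minLen || n > criteria$maxLen)
    return(list(pass = FALSE, reason = "length"))
  if (max_homopolymer(seq) > criteria$maxHomopolymer)
    return(list(pass = FALSE, reason = "homopolymer"))
  list(pass = TRUE, reason = NA_character_)
}

#' Average-quality filter (pyrosequencing mode)
#'
#' Passes iff the mean Phred quality is strictly greater than
#' `minMean` (default 27).
#'
#' @param qual integer Phred qualities.
#' @param minMean strict lower bound on the mean quality.
#' @return logical.
#' @export
averageQualityFilter <- function(qual, minMean = 27) {
  mean(qual) > minMean
}

qc_report <- function(input, reasons, stages) {
  reasons <- reasons[!is.na(reasons)]
  tab <- sort(table(reasons), decreasing = TRUE)
  structure(list(input = input, output = input - length(reasons),
                 reasons = stats::setNames(as.integer(tab), names(tab)),
                 stages = stages),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QC report: %d reads in, %d out (%.1f%%)\n", x$input,
              x$output, if (x$input) 100 * x$output / x$input else 0))
  if (length(x$reasons)) {
    cat("rejections:\n")
    for (r in names(x$reasons))
      cat(sprintf("  %-16s %d\n", r, x$reasons[[r]]))
  }
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Paired-end quality control to primer-stripped interiors
#'
#' Runs the full MiSeq-style QC chain: per-mate trimming, pair
#' merging, primer location/stripping (both orientations), then the
#' three merged-read criteria. Each rejected pair carries exactly one
#' reason (the first failing stage).
#'
#' @param r1,r2 `QualityScaledDNAStringSet` mates (same length/order).
#' @param params pipeline parameter list ([defaultPipelineParams()]).
#' @param verbose log per-stage survivor counts to stderr.
#' @return list: `interiors` (named character vector of interior
#'   sequences), `sample` labels per surviving read, `report` (a
#'   `QcReport`).
#' @export
qcPaired <- function(r1, r2, params = defaultPipelineParams(),
                     verbose = FALSE) {
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  tp <- trimParams(params$crop, params$min_len, params$leading_q,
                   params$trailing_q, params$window_size, params$window_q)
  fc <- filterCriteria(0L, params$min_interior, params$max_interior,
                       params$max_homopolymer)
  s1 <- as.character(r1); s2 <- as.character(r2)
  q1 <- quality_ints(r1); q2 <- quality_ints(r2)
  samples <- S4Vectors::mcols(r1)$sample %||% rep("sample1", n)
  ids <- names(r1) %||% sprintf("read_%06d", seq_len(n))

  reasons <- rep(NA_character_, n)
  interiors <- rep(NA_character_, n)
  nTrim <- 0L; nMerge <- 0L; nPrimer <- 0L; nFilter <- 0L
  for (i in seq_len(n)) {
    t1 <- trimRead(s1[i], q1[[i]], tp)
    t2 <- trimRead(s2[i], q2[[i]], tp)
    if (!t1$pass || !t2$pass) { reasons[i] <- "trim_min_length"; next }
    nTrim <- nTrim + 1L
    m <- mergePairs(t1$seq, t1$qual, t2$seq, t2$qual,
                    params$min_overlap, params$max_overlap_mismatch)
    if (!m$pass) { reasons[i] <- m$reason; next }
    nMerge <- nMerge + 1L
    p <- findAndStripPrimers(m$seq, params$fwd_primer, params$rev_primer,
                             params$max_primer_mismatch)
    if (!p$pass) { reasons[i] <- p$reason; next }
    nPrimer <- nPrimer + 1L
    f <- filterMerged(p$interior, fc)
    if (!f$pass) { reasons[i] <- f$reason; next }
    nFilter <- nFilter + 1L
    interiors[i] <- p$interior
  }
  stages <- data.frame(
    stage = c("input", "trimmed", "merged", "primer_stripped",
              "filtered"),
    surviving = c(n, nTrim, nMerge, nPrimer, nFilter))
  keep <- !is.na(interiors)
  stage_log(verbose, "qcPaired: %d -> %d reads", n, sum(keep))
  list(interiors = stats::setNames(interiors[keep], ids[keep]),
       sample = samples[keep],
       report = qc_report(n, reasons, stages))
}

#' Single-end (pyrosequencing-mode) quality control
#'
#' Applies the strict average-quality filter (> `min_mean_quality`,
#' default 27), then primer stripping and the merged-read criteria.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @inheritParams qcPaired
#' @return as [qcPaired()].
#' @export
qcPyro <- function(reads, params = defaultPipelineParams(),
                   verbose = FALSE) {
  n <- length(reads)
  fc <- filterCriteria(0L, params$min_interior, params$max_interior,
                       params$max_homopolymer)
  s <- as.character(reads)
  q <- quality_ints(reads)
  samples <- S4Vectors::mcols(reads)$sample %||% rep("sample1", n)
  ids <- names(reads) %||% sprintf("read_%06d", seq_len(n))

  reasons <- rep(NA_character_, n)
  interiors <- rep(NA_character_, n)
  nQual <- 0L; nPrimer <- 0L; nFilter <- 0L
  for (i in seq_len(n)) {
    if (!averageQualityFilter(q[[i]], params$min_mean_quality)) {
      reasons[i] <- "low_mean_quality"; next
    }
    nQual <- nQual + 1L
    p <- findAndStripPrimers(s[i], params$fwd_primer, params$rev_primer,
                             params$max_primer_mismatch)
    if (!p$pass) { reasons[i] <- p$reason; next }
    nPrimer <- nPrimer + 1L
    f <- filterMerged(p$interior, fc)
    if (!f$pass) { reasons[i] <- f$reason; next }
    nFilter <- nFilter + 1L
    interiors[i] <- p$interior
  }
  stages <- data.frame(
    stage = c("input", "mean_quality", "primer_stripped", "filtered"),
    surviving = c(n, nQual, nPrimer, nFilter))
  keep <- !is.na(interiors)
  stage_log(verbose, "qcPyro: %d -> %d reads", n, sum(keep))
  list(interiors = stats::setNames(interiors[keep], ids[keep]),
       sample = samples[keep],
       report = qc_report(n, reasons, stages))
}
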