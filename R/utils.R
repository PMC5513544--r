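## Internal helpers shared across modules.

#' @importFrom methods as is new validObject slot
#' @importFrom stats rlnorm rnorm runif rbinom cor.test setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic operations in the package funnel their randomness
#' through this helper so that a single integer seed makes a whole
#' analysis reproducible without touching the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Derive a stream-specific child seed from a master seed, keeping the
## result inside 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 +
                as.numeric(stream) * 104729) %% 2147483111)
}

## Reverse complement of plain character strings (A/C/G/T/N/-).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste0(chartr("ACGTacgt", "TGCAtgca", paste0(ch, collapse = "")),
           collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Split a string into a character vector of single bases.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Run-length view of a sequence: data.frame(base, length, start).
homopolymer_runs <- function(seq) {
  ch <- str_chars(seq)
  r <- rle(ch)
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(base = r$values, length = r$lengths, start = start,
             stringsAsFactors = FALSE)
}

## Longest single-base run in a sequence.
max_homopolymer <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  max(rle(str_chars(seq))$lengths)
}

## Hamming distance between two equal-length strings.
hamming_chr <- function(a, b) {
  ca <- str_chars(a); cb <- str_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

## Encode gapped rows (character vector, equal nchar) as a matrix of
## single characters; rows are sequences.
rows_to_matrix <- function(rows) {
  stopifnot(length(unique(nchar(rows))) <= 1L)
  if (length(rows) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

## Collapse a character matrix back to strings.
matrix_to_rows <- function(m) apply(m, 1L, paste0, collapse = "")

## Remove gap characters from gapped rows.
degap <- function(x) gsub("-", "", x, fixed = TRUE)

stage_log <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
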