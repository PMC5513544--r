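## Reading and writing of the formats every other stage consumes:
## FASTA, FASTQ (Phred+33), the mothur-style taxonomy table, the TSV
## MOTU table, and YAML pipeline configuration. Parsing is delegated to
## Biostrings; the wrappers add the format checks and normalisation the
## pipeline relies on (uppercase, U->T, unique non-empty ids).

## readLines with transparent gzip support.
read_lines_any <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

first_content_line <- function(path) {
  lines <- read_lines_any(path)
  idx <- which(nzchar(trimws(lines)))
  if (length(idx) == 0L) return(NULL)
  list(line = lines[idx[1L]], number = idx[1L])
}

#' Read a FASTA file of sequence records
#'
#' Sequences are uppercased and U is mapped to T so that all downstream
#' comparison is over the alphabet {A,C,G,T,N} (gaps `-` are preserved,
#' allowing gapped reference alignments to be read with the same
#' function).
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`; names are record ids (text up to the
#'   first whitespace), with any remaining header text kept in the
#'   element metadata column `description`.
#' @export
readAmpliconFasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fc <- first_content_line(path)
  if (is.null(fc))
    stop(sprintf("format error in %s: empty FASTA file", path))
  if (!startsWith(trimws(fc$line), ">"))
    stop(sprintf("format error in %s, line %d: expected '>' header, got %s",
                 path, fc$number, sQuote(substr(fc$line, 1, 30))))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("format error in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids)))
    stop(sprintf("format error in %s: empty record id (record %d)",
                 path, which(!nzchar(ids))[1L]))
  if (anyDuplicated(ids))
    stop(sprintf("format error in %s: duplicate id %s", path,
                 sQuote(ids[duplicated(ids)][1L])))
  seqs <- chartr("u", "t", as.character(raw))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L))
    stop(sprintf("format error in %s: zero-length sequence for id %s",
                 path, sQuote(ids[nchar(seqs) == 0L][1L])))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop(sprintf("format error in %s: non-ACGTN character in record %s",
                 path, sQuote(ids[bad][1L])))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- ifelse(desc == headers, "", desc)
  out
}

#' Write sequence records to FASTA
#'
#' @param x a named `DNAStringSet` (or character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAmpliconFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read single-end FASTQ reads (Phred+33)
#'
#' @param path path to an (optionally gzipped) FASTQ file.
#' @param sample sample label attached to every read.
#' @return a `QualityScaledDNAStringSet`; per-read sample labels are in
#'   `mcols(x)$sample`. An empty file yields an empty set.
#' @export
readAmpliconFastq <- function(path, sample) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(first_content_line(path))) {
    out <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0)))
    return(out)
  }
  ## validate the 4-line record structure before handing to the
  ## parser: it decodes qualities by position and would silently accept
  ## a quality line of the wrong length
  lines <- read_lines_any(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("format error in %s: truncated FASTQ record", path))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(startsWith(heads, "@")))
    stop(sprintf("format error in %s: record header lacking '@'", path))
  nseq <- nchar(lines[seq(2L, length(lines), by = 4L)])
  nqual <- nchar(lines[seq(4L, length(lines), by = 4L)])
  if (any(nseq != nqual)) {
    i <- which(nseq != nqual)[1L]
    stop(sprintf(
      "format error in %s: sequence/quality length mismatch for read %s (%d vs %d)",
      path, sQuote(sub("^@", "", sub("\\s.*$", "", heads[i]))),
      nseq[i], nqual[i]))
  }
  x <- tryCatch(
    ## the reader warns about dropping its own temporary metadata
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e)
      stop(sprintf("format error in %s: %s", path, conditionMessage(e)),
           call. = FALSE))
  S4Vectors::mcols(x)$sample <- rep(sample, length(x))
  x
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param x a `QualityScaledDNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAmpliconFastq <- function(x, path) {
  Biostrings::writeXStringSet(as(x, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(x))
  invisible(path)
}

## Decode per-read Phred qualities to a list of integer vectors.
quality_ints <- function(x) {
  as(as(Biostrings::quality(x), "PhredQuality"), "IntegerList")
}

#' Read a mothur-style taxonomy table
#'
#' Expects two tab-separated columns: reference id and a
#' semicolon-delimited lineage (a trailing separator is tolerated).
#' All lineages in a database must have the same depth.
#'
#' @param path path to the taxonomy file.
#' @return a `TaxonomyMap`: data.frame with rownames = reference ids,
#'   one column per rank (`rank1`..`rankD`), plus attribute `depth`.
#' @export
readTaxonomyMap <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("format error in %s: empty taxonomy file", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("format error in %s, line %d: expected id<TAB>lineage",
                 path, bad[1L]))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id in %s: %s", path,
                 paste(sQuote(unique(ids[duplicated(ids)])),
                       collapse = ", ")))
  lin <- vapply(parts, `[[`, character(1), 2L)
  lin <- sub(";\\s*$", "", lin)
  ranks <- strsplit(lin, ";", fixed = TRUE)
  ranks <- lapply(ranks, trimws)
  depth <- unique(lengths(ranks))
  if (length(depth) != 1L)
    stop(sprintf(
      "lineage depth inconsistency in %s: depths %s observed",
      path, paste(sort(depth), collapse = " and ")))
  taxonomyMap(ids, ranks)
}

#' Construct a TaxonomyMap from ids and lineages
#'
#' @param ids character vector of reference ids.
#' @param lineages list of character vectors (one lineage per id,
#'   constant depth) or a character matrix.
#' @return a `TaxonomyMap` data.frame (see [readTaxonomyMap()]).
#' @export
taxonomyMap <- function(ids, lineages) {
  if (is.matrix(lineages)) {
    m <- lineages
  } else {
    depth <- unique(lengths(lineages))
    stopifnot(length(depth) == 1L)
    m <- do.call(rbind, lineages)
  }
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  colnames(df) <- paste0("rank", seq_len(ncol(df)))
  rownames(df) <- ids
  attr(df, "depth") <- ncol(df)
  class(df) <- c("TaxonomyMap", "data.frame")
  df
}

#' Write a taxonomy table in mothur style
#' @param tax a `TaxonomyMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyMap <- function(tax, path) {
  lin <- apply(as.matrix(tax), 1L, paste0, collapse = ";")
  writeLines(paste0(rownames(tax), "\t", lin, ";"), path)
  invisible(path)
}

#' Write a MotuTable as TSV
#'
#' Serialisation is deterministic: rows sorted by decreasing total
#' count with ties broken lexicographically by MOTU id (the canonical
#' `MotuTable` order), so identical inputs give byte-identical files.
#'
#' @param table a [MotuTable-class] with at least one MOTU and sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotuTable <- function(table, path) {
  stopifnot(is(table, "MotuTable"))
  cnt <- motuCounts(table)
  if (nrow(cnt) < 1L || ncol(cnt) < 1L)
    stop("MOTU table must have at least one MOTU and one sample")
  rd <- SummarizedExperiment::rowData(table)
  lineage <- if ("lineage" %in% colnames(rd)) rd$lineage else
    rep(NA_character_, nrow(cnt))
  df <- data.frame(
    motu_id = rownames(cnt),
    rep_id = rd$rep_id,
    rep_seq = rd$rep_seq,
    lineage = lineage,
    total = rd$total,
    cnt,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    stop("cannot write MOTU table to ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a MotuTable written by [writeMotuTable()]
#'
#' @param path path to a MOTU table TSV.
#' @param similarityThreshold similarity recorded in the returned
#'   object (the TSV does not store it).
#' @return a [MotuTable-class].
#' @export
readMotuTable <- function(path, similarityThreshold = 0.97) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("motu_id", "rep_id", "rep_seq", "lineage", "total")
  if (!all(meta %in% colnames(df)))
    stop(sprintf("format error in %s: missing MOTU table columns", path))
  samples <- setdiff(colnames(df), meta)
  cnt <- as.matrix(df[, samples, drop = FALSE])
  rownames(cnt) <- df$motu_id
  MotuTable(cnt, repIds = df$rep_id, repSeqs = df$rep_seq,
            similarityThreshold = similarityThreshold,
            lineages = if (all(is.na(df$lineage))) NULL else df$lineage)
}

#' Read pipeline configuration from YAML
#'
#' Overrides for trimming parameters, filter criteria, preclustering
#' width, chimera thresholds etc. Unknown keys are rejected to catch
#' typos. See [defaultPipelineParams()] for the full set.
#'
#' @param path path to a YAML file.
#' @return a parameter list merged over [defaultPipelineParams()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultPipelineParams()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' Default pipeline parameters
#'
#' @return a named list of tunable parameters with their defaults:
#'   trimming settings (crop 300, min length 100, leading/trailing
#'   quality 20, 30-base sliding window at mean quality 30), merge
#'   overlap settings, the five merged-read filter criteria, the
#'   pyrosequencing average-quality cutoff (27), classifier settings
#'   (k = 8, 100 bootstraps, confidence > 0.70), precluster width
#'   (2 mismatches), chimera score thresholds, and clustering cutoffs
#'   (0.03 and 0.01).
#' @export
defaultPipelineParams <- function() {
  list(
    crop = 300L, min_len = 100L, leading_q = 20L, trailing_q = 20L,
    window_size = 30L, window_q = 30,
    min_overlap = 20L, max_overlap_mismatch = 0.1,
    fwd_primer = "AGACCGATAGCAAACAAGTAC",
    rev_primer = "GTCCGTGTTTCAAGACGG",
    max_primer_mismatch = 3L,
    min_interior = 300L, max_interior = 420L, max_homopolymer = 5L,
    min_mean_quality = 27,
    classifier_k = 8L, n_bootstrap = 100L, confidence_threshold = 0.70,
    precluster_max_diffs = 2L,
    chimera_min_gain = 0.02, chimera_min_parent_identity = 0.80,
    chimera_min_model_identity = 0.97, chimera_abundance_skew = 2,
    cutoffs = c(0.03, 0.01)
  )
}
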