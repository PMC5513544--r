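## End-to-end pipeline: QC -> dedupe -> taxonomic screen -> reference
## anchoring -> precluster -> singleton removal -> chimera removal ->
## contaminant re-screen -> rarefaction -> average-neighbor clustering
## at one or more cutoffs, with per-stage read accounting.

#' Run the full MOTU pipeline on simulated or real reads
#'
#' @param dataset a `SimulatedDataset` (from [simulateReads()]), or a
#'   list with elements `r1`/`r2` (paired) or `reads` (single), each a
#'   `QualityScaledDNAStringSet` with per-read `mcols()$sample`.
#' @param refs a `ReferenceSet`: taxonomy and interiors train the
#'   screen classifier, the reference alignment anchors the queries,
#'   and the reference rows drive reference-mode chimera flagging.
#' @param mode platform conventions: `"miseq"` removes singleton
#'   preclusters, `"pyro"` keeps them. The QC path follows the data
#'   shape: paired input (r1/r2) goes through trimming and merging,
#'   single-end input through the average-quality filter.
#' @param params pipeline parameters ([defaultPipelineParams()]).
#' @param targetPrefix lineage prefix of the target group
#'   (default `"Copepoda"`).
#' @param depth subsampling depth (default: minimum per-sample total
#'   after denoising).
#' @param seed integer seed (screen bootstrap and rarefaction).
#' @param verbose log per-stage read counts to stderr.
#' @return a `MotuPipelineResult` list: `motus` (named list of
#'   [MotuTable-class], one per cutoff, names like "97"/"99"),
#'   `qc` (the `QcReport`), `stages` (data.frame of surviving read
#'   counts per stage), `depth`, `uniques` (the final `UniqueSet`),
#'   `distances` (its distance matrix), `unalignable`, `chimeras`.
#' @export
runMotuPipeline <- function(dataset, refs, mode = c("miseq", "pyro"),
                            params = defaultPipelineParams(),
                            targetPrefix = "Copepoda", depth = NULL,
                            seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  qc <- if (!is.null(dataset$r1) && !is.null(dataset$r2)) {
    qcPaired(dataset$r1, dataset$r2, params, verbose)
  } else if (!is.null(dataset$reads)) {
    qcPyro(dataset$reads, params, verbose)
  } else {
    stop("dataset must carry r1/r2 (paired) or reads (single-end)")
  }
  nQc <- length(qc$interiors)
  if (nQc == 0L) stop("no reads survived quality control")

  uniq <- dedupeReads(qc$interiors, qc$sample)
  stage_log(verbose, "dedupe: %d reads -> %d unique sequences",
            nQc, length(uniq$ids))

  model <- trainClassifier(refs$interiors, refs$taxonomy,
                           params$classifier_k)
  scr <- screenTargetGroup(uniq$seqs, model, targetPrefix,
                           params$n_bootstrap,
                           params$confidence_threshold,
                           seed = child_seed(seed, 11L))
  uniq <- subset_unique(uniq, uniq$ids %in% names(scr$kept))
  nScreen <- sum(uniq$counts)
  stage_log(verbose, "target screen: %d reads kept", nScreen)

  aln <- alignToReference(uniq$seqs, refs$alignment)
  uniq <- subset_unique(uniq, uniq$ids %in% names(aln$rows))
  nAlign <- sum(uniq$counts)

  pre <- precluster(uniq, aln$rows, params$precluster_max_diffs)
  nPre <- sum(pre$counts)
  stage_log(verbose, "precluster: %d attractors (%d reads)",
            length(pre$ids), nPre)

  pre <- removeSingletons(pre, mode)
  nSingle <- sum(pre$counts)

  chim <- detectChimeras(pre, referenceRows = refs$alignment,
                         deNovo = TRUE,
                         minGain = params$chimera_min_gain,
                         minParentIdentity =
                           params$chimera_min_parent_identity,
                         minModelIdentity =
                           params$chimera_min_model_identity,
                         abundanceSkew = params$chimera_abundance_skew)
  pre <- subset_unique(pre, !chim)
  nChim <- sum(pre$counts)
  stage_log(verbose, "chimera removal: %d flagged, %d reads left",
            sum(chim), nChim)

  scr2 <- screenTargetGroup(pre$seqs, model, targetPrefix,
                            params$n_bootstrap,
                            params$confidence_threshold,
                            seed = child_seed(seed, 13L))
  pre <- subset_unique(pre, pre$ids %in% names(scr2$kept))
  nScreen2 <- sum(pre$counts)

  if (is.null(depth)) depth <- min(colSums(pre$counts))
  pre$counts <- subsampleCounts(pre$counts, depth,
                                seed = child_seed(seed, 17L))
  pre <- subset_unique(pre, rowSums(pre$counts) > 0L)
  nSub <- sum(pre$counts)
  stage_log(verbose, "subsample: depth %d (%d reads, %d uniques)",
            depth, nSub, length(pre$ids))

  d <- distanceMatrix(pre$rows)
  motus <- lapply(params$cutoffs, function(cutoff)
    clusterMotus(d, pre, cutoff))
  names(motus) <- sprintf("%.0f", 100 * (1 - params$cutoffs))

  stages <- data.frame(
    stage = c("input", "qc", "target_screen", "aligned", "precluster",
              "singleton_removal", "chimera_removal", "rescreen",
              "subsampled"),
    reads = c(qc$report$input, nQc, nScreen, nAlign, nPre, nSingle,
              nChim, nScreen2, nSub))
  structure(list(motus = motus, qc = qc$report, stages = stages,
                 depth = depth, uniques = pre, distances = d,
                 unalignable = aln$unalignable,
                 chimeras = names(chim)[chim]),
            class = "MotuPipelineResult")
}

#' @export
print.MotuPipelineResult <- function(x, ...) {
  cat("MOTU pipeline result\n")
  print(x$stages, row.names = FALSE)
  for (nm in names(x$motus))
    cat(sprintf("  %s%% similarity: %d MOTUs\n", nm,
                nrow(x$motus[[nm]])))
  invisible(x)
}
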