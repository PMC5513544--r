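## Field-sample comparisons: abundance-threshold filtering, rank-level
## aggregation of MOTUs, wet-to-dry biomass conversion, Pearson
## correlations between morphological and sequence-based profiles,
## strict species assignment of representatives, and dominant-taxon
## tables with log(x+1)-transformed proportions.

#' Apply the calibrated abundance threshold to a MOTU table
#'
#' Per sample, MOTUs with fewer reads than the threshold are zeroed in
#' that sample; MOTUs left with zero reads everywhere are dropped.
#' Never increases any count and is idempotent.
#'
#' @param motuTable a [MotuTable-class].
#' @param count threshold read count (>= 1).
#' @return the filtered [MotuTable-class].
#' @export
applyAbundanceThreshold <- function(motuTable, count) {
  stopifnot(count >= 1)
  cnt <- motuCounts(motuTable)
  cnt[cnt < count] <- 0L
  keep <- rowSums(cnt) > 0L
  cnt <- cnt[keep, , drop = FALSE]
  rd <- SummarizedExperiment::rowData(motuTable)[keep, , drop = FALSE]
  if (nrow(cnt) == 0L) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cnt),
      rowData = S4Vectors::DataFrame(rep_id = character(0),
                                     rep_seq = character(0),
                                     total = integer(0)))
    return(new("MotuTable", se,
               similarityThreshold = similarityThreshold(motuTable)))
  }
  MotuTable(cnt, repIds = rd$rep_id, repSeqs = rd$rep_seq,
            members = if ("members" %in% colnames(rd)) rd$members,
            similarityThreshold = similarityThreshold(motuTable),
            lineages = if ("lineage" %in% colnames(rd)) rd$lineage)
}

## Extract one taxon label per MOTU at a lineage rank from classifier
## assignments (list of Assignment or character vector); MOTUs without
## a confident assignment at that rank become "Unclassified".
rank_labels <- function(assignments, rank, motuIds) {
  if (is.character(assignments)) {
    lab <- assignments[motuIds]
    lab[is.na(lab)] <- "Unclassified"
    return(lab)
  }
  vapply(motuIds, function(id) {
    a <- assignments[[id]]
    if (is.null(a) || length(a$assigned) < rank) "Unclassified"
    else a$assigned[rank]
  }, character(1))
}

#' Aggregate a MOTU table by taxonomic rank
#'
#' MOTU richness and read proportions are grouped by the taxon each
#' MOTU is assigned to at the chosen rank; MOTUs without a confident
#' assignment at that rank are grouped as "Unclassified".
#'
#' @param motuTable a [MotuTable-class].
#' @param assignments assignments for the representatives, named by
#'   MOTU id: either the list returned by [classifySequences()] or a
#'   character vector of taxon labels.
#' @param rank lineage rank index (e.g. 2 = order, 3 = family for the
#'   default class/order/family/species lineages).
#' @return a `CommunityProfile` data.frame: `taxon`, `n_motus`, then
#'   one read-proportion column per sample (columns sum to 1).
#' @export
aggregateByRank <- function(motuTable, assignments, rank) {
  cnt <- motuCounts(motuTable)
  lab <- rank_labels(assignments, rank, rownames(cnt))
  taxa <- sort(unique(lab))
  agg <- rowsum(cnt, group = factor(lab, levels = taxa))
  prop <- sweep(agg, 2L, pmax(colSums(agg), 1), "/")
  out <- data.frame(taxon = taxa,
                    n_motus = as.integer(table(factor(lab,
                                                      levels = taxa))),
                    prop, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CommunityProfile", "data.frame")
  out
}

#' Convert wet weights to dry weights by taxon factors
#'
#' Rows with a dry weight keep it; rows without one take
#' `wet_weight * factor` for their taxon. Taxa lacking both a dry
#' weight and a conversion factor are an error (listed).
#'
#' @param morphology data.frame with columns `species` (or any taxon
#'   column named by `by`), `wet_weight`, `dry_weight` (NA where
#'   unknown).
#' @param factors named numeric vector of dry/wet ratios per taxon.
#' @param by name of the taxon column the factors key on (default
#'   `"order"`).
#' @return the morphology table with `dry_weight` completed.
#' @export
convertDryWeight <- function(morphology, factors, by = "order") {
  stopifnot(by %in% colnames(morphology),
            all(c("wet_weight", "dry_weight") %in% colnames(morphology)))
  missing <- is.na(morphology$dry_weight)
  taxa <- morphology[[by]][missing]
  noFactor <- !(taxa %in% names(factors))
  if (any(noFactor))
    stop("no dry-weight conversion factor for: ",
         paste(sort(unique(taxa[noFactor])), collapse = ", "))
  morphology$dry_weight[missing] <-
    morphology$wet_weight[missing] * factors[taxa]
  morphology
}

#' Pearson correlation between two community profiles
#'
#' Vectors may be named (taxon -> value); they are then outer-joined
#' over the union of taxa with zeros for absences, since the compared
#' methods detect different taxon sets.
#'
#' @param x,y numeric vectors (length >= 3 after joining).
#' @return list(`r`, `p`): Pearson's r and the two-sided p-value from
#'   the t transform.
#' @export
correlateProfiles <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    taxa <- union(names(x), names(y))
    x <- stats::setNames(x[taxa], taxa); x[is.na(x)] <- 0
    y <- stats::setNames(y[taxa], taxa); y[is.na(y)] <- 0
  }
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a profile")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Assign a representative sequence to a species
#'
#' Strict assignment: the best-identity reference species is reported
#' only when identity reaches `minIdentity` (default 0.99); otherwise
#' `NA` (not assignable to any known species). Ties above the
#' threshold go to the lexicographically first species and are
#' messaged.
#'
#' @param representative ungapped sequence (character).
#' @param referenceDb named `DNAStringSet`/character vector; names are
#'   species.
#' @param minIdentity identity threshold (default 0.99).
#' @return species name or `NA_character_`.
#' @export
assignSpecies <- function(representative, referenceDb,
                          minIdentity = 0.99) {
  refs <- as.character(referenceDb)
  if (length(refs) == 0L) stop("empty reference database")
  ident <- vapply(refs, function(r)
    alignment_identity(representative, r), numeric(1))
  best <- max(ident)
  if (best < minIdentity) return(NA_character_)
  hits <- sort(names(refs)[ident == best])
  if (length(hits) > 1L)
    message("species assignment tie at identity ",
            sprintf("%.4f", best), ": ",
            paste(hits, collapse = ", "), "; taking the first")
  hits[1L]
}

#' Dominant-taxon comparison table
#'
#' The union of the top-k taxa by biomass proportion and the top-k by
#' read proportion, with individual-count, biomass, and read
#' percentages log(x+1)-transformed (natural log of percentage + 1 by
#' default; the base is configurable).
#'
#' @param profiles data.frame with columns `taxon`, `individual_pct`,
#'   `biomass_pct`, `read_pct` (percentages on 0-100).
#' @param k how many dominant taxa per criterion (default 12).
#' @param logBase base of the log transform.
#' @return data.frame of the selected taxa with transformed columns
#'   `log_individual`, `log_biomass`, `log_reads`, ordered by
#'   decreasing biomass percentage.
#' @export
dominantTable <- function(profiles, k = 12L, logBase = exp(1)) {
  stopifnot(k >= 1,
            all(c("taxon", "individual_pct", "biomass_pct",
                  "read_pct") %in% colnames(profiles)))
  topBio <- profiles$taxon[order(-profiles$biomass_pct,
                                 profiles$taxon)][seq_len(
                                   min(k, nrow(profiles)))]
  topRead <- profiles$taxon[order(-profiles$read_pct,
                                  profiles$taxon)][seq_len(
                                    min(k, nrow(profiles)))]
  keep <- profiles$taxon %in% union(topBio, topRead)
  out <- profiles[keep, , drop = FALSE]
  tr <- function(x) log(x + 1, base = logBase)
  out$log_individual <- tr(out$individual_pct)
  out$log_biomass <- tr(out$biomass_pct)
  out$log_reads <- tr(out$read_pct)
  out[order(-out$biomass_pct, out$taxon), , drop = FALSE]
}
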