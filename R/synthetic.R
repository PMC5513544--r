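## Synthetic amplicon data: reference sets with controlled divergence
## structure, mock/field community designs, and error-bearing reads
## under substitution (MiSeq-like) or homopolymer-indel
## (pyrosequencing-like) regimes. Everything is driven by one integer
## seed; no global RNG state leaks.

FWD_PRIMER <- "AGACCGATAGCAAACAAGTAC"
REV_PRIMER <- "GTCCGTGTTTCAAGACGG"

#' Sequencing error profile
#'
#' @param mode `"substitution"` (short-read, per-base miscalls) or
#'   `"pyro"` (pyrosequencing-like, homopolymer-length miscalls on top
#'   of a substitution floor).
#' @param substitutionRate per-base substitution probability.
#' @param homopolymerRate per-run probability scale for +/-1
#'   homopolymer length changes; the probability applied to a run of
#'   length L is `min(1, homopolymerRate * L / 4)` (normalised to a
#'   4-mer run). Must be 0 in substitution mode.
#' @param chimeraFraction fraction of reads built as two-parent
#'   (bimeric) chimeras; must be < 1.
#' @param qualityMean Phred quality at the 5' end.
#' @param qualityDecay linear per-base quality decline toward 3'.
#' @param qualitySd per-base Gaussian jitter of quality scores.
#' @return an `ErrorProfile` list.
#' @export
errorProfile <- function(mode = c("substitution", "pyro"),
                         substitutionRate = 0.002,
                         homopolymerRate = if (mode == "pyro") 0.01 else 0,
                         chimeraFraction = 0,
                         qualityMean = if (mode == "pyro") 34 else 38,
                         qualityDecay = if (mode == "pyro") 0.01 else 0.025,
                         qualitySd = 1) {
  mode <- match.arg(mode)
  rates <- c(substitutionRate, homopolymerRate, chimeraFraction)
  if (any(!is.finite(rates)) || any(rates < 0) ||
      substitutionRate > 1 || homopolymerRate > 1)
    stop("parameter error: rates must lie in [0, 1]")
  if (chimeraFraction >= 1)
    stop("parameter error: chimera fraction must be < 1")
  if (mode == "substitution" && homopolymerRate != 0)
    stop("parameter error: substitution mode requires homopolymerRate 0")
  structure(list(mode = mode, substitutionRate = substitutionRate,
                 homopolymerRate = homopolymerRate,
                 chimeraFraction = chimeraFraction,
                 qualityMean = qualityMean, qualityDecay = qualityDecay,
                 qualitySd = qualitySd),
            class = "ErrorProfile")
}

#' @rdname errorProfile
#' @export
miseqProfile <- function(substitutionRate = 0.002, chimeraFraction = 0.01)
  errorProfile("substitution", substitutionRate = substitutionRate,
               chimeraFraction = chimeraFraction)

#' @rdname errorProfile
#' @export
pyroProfile <- function(substitutionRate = 0.003, homopolymerRate = 0.01,
                        chimeraFraction = 0.01)
  errorProfile("pyro", substitutionRate = substitutionRate,
               homopolymerRate = homopolymerRate,
               chimeraFraction = chimeraFraction)

## Pick a replacement base differing from the current one and, when
## possible, from both neighbours (so substitutions never lengthen a
## homopolymer run).
mutate_at <- function(chars, positions) {
  n <- length(chars)
  for (p in positions) {
    nb <- chars[c(max(1L, p - 1L), min(n, p + 1L))]
    cand <- setdiff(DNA_BASES4, c(chars[p], nb))
    if (length(cand) == 0L) cand <- setdiff(DNA_BASES4, chars[p])
    chars[p] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  chars
}

## Cap homopolymer runs in a gapped row at maxRun by rewriting the
## middle base of any longer run.
break_long_runs <- function(row, maxRun = 5L) {
  chars <- str_chars(row)
  idx <- which(chars != "-")
  seq <- chars[idx]
  repeat {
    r <- rle(seq)
    long <- which(r$lengths > maxRun & r$values %in% DNA_BASES4)
    if (length(long) == 0L) break
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    for (j in long) {
      mid <- starts[j] + r$lengths[j] %/% 2L
      seq <- mutate_at(seq, mid)
    }
  }
  chars[idx] <- seq
  paste0(chars, collapse = "")
}

## Indel-excluded divergence between two gapped rows (shared non-gap
## columns only); NA when no columns are shared.
row_divergence <- function(a, b) {
  ca <- str_chars(a); cb <- str_chars(b)
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(NA_real_)
  mean(ca[keep] != cb[keep])
}

#' Generate a reference set with controlled divergence structure
#'
#' Species sequences are derived from one random ancestor: each clade
#' founder receives random substitutions plus deletions that bring its
#' length to a uniform draw from `lengthRange` (the marker length is
#' variable), and founders are resampled until all inter-founder
#' indel-excluded divergences are at least `minSeparation`.
#' Near-identical species are then created as satellites of selected
#' founders: each satellite is mutated at exactly
#' `round(radius * L)` shared positions, disjoint across satellites of
#' the same founder, so realised divergences equal the requested radius
#' (founder-satellite) and twice the radius (satellite-satellite) to
#' within half a percentage point. Amplicons carry the 28S D2 primer
#' pair; interiors are primer-free. Because length variation uses
#' deletions from the maximal-length ancestor, the true multiple
#' alignment is simply the ancestor coordinate system and is returned.
#'
#' @param nSpecies number of species (>= 2).
#' @param lengthRange interior length range, within [300, 420].
#' @param nNearPairs number of near-identical species pairs to force
#'   below 3\% divergence (ignored when `nearGroups` is given).
#' @param nearDivergence pair divergence (satellite radius) for the
#'   `nNearPairs` pairs; must be < 0.03.
#' @param nearGroups optional list of `list(members = <indices>,
#'   radius = <divergence>)`; the first member of each group is the
#'   founder, the rest satellites.
#' @param founderDivergence range of per-founder divergence from the
#'   ancestor.
#' @param minSeparation minimum inter-founder divergence.
#' @param seed integer seed.
#' @param speciesNames optional species names (default Species_01...).
#' @param lineages optional list/matrix of lineages per species
#'   (constant depth); default is a synthetic 4-rank copepod-like
#'   taxonomy (class, order, family, species) in which satellites share
#'   their founder's family.
#' @return a `ReferenceSet` list: `amplicons` (primer-flanked
#'   `DNAStringSet`), `interiors`, `alignment` (gapped interiors, one
#'   column per ancestor position), `taxonomy` (a `TaxonomyMap`),
#'   `primers`.
#' @export
generateReferenceSet <- function(nSpecies, lengthRange = c(340, 420),
                                 nNearPairs = 0, nearDivergence = 0.015,
                                 nearGroups = NULL,
                                 founderDivergence = c(0.05, 0.09),
                                 minSeparation = 0.06, seed,
                                 speciesNames = NULL, lineages = NULL) {
  if (nSpecies < 2L) stop("parameter error: nSpecies must be >= 2")
  if (lengthRange[1L] < 300 || lengthRange[2L] > 420 ||
      lengthRange[1L] > lengthRange[2L])
    stop("parameter error: lengthRange must lie within [300, 420]")
  if (is.null(nearGroups) && nNearPairs > 0) {
    if (2L * nNearPairs > nSpecies)
      stop("parameter error: unsatisfiable divergence constraints ",
           "(too many near pairs for nSpecies)")
    nearGroups <- lapply(seq_len(nNearPairs), function(i)
      list(members = c(2L * i - 1L, 2L * i), radius = nearDivergence))
  }
  nearGroups <- nearGroups %||% list()
  for (g in nearGroups) {
    if (any(g$members > nSpecies) || length(g$members) < 2L)
      stop("parameter error: invalid near-group member indices")
    if (g$radius < 0 || 2 * g$radius >= minSeparation)
      stop("parameter error: unsatisfiable divergence constraints ",
           "(group radius too large for minSeparation)")
  }
  satellites <- unlist(lapply(nearGroups, function(g) g$members[-1L]))
  if (anyDuplicated(satellites))
    stop("parameter error: a species cannot be a satellite twice")
  founders <- setdiff(seq_len(nSpecies), satellites)

  with_seed(seed, {
    ancLen <- as.integer(lengthRange[2L])
    ancestor <- break_long_runs(paste0(
      sample(DNA_BASES4, ancLen, replace = TRUE), collapse = ""), 3L)
    ancChars <- str_chars(ancestor)

    rows <- character(nSpecies)
    ## founders: deletions to target length, then substitutions
    for (tries in 1:60) {
      for (f in founders) {
        len <- sample(lengthRange[1L]:lengthRange[2L], 1L)
        del <- sample(ancLen, ancLen - len)
        chars <- ancChars
        keep <- setdiff(seq_len(ancLen), del)
        d <- runif(1L, founderDivergence[1L], founderDivergence[2L])
        mut <- sample(keep, round(d * length(keep)))
        chars <- mutate_at(chars, mut)
        chars[del] <- "-"
        rows[f] <- break_long_runs(paste0(chars, collapse = ""))
      }
      if (length(founders) < 2L) break
      div <- outer(founders, founders, Vectorize(function(i, j)
        if (i == j) 1 else row_divergence(rows[i], rows[j])))
      if (min(div) >= minSeparation) break
      if (tries == 60L)
        stop("parameter error: unsatisfiable divergence constraints ",
             "(could not separate founders by ", minSeparation, ")")
    }

    ## satellites: exact-Hamming mutations at disjoint shared positions
    for (g in nearGroups) {
      f <- g$members[1L]
      fChars <- str_chars(rows[f])
      nonGap <- which(fChars != "-")
      pool <- sample(nonGap)  # disjoint draws across satellites
      m <- round(g$radius * length(nonGap))
      for (s in g$members[-1L]) {
        if (m > length(pool))
          stop("parameter error: unsatisfiable divergence constraints ",
               "(near-group radius too large)")
        pos <- pool[seq_len(m)]
        pool <- pool[-seq_len(m)]
        chars <- mutate_at(fChars, pos)
        rows[s] <- paste0(chars, collapse = "")
      }
    }

    if (is.null(speciesNames))
      speciesNames <- sprintf("Species_%02d", seq_len(nSpecies))
    if (is.null(lineages)) {
      family <- character(nSpecies)
      famOf <- sprintf("Family_%02d", match(seq_len(nSpecies), founders))
      family[founders] <- famOf[founders]
      for (g in nearGroups)
        family[g$members] <- family[g$members[1L]]
      ord <- rep("Calanoida", nSpecies)
      if (nSpecies >= 3L) {
        ord[nSpecies - 1L] <- "Cyclopoida"
        ord[nSpecies] <- "Poecilostomatoida"
      }
      lineages <- cbind("Copepoda", ord, family, speciesNames)
    }
    tax <- taxonomyMap(sprintf("ref_%02d", seq_len(nSpecies)), lineages)

    interiors <- degap(rows)
    names(rows) <- names(interiors) <- rownames(tax)
    amplicons <- paste0(FWD_PRIMER, interiors, revcomp_chr(REV_PRIMER))
    names(amplicons) <- rownames(tax)

    structure(list(
      amplicons = Biostrings::DNAStringSet(amplicons),
      interiors = Biostrings::DNAStringSet(interiors),
      alignment = Biostrings::DNAStringSet(rows),
      taxonomy = tax,
      species = stats::setNames(speciesNames, rownames(tax)),
      primers = list(fwd = FWD_PRIMER, rev = REV_PRIMER)
    ), class = "ReferenceSet")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indel-excluded pairwise divergences of a reference set
#'
#' @param refs a `ReferenceSet`.
#' @return symmetric matrix of divergences computed on the true
#'   alignment, shared non-gap columns only.
#' @export
referenceDivergences <- function(refs) {
  rows <- as.character(refs$alignment)
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- row_divergence(rows[i], rows[j])
  d
}

#' Synthetic stand-in for the 33-species mock community references
#'
#' A synthetic reference set of the 33 copepod species used in the
#' mock community (30 Calanoida, 1 Cyclopoida, 2 Poecilostomatoida),
#' with the published near-identity structure: a Calanidae quartet
#' (Calanus sinicus, Cosmocalanus darwini, Mesocalanus tenuicornis,
#' Nannocalanus minor) within 3\% of each other, an Undeuchaeta pair
#' below 1\%, and Pareucalanus and Pleuromamma pairs between 1 and
#' 3\%. Clustering these references at 97\% similarity is expected to
#' give 27 MOTUs and at 99\% similarity 32 MOTUs. The sequences are
#' synthetic (not Sanger data); only the divergence structure and the
#' species/family/order labels follow the published mock community.
#'
#' @param seed integer seed.
#' @return a `ReferenceSet` (see [generateReferenceSet()]).
#' @export
mockCommunityReferences <- function(seed = 181452) {
  sp <- c(
    "Aetideus acutus", "Euchirella curticauda", "Euchirella messinensis",
    "Gaetanus minor", "Undeuchaeta major", "Undeuchaeta plumosa",
    "Haloptilus sp.", "Calanus sinicus", "Cosmocalanus darwini",
    "Mesocalanus tenuicornis", "Nannocalanus minor",
    "Neocalanus gracilis", "Candacia curta", "Centropages sp.",
    "Eucalanus californicus", "Pareucalanus sp.",
    "Pareucalanus attenuatus", "Subeucalanus subtenuis",
    "Paraeuchaeta media", "Lucicutia flavicornis", "Mecynocera clause",
    "Metridia brevicauda", "Metridia venusta",
    "Pleuromamma abdominalis", "Pleuromamma gracilis",
    "Calocalanus sp.", "Paracalanus sp.", "Pontellina plumata",
    "Scolecithrix danae", "Temora discaudata", "Oithona sp.",
    "Corycaeus sp.", "Oncaea sp.")
  fam <- c(rep("Aetideidae", 6), "Augaptilidae", rep("Calanidae", 5),
           "Candaciidae", "Centropagidae", rep("Eucalanidae", 4),
           "Euchaetidae", "Lucicutiidae", "Mecynoceridae",
           rep("Metridinidae", 4), rep("Paracalanidae", 2),
           "Pontellidae", "Scolecitrichidae", "Temoridae",
           "Oithonidae", "Corycaeidae", "Oncaeidae")
  ord <- c(rep("Calanoida", 30), "Cyclopoida",
           rep("Poecilostomatoida", 2))
  lineages <- cbind("Copepoda", ord, fam, sp)
  groups <- list(
    list(members = c(8L, 9L, 10L, 11L), radius = 0.012),  # Calanidae
    list(members = c(5L, 6L), radius = 0.005),   # Undeuchaeta
    list(members = c(16L, 17L), radius = 0.020), # Pareucalanus
    list(members = c(24L, 25L), radius = 0.020)) # Pleuromamma
  generateReferenceSet(33L, nearGroups = groups, seed = seed,
                       speciesNames = sp, lineages = lineages)
}

#' Mock community design with biomass-proportional read fractions
#'
#' @param refs a `ReferenceSet`.
#' @param biomass optional positive biomasses per species; by default
#'   drawn log-normal (`meanlog`, `sdlog`).
#' @param meanlog,sdlog log-normal biomass parameters.
#' @param exponent read fraction is proportional to biomass^exponent
#'   (1 = strictly proportional).
#' @param contaminant logical vector flagging non-target species.
#' @param seed integer seed (used only when `biomass` is NULL).
#' @return a `MockDesign` data.frame: species, ref_id, lineage,
#'   biomass, read_fraction, contaminant. Read fractions sum to 1.
#' @export
mockDesign <- function(refs, biomass = NULL, meanlog = 0, sdlog = 1,
                       exponent = 1, contaminant = NULL, seed = 1) {
  n <- length(refs$interiors)
  if (is.null(biomass))
    biomass <- with_seed(seed, rlnorm(n, meanlog, sdlog))
  if (length(biomass) != n || any(biomass <= 0))
    stop("parameter error: biomasses must be positive, one per species")
  frac <- biomass^exponent
  frac <- frac / sum(frac)
  lin <- apply(as.matrix(refs$taxonomy), 1L, paste0, collapse = ";")
  out <- data.frame(
    species = unname(refs$species), ref_id = rownames(refs$taxonomy),
    lineage = unname(lin), biomass = biomass, read_fraction = frac,
    contaminant = contaminant %||% rep(FALSE, n),
    stringsAsFactors = FALSE)
  class(out) <- c("MockDesign", "data.frame")
  out
}

#' Field community design with rare species and contaminants
#'
#' Emulates a field sample: many species with log-normal relative
#' biomasses (hence many rare species) and a stated fraction of
#' flagged contaminant species carrying a non-target lineage.
#'
#' @param nSpecies number of species (>= 1).
#' @param meanlog,sdlog log-normal biomass parameters (`sdlog = 0`
#'   gives equal biomasses).
#' @param contaminantFraction fraction of species flagged as
#'   non-target contaminants.
#' @param seed integer seed.
#' @param refs optional `ReferenceSet`; generated when NULL.
#' @param exponent read-fraction exponent (see [mockDesign()]).
#' @return a `MockDesign` with the reference set in
#'   `attr(, "references")`; contaminant species carry a
#'   Malacostraca lineage.
#' @export
makeFieldDesign <- function(nSpecies, meanlog = 0, sdlog = 1,
                            contaminantFraction = 0, seed,
                            refs = NULL, exponent = 1) {
  if (nSpecies < 1L) stop("parameter error: nSpecies must be >= 1")
  if (contaminantFraction < 0 || contaminantFraction >= 1)
    stop("parameter error: contaminantFraction must be in [0, 1)")
  if (is.null(refs))
    refs <- generateReferenceSet(max(2L, nSpecies),
                                 seed = child_seed(seed, 1L))
  nCont <- round(contaminantFraction * nSpecies)
  contaminant <- rep(FALSE, nSpecies)
  if (nCont > 0) {
    idx <- with_seed(child_seed(seed, 2L),
                     sample(nSpecies, nCont))
    contaminant[idx] <- TRUE
    tax <- refs$taxonomy
    tax[idx, 1L] <- "Malacostraca"
    tax[idx, 2L] <- "Euphausiacea"
    tax[idx, 3L] <- "Euphausiidae"
    refs$taxonomy <- tax
  }
  design <- mockDesign(refs, meanlog = meanlog, sdlog = sdlog,
                       exponent = exponent, contaminant = contaminant,
                       seed = child_seed(seed, 3L))
  attr(design, "references") <- refs
  design
}

## Apply +/-1 homopolymer-length errors to a character vector of bases.
apply_homopolymer_errors <- function(chars, rate) {
  r <- rle(chars)
  n <- length(r$lengths)
  runIdx <- which(r$lengths >= 2L)
  if (length(runIdx) == 0L || rate == 0) return(chars)
  p <- pmin(1, rate * r$lengths[runIdx] / 4)
  hit <- runIdx[runif(length(runIdx)) < p]
  if (length(hit) == 0L) return(chars)
  dir <- sample(c(-1L, 1L), length(hit), replace = TRUE)
  r$lengths[hit] <- pmax(1L, r$lengths[hit] + dir)
  inverse.rle(r)
}

apply_substitutions <- function(chars, rate) {
  if (rate == 0) return(chars)
  nerr <- rbinom(1L, length(chars), rate)
  if (nerr == 0L) return(chars)
  pos <- sample(length(chars), nerr)
  ## independent of neighbours: sequencing errors may extend runs
  for (p in pos)
    chars[p] <- sample(setdiff(DNA_BASES4, chars[p]), 1L)
  chars
}

simulate_quality <- function(len, profile) {
  q <- profile$qualityMean - profile$qualityDecay * (seq_len(len) - 1L) +
    rnorm(len, 0, profile$qualitySd)
  as.integer(pmin(40L, pmax(2L, round(q))))
}

phred_string <- function(q) {
  intToUtf8(q + 33L)
}

#' Simulate amplicon reads from a community design
#'
#' Reads are drawn from species with probability equal to the design's
#' expected read fraction. A `chimeraFraction` of reads are bimeras:
#' the prefix of one parent joined to the suffix of another at a
#' uniform breakpoint. Template-level homopolymer errors (pyro mode)
#' are applied first, then per-read (per-mate) substitutions. Paired
#' mode emits overlapping 2 x `readLength` mates (reverse mate
#' reverse-complemented) with linearly decaying quality; single mode
#' emits the full amplicon as one read.
#'
#' @param design a `MockDesign`.
#' @param refs a `ReferenceSet` containing every `ref_id` in the design.
#' @param profile an `ErrorProfile`.
#' @param nReads number of reads (>= 1).
#' @param paired emit overlapping read pairs (default: substitution
#'   mode is paired, pyro single-end).
#' @param seed integer seed.
#' @param sample sample label.
#' @param readLength mate length in paired mode.
#' @return a `SimulatedDataset` list: `reads` (single mode: a
#'   `QualityScaledDNAStringSet`) or `r1`/`r2` (paired mode), and
#'   `truth`: data.frame(read_id, species, ref_id, parent2, chimera,
#'   contaminant) with one row per read.
#' @export
simulateReads <- function(design, refs, profile, nReads,
                          paired = profile$mode == "substitution",
                          seed, sample = "sample1", readLength = 300L) {
  stopifnot(inherits(profile, "ErrorProfile"))
  if (nReads < 1L) stop("parameter error: nReads must be >= 1")
  if (!all(design$ref_id %in% names(refs$amplicons)))
    stop("parameter error: design reference ids missing from refs")
  amp <- as.character(refs$amplicons)[design$ref_id]
  ampChars <- strsplit(amp, "", fixed = TRUE)

  with_seed(seed, {
    spIdx <- sample.int(nrow(design), nReads, replace = TRUE,
                        prob = design$read_fraction)
    isChim <- runif(nReads) < profile$chimeraFraction
    ids <- sprintf("%s_read_%06d", sample, seq_len(nReads))
    seqs <- vector("list", nReads)
    p2 <- rep(NA_character_, nReads)
    for (i in seq_len(nReads)) {
      if (isChim[i]) {
        pair <- sample.int(nrow(design), 2L, replace = FALSE,
                           prob = design$read_fraction)
        a <- ampChars[[pair[1L]]]; b <- ampChars[[pair[2L]]]
        minL <- min(length(a), length(b))
        bp <- sample(seq(40L, minL - 40L), 1L)
        tmpl <- c(a[seq_len(bp)], b[(bp + 1L):length(b)])
        spIdx[i] <- pair[1L]
        p2[i] <- design$ref_id[pair[2L]]
      } else {
        tmpl <- ampChars[[spIdx[i]]]
      }
      if (profile$mode == "pyro")
        tmpl <- apply_homopolymer_errors(tmpl, profile$homopolymerRate)
      seqs[[i]] <- tmpl
    }

    truth <- data.frame(
      read_id = ids,
      species = ifelse(isChim, NA_character_, design$species[spIdx]),
      ref_id = design$ref_id[spIdx],
      parent2 = p2,
      chimera = isChim,
      contaminant = ifelse(isChim, FALSE, design$contaminant[spIdx]),
      stringsAsFactors = FALSE)

    if (paired) {
      r1s <- character(nReads); r2s <- character(nReads)
      q1s <- character(nReads); q2s <- character(nReads)
      for (i in seq_len(nReads)) {
        tmpl <- seqs[[i]]
        L <- length(tmpl)
        rl <- min(readLength, L)
        m1 <- apply_substitutions(tmpl[seq_len(rl)],
                                  profile$substitutionRate)
        m2 <- rev(chartr_complement(
          apply_substitutions(tmpl[(L - rl + 1L):L],
                              profile$substitutionRate)))
        r1s[i] <- paste0(m1, collapse = "")
        r2s[i] <- paste0(m2, collapse = "")
        q1s[i] <- phred_string(simulate_quality(rl, profile))
        q2s[i] <- phred_string(simulate_quality(rl, profile))
      }
      r1 <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(stats::setNames(r1s, ids)),
        Biostrings::PhredQuality(q1s))
      r2 <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(stats::setNames(r2s, ids)),
        Biostrings::PhredQuality(q2s))
      S4Vectors::mcols(r1)$sample <- rep(sample, nReads)
      S4Vectors::mcols(r2)$sample <- rep(sample, nReads)
      structure(list(r1 = r1, r2 = r2, truth = truth, paired = TRUE,
                     sample = sample), class = "SimulatedDataset")
    } else {
      rs <- character(nReads); qs <- character(nReads)
      for (i in seq_len(nReads)) {
        m <- apply_substitutions(seqs[[i]], profile$substitutionRate)
        rs[i] <- paste0(m, collapse = "")
        qs[i] <- phred_string(simulate_quality(length(m), profile))
      }
      reads <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(stats::setNames(rs, ids)),
        Biostrings::PhredQuality(qs))
      S4Vectors::mcols(reads)$sample <- rep(sample, nReads)
      structure(list(reads = reads, truth = truth, paired = FALSE,
                     sample = sample), class = "SimulatedDataset")
    }
  })
}

## Complement of a character vector of bases (no reversal).
chartr_complement <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(comp[chars])
}
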