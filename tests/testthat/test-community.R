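# Community comparison: threshold filtering, rank aggregation, weight
# conversion, correlations, species assignment, dominant taxa.

test_that("the abundance threshold filters per sample and is idempotent", {
  counts <- matrix(c(3L, 12L, 30L, 40L, 2L, 1L), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(sprintf("motu_%03d", 1:3),
                                   c("s1", "s2")))
  tab <- MotuTable(counts, repIds = paste0("u", 1:3),
                   repSeqs = c("AAAA", "CCCC", "GGGG"),
                   similarityThreshold = 0.97)
  t1 <- applyAbundanceThreshold(tab, 1)
  expect_identical(motuCounts(t1), motuCounts(tab))

  t11 <- applyAbundanceThreshold(tab, 11)
  cnt <- motuCounts(t11)
  # the (3, 12) MOTU survives only in its second sample
  expect_identical(unname(cnt["motu_001", ]), c(0L, 12L))
  expect_false("motu_003" %in% rownames(cnt))
  expect_true(all(motuCounts(t11) <= motuCounts(tab)[
    rownames(cnt), , drop = FALSE]))
  # idempotent
  expect_identical(motuCounts(applyAbundanceThreshold(t11, 11)), cnt)

  tAll <- applyAbundanceThreshold(tab, 1000)
  expect_identical(nrow(tAll), 0L)
})

test_that("rank aggregation groups reads and keeps proportions normalised", {
  counts <- matrix(c(60L, 30L, 10L), ncol = 1,
                   dimnames = list(sprintf("motu_%03d", 1:3), "s1"))
  tab <- MotuTable(counts, repIds = paste0("u", 1:3),
                   repSeqs = c("AAAA", "CCCC", "GGGG"),
                   similarityThreshold = 0.97)
  lab <- c(motu_001 = "Calanidae", motu_002 = "Calanidae",
           motu_003 = NA)
  prof <- aggregateByRank(tab, lab, rank = 3)
  expect_identical(sort(prof$taxon), c("Calanidae", "Unclassified"))
  expect_equal(sum(prof$s1), 1)
  expect_identical(prof$n_motus[prof$taxon == "Calanidae"], 2L)
  expect_equal(prof$s1[prof$taxon == "Calanidae"], 0.9)

  oneFam <- aggregateByRank(tab, c(motu_001 = "F", motu_002 = "F",
                                   motu_003 = "F"), 3)
  expect_identical(nrow(oneFam), 1L)
  expect_equal(oneFam$s1, 1)
})

test_that("wet weights convert to dry weights by taxon factors", {
  morph <- data.frame(
    species = c("a", "b", "c"),
    order = c("Cyclopoida", "Poecilostomatoida", "Calanoida"),
    wet_weight = c(10, 4, 2),
    dry_weight = c(NA, NA, 0.5))
  out <- convertDryWeight(morph, c(Cyclopoida = 0.2,
                                   Poecilostomatoida = 0.25))
  expect_equal(out$dry_weight, c(2, 1, 0.5))

  bad <- morph
  bad$order[1] <- "Harpacticoida"
  expect_error(convertDryWeight(bad, c(Poecilostomatoida = 0.25)),
               "Harpacticoida")
})

test_that("profile correlations use Pearson's r with outer-joined taxa", {
  expect_equal(correlateProfiles(1:5, 2 * (1:5))$r, 1)
  expect_equal(correlateProfiles(1:5, -(1:5))$r, -1)
  r <- correlateProfiles(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r, 0.6)
  expect_equal(r$p, stats::cor.test(c(1, 2, 3, 4),
                                    c(2, 1, 4, 3))$p.value)

  # named vectors join over the union with zero fill
  x <- c(A = 3, B = 1, C = 2)
  y <- c(B = 1, D = 5, A = 3)
  joined <- correlateProfiles(x, y)
  expect_equal(joined$r,
               stats::cor(c(3, 1, 2, 0), c(3, 1, 0, 5)))

  expect_error(correlateProfiles(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlateProfiles(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("species assignment is strict at 99% identity", {
  refs <- small_refs()
  ints <- as.character(refs$interiors)
  db <- Biostrings::DNAStringSet(ints)
  names(db) <- unname(refs$species)

  expect_identical(assignSpecies(ints[4], db), unname(refs$species[4]))

  # one substitution in ~400 bp stays above 99%
  nearHit <- ints[4]
  substr(nearHit, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                     substr(nearHit, 11, 11))[1]
  expect_identical(assignSpecies(nearHit, db),
                   unname(refs$species[4]))

  # ~2% divergence falls below the threshold
  ch <- strsplit(ints[4], "")[[1]]
  pos <- seq(5, by = 40, length.out = ceiling(0.02 * length(ch)))
  ch[pos] <- vapply(ch[pos], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  expect_identical(assignSpecies(paste(ch, collapse = ""), db),
                   NA_character_)

  # exact tie: lexicographically first species, with a message
  dbTie <- Biostrings::DNAStringSet(c(Zeta = unname(ints[1]),
                                      Alpha = unname(ints[1])))
  expect_message(tie <- assignSpecies(ints[1], dbTie), "tie")
  expect_identical(tie, "Alpha")

  expect_error(assignSpecies(ints[1], Biostrings::DNAStringSet()),
               "empty")
})

test_that("dominant tables take the top-k union with log(x+1) columns", {
  prof <- data.frame(
    taxon = c("a", "b", "c", "d"),
    individual_pct = c(40, 30, 20, 10),
    biomass_pct = c(50, 30, 15, 5),
    read_pct = c(5, 15, 30, 50))
  d1 <- dominantTable(prof, k = 1)
  expect_identical(sort(d1$taxon), c("a", "d"))  # union of two leaders
  expect_equal(d1$log_biomass[d1$taxon == "a"], log(51))
  expect_equal(d1$log_reads[d1$taxon == "a"], log(6))

  dAll <- dominantTable(prof, k = 10)
  expect_identical(nrow(dAll), 4L)
  zero <- dominantTable(data.frame(taxon = "z", individual_pct = 0,
                                   biomass_pct = 0, read_pct = 0),
                        k = 2)
  expect_equal(zero$log_biomass, 0)

  # configurable base
  d2 <- dominantTable(prof, k = 10, logBase = 10)
  expect_equal(d2$log_biomass[d2$taxon == "a"], log10(51))
})

test_that("biomass-proportional error-free reads correlate with biomass", {
  m <- clean_mock()
  sim <- simulateReads(m$design, m$refs,
                       errorProfile("substitution",
                                    substitutionRate = 0,
                                    chimeraFraction = 0),
                       nReads = 2000, paired = FALSE, seed = 19,
                       sample = "s")
  reads <- table(factor(sim$truth$ref_id,
                        levels = m$design$ref_id))
  r <- correlateProfiles(m$design$biomass, as.numeric(reads))
  expect_gt(r$r, 0.98)

  # and at the family rank after aggregation
  fam <- m$refs$taxonomy$rank3
  bioFam <- tapply(m$design$biomass, fam, sum)
  readFam <- tapply(as.numeric(reads), fam, sum)
  rf <- correlateProfiles(as.numeric(bioFam), as.numeric(readFam))
  expect_gt(rf$r, 0.98)
})
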