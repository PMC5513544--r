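# Synthetic data generation: divergence control, determinism, error
# models, and community designs.

test_that("near pairs hit the requested divergence and nothing else does", {
  refs <- generateReferenceSet(33, nNearPairs = 2, seed = 7)
  expect_length(refs$interiors, 33L)
  d <- referenceDivergences(refs)
  below <- which(d < 0.03 & upper.tri(d), arr.ind = TRUE)
  expect_identical(nrow(below), 2L)
  # the constructed pairs are (1,2) and (3,4); check alignment-free
  # Hamming on the equal-length interiors directly
  ints <- as.character(refs$interiors)
  for (pair in list(c(1, 2), c(3, 4))) {
    a <- unname(ints[pair[1]]); b <- unname(ints[pair[2]])
    expect_identical(nchar(a), nchar(b))
    ham <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    realized <- ham / nchar(a)
    expect_lt(abs(realized - 0.015), 0.005)
  }
})

test_that("generation is deterministic and honours degenerate requests", {
  a <- generateReferenceSet(6, nNearPairs = 1, seed = 99)
  b <- generateReferenceSet(6, nNearPairs = 1, seed = 99)
  expect_identical(as.character(a$interiors), as.character(b$interiors))
  expect_identical(a$taxonomy, b$taxonomy)

  z <- generateReferenceSet(2, nNearPairs = 1, nearDivergence = 0,
                            seed = 3)
  expect_identical(as.character(z$interiors[[1]]),
                   as.character(z$interiors[[2]]))

  expect_error(generateReferenceSet(3, nNearPairs = 2, seed = 1),
               "unsatisfiable")
  expect_error(generateReferenceSet(4, nNearPairs = 1,
                                    nearDivergence = 0.05, seed = 1),
               "unsatisfiable")
})

test_that("interior lengths vary in range and runs are capped", {
  refs <- generateReferenceSet(12, seed = 4, lengthRange = c(320, 420))
  w <- nchar(as.character(refs$interiors))
  expect_true(all(w >= 320 & w <= 420))
  expect_gt(length(unique(w)), 1L)
  runs <- vapply(as.character(refs$interiors), function(s)
    max(rle(strsplit(s, "")[[1]])$lengths), numeric(1))
  expect_true(all(runs <= 5))
  # amplicons are primer-flanked interiors
  amp <- as.character(refs$amplicons[[1]])
  expect_match(amp, "^AGACCGATAGCAAACAAGTAC")
})

test_that("error profiles validate their rates", {
  expect_error(errorProfile("substitution", chimeraFraction = 1),
               "chimera")
  expect_error(errorProfile("substitution", homopolymerRate = 0.1),
               "homopolymerRate 0")
  expect_error(errorProfile("pyro", substitutionRate = -0.1), "rates")
  expect_identical(miseqProfile()$mode, "substitution")
  expect_identical(pyroProfile()$mode, "pyro")
})

test_that("zero-rate simulation copies amplicons faithfully", {
  m <- clean_mock()
  prof <- errorProfile("substitution", substitutionRate = 0,
                       chimeraFraction = 0)
  sim <- simulateReads(m$design, m$refs, prof, nReads = 50,
                       paired = FALSE, seed = 2, sample = "s")
  amp <- as.character(m$refs$amplicons)
  expect_identical(unname(as.character(sim$reads)),
                   unname(amp[sim$truth$ref_id]))
  # truth table covers every read exactly once
  expect_identical(sort(sim$truth$read_id),
                   sort(names(sim$reads)))
  expect_false(any(duplicated(sim$truth$read_id)))
})

test_that("substitution counts match the binomial error model", {
  refs <- small_refs()
  des <- mockDesign(refs, sdlog = 0.5, seed = 8)
  rate <- 0.01
  prof <- errorProfile("substitution", substitutionRate = rate,
                       chimeraFraction = 0)
  sim <- simulateReads(des, refs, prof, nReads = 10000,
                       paired = FALSE, seed = 31, sample = "s")
  amp <- as.character(refs$amplicons)
  reads <- as.character(sim$reads)
  mism <- 0L; bases <- 0L
  for (i in seq_along(reads)) {
    a <- strsplit(reads[i], "")[[1]]
    b <- strsplit(amp[sim$truth$ref_id[i]], "")[[1]]
    mism <- mism + sum(a != b)
    bases <- bases + length(a)
  }
  # per-base replacements are guaranteed to differ from the original,
  # so the observed mismatch count is Binomial(bases, rate)
  expect_lt(abs(mism - bases * rate),
            3 * sqrt(bases * rate * (1 - rate)))
})

test_that("homopolymer errors hit runs at the normalised per-run rate", {
  # rate 0.5 on a 4-base run (the only run of length >= 2 in the
  # template): about half of the reads change length
  tmpl <- strsplit("GCTAGCAAAAGCTAGC", "")[[1]]
  n <- 2000
  changed <- withr::with_seed(77, {
    sum(vapply(seq_len(n), function(i) {
      out <- motucal:::apply_homopolymer_errors(tmpl, 0.5)
      length(out) != length(tmpl)
    }, logical(1)))
  })
  p <- changed / n
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n) + 0.01)
})

test_that("pyro-mode reads carry indels; substitution-mode do not", {
  m <- clean_mock()
  pyro <- simulateReads(m$design, m$refs,
                        pyroProfile(substitutionRate = 0,
                                    homopolymerRate = 0.05,
                                    chimeraFraction = 0),
                        nReads = 200, paired = FALSE, seed = 5,
                        sample = "s")
  amp <- as.character(m$refs$amplicons)
  lens <- nchar(as.character(pyro$reads))
  srcLens <- nchar(amp[pyro$truth$ref_id])
  expect_gt(sum(lens != srcLens), 0L)
})

test_that("chimeric reads are bimeras of two design parents", {
  m <- clean_mock()
  prof <- errorProfile("substitution", substitutionRate = 0,
                       chimeraFraction = 0.5)
  sim <- simulateReads(m$design, m$refs, prof, nReads = 200,
                       paired = FALSE, seed = 13, sample = "s")
  chim <- which(sim$truth$chimera)
  expect_gt(length(chim), 50L)
  amp <- as.character(m$refs$amplicons)
  i <- chim[1L]
  r <- as.character(sim$reads)[[i]]
  p1 <- unname(amp[sim$truth$ref_id[i]])
  p2 <- unname(amp[sim$truth$parent2[i]])
  # read starts with a prefix of parent 1 and ends with a suffix of
  # parent 2
  expect_identical(substr(r, 1, 40), substr(p1, 1, 40))
  expect_identical(substr(r, nchar(r) - 39, nchar(r)),
                   substr(p2, nchar(p2) - 39, nchar(p2)))
})

test_that("paired mode emits overlapping mates that reconstruct the template", {
  m <- clean_mock()
  prof <- errorProfile("substitution", substitutionRate = 0,
                       chimeraFraction = 0)
  sim <- simulateReads(m$design, m$refs, prof, nReads = 20,
                       paired = TRUE, seed = 4, sample = "s")
  amp <- as.character(m$refs$amplicons)
  r1 <- as.character(sim$r1); r2 <- as.character(sim$r2)
  for (i in seq_along(r1)) {
    tmpl <- unname(amp[sim$truth$ref_id[i]])
    L <- nchar(tmpl)
    expect_identical(unname(r1[i]), substr(tmpl, 1, min(300, L)))
    rc <- motucal:::revcomp_chr(r2[i])
    expect_identical(rc, substr(tmpl, L - min(300, L) + 1, L))
    # overlap of the mates is at least 50 bases
    expect_gte(nchar(r1[i]) + nchar(r2[i]) - L, 50)
  }
})

test_that("community designs validate and behave at the margins", {
  refs <- small_refs()
  des <- mockDesign(refs, sdlog = 1, seed = 6)
  expect_equal(sum(des$read_fraction), 1)
  expect_true(all(des$biomass > 0))
  # read fraction proportional to biomass at exponent 1
  expect_equal(des$read_fraction,
               des$biomass / sum(des$biomass))

  f0 <- makeFieldDesign(8, contaminantFraction = 0, seed = 12)
  expect_false(any(f0$contaminant))
  expect_true(all(grepl("^Copepoda", f0$lineage)))

  f <- makeFieldDesign(10, contaminantFraction = 0.2, seed = 12)
  expect_identical(sum(f$contaminant), 2L)
  expect_true(all(grepl("^Malacostraca", f$lineage[f$contaminant])))

  fEq <- makeFieldDesign(5, sdlog = 0, seed = 3)
  expect_equal(var(fEq$biomass), 0)

  fA <- makeFieldDesign(100, seed = 9)
  fB <- makeFieldDesign(100, seed = 9)
  expect_identical(fA, fB)

  expect_error(makeFieldDesign(0, seed = 1), "nSpecies")
  expect_error(simulateReads(des[0, ], refs,
                             miseqProfile(), 0, seed = 1),
               "nReads")
})
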