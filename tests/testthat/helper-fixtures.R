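# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small 10-species reference set with one near pair (< 3%).
small_refs <- function() {
  cached("small_refs",
         generateReferenceSet(10, nNearPairs = 1, seed = 42))
}

# Error-free paired-end mock dataset over the small reference set.
clean_mock <- function() {
  cached("clean_mock", {
    refs <- small_refs()
    des <- mockDesign(refs, sdlog = 0.8, seed = 5)
    prof <- errorProfile("substitution", substitutionRate = 0,
                         chimeraFraction = 0)
    list(refs = refs, design = des,
         sim = simulateReads(des, refs, prof, nReads = 600, seed = 9,
                             sample = "mock"))
  })
}

clean_pipeline <- function() {
  cached("clean_pipeline", {
    m <- clean_mock()
    runMotuPipeline(m$sim, m$refs, mode = "miseq", seed = 3)
  })
}

# Noisy paired-end dataset (substitutions + chimeras) and its QC run.
noisy_mock <- function() {
  cached("noisy_mock", {
    refs <- small_refs()
    des <- mockDesign(refs, sdlog = 0.8, seed = 5)
    list(refs = refs, design = des,
         sim = simulateReads(des, refs,
                             miseqProfile(substitutionRate = 0.004,
                                          chimeraFraction = 0.02),
                             nReads = 800, seed = 17, sample = "mock"))
  })
}

noisy_qc <- function() {
  cached("noisy_qc", {
    m <- noisy_mock()
    qcPaired(m$sim$r1, m$sim$r2)
  })
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal hand-built MotuTable.
toy_motu_table <- function(counts = NULL, similarity = 0.97) {
  if (is.null(counts)) {
    counts <- matrix(c(120L, 30L, 15L, 5L, 800L, 100L),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("motu_001", "motu_002",
                                       "motu_003"),
                                     c("s1", "s2")))
  }
  seqs <- c("ACGTACGTACGTACGTACGT", "TTGCATGCATGCATGCATGC",
            "GGGTACCCGTACGTTACGTA")[seq_len(nrow(counts))]
  MotuTable(counts,
            repIds = paste0("u", seq_len(nrow(counts))),
            repSeqs = seqs,
            members = lapply(seq_len(nrow(counts)), function(i)
              stats::setNames(as.integer(sum(counts[i, ])),
                              paste0("u", i))),
            similarityThreshold = similarity)
}
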