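# Distances, preclustering, chimera flagging, subsampling and
# average-neighbor clustering, cross-checked against naive oracles.

test_that("indel-excluded distance drops gap columns and is a premetric", {
  expect_identical(pairwiseDistance("ACGT", "ACGT"), 0)
  expect_identical(pairwiseDistance("ACGT", "ACGA"), 0.25)
  expect_identical(pairwiseDistance("AC-GT", "ACAGA"), 0.25)
  expect_identical(pairwiseDistance("----", "AC--"), 1.0)
  expect_error(pairwiseDistance("ACG", "ACGT"), "equal length")

  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      mk <- function() paste(sample(c("A", "C", "G", "T", "-"), n,
                                    TRUE), collapse = "")
      a <- mk(); b <- mk()
      expect_identical(pairwiseDistance(a, b), pairwiseDistance(b, a))
      expect_identical(pairwiseDistance(a, a), 0)
      expect_true(pairwiseDistance(a, b) >= 0 &&
                    pairwiseDistance(a, b) <= 1)
    }
  })
})

test_that("the distance matrix agrees with the pairwise definition", {
  rows <- c(a = "ACGT-ACGT", b = "ACGTAAC-T", c = "TTGCA--GT")
  d <- distanceMatrix(rows)
  expect_identical(diag(d), c(a = 0, b = 0, c = 0))
  for (i in 1:3) for (j in 1:3)
    expect_identical(d[i, j], pairwiseDistance(rows[i], rows[j]))
})

test_that("queries thread into reference coordinates correctly", {
  refs <- small_refs()
  aln <- as.character(refs$alignment)

  # a query identical to a reference reproduces its aligned row
  q <- as.character(refs$interiors[[2]])
  a <- alignToReference(c(q1 = q), refs$alignment)
  expect_identical(unname(a$rows["q1"]), unname(aln[2]))

  # one internal deletion appears as one extra gap at that column
  nonGap <- which(strsplit(aln[2], "")[[1]] != "-")
  delAt <- 101L  # interior position
  qDel <- paste0(substr(q, 1, delAt - 1L),
                 substr(q, delAt + 1L, nchar(q)))
  aDel <- alignToReference(c(q1 = qDel), refs$alignment)
  got <- strsplit(aDel$rows[["q1"]], "")[[1]]
  want <- strsplit(aln[2], "")[[1]]
  want[nonGap[delAt]] <- "-"
  expect_identical(got, want)

  # an insertion is projected out but counted
  qIns <- paste0(substr(q, 1, 150), "A", substr(q, 151, nchar(q)))
  aIns <- alignToReference(c(q1 = qIns), refs$alignment)
  expect_identical(unname(aIns$insertions["q1"]), 1L)
  expect_identical(unname(aIns$rows["q1"]), unname(aln[2]))

  # junk is unalignable; an empty query set yields an empty set
  junk <- paste(rep("AC", 180), collapse = "")
  aJunk <- alignToReference(c(q1 = junk), refs$alignment)
  expect_identical(aJunk$unalignable, "q1")
  expect_length(alignToReference(character(0), refs$alignment)$rows, 0L)
})

test_that("preclustering absorbs error variants into abundant attractors", {
  base <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  oneOff <- base
  substr(oneOff, 50, 50) <- "A"
  seqs <- c(rep(base, 100), oneOff)
  names(seqs) <- sprintf("r%03d", seq_along(seqs))
  u <- dedupeReads(seqs)
  pc <- precluster(u, stats::setNames(u$seqs, u$ids), maxDiffs = 2L)
  expect_length(pc$ids, 1L)
  expect_identical(sum(pc$counts), 101L)
  expect_identical(unname(pc$seqs[1]), base)

  # equal-count distant sequences stay apart
  far <- paste(rep(c("T", "T", "G", "A"), 25), collapse = "")
  u2 <- dedupeReads(stats::setNames(c(base, far), c("r1", "r2")))
  pc2 <- precluster(u2, stats::setNames(u2$seqs, u2$ids), 2L)
  expect_length(pc2$ids, 2L)
})

test_that("preclustering chains through absorbed intermediates", {
  # b (abundant) - a (1 diff from b) - c (2 diffs from b, 1 from a);
  # a sorts before c so the chain attaches through the absorbed a
  b <- paste(rep(c("A", "C", "G", "T"), 30), collapse = "")
  a <- b; substr(a, 20, 20) <- "A"
  c_ <- a; substr(c_, 61, 61) <- "G"
  seqs <- c(rep(b, 50), a, c_)
  names(seqs) <- sprintf("r%03d", seq_along(seqs))
  u <- dedupeReads(seqs)
  pc <- precluster(u, stats::setNames(u$seqs, u$ids), maxDiffs = 1L)
  expect_length(pc$ids, 1L)
  expect_identical(sum(pc$counts), 52L)
  expect_identical(unname(pc$seqs[1]), b)
})

test_that("singleton removal drops count-1 preclusters except in pyro mode", {
  counts <- matrix(c(5L, 1L, 2L), ncol = 1,
                   dimnames = list(c("u1", "u2", "u3"), "s1"))
  u <- structure(list(ids = c("u1", "u2", "u3"),
                      seqs = c(u1 = "AAAA", u2 = "CCCC", u3 = "GGGG"),
                      counts = counts,
                      rows = c(u1 = "AAAA", u2 = "CCCC", u3 = "GGGG")),
                 class = "UniqueSet")
  expect_identical(removeSingletons(u, "miseq")$ids, c("u1", "u3"))
  expect_identical(removeSingletons(u, "pyro")$ids,
                   c("u1", "u2", "u3"))
  allSingle <- structure(list(ids = c("u1", "u2"),
                              seqs = c(u1 = "AAAA", u2 = "CCCC"),
                              counts = matrix(c(1L, 1L), ncol = 1,
                                              dimnames = list(
                                                c("u1", "u2"), "s1"))),
                         class = "UniqueSet")
  expect_length(removeSingletons(allSingle, "miseq")$ids, 0L)
})

test_that("chimera flagging matches an exhaustive breakpoint oracle", {
  refs <- small_refs()
  aln <- as.character(refs$alignment)
  # error-free bimera of two references with a midpoint breakpoint
  L <- nchar(aln[1])
  bp <- L %/% 2
  bimera <- paste0(substr(aln[1], 1, bp),
                   substr(aln[3], bp + 1, L))
  mkset <- function(rows, tot) {
    ids <- sprintf("u%d", seq_along(rows))
    structure(list(ids = ids, seqs = stats::setNames(degapped <-
        gsub("-", "", rows, fixed = TRUE), ids),
      counts = matrix(as.integer(tot), ncol = 1,
                      dimnames = list(ids, "s1")),
      rows = stats::setNames(rows, ids)), class = "UniqueSet")
  }
  u <- mkset(c(aln[1], aln[3], bimera), c(100, 90, 2))
  flags <- detectChimeras(u, referenceRows = refs$alignment)
  expect_identical(unname(flags), c(FALSE, FALSE, TRUE))

  # the oracle agrees: a near-perfect bimera model exists for the
  # chimera but not for the genuine references
  others <- aln[c(2:10)]
  expect_gt(oracle_best_bimera(bimera, aln[c(1, 3)]), 0.999)
  expect_lt(oracle_best_bimera(aln[2], aln[-2]) -
              oracle_best_single(aln[2], aln[-2]), 0.02)

  # de novo mode: most abundant sequence is exempt, low-abundance
  # bimera of abundant parents is caught
  flagsDn <- detectChimeras(u, referenceRows = NULL, deNovo = TRUE)
  expect_identical(unname(flagsDn), c(FALSE, FALSE, TRUE))
  uTop <- mkset(c(bimera, aln[1], aln[3]), c(200, 90, 80))
  flagsTop <- detectChimeras(uTop, referenceRows = NULL, deNovo = TRUE)
  expect_false(flagsTop[["u1"]])
})

test_that("subsampling is an exact hypergeometric draw", {
  counts <- matrix(c(90L, 10L), ncol = 1,
                   dimnames = list(c("A", "B"), "s1"))
  expect_identical(subsampleCounts(counts, depth = 100, seed = 1),
                   counts)
  expect_error(subsampleCounts(counts, depth = 101, seed = 1),
               "depth exceeds")
  draws <- vapply(1:1000, function(s)
    subsampleCounts(counts, depth = 10, seed = s)["B", 1],
    integer(1))
  expect_lt(abs(mean(draws) - 1), 0.1)  # E[B] = 10 * 10/100
  expect_identical(subsampleCounts(counts, depth = 10, seed = 7),
                   subsampleCounts(counts, depth = 10, seed = 7))
  # per-sample totals hit the depth exactly
  multi <- matrix(c(30L, 25L, 40L, 5L), nrow = 2,
                  dimnames = list(c("A", "B"), c("s1", "s2")))
  sub <- subsampleCounts(multi, depth = 20, seed = 3)
  expect_identical(unname(colSums(sub)), c(20, 20))
})

test_that("average-neighbor clustering follows the worked example", {
  d <- matrix(c(0, 0.01, 0.02,
                0.01, 0, 0.05,
                0.02, 0.05, 0), 3, 3)
  u <- structure(list(ids = c("ua", "ub", "uc"),
                      seqs = c(ua = "AAAA", ub = "AAAT", uc = "CCCC"),
                      counts = matrix(c(5L, 3L, 2L), ncol = 1,
                                      dimnames = list(
                                        c("ua", "ub", "uc"), "s1"))),
                 class = "UniqueSet")
  tab <- clusterMotus(d, u, cutoff = 0.03)
  # {a,b} merge at 0.01; avg({a,b},c) = 0.035 > 0.03 -> two MOTUs
  expect_identical(nrow(tab), 2L)
  expect_identical(unname(SummarizedExperiment::rowData(tab)$total),
                   c(8L, 2L))

  expect_identical(nrow(clusterMotus(matrix(0, 3, 3), u, 0.03)), 1L)
  dFar <- matrix(0.5, 3, 3); diag(dFar) <- 0
  expect_identical(nrow(clusterMotus(dFar, u, 0.03)), 3L)

  dAsym <- d; dAsym[1, 2] <- 0.2
  expect_error(clusterMotus(dAsym, u, 0.03), "symmetric")
})

test_that("clustering equals the naive recompute-everything oracle", {
  withr::with_seed(29, {
    for (trial in 1:150) {
      n <- sample(2:7, 1)
      d <- random_distance_matrix(n)
      cutoff <- sample(c(0.01, 0.03, 0.06), 1)
      got <- canonical_partition(motucal:::average_neighbor(d, cutoff))
      want <- canonical_partition(oracle_average_neighbor(d, cutoff))
      expect_identical(got, want)
    }
  })
})

test_that("clustering agrees with hclust/cutree on tie-free instances", {
  withr::with_seed(17, {
    for (trial in 1:25) {
      n <- sample(4:12, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.001, 0.2)
      d <- d + t(d)
      cutoff <- 0.05
      got <- motucal:::average_neighbor(d, cutoff)
      memb <- integer(n)
      for (i in seq_along(got)) memb[got[[i]]] <- i
      hc <- stats::cutree(stats::hclust(stats::as.dist(d),
                                        method = "average"),
                          h = cutoff)
      expect_identical(length(unique(memb)), length(unique(hc)))
      # identical partitions up to label permutation
      expect_identical(unname(split(seq_len(n), memb)[
        order(vapply(split(seq_len(n), memb), min, integer(1)))]),
        unname(split(seq_len(n), hc)[
          order(vapply(split(seq_len(n), hc), min, integer(1)))]))
    }
  })
})

test_that("MOTU counts are monotone in the similarity threshold", {
  withr::with_seed(41, {
    for (trial in 1:20) {
      n <- sample(3:10, 1)
      d <- random_distance_matrix(n)
      n99 <- length(motucal:::average_neighbor(d, 0.01))
      n97 <- length(motucal:::average_neighbor(d, 0.03))
      expect_gte(n99, n97)
    }
  })
})

test_that("representatives are the most abundant member, ties lexicographic", {
  expect_identical(representativeSequence(c("GGG", "AAA"), c(10, 3)),
                   1L)
  expect_identical(representativeSequence(c("GGG", "AAA"), c(5, 5)),
                   2L)
  expect_identical(representativeSequence("CCC", 1), 1L)
})
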