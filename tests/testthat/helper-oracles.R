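# Independent oracles used to cross-check the implementation.

# Naive average-neighbor clustering: recompute every cluster-pair
# average from the original matrix at each step (no Lance-Williams
# update), merge the minimum (ties: smallest sorted id pair, id =
# smallest member), stop when the minimum exceeds the cutoff.
oracle_average_neighbor <- function(d, cutoff, eps = 1e-9) {
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        idp <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || avg < best$avg - eps ||
            (abs(avg - best$avg) <= eps &&
             (idp[1] < best$idp[1] ||
              (idp[1] == best$idp[1] && idp[2] < best$idp[2])))) {
          best <- list(avg = avg, i = i, j = j, idp = idp)
        }
      }
    }
    if (best$avg > cutoff + eps) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  clusters
}

# Canonical form of a partition for comparison.
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, numeric(1), 1L))]
}

# Random symmetric distance matrix drawn from a small value grid so
# that ties occur and the tie rule is exercised.
random_distance_matrix <- function(n, grid = c(0.005, 0.01, 0.02,
                                               0.03, 0.05, 0.2)) {
  d <- matrix(0, n, n)
  vals <- sample(grid, n * (n - 1) / 2, replace = TRUE)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Exhaustive single-breakpoint bimera scan on ungapped equal-width
# aligned rows: for every breakpoint and ordered parent pair, the
# combined indel-excluded identity of prefix+suffix against the query.
oracle_best_bimera <- function(qRow, parentRows) {
  qc <- strsplit(qRow, "")[[1]]
  best <- 0
  for (a in seq_along(parentRows)) for (b in seq_along(parentRows)) {
    if (a == b) next
    pa <- strsplit(parentRows[a], "")[[1]]
    pb <- strsplit(parentRows[b], "")[[1]]
    L <- length(qc)
    for (cp in seq_len(L - 1L)) {
      model <- c(pa[seq_len(cp)], pb[(cp + 1L):L])
      cmp <- model != "-" & qc != "-"
      if (!any(cmp)) next
      best <- max(best, mean(model[cmp] == qc[cmp]))
    }
  }
  best
}

oracle_best_single <- function(qRow, parentRows) {
  qc <- strsplit(qRow, "")[[1]]
  max(vapply(parentRows, function(p) {
    pc <- strsplit(p, "")[[1]]
    cmp <- pc != "-" & qc != "-"
    if (!any(cmp)) return(0)
    mean(pc[cmp] == qc[cmp])
  }, numeric(1)))
}

# Trimmomatic-style sliding-window trace, written independently of
# trimRead: crop, leading, trailing, then scan window starts and cut
# before the first window whose mean is below the threshold.
oracle_trim <- function(qual, crop, minLen, leadQ, trailQ, ws, wq) {
  q <- qual[seq_len(min(length(qual), crop))]
  from <- 1L; to <- length(q)
  while (from <= to && q[from] < leadQ) from <- from + 1L
  while (to >= from && q[to] < trailQ) to <- to - 1L
  if (from <= to) {
    q2 <- q[from:to]
    if (length(q2) >= ws) {
      for (s in seq_len(length(q2) - ws + 1L)) {
        if (mean(q2[s:(s + ws - 1L)]) < wq) {
          to <- from + s - 2L
          break
        }
      }
    }
  }
  if (to < from || to - from + 1L < minLen) return(NULL)
  c(from, to)
}
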