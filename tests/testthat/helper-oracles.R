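# Independent oracles used across the suite.  These deliberately share no
# code with the package internals they check.

# plain Needleman-Wunsch global alignment score, linear gaps
nw_score <- function(a, b, scoring = poaScoring()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1, m + 1)
  S[, 1] <- (0:n) * scoring$gap
  S[1, ] <- (0:m) * scoring$gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (A[i] == B[j] && A[i] != "N") scoring$match else scoring$mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sub,
                             S[i, j + 1] + scoring$gap,
                             S[i + 1, j] + scoring$gap)
    }
  }
  S[n + 1, m + 1]
}

# all complete source-to-sink node paths of a POA graph (real nodes only)
enumerate_paths <- function(g) {
  et <- edgeTable(g)
  out <- list()
  walk <- function(node, acc) {
    nxt <- et$to[et$from == node]
    for (v in nxt) {
      if (v == -1L) out[[length(out) + 1L]] <<- acc
      else walk(v, c(acc, v))
    }
  }
  walk(0L, integer(0))
  out
}

path_weight <- function(g, path) {
  et <- edgeTable(g)
  us <- c(0L, path); vs <- c(path, -1L)
  sum(vapply(seq_along(us), function(k) {
    w <- et$weight[et$from == us[k] & et$to == vs[k]]
    if (length(w)) w[1] else 0L
  }, numeric(1)))
}

# Parallel-base counts by explicit per-sequence path tracking: for every
# aligned sequence, find the edge of its own path that crosses the cut in
# front of the calling node and attribute its base (or gap) directly.
# Aggregates sequences, never edge weights, so it checks both the cut
# logic and the weight bookkeeping of the implementation.
path_tracking_counts <- function(g, callingNode) {
  ranks <- nodeRanks(g)
  n <- numNodes(g)
  et <- edgeTable(g)
  parents <- et$from[et$to == callingNode]
  r <- ranks[callingNode]
  rk <- function(v) if (v == 0L) -1L else if (v == -1L) n else ranks[v]
  counts <- setNames(rep(0L, 5L), c("A", "C", "G", "T", "-"))
  for (aln in g@alignments) {
    nodes <- aln[!is.na(aln[, 1]) & !is.na(aln[, 2]), 1]
    full <- c(0L, nodes, -1L)
    for (k in seq_len(length(full) - 1L)) {
      u <- full[k]; v <- full[k + 1L]
      if (rk(u) < r && rk(v) >= r) {
        col <- if (v == callingNode) nodeBases(g)[callingNode]
        else if (u == 0L || u %in% parents) "-"
        else nodeBases(g)[u]
        counts[col] <- counts[col] + 1L
        break
      }
    }
  }
  counts
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(seq, nsub = 1L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(ch), nsub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
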