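#' Identify the parallel bases of a calling base
#'
#' Cuts the topologically ranked POA graph in front of the calling node and
#' tallies the weights of the edges crossing the cut, per base.  The
#' calling node's incoming edge weights count towards its own base; every
#' other crossing edge `(u, v)` (with `rank(u) < rank(callingNode) <
#' rank(v)`) is attributed to `base(u)` — `u` is the parallel node carrying
#' the alternative base — unless `u` is a direct parent of the calling node
#' (or the virtual source), in which case the sequences on that edge skip
#' the locus entirely and count as gaps.
#'
#' When the forward tally does not account for every aligned sequence, the
#' mirrored reverse pass (cut behind the calling base, outgoing edges) is
#' used; if neither pass is complete the elementwise maximum is returned
#' and flagged (`direction = "merged"`, `complete = FALSE`).
#'
#' @param graph a ranked [PoaGraph-class] (see [topoSort()]).
#' @param callingNode node id of the base under evaluation.
#' @return named integer vector over `A, C, G, T, -` with attributes
#'   `total`, `complete` and `direction`.
#' @examples
#' g <- buildPoa("ACGT", c("ACGT", "ACGT"))
#' identifyParallelBases(g, backbone(g)[2])
#' @export
identifyParallelBases <- function(graph, callingNode) {
  stopifnot(is(graph, "PoaGraph"))
  n <- numNodes(graph)
  callingNode <- as.integer(callingNode)
  if (length(callingNode) != 1L || is.na(callingNode) ||
      callingNode < 1L || callingNode > n)
    stop("calling node is not a node of the graph")
  if (n > 0 && anyNA(graph@ranks))
    stop("graph is not ranked; run topoSort() first")

  rkFrom <- .rank_of(graph, graph@edgeFrom)
  rkTo <- .rank_of(graph, graph@edgeTo)

  fwd <- .cut_counts(graph, callingNode, rkFrom, rkTo, reverse = FALSE)
  if (sum(fwd) == numSequences(graph))
    return(.pb_result(fwd, numSequences(graph), "forward"))
  rev <- .cut_counts(graph, callingNode, rkFrom, rkTo, reverse = TRUE)
  if (sum(rev) == numSequences(graph))
    return(.pb_result(rev, numSequences(graph), "reverse"))
  .pb_result(pmax(fwd, rev), numSequences(graph), "merged")
}

.rank_of <- function(graph, ids) {
  n <- numNodes(graph)
  r <- rep(NA_integer_, length(ids))
  r[ids == 0L] <- -1L          # virtual source precedes everything
  r[ids == -1L] <- n           # virtual sink follows everything
  real <- ids >= 1L
  r[real] <- graph@ranks[ids[real]]
  r
}

# One pass of the cut tally.  Forward: cut between ranks r-1 | r, incoming
# edges of the calling node plus sandwiching edges attributed to their
# upstream node.  Reverse: mirrored on the reversed graph (cut r | r+1,
# outgoing edges, sandwiching edges still attributed to their upstream
# node unless that node is a direct parent of the calling base).
.cut_counts <- function(graph, c, rkFrom, rkTo, reverse = FALSE) {
  counts <- stats::setNames(rep(0L, 5L), .ALPHABET)
  r <- graph@ranks[c]
  ef <- graph@edgeFrom; et <- graph@edgeTo; ew <- graph@edgeWeight
  parents <- ef[et == c]
  if (!reverse) {
    own <- et == c
    cross <- !own & rkFrom < r & rkTo > r
  } else {
    own <- ef == c
    cross <- !own & rkFrom <= r & rkTo > r
  }
  counts[.base_col(graph@bases[c])] <- counts[.base_col(graph@bases[c])] +
    sum(ew[own])
  if (any(cross)) {
    u <- ef[cross]; w <- ew[cross]
    gap <- u == 0L | u %in% parents
    for (k in seq_along(u)) {
      col <- if (gap[k]) "-" else .base_col(graph@bases[u[k]])
      counts[col] <- counts[col] + w[k]
    }
  }
  counts
}

.base_col <- function(b) if (b %in% .BASES) b else "-"

.pb_result <- function(counts, num, direction) {
  structure(counts, total = sum(counts),
            complete = sum(counts) == num, direction = direction)
}

#' Parallel-base counts for every base of the consensus read
#'
#' Applies [identifyParallelBases()] to each backbone node of the graph, in
#' read order.
#'
#' @param graph a ranked [PoaGraph-class] built with [buildPoa()].
#' @param backbone optional node ids for the consensus bases; defaults to
#'   `backbone(graph)`.
#' @return a [ParallelBases-class] with one row per consensus base.
#' @examples
#' g <- buildPoa("ACGT", c("ACGT", "AAGT"))
#' parallelCounts(parallelBasesForRead(g))
#' @export
parallelBasesForRead <- function(graph, backbone = NULL) {
  stopifnot(is(graph, "PoaGraph"))
  if (is.null(backbone)) backbone <- backbone(graph)
  if (length(backbone) == 0L) stop("graph has no backbone mapping")
  if (any(backbone < 1L | backbone > numNodes(graph)))
    stop("backbone refers to nodes outside the graph")
  counts <- matrix(0L, nrow = length(backbone), ncol = 5L,
                   dimnames = list(NULL, .ALPHABET))
  complete <- logical(length(backbone))
  direction <- character(length(backbone))
  for (i in seq_along(backbone)) {
    pb <- identifyParallelBases(graph, backbone[i])
    counts[i, ] <- as.integer(pb)
    complete[i] <- attr(pb, "complete")
    direction[i] <- attr(pb, "direction")
  }
  new("ParallelBases", counts = counts, complete = complete,
      direction = direction, numSequences = numSequences(graph))
}

#' @rdname ParallelBases-class
#' @export
setMethod("parallelCounts", "ParallelBases", function(x) x@counts)

setMethod("show", "ParallelBases", function(object) {
  cat(sprintf("ParallelBases: %d positions over %d sequences (%d complete)\n",
              nrow(object@counts), object@numSequences, sum(object@complete)))
})

#' Write parallel-base counts as a TSV debug table
#'
#' @param pb a [ParallelBases-class].
#' @param file path or connection passed to [utils::write.table()].
#' @return the data.frame, invisibly.
#' @export
parallelBasesToTsv <- function(pb, file = "") {
  stopifnot(is(pb, "ParallelBases"))
  df <- data.frame(position = seq_len(nrow(pb@counts)), pb@counts,
                   check.names = FALSE)
  df$total <- rowSums(pb@counts)
  df$complete <- pb@complete
  if (!identical(file, "")) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
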