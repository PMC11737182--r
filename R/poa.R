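#' Alignment scoring parameters
#'
#' Integer match/mismatch/gap scores for aligning a sequence against a POA
#' graph (linear gap penalty).  The defaults keep arithmetic exact and are
#' recorded in pipeline output headers.
#'
#' @param match,mismatch,gap integer scores; `match` must be positive,
#'   `mismatch` and `gap` non-positive.
#' @return a named list of class `poaScoring`.
#' @examples
#' poaScoring()
#' @export
poaScoring <- function(match = 2L, mismatch = -4L, gap = -4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (is.na(match) || match <= 0L) stop("match score must be a positive integer")
  if (is.na(mismatch) || mismatch > 0L) stop("mismatch score must be <= 0")
  if (is.na(gap) || gap > 0L) stop("gap score must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "poaScoring")
}

.as_base_int <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(s, .BASES) - 1L
  code[is.na(code) & s == "N"] <- 4L
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

.check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a single non-empty string")
  invisible(seq)
}

#' Create an empty POA graph
#'
#' @return an empty [PoaGraph-class].
#' @export
poaGraph <- function() new("PoaGraph")

#' @rdname PoaGraph-class
#' @export
setMethod("numNodes", "PoaGraph", function(x) length(x@bases))

#' @rdname PoaGraph-class
#' @export
setMethod("numSequences", "PoaGraph", function(x) x@numSequences)

#' @rdname PoaGraph-class
#' @export
setMethod("nodeBases", "PoaGraph", function(x) x@bases)

#' @rdname PoaGraph-class
#' @export
setMethod("nodeRanks", "PoaGraph", function(x) x@ranks)

#' @rdname PoaGraph-class
#' @export
setMethod("edgeTable", "PoaGraph", function(x)
  data.frame(from = x@edgeFrom, to = x@edgeTo, weight = x@edgeWeight))

#' @rdname PoaGraph-class
#' @export
setMethod("backbone", "PoaGraph", function(x) x@backbone)

setMethod("show", "PoaGraph", function(object) {
  cat(sprintf("PoaGraph: %d nodes, %d edges, %d sequences, %s\n",
              numNodes(object), length(object@edgeFrom),
              numSequences(object),
              if (anyNA(object@ranks) || numNodes(object) == 0)
                "unranked" else "ranked"))
})

setMethod("show", "GraphAlignment", function(object) {
  cat(sprintf("GraphAlignment: score %d, %d aligned columns\n",
              object@score, nrow(object@path)))
})

#' Align a sequence against a POA graph
#'
#' Optimal global alignment of a nucleotide sequence against the DAG by
#' dynamic programming over nodes in topological order.  On a linear
#' (single-path) graph the score equals the Needleman-Wunsch score of the
#' two sequences under the same scoring.  On an empty graph the alignment is
#' all insertions.
#'
#' Equal-scoring tracebacks are resolved deterministically, preferring
#' match, then deletion (gap in the sequence), then mismatch, then insertion
#' (gap in the graph); remaining ties take the smallest parent node id.
#' Preferring a deletion over a mismatch anchors a substitution that is
#' directly followed by a deletion on the substituted locus instead of its
#' downstream neighbour, which keeps parallel nodes attached to the locus
#' they contest.
#'
#' @param graph a [PoaGraph-class].
#' @param seq nucleotide string over `A,C,G,T` (`N` scores as a mismatch
#'   against everything).
#' @param scoring a [poaScoring()] list.
#' @return a [GraphAlignment-class].
#' @examples
#' g <- addSequence(poaGraph(), "ACGT")
#' alignToGraph(g, "ACGT")
#' @export
alignToGraph <- function(graph, seq, scoring = poaScoring()) {
  stopifnot(is(graph, "PoaGraph"))
  .check_seq(seq)
  n <- numNodes(graph)
  ord <- if (n > 0) .cpp_topo_order(n, graph@edgeFrom, graph@edgeTo) else integer()
  res <- .cpp_align_graph(n, .encode_bases(graph@bases), graph@edgeFrom,
                          graph@edgeTo, ord, .as_base_int(seq),
                          scoring$match, scoring$mismatch, scoring$gap)
  path <- res$path
  colnames(path) <- c("node", "pos")
  new("GraphAlignment", path = path, score = as.integer(res$score))
}

.encode_bases <- function(bases) {
  code <- match(bases, .BASES) - 1L
  code[is.na(code)] <- 4L
  code
}

#' Add a sequence to a POA graph
#'
#' Threads `seq` through the graph along `alignment`: matched positions
#' reuse the existing node when the bases agree and otherwise create a
#' parallel node; insertions create new nodes; edges along the resulting
#' path (including virtual source/sink edges) have their weight incremented,
#' or are created with weight 1.  `numSequences` increases by one.
#'
#' @param graph a [PoaGraph-class].
#' @param seq the nucleotide string to add.
#' @param alignment a [GraphAlignment-class] of `seq` against `graph`; if
#'   `NULL`, it is computed with `scoring`.
#' @param scoring a [poaScoring()] list, used when `alignment` is `NULL`.
#' @param weight weight contributed by this sequence to the edges along its
#'   path (0 is allowed so a backbone can be threaded without contributing
#'   to the parallel-base tallies; see [buildPoa()]).
#' @return the updated [PoaGraph-class] (ranks are reset; call [topoSort()]).
#' @examples
#' g <- addSequence(poaGraph(), "ACGT")
#' g <- addSequence(g, "AAGT")
#' edgeTable(g)
#' @export
addSequence <- function(graph, seq, alignment = NULL,
                        scoring = poaScoring(), weight = 1L) {
  stopifnot(is(graph, "PoaGraph"))
  .check_seq(seq)
  weight <- as.integer(weight)
  if (is.null(alignment)) alignment <- alignToGraph(graph, seq, scoring)
  stopifnot(is(alignment, "GraphAlignment"))
  path <- alignment@path
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (sum(!is.na(path[, 2])) != length(chars))
    stop("alignment does not cover the sequence")

  bases <- graph@bases
  nodePath <- integer(0)  # nodes carrying this sequence's bases, in order
  posPath <- integer(0)
  newPairs <- path
  for (k in seq_len(nrow(path))) {
    nd <- path[k, 1]; pos <- path[k, 2]
    if (is.na(pos)) next           # deletion: sequence skips this node
    if (!is.na(nd) && bases[nd] == chars[pos]) {
      node <- nd                   # match: reuse
    } else {
      bases <- c(bases, chars[pos])  # mismatch or insertion: new node
      node <- length(bases)
    }
    newPairs[k, 1] <- node
    nodePath <- c(nodePath, node)
    posPath <- c(posPath, pos)
  }

  ef <- graph@edgeFrom; et <- graph@edgeTo; ew <- graph@edgeWeight
  us <- c(0L, nodePath)            # virtual source ... virtual sink
  vs <- c(nodePath, -1L)
  keyAll <- as.numeric(ef) * 1e7 + as.numeric(et + 2L)
  keyNew <- as.numeric(us) * 1e7 + as.numeric(vs + 2L)
  idx <- match(keyNew, keyAll)
  hit <- !is.na(idx)
  if (any(hit)) ew[idx[hit]] <- ew[idx[hit]] + weight
  if (any(!hit)) {
    ef <- c(ef, us[!hit]); et <- c(et, vs[!hit]); ew <- c(ew, rep(weight, sum(!hit)))
  }

  keep <- !is.na(newPairs[, 1]) | !is.na(newPairs[, 2])
  aln <- newPairs[keep, , drop = FALSE]
  initialize(graph,
             bases = bases, edgeFrom = ef, edgeTo = et, edgeWeight = ew,
             numSequences = graph@numSequences + 1L,
             ranks = rep(NA_integer_, length(bases)),
             alignments = c(graph@alignments, list(aln)))
}

#' Topologically sort a POA graph
#'
#' Kahn's algorithm over the node set; the resulting 0-based ranks satisfy
#' `rank(parent) < rank(child)` for every edge.  Ties are broken by taking
#' the highest node id first, so later-created parallel nodes rank ahead of
#' the backbone node they compete with; the cut in front of a backbone base
#' then keeps its same-locus alternatives upstream of the cut.
#'
#' @param graph a [PoaGraph-class].
#' @return the graph with `ranks` populated.
#' @export
topoSort <- function(graph) {
  stopifnot(is(graph, "PoaGraph"))
  n <- numNodes(graph)
  if (n == 0) return(graph)
  ord <- .cpp_topo_order(n, graph@edgeFrom, graph@edgeTo)
  ranks <- integer(n)
  ranks[ord] <- 0:(n - 1)
  initialize(graph, ranks = ranks)
}

#' Build a POA graph from a CCS read and its subreads
#'
#' Seeds the graph with the consensus (CCS) read, then aligns and adds each
#' subread in input order.  Reverse-orientation subreads are
#' reverse-complemented before alignment.  The returned graph is
#' topologically sorted and carries the backbone mapping (consensus base ->
#' node id) in `backbone(graph)`.
#'
#' @param ccs consensus nucleotide string.
#' @param subreads character vector of subread sequences (at least one).
#' @param orientation optional character vector (`"+"`/`"-"`) per subread.
#' @param scoring a [poaScoring()] list.
#' @param countCcs logical; when `TRUE` (default) the consensus read counts
#'   as one of the aligned sequences, so `numSequences` is
#'   `1 + length(subreads)` and the backbone contributes weight to its
#'   edges.  When `FALSE` the backbone is threaded with weight 0 and only
#'   subreads are counted.
#' @return a ranked [PoaGraph-class] with `backbone` set.
#' @examples
#' g <- buildPoa("ACGT", c("ACGT", "ACGT"))
#' numSequences(g)
#' @export
buildPoa <- function(ccs, subreads, orientation = NULL,
                     scoring = poaScoring(), countCcs = TRUE) {
  .check_seq(ccs)
  if (length(subreads) < 1L) stop("at least one subread is required")
  if (is.null(orientation)) orientation <- rep("+", length(subreads))
  stopifnot(length(orientation) == length(subreads),
            all(orientation %in% c("+", "-")))
  g <- addSequence(poaGraph(), ccs, scoring = scoring,
                   weight = if (countCcs) 1L else 0L)
  if (!countCcs) g@numSequences <- 0L
  bb <- g@alignments[[1]][, 1]
  for (i in seq_along(subreads)) {
    s <- subreads[i]
    if (orientation[i] == "-") s <- revComp(s)
    g <- addSequence(g, s, scoring = scoring)
  }
  g@backbone <- bb
  topoSort(g)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq nucleotide string (`A,C,G,T,N`).
#' @return the reverse complement.
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Heaviest-path consensus of a POA graph
#'
#' The bases along the maximum-total-edge-weight path from the virtual
#' source to the virtual sink (ties prefer the smaller node id), the
#' canonical POA consensus.
#'
#' @param graph a ranked [PoaGraph-class].
#' @return the consensus nucleotide string, with the node-id path in
#'   `attr(, "path")`; the empty string for an empty graph.
#' @export
heaviestConsensus <- function(graph) {
  stopifnot(is(graph, "PoaGraph"))
  n <- numNodes(graph)
  if (n == 0) return(structure("", path = integer()))
  if (anyNA(graph@ranks)) graph <- topoSort(graph)
  ord <- order(graph@ranks)
  path <- .cpp_heaviest_path(n, graph@edgeFrom, graph@edgeTo,
                             graph@edgeWeight, ord)
  structure(paste(graph@bases[path], collapse = ""), path = path)
}

#' Dump a POA graph in DOT format
#'
#' Debug view of the graph for Graphviz; nodes are labelled `id:base(rank)`.
#'
#' @param graph a [PoaGraph-class].
#' @return a character vector of DOT lines.
#' @export
graphToDot <- function(graph) {
  stopifnot(is(graph, "PoaGraph"))
  rk <- graph@ranks
  lab <- sprintf("n%d [label=\"%d:%s%s\"];", seq_along(graph@bases),
                 seq_along(graph@bases), graph@bases,
                 ifelse(is.na(rk), "", sprintf(" (%d)", rk)))
  enm <- function(v) ifelse(v == 0L, "SRC", ifelse(v == -1L, "SNK", paste0("n", v)))
  edg <- sprintf("%s -> %s [label=%d];", enm(graph@edgeFrom),
                 enm(graph@edgeTo), graph@edgeWeight)
  c("digraph poa {", "rankdir=LR;", lab, edg, "}")
}
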