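#' @useDynLib ccspolish, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.BASES <- c("A", "C", "G", "T")
.ALPHABET <- c("A", "C", "G", "T", "-")

#' Partial-order alignment graph
#'
#' A directed acyclic graph in which nodes carry single bases and edge
#' weights count the sequences agreeing on that transition.  Node ids are
#' `1..n`; a virtual source (id 0) and virtual sink (id -1) appear only in
#' the edge table, so that every aligned sequence spans the graph end to end
#' and every full cut of the ranked graph carries a total edge weight equal
#' to the number of aligned sequences.
#'
#' @slot bases character vector of node bases (`A`, `C`, `G`, `T`, `N`).
#' @slot edgeFrom,edgeTo,edgeWeight parallel integer vectors defining the
#'   weighted edge list (`edgeFrom` 0 = virtual source, `edgeTo` -1 =
#'   virtual sink).
#' @slot numSequences number of sequences aligned into the graph.
#' @slot ranks integer topological rank per node (0-based), `NA` until
#'   [topoSort()] has run.
#' @slot backbone node ids of the seed (consensus) read, in read order.
#' @slot alignments per-sequence alignment paths as two-column matrices
#'   (node id, sequence position), kept for kinetics averaging and for
#'   path-level debugging.
#'
#' @seealso [poaGraph()], [buildPoa()], [topoSort()], [heaviestConsensus()]
#' @export
setClass("PoaGraph",
  representation(
    bases = "character",
    edgeFrom = "integer",
    edgeTo = "integer",
    edgeWeight = "integer",
    numSequences = "integer",
    ranks = "integer",
    backbone = "integer",
    alignments = "list"
  ),
  prototype(
    bases = character(), edgeFrom = integer(), edgeTo = integer(),
    edgeWeight = integer(), numSequences = 0L, ranks = integer(),
    backbone = integer(), alignments = list()
  )
)

setValidity("PoaGraph", function(object) {
  n <- length(object@bases)
  msg <- character()
  if (length(object@edgeFrom) != length(object@edgeTo) ||
      length(object@edgeFrom) != length(object@edgeWeight))
    msg <- c(msg, "edge vectors must have equal length")
  if (length(object@ranks) != n)
    msg <- c(msg, "ranks must have one entry per node")
  if (any(object@edgeWeight < 0L))
    msg <- c(msg, "edge weights must be non-negative")
  if (n > 0 && length(object@edgeFrom) > 0) {
    bad <- object@edgeFrom < 0L | object@edgeFrom > n |
      (object@edgeTo != -1L & (object@edgeTo < 1L | object@edgeTo > n))
    if (any(bad)) msg <- c(msg, "edge endpoints out of range")
  }
  if (!anyNA(object@ranks) && n > 0) {
    if (!setequal(object@ranks, 0:(n - 1)))
      msg <- c(msg, "ranks must be a permutation of 0..n-1")
    real <- object@edgeFrom >= 1L & object@edgeTo >= 1L
    if (any(real)) {
      ru <- object@ranks[object@edgeFrom[real]]
      rv <- object@ranks[object@edgeTo[real]]
      if (any(ru >= rv)) msg <- c(msg, "rank(parent) must be < rank(child)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Alignment of a sequence against a POA graph
#'
#' @slot path two-column integer matrix of (node id, sequence position)
#'   pairs; `NA` in the first column marks an insertion relative to the
#'   graph, `NA` in the second a deletion of the graph node.
#' @slot score integer alignment score.
#' @export
setClass("GraphAlignment",
  representation(path = "matrix", score = "integer"))

setValidity("GraphAlignment", function(object) {
  p <- object@path
  if (ncol(p) != 2) return("path must have two columns")
  sp <- p[, 2][!is.na(p[, 2])]
  if (is.unsorted(sp, strictly = TRUE)) return("sequence positions must be strictly increasing")
  if (any(is.na(p[, 1]) & is.na(p[, 2]))) return("(GAP, GAP) pair in path")
  TRUE
})

#' Parallel-base counts for the bases of a read
#'
#' One row per consensus base, produced by cutting the topologically ranked
#' POA graph in front of the base's node and tallying the weights of
#' crossing edges per base (`A`, `C`, `G`, `T`) or gap (`-`, sequences that
#' skip the locus).
#'
#' @slot counts integer matrix, one row per base, columns `A,C,G,T,-`.
#' @slot complete logical per base: does the row total equal the number of
#'   sequences in the graph?
#' @slot direction character per base: which pass produced the counts
#'   (`forward`, `reverse`, or `merged` when neither pass was complete).
#' @slot numSequences number of sequences in the source graph.
#' @export
setClass("ParallelBases",
  representation(counts = "matrix", complete = "logical",
                 direction = "character", numSequences = "integer"))

setValidity("ParallelBases", function(object) {
  if (!identical(colnames(object@counts), .ALPHABET))
    return("counts columns must be A,C,G,T,-")
  if (nrow(object@counts) != length(object@complete) ||
      nrow(object@counts) != length(object@direction))
    return("slot lengths disagree")
  if (any(object@counts < 0)) return("negative count")
  ok <- rowSums(object@counts) == object@numSequences
  if (!identical(unname(ok), unname(object@complete)))
    return("complete flag inconsistent with row totals")
  TRUE
})

#' A polished consensus read
#'
#' @slot sequence polished nucleotide string.
#' @slot perBaseOrigin factor over the polished bases with levels
#'   `UNCHANGED`, `PARALLEL`, `POA_SUB`.
#' @slot deletions original (1-based) consensus positions removed by the
#'   POA-consensus step (`POA_DEL`).
#' @slot originalPosition for each polished base, the 1-based position it
#'   occupied in the input consensus read.
#' @slot correctionCounts named integer vector over
#'   `POA_SUB`, `POA_DEL`, `PARALLEL`.
#' @export
setClass("PolishedRead",
  representation(sequence = "character", perBaseOrigin = "factor",
                 deletions = "integer", originalPosition = "integer",
                 correctionCounts = "integer"))

setValidity("PolishedRead", function(object) {
  n <- nchar(object@sequence)
  if (length(object@perBaseOrigin) != n || length(object@originalPosition) != n)
    return("per-base slots must match sequence length")
  if (!identical(names(object@correctionCounts), c("POA_SUB", "POA_DEL", "PARALLEL")))
    return("correctionCounts must be named POA_SUB, POA_DEL, PARALLEL")
  cc <- object@correctionCounts
  if (cc["POA_DEL"] != length(object@deletions))
    return("POA_DEL count disagrees with deletions")
  tab <- table(object@perBaseOrigin)
  if (cc["POA_SUB"] != tab[["POA_SUB"]] || cc["PARALLEL"] != tab[["PARALLEL"]])
    return("correctionCounts disagree with perBaseOrigin")
  TRUE
})

#' One CCS molecule: consensus read, subreads and kinetics
#'
#' @slot id molecule identifier (`movie/zmw`).
#' @slot ccs consensus nucleotide string.
#' @slot ccsQual integer Phred qualities (1-93), one per consensus base.
#' @slot subreads character vector of subread sequences, as sequenced.
#' @slot orientation character per subread, `"+"` or `"-"` (reverse-strand
#'   passes are reverse-complemented before alignment).
#' @slot ipd,pw lists of non-negative numeric vectors (frames), one per
#'   subread, or zero-length vectors when kinetics are missing.
#' @slot snr numeric length-4 per-read signal-to-noise (A, C, G, T channels).
#' @export
setClass("CcsMolecule",
  representation(id = "character", ccs = "character", ccsQual = "integer",
                 subreads = "character", orientation = "character",
                 ipd = "list", pw = "list", snr = "numeric"))

setValidity("CcsMolecule", function(object) {
  msg <- character()
  if (length(object@ccsQual) != nchar(object@ccs))
    msg <- c(msg, "ccsQual must match ccs length")
  if (any(object@ccsQual < 1L | object@ccsQual > 93L))
    msg <- c(msg, "ccs qualities must lie in [1, 93]")
  ns <- length(object@subreads)
  if (length(object@orientation) != ns || length(object@ipd) != ns ||
      length(object@pw) != ns)
    msg <- c(msg, "per-subread slots must match the number of subreads")
  if (!all(object@orientation %in% c("+", "-")))
    msg <- c(msg, "orientation must be '+' or '-'")
  kl <- vapply(seq_len(ns), function(i) {
    length(object@ipd[[i]]) %in% c(0L, nchar(object@subreads[i])) &&
      length(object@pw[[i]]) %in% c(0L, nchar(object@subreads[i]))
  }, logical(1))
  if (ns > 0 && !all(kl))
    msg <- c(msg, "ipd/pw arrays must match their subread lengths (or be empty)")
  if (length(object@snr) != 4L) msg <- c(msg, "snr must have 4 channels")
  if (length(msg)) msg else TRUE
})

#' A fitted base-quality calibration model
#'
#' A small feed-forward network (or logistic-regression baseline) mapping
#' per-base features to the probability that the base is correct.
#'
#' @slot architecture descriptor string, e.g. `"mlp:64,32"` or `"logistic"`.
#' @slot params list of weight matrices / coefficient vectors.
#' @slot featureNames feature schema the model was trained on.
#' @slot center,scale feature-normalisation statistics.
#' @slot classWeights length-2 weights (class 0, class 1) used in the loss;
#'   predictions are prior-corrected back to calibrated probabilities.
#' @slot seed training seed.
#' @slot version serialisation schema version.
#' @export
setClass("CalibrationModel",
  representation(architecture = "character", params = "list",
                 featureNames = "character", center = "numeric",
                 scale = "numeric", classWeights = "numeric",
                 seed = "integer", version = "character"))

#' Predicted-versus-observed quality calibration report
#'
#' @slot bins data.frame with columns `predictedQ`, `n`, `mismatches`,
#'   `observedQ`, `lowerBound` (TRUE when the bin had zero mismatches and
#'   `observedQ` is the one-sided bound).
#' @slot maxValidatedQ largest predicted quality bin, with at least
#'   `minBinCount` bases, whose observed quality reaches its prediction.
#' @slot totals named numeric: `bases`, `mismatches`, `errorRate`,
#'   `observedQ` over all bases.
#' @slot minBinCount support threshold used for `maxValidatedQ`.
#' @export
setClass("CalibrationReport",
  representation(bins = "data.frame", maxValidatedQ = "integer",
                 totals = "numeric", minBinCount = "numeric"))
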