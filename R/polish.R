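#' Polish a consensus read
#'
#' Applies the three correction rules and tags every corrected base with
#' the method that produced it:
#'
#' * `POA_SUB` / `POA_DEL`: the heaviest-path POA consensus is aligned back
#'   to the consensus read; where it substitutes a base the base is
#'   replaced, where it deletes one the base is removed.
#' * `PARALLEL`: at positions the consensus step left untouched, if some
#'   alternative base has a strictly higher parallel count than the
#'   original base, the original is replaced by the highest-count
#'   alternative (ties keep the original; a gap majority is never applied
#'   as a deletion — deletions come only from the POA consensus).
#'
#' Each corrected base carries exactly one origin; POA-consensus
#' corrections take precedence over the parallel-base rule so the
#' categories stay disjoint.
#'
#' @param ccs the consensus nucleotide string that was polished.
#' @param graph the ranked [PoaGraph-class] from [buildPoa()].
#' @param counts a [ParallelBases-class] with one row per `ccs` base.
#' @param scoring [poaScoring()] used to align the POA consensus to `ccs`.
#' @return a [PolishedRead-class].
#' @examples
#' g <- buildPoa("ACGT", c("AAGT", "AAGT", "AAGT"))
#' polishRead("ACGT", g, parallelBasesForRead(g))
#' @export
polishRead <- function(ccs, graph, counts, scoring = poaScoring()) {
  .check_seq(ccs)
  stopifnot(is(graph, "PoaGraph"), is(counts, "ParallelBases"))
  cc <- strsplit(ccs, "", fixed = TRUE)[[1]]
  n <- length(cc)
  if (nrow(counts@counts) != n)
    stop("parallel-base counts do not match the consensus length")

  cons <- heaviestConsensus(graph)
  # align the consensus string to the CCS read on a linear graph of the CCS
  lin <- addSequence(poaGraph(), ccs)
  aln <- alignToGraph(lin, as.character(cons), scoring)@path

  newBase <- cc
  origin <- rep("UNCHANGED", n)
  deleted <- logical(n)
  consChars <- strsplit(as.character(cons), "", fixed = TRUE)[[1]]
  for (k in seq_len(nrow(aln))) {
    nd <- aln[k, 1]; pos <- aln[k, 2]
    if (is.na(pos)) {                # consensus deletes this CCS base
      deleted[nd] <- TRUE
    } else if (!is.na(nd) && consChars[pos] != cc[nd]) {
      newBase[nd] <- consChars[pos]  # consensus substitutes
      origin[nd] <- "POA_SUB"
    }                                # consensus insertions are ignored
  }

  cmat <- counts@counts
  for (i in which(!deleted & origin == "UNCHANGED")) {
    own <- cmat[i, cc[i]]
    alt <- cmat[i, .BASES]
    alt[cc[i]] <- -1L
    best <- which.max(alt)           # ties: first of A < C < G < T
    if (alt[best] > own) {
      newBase[i] <- .BASES[best]
      origin[i] <- "PARALLEL"
    }
  }

  keep <- !deleted
  cc_counts <- c(POA_SUB = sum(origin == "POA_SUB" & keep),
                 POA_DEL = sum(deleted),
                 PARALLEL = sum(origin == "PARALLEL" & keep))
  new("PolishedRead",
      sequence = paste(newBase[keep], collapse = ""),
      perBaseOrigin = factor(origin[keep],
                             levels = c("UNCHANGED", "PARALLEL", "POA_SUB")),
      deletions = which(deleted),
      originalPosition = which(keep),
      correctionCounts = vapply(cc_counts, as.integer, integer(1)))
}

#' @rdname PolishedRead-class
#' @export
setMethod("polishedSequence", "PolishedRead", function(x) x@sequence)

#' @rdname PolishedRead-class
#' @export
setMethod("correctionCounts", "PolishedRead", function(x) x@correctionCounts)

setMethod("show", "PolishedRead", function(object) {
  cc <- object@correctionCounts
  cat(sprintf(
    "PolishedRead: %d bases (POA_SUB %d, POA_DEL %d, PARALLEL %d)\n",
    nchar(object@sequence), cc["POA_SUB"], cc["POA_DEL"], cc["PARALLEL"]))
})

#' Tally corrections over a set of polished reads
#'
#' Aggregates per-method correction counts and, when truth is available,
#' polishing sensitivity and specificity.  A consensus base counted as a
#' true error is "corrected" when its polished base equals the true
#' (reference) base; a correct consensus base counts against specificity
#' when it was substituted or deleted.
#'
#' @param reads list of [PolishedRead-class] objects.
#' @param truth optional list (parallel to `reads`) of lists with elements
#'   `reference` (true base per consensus position, `""` marking positions
#'   that have no reference base) and `isError` (logical per consensus
#'   position).
#' @return a list with `counts` (named totals per method) and, when truth
#'   was given, `sensitivity`, `specificity`, `errors`, `correctBases`.
#' @export
tallyCorrections <- function(reads, truth = NULL) {
  stopifnot(all(vapply(reads, is, logical(1), "PolishedRead")))
  counts <- Reduce(`+`, lapply(reads, correctionCounts),
                   accumulate = FALSE,
                   init = c(POA_SUB = 0L, POA_DEL = 0L, PARALLEL = 0L))
  out <- list(counts = counts)
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(reads))
    corrected <- 0L; errors <- 0L; falseChanges <- 0L; correctBases <- 0L
    for (i in seq_along(reads)) {
      rd <- reads[[i]]
      ref <- truth[[i]]$reference
      isErr <- truth[[i]]$isError
      polished <- strsplit(rd@sequence, "", fixed = TRUE)[[1]]
      final <- rep(NA_character_, length(ref))   # NA = deleted
      final[rd@originalPosition] <- polished
      errPos <- which(isErr)
      okPos <- which(!isErr)
      errors <- errors + length(errPos)
      correctBases <- correctBases + length(okPos)
      corrected <- corrected +
        sum(!is.na(final[errPos]) & final[errPos] == ref[errPos])
      falseChanges <- falseChanges +
        sum(is.na(final[okPos]) | final[okPos] != ref[okPos])
    }
    out$errors <- errors
    out$correctBases <- correctBases
    out$sensitivity <- if (errors > 0) corrected / errors else NA_real_
    out$specificity <- if (correctBases > 0)
      1 - falseChanges / correctBases else NA_real_
  }
  out
}
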