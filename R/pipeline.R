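#' Polish one molecule end to end
#'
#' Builds the POA graph from the consensus read and its subreads, ranks
#' it, computes parallel-base counts for every consensus base, applies the
#' correction rules, extracts calibration features and (when a model is
#' supplied) predicts recalibrated qualities.
#'
#' @param molecule a [CcsMolecule-class].
#' @param model optional [CalibrationModel-class]; without it the original
#'   consensus qualities are carried over (deleted positions dropped).
#' @param scoring a [poaScoring()] list.
#' @param maxPasses optional cap on the number of subreads used (uniform
#'   seeded subsample).
#' @param seed seed for the subsampling draw.
#' @return list with `id`, `polished` ([PolishedRead-class]), `counts`
#'   ([ParallelBases-class]), `features`, `quality` (integer Phred per
#'   polished base) and `graph`.
#' @export
polishMolecule <- function(molecule, model = NULL, scoring = poaScoring(),
                           maxPasses = NULL, seed = 1L) {
  stopifnot(is(molecule, "CcsMolecule"))
  if (length(molecule@subreads) == 0L)
    stop("molecule has no subreads; nothing to polish with")
  mol <- molecule
  if (!is.null(maxPasses) && length(mol@subreads) > maxPasses) {
    set.seed(as.integer(seed))
    keep <- sort(sample(seq_along(mol@subreads), maxPasses))
    mol <- initialize(mol, subreads = mol@subreads[keep],
                      orientation = mol@orientation[keep],
                      ipd = mol@ipd[keep], pw = mol@pw[keep])
  }
  g <- buildPoa(mol@ccs, mol@subreads, mol@orientation, scoring)
  counts <- parallelBasesForRead(g)
  polished <- polishRead(mol@ccs, g, counts, scoring)
  feats <- extractFeatures(polished, mol@ccsQual, counts, mol, g)
  qual <- if (is.null(model)) {
    mol@ccsQual[polished@originalPosition]
  } else {
    predictQuality(model, feats)
  }
  list(id = mol@id, polished = polished, counts = counts,
       features = feats, quality = qual, graph = g)
}

#' Run the polishing pipeline over a set of molecules
#'
#' Streams molecules one at a time (memory stays bounded by a single
#' molecule), polishing and recalibrating each, and optionally writes the
#' result as FASTQ.  Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param molecules list of [CcsMolecule-class], or a fixture directory
#'   written by [writeFixture()] (its `subreads.bam` + `ccs.bam` are read).
#' @param model optional [CalibrationModel-class] (or path to a model
#'   file); `NULL` keeps original qualities.
#' @param out optional FASTQ output path.
#' @param scoring a [poaScoring()] list.
#' @param maxPasses optional subread cap per molecule.
#' @param seed master seed.
#' @return list with `reads` (per-molecule results of [polishMolecule()],
#'   without graphs) and `summary` (molecules, bases, corrections by
#'   method, quality histogram, configuration string).
#' @export
runPolishPipeline <- function(molecules, model = NULL, out = NULL,
                              scoring = poaScoring(), maxPasses = NULL,
                              seed = 1L) {
  if (is.character(molecules) && length(molecules) == 1L) {
    molecules <- readMolecules(file.path(molecules, "subreads.bam"),
                               file.path(molecules, "ccs.bam"))
  }
  if (is.character(model)) model <- readCalibrationModel(model)
  cfg <- sprintf(
    "ccspolish %s scoring=%d,%d,%d maxPasses=%s seed=%d recalibrate=%s",
    as.character(utils::packageVersion("ccspolish")),
    scoring$match, scoring$mismatch, scoring$gap,
    ifelse(is.null(maxPasses), "all", maxPasses), as.integer(seed),
    ifelse(is.null(model), "no", "yes"))

  reads <- vector("list", length(molecules))
  qhist <- integer(93)
  corr <- c(POA_SUB = 0L, POA_DEL = 0L, PARALLEL = 0L)
  bases <- 0L
  for (i in seq_along(molecules)) {
    res <- polishMolecule(molecules[[i]], model = model, scoring = scoring,
                          maxPasses = maxPasses,
                          seed = (as.integer(seed) + i) %% .Machine$integer.max)
    res$graph <- NULL
    reads[[i]] <- res
    corr <- corr + correctionCounts(res$polished)
    bases <- bases + nchar(polishedSequence(res$polished))
    tb <- tabulate(res$quality, nbins = 93)
    qhist <- qhist + tb
  }
  if (!is.null(out)) {
    writePolishedFastq(
      ids = vapply(reads, `[[`, character(1), "id"),
      sequences = vapply(reads, function(r) polishedSequence(r$polished),
                         character(1)),
      qualities = lapply(reads, `[[`, "quality"),
      file = out, header = cfg)
  }
  list(reads = reads,
       summary = list(molecules = length(molecules), bases = bases,
                      corrections = corr, qualityHistogram = qhist,
                      config = cfg))
}
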