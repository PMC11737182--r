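#' Empirical Phred quality from mismatch counts
#'
#' `Q = -10 * log10(mismatches / total)`.  With zero mismatches the
#' one-sided bound `-10 * log10(1 / total)` is returned, flagged with
#' `attr(, "lowerBound") = TRUE`; an observed quality is never reported as
#' infinite.  Summaries that quote a single integer "effective quality"
#' floor this value.
#'
#' @param mismatches non-negative mismatch count.
#' @param total positive total base count (`mismatches <= total`).
#' @return numeric quality (dB), with attribute `lowerBound`.
#' @examples
#' floor(empiricalPhred(934358, 33436615032))
#' @export
empiricalPhred <- function(mismatches, total) {
  if (total <= 0) stop("total must be positive")
  if (mismatches > total) stop("mismatches cannot exceed total")
  if (mismatches < 0) stop("mismatches must be non-negative")
  if (mismatches == 0)
    return(structure(-10 * log10(1 / total), lowerBound = TRUE))
  structure(-10 * log10(mismatches / total), lowerBound = FALSE)
}

#' Base-call accuracy implied by a Phred quality
#'
#' `100 * (1 - 10^(-q/10))` percent; Q1 is 20.6% and Q93 is 99.99999995%.
#'
#' @param q Phred quality (>= 1).
#' @return accuracy percentage.
#' @examples
#' phredToAccuracy(93)
#' @export
phredToAccuracy <- function(q) {
  if (any(q < 1)) stop("q must be >= 1")
  100 * (1 - 10^(-q / 10))
}

#' Error rate as a percentage
#'
#' `100 * errors / total`, rounded half-up to `decimals` digits, as both a
#' number and a formatted string.
#'
#' @param errors,total base counts (`total > 0`).
#' @param decimals digits after the decimal point.
#' @return numeric percentage with the formatted string in
#'   `attr(, "formatted")`.
#' @examples
#' errorRatePercent(263000, 2.7e9)   # 0.010
#' @export
errorRatePercent <- function(errors, total, decimals = 3L) {
  if (total <= 0) stop("total must be positive")
  raw <- 100 * errors / total
  # round half away from zero, not banker's rounding; the epsilon keeps
  # exact halves (e.g. 0.0105) from dropping just below .5 in binary
  f <- 10^decimals
  val <- sign(raw) * floor(abs(raw) * f + 0.5 + 1e-9) / f
  structure(val, formatted = sprintf(paste0("%.", decimals, "f%%"), val))
}

#' Predicted-versus-observed quality calibration report
#'
#' Bins bases by integer predicted quality; per bin the observed quality is
#' [empiricalPhred()] of its mismatch count (zero-mismatch bins carry the
#' one-sided bound).  The maximum validated quality is the largest
#' predicted bin holding at least `minBinCount` bases whose observed
#' quality reaches the prediction.
#'
#' @param predictedQ integer vector of predicted Phred qualities.
#' @param isError logical (or 0/1) vector: is the base a mismatch?
#' @param minBinCount support threshold for the maximum validated quality.
#' @return a [CalibrationReport-class].
#' @examples
#' calibrationReport(rep(20L, 1000), runif(1000) < 0.01, minBinCount = 100)
#' @export
calibrationReport <- function(predictedQ, isError, minBinCount = 1e5) {
  if (length(predictedQ) == 0L) stop("empty input")
  if (length(predictedQ) != length(isError)) stop("inputs differ in length")
  q <- as.integer(predictedQ)
  e <- as.logical(isError)
  qs <- sort(unique(q))
  bins <- data.frame(predictedQ = qs,
                     n = vapply(qs, function(b) sum(q == b), numeric(1)),
                     mismatches = vapply(qs, function(b) sum(e[q == b]),
                                         numeric(1)))
  obs <- mapply(function(m, n) empiricalPhred(m, n),
                bins$mismatches, bins$n, SIMPLIFY = FALSE)
  bins$observedQ <- vapply(obs, as.numeric, numeric(1))
  bins$lowerBound <- vapply(obs, function(x) attr(x, "lowerBound"), logical(1))
  ok <- bins$n >= minBinCount & bins$observedQ >= bins$predictedQ
  maxQ <- if (any(ok)) max(bins$predictedQ[ok]) else NA_integer_
  totQ <- empiricalPhred(sum(bins$mismatches), sum(bins$n))
  new("CalibrationReport", bins = bins,
      maxValidatedQ = as.integer(maxQ),
      totals = c(bases = sum(bins$n), mismatches = sum(bins$mismatches),
                 errorRate = sum(bins$mismatches) / sum(bins$n),
                 observedQ = as.numeric(totQ)),
      minBinCount = as.numeric(minBinCount))
}

setMethod("show", "CalibrationReport", function(object) {
  cat(sprintf(
    "CalibrationReport: %d bins, %.0f bases, overall observed Q %.1f, max validated Q %s\n",
    nrow(object@bins), object@totals["bases"], object@totals["observedQ"],
    ifelse(is.na(object@maxValidatedQ), "NA", object@maxValidatedQ)))
})

#' Report bins of a calibration report
#' @param report a [CalibrationReport-class].
#' @return data.frame of bins.
#' @export
reportBins <- function(report) report@bins

#' Maximum validated quality of a calibration report
#' @param report a [CalibrationReport-class].
#' @return integer (NA when no bin meets the support threshold).
#' @export
maxValidatedQ <- function(report) report@maxValidatedQ

#' Expected number of observed somatic substitutions
#'
#' With `subsPerCell` somatic substitutions per cell and sequencing depth
#' `depth` over a `ploidy`-ploid genome, each variant (present on one of
#' `ploidy` haplotypes) is expected to be sampled `depth / ploidy` times:
#' `subsPerCell * depth / ploidy`.
#'
#' @param subsPerCell somatic substitutions per cell.
#' @param depth mean sequencing depth.
#' @param ploidy genome copy number (default diploid).
#' @return expected count of somatic-variant observations.
#' @examples
#' expectedSomaticObservations(45, 30)  # 675
#' @export
expectedSomaticObservations <- function(subsPerCell, depth, ploidy = 2L) {
  if (subsPerCell < 0 || depth <= 0 || ploidy <= 0)
    stop("arguments must be positive")
  subsPerCell * depth / ploidy
}

#' Substitution counts by trinucleotide context
#'
#' Tallies reference-to-read substitutions stratified by the flanking
#' reference bases, for 1:1-aligned read/reference pairs (e.g. consensus
#' reads before and after polishing).  Germline-variant positions can be
#' masked out.
#'
#' @param readSeqs,refSeqs character vectors of equal-length aligned
#'   sequences.
#' @param germline optional data.frame (`pos`, `alt`) of germline variants
#'   on the shared reference coordinates; matching mismatches are skipped.
#' @return data.frame with columns `context` (reference trinucleotide),
#'   `ref`, `alt`, `count`, covering all 16 contexts x 4 ref x 3 alt.
#' @export
mismatchTable <- function(readSeqs, refSeqs, germline = NULL) {
  stopifnot(length(readSeqs) == length(refSeqs))
  ctx <- expand.grid(prev = .BASES, ref = .BASES, nxt = .BASES,
                     alt = .BASES, stringsAsFactors = FALSE)
  ctx <- ctx[ctx$ref != ctx$alt, ]
  key <- paste(ctx$prev, ctx$ref, ctx$nxt, ctx$alt)
  counts <- stats::setNames(rep(0L, length(key)), key)
  for (i in seq_along(readSeqs)) {
    rd <- strsplit(readSeqs[i], "", fixed = TRUE)[[1]]
    rf <- strsplit(refSeqs[i], "", fixed = TRUE)[[1]]
    if (length(rd) != length(rf))
      stop("read and reference must be 1:1 aligned")
    mism <- which(rd != rf & rd %in% .BASES & rf %in% .BASES)
    if (!is.null(germline) && nrow(germline) > 0) {
      idx <- match(mism, germline$pos)
      mism <- mism[is.na(idx) | rd[mism] != germline$alt[idx]]
    }
    mism <- mism[mism > 1 & mism < length(rf)]   # need both flanks
    if (!length(mism)) next
    k <- paste(rf[mism - 1], rf[mism], rf[mism + 1], rd[mism])
    tb <- table(k)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  data.frame(context = paste0(ctx$prev, ctx$ref, ctx$nxt),
             ref = ctx$ref, alt = ctx$alt, count = unname(counts),
             stringsAsFactors = FALSE)
}
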