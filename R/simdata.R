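#' Default kinetics-generator parameters
#'
#' Per-base inter-pulse durations and pulse widths are drawn from
#' lognormal distributions (frames), the per-read SNR from a normal
#' truncated at `snrMin`.  Bases carrying a sequencing error draw their
#' kinetics from a distribution shifted by `errorShift` on the log scale,
#' so kinetics are an informative (and configurable) error signal.
#'
#' @param ipdMeanlog,ipdSdlog lognormal parameters for inter-pulse
#'   duration.
#' @param pwMeanlog,pwSdlog lognormal parameters for pulse width.
#' @param snrMean,snrSd,snrMin truncated-normal parameters for the
#'   per-read SNR channels.
#' @param errorShift added to the meanlog of error-bearing bases.
#' @return named list of parameters.
#' @export
kineticsParams <- function(ipdMeanlog = 2.0, ipdSdlog = 0.5,
                           pwMeanlog = 1.8, pwSdlog = 0.4,
                           snrMean = 10, snrSd = 2, snrMin = 0.1,
                           errorShift = 0.5) {
  list(ipdMeanlog = ipdMeanlog, ipdSdlog = ipdSdlog,
       pwMeanlog = pwMeanlog, pwSdlog = pwSdlog,
       snrMean = snrMean, snrSd = snrSd, snrMin = snrMin,
       errorShift = errorShift)
}

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.other_base <- function(b) vapply(b, function(x)
  sample(setdiff(.BASES, x), 1L), character(1), USE.NAMES = FALSE)

# Mutate a reference into one sequencing pass; returns the pass characters
# and a flag per emitted base marking sequencing errors (substituted or
# inserted bases).
.mutate_pass <- function(refChars, subRate, insRate, delRate) {
  out <- character(0); isErr <- logical(0)
  for (b in refChars) {
    if (stats::runif(1) < delRate) next
    if (stats::runif(1) < subRate) {
      out <- c(out, .other_base(b)); isErr <- c(isErr, TRUE)
    } else {
      out <- c(out, b); isErr <- c(isErr, FALSE)
    }
    if (stats::runif(1) < insRate) {
      out <- c(out, sample(.BASES, 1L)); isErr <- c(isErr, TRUE)
    }
  }
  if (length(out) == 0L) { out <- sample(.BASES, 1L); isErr <- TRUE }
  list(chars = out, isErr = isErr)
}

#' Simulate one CCS molecule with ground truth
#'
#' Draws a uniform random reference, generates `nPasses` independent
#' sequencing passes with the given per-base substitution/insertion/
#' deletion rates (indels are single-base), alternates pass orientation as
#' in circular sequencing (reverse passes are stored reverse-complemented,
#' with reversed kinetics), attaches lognormal kinetics and truncated-
#' normal SNR, and plants consensus-read errors (substitutions) at
#' `ccsErrorRate` with per-base truth labels.
#'
#' The default per-pass error profile (substitutions 1.5%, insertions 5%,
#' deletions 4%) is skewed towards indels as in real PacBio passes; the
#' default planted consensus error rate of 0.02% mirrors the error-rate
#' magnitude of raw HiFi consensus reads.
#'
#' @param refLength reference length (>= 10).
#' @param nPasses number of passes (>= 1).
#' @param subRate,insRate,delRate per-base per-pass error rates in `[0, 1)`.
#' @param ccsErrorRate rate of planted consensus substitution errors.
#' @param kinetics a [kineticsParams()] list.
#' @param seed integer seed; the molecule is reproducible per seed.
#' @param id molecule identifier.
#' @return a list of class `SimulatedMolecule`: `reference`, `ccs`,
#'   `molecule` (a [CcsMolecule-class]), `truthError` (logical per
#'   consensus base), `seed`.
#' @examples
#' m <- simulateMolecule(50, 5, seed = 7)
#' m$molecule
#' @export
simulateMolecule <- function(refLength = 200L, nPasses = 8L,
                             subRate = 0.015, insRate = 0.05, delRate = 0.04,
                             ccsErrorRate = 2e-4,
                             kinetics = kineticsParams(), seed = 1L,
                             id = "sim/1") {
  if (refLength < 10L) stop("refLength must be >= 10")
  set.seed(as.integer(seed))
  refChars <- strsplit(.rand_seq(refLength), "", fixed = TRUE)[[1]]
  sm <- .sim_core(refChars, nPasses, subRate, insRate, delRate,
                  ccsErrorRate, kinetics, id)
  sm$seed <- as.integer(seed)
  sm
}

# Everything after the reference draw; consumes the current RNG stream.
.sim_core <- function(refChars, nPasses, subRate, insRate, delRate,
                      ccsErrorRate, kinetics, id) {
  if (nPasses < 1L) stop("nPasses must be >= 1")
  rates <- c(subRate, insRate, delRate, ccsErrorRate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  refLength <- length(refChars)
  subreads <- character(nPasses)
  orientation <- character(nPasses)
  ipd <- vector("list", nPasses); pw <- vector("list", nPasses)
  for (p in seq_len(nPasses)) {
    ps <- .mutate_pass(refChars, subRate, insRate, delRate)
    L <- length(ps$chars)
    shift <- ifelse(ps$isErr, kinetics$errorShift, 0)
    ip <- round(stats::rlnorm(L, kinetics$ipdMeanlog + shift,
                              kinetics$ipdSdlog))
    pws <- round(stats::rlnorm(L, kinetics$pwMeanlog + shift,
                               kinetics$pwSdlog))
    s <- paste(ps$chars, collapse = "")
    if (p %% 2L == 0L) {            # even passes read the reverse strand
      orientation[p] <- "-"
      s <- revComp(s)
      ip <- rev(ip); pws <- rev(pws)
    } else orientation[p] <- "+"
    subreads[p] <- s
    ipd[[p]] <- pmax(ip, 0); pw[[p]] <- pmax(pws, 0)
  }
  snr <- pmax(stats::rnorm(4, kinetics$snrMean, kinetics$snrSd),
              kinetics$snrMin)

  ccsChars <- refChars
  errAt <- which(stats::runif(refLength) < ccsErrorRate)
  if (length(errAt)) ccsChars[errAt] <- .other_base(ccsChars[errAt])
  truthError <- logical(refLength); truthError[errAt] <- TRUE
  # crude quality emulation: near-max quality everywhere, with planted
  # errors overestimated as in raw consensus reads
  qual <- rep(93L, refLength)
  wobble <- which(stats::runif(refLength) < 0.1)
  qual[wobble] <- sample(60:92, length(wobble), replace = TRUE)

  mol <- new("CcsMolecule", id = id, ccs = paste(ccsChars, collapse = ""),
             ccsQual = qual, subreads = subreads, orientation = orientation,
             ipd = ipd, pw = pw, snr = snr)
  structure(list(reference = paste(refChars, collapse = ""),
                 ccs = mol@ccs, molecule = mol, truthError = truthError,
                 seed = NA_integer_),
            class = "SimulatedMolecule")
}

#' Simulate a cohort of molecules sharing a reference
#'
#' All molecules derive from one reference.  Germline variants are planted
#' at `germlineRate` per base as heterozygous substitutions: each molecule
#' carries the ALT allele with probability 1/2.  Somatic variants are
#' planted at `somaticRate` per molecule-base, each on a single molecule
#' only.  Per-molecule RNG streams are derived from `(seed, molecule
#' index)` so the cohort is reproducible and order-independent.
#'
#' @param nMolecules number of molecules (>= 1).
#' @param refLength shared reference length.
#' @param germlineRate per-base probability of a germline variant site.
#' @param somaticRate per-molecule-base probability of a somatic variant.
#' @param seed master seed.
#' @param ... passed to [simulateMolecule()] (rates, passes, kinetics).
#' @return list with `reference`, `molecules` (list of
#'   `SimulatedMolecule`), `germline` (data.frame `pos`, `ref`, `alt`),
#'   `somatic` (data.frame `molecule`, `pos`, `ref`, `alt`), `truth`
#'   (data.frame per consensus base: `molecule`, `pos`, `refBase`,
#'   `ccsBase`, `label`).
#' @export
simulateCohort <- function(nMolecules, refLength = 200L,
                           germlineRate = 0.001, somaticRate = 0,
                           seed = 1L, ...) {
  if (nMolecules < 1L) stop("nMolecules must be >= 1")
  set.seed(as.integer(seed))
  refChars <- strsplit(.rand_seq(refLength), "", fixed = TRUE)[[1]]
  gpos <- which(stats::runif(refLength) < germlineRate)
  galt <- if (length(gpos)) .other_base(refChars[gpos]) else character(0)
  germline <- data.frame(pos = gpos, ref = refChars[gpos], alt = galt,
                         stringsAsFactors = FALSE)

  molecules <- vector("list", nMolecules)
  somatic <- list()
  truth <- list()
  for (i in seq_len(nMolecules)) {
    molSeed <- (as.integer(seed) * 1009L + i * 7919L) %% .Machine$integer.max
    set.seed(molSeed)
    hap <- refChars
    if (length(gpos)) {
      carry <- stats::runif(length(gpos)) < 0.5
      hap[gpos[carry]] <- galt[carry]
    }
    spos <- which(stats::runif(refLength) < somaticRate)
    spos <- setdiff(spos, gpos)
    if (length(spos)) {
      salt <- .other_base(hap[spos])
      hap[spos] <- salt
      somatic[[length(somatic) + 1L]] <-
        data.frame(molecule = i, pos = spos, ref = refChars[spos],
                   alt = salt, stringsAsFactors = FALSE)
    }
    seqSeed <- (molSeed + 31337L) %% .Machine$integer.max
    sm <- .simulate_from_reference(hap, seed = seqSeed,
                                   id = sprintf("sim/%d", i), ...)
    molecules[[i]] <- sm
    ccsChars <- strsplit(sm$ccs, "", fixed = TRUE)[[1]]
    truth[[i]] <- data.frame(molecule = i, pos = seq_len(refLength),
                             refBase = hap, ccsBase = ccsChars,
                             label = as.integer(!sm$truthError),
                             stringsAsFactors = FALSE)
  }
  list(reference = paste(refChars, collapse = ""),
       molecules = molecules, germline = germline,
       somatic = if (length(somatic)) do.call(rbind, somatic)
       else data.frame(molecule = integer(), pos = integer(),
                       ref = character(), alt = character()),
       truth = do.call(rbind, truth))
}

# simulateMolecule with a fixed (possibly variant-carrying) reference.
.simulate_from_reference <- function(refChars, seed, id, nPasses = 8L,
                                     subRate = 0.015, insRate = 0.05,
                                     delRate = 0.04, ccsErrorRate = 2e-4,
                                     kinetics = kineticsParams()) {
  set.seed(as.integer(seed))
  sm <- .sim_core(refChars, nPasses, subRate, insRate, delRate,
                  ccsErrorRate, kinetics, id)
  sm$seed <- as.integer(seed)
  sm
}

#' Synthetic feature generator with known per-base error probability
#'
#' Generates calibration-model features whose true error probability is a
#' known function of the parallel-count fraction and the original
#' consensus quality:  each base draws a pass depth and an agreement level,
#' its parallel counts from a binomial on that agreement, and its true
#' error probability from a logistic function of the supporting-count
#' fraction and quality; the 0/1 label is then drawn from that
#' probability.  Used to test parameter recovery and Phred calibration of
#' the model.
#'
#' @param n number of bases.
#' @param seed RNG seed.
#' @param errorScale stratum control (default 1): scales the Beta
#'   parameters of the per-base agreement level, so larger values produce
#'   noisier parallel counts and therefore higher true error
#'   probabilities; error-rate strata generated this way are visible to a
#'   fixed model through its features.
#' @return list with `features` (matrix with [featureSchema()] columns),
#'   `labels` (0/1), `trueP` (true per-base error probability) and
#'   `molecule` (synthetic molecule ids for split-by-molecule training).
#' @export
simulateFeatureSet <- function(n, seed = 1L, errorScale = 1) {
  set.seed(as.integer(seed))
  depth <- sample(6:14, n, replace = TRUE)
  agree <- stats::rbeta(n, 8, 2 * errorScale)    # per-base agreement level
  own <- stats::rbinom(n, depth, agree)
  rest <- depth - own
  alt <- vapply(rest, function(r) {
    if (r == 0) return(c(0L, 0L))
    a <- stats::rbinom(1L, r, 0.7); c(a, r - a)
  }, integer(2))
  cur <- sample(.BASES, n, replace = TRUE)
  altBase <- .other_base(cur)
  prev <- sample(.BASES, n, replace = TRUE)
  nxt <- sample(.BASES, n, replace = TRUE)
  qual <- sample(20:93, n, replace = TRUE)

  frac <- own / depth
  # centred so the bulk of bases sit at a few percent error (Q ~ 6-16),
  # falling with the supporting fraction and the nominal quality
  trueP <- pmin(stats::plogis(-2.5 - 8 * (frac - 0.8) -
                                0.015 * (qual - 56)), 0.95)
  labels <- as.integer(stats::runif(n) >= trueP)   # 1 = correct

  cmat <- matrix(0L, n, 5L, dimnames = list(NULL, .ALPHABET))
  cmat[cbind(seq_len(n), match(cur, .ALPHABET))] <- own
  cmat[cbind(seq_len(n), match(altBase, .ALPHABET))] <- alt[1L, ]
  cmat[, "-"] <- alt[2L, ]
  ipd <- stats::rlnorm(n, 2.0 + 0.4 * (labels == 0L), 0.5)
  pw <- stats::rlnorm(n, 1.8 + 0.4 * (labels == 0L), 0.4)
  snr <- matrix(pmax(stats::rnorm(4L * n, 10, 2), 0.1), ncol = 4L)

  X <- cbind(.one_hot(prev), .one_hot(cur), .one_hot(nxt), qual,
             cmat, depth, cmat / depth, ipd, 1, pw, 1, snr)
  colnames(X) <- featureSchema()
  list(features = X, labels = labels, trueP = trueP,
       molecule = rep(seq_len(max(1L, n %/% 100L)), length.out = n))
}

#' Write a simulated cohort as a standard-format fixture directory
#'
#' Emits `subreads.bam` (unaligned, with `ip`/`pw` per-base kinetics and
#' `sn` per-read SNR tags), `ccs.bam` (consensus reads with qualities),
#' `ref.fasta`, `germline.vcf` and `truth.tsv`, the formats the readers in
#' this package consume; records round-trip bit-exactly through
#' [readMolecules()].
#'
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subSam <- file.path(dir, "subreads.sam")
  ccsSam <- file.path(dir, "ccs.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown", "@RG\tID:sim\tPL:PACBIO")
  sub <- hdr; ccs <- hdr
  for (i in seq_along(cohort$molecules)) {
    mol <- cohort$molecules[[i]]$molecule
    zmw <- sub("^.*/", "", mol@id)
    off <- 0L
    for (s in seq_along(mol@subreads)) {
      sq <- mol@subreads[s]
      flag <- if (mol@orientation[s] == "-") 20L else 4L
      tags <- c(
        sprintf("ip:B:S,%s", paste(mol@ipd[[s]], collapse = ",")),
        sprintf("pw:B:S,%s", paste(mol@pw[[s]], collapse = ",")),
        sprintf("sn:B:f,%s", paste(format(mol@snr, trim = TRUE), collapse = ",")),
        sprintf("zm:i:%s", zmw))
      sub <- c(sub, paste(c(sprintf("%s/%d_%d", mol@id, off,
                                    off + nchar(sq)),
                            flag, "*", 0L, 255L, "*", "*", 0L, 0L,
                            sq, "*", tags), collapse = "\t"))
      off <- off + nchar(sq)
    }
    qual <- rawToChar(as.raw(33L + mol@ccsQual))
    ccs <- c(ccs, paste(c(sprintf("%s/ccs", mol@id), 4L, "*", 0L, 255L,
                          "*", "*", 0L, 0L, mol@ccs, qual,
                          sprintf("zm:i:%s", zmw)), collapse = "\t"))
  }
  writeLines(sub, subSam); writeLines(ccs, ccsSam)
  Rsamtools::asBam(subSam, file.path(dir, "subreads"), overwrite = TRUE,
                   indexDestination = FALSE)
  Rsamtools::asBam(ccsSam, file.path(dir, "ccs"), overwrite = TRUE,
                   indexDestination = FALSE)
  unlink(c(subSam, ccsSam))

  ref <- Biostrings::DNAStringSet(stats::setNames(cohort$reference, "ref"))
  Biostrings::writeXStringSet(ref, file.path(dir, "ref.fasta"))

  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=ref>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(cohort$germline) > 0) {
    vcf <- c(vcf, sprintf("ref\t%d\t.\t%s\t%s\t.\tPASS\t.",
                          cohort$germline$pos, cohort$germline$ref,
                          cohort$germline$alt))
  }
  writeLines(vcf, file.path(dir, "germline.vcf"))

  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
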