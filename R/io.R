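#' Read CCS molecules and their subreads
#'
#' Reads a subread BAM (or SAM, converted on the fly) and a matching CCS
#' BAM, groups subreads by ZMW (`movie/zmw` parsed from the read names),
#' and returns one [CcsMolecule-class] per consensus read.  PacBio
#' per-base kinetics (`ip`, `pw`) and per-read SNR (`sn`) tags are
#' attached when present and flagged as missing otherwise; orientation is
#' taken from the reverse-strand flag, falling back to the alternating
#' forward/reverse pass convention when flags are unset.
#'
#' @param subreadFile path to the subread BAM/SAM.
#' @param ccsFile path to the CCS BAM/SAM (qualities required).
#' @return list of [CcsMolecule-class]; CCS reads with no subreads are
#'   skipped with a warning.
#' @export
readMolecules <- function(subreadFile, ccsFile) {
  subs <- .scan_pacbio(subreadFile, tags = c("ip", "pw", "sn"))
  ccs <- .scan_pacbio(ccsFile, tags = character(0), qualities = TRUE)

  subId <- sub("/[0-9]+_[0-9]+$", "", subs$qname)
  ccsId <- sub("/ccs$", "", ccs$qname)

  out <- list()
  for (k in seq_along(ccsId)) {
    id <- ccsId[k]
    idx <- which(subId == id)
    if (!length(idx)) {
      warning("CCS read ", id, " has no subreads; skipped")
      next
    }
    flags <- subs$flag[idx]
    strand <- ifelse(bitwAnd(flags, 16L) > 0L, "-", "+")
    if (all(strand == "+") && length(idx) > 1L)
      strand <- rep(c("+", "-"), length.out = length(idx))
    ipd <- lapply(idx, function(i) {
      v <- subs$tag$ip[[i]]
      if (is.null(v)) numeric(0) else as.numeric(v)
    })
    pw <- lapply(idx, function(i) {
      v <- subs$tag$pw[[i]]
      if (is.null(v)) numeric(0) else as.numeric(v)
    })
    snr <- subs$tag$sn[[idx[1]]]
    if (is.null(snr) || length(snr) != 4L) snr <- rep(0, 4)
    out[[length(out) + 1L]] <- new(
      "CcsMolecule", id = id, ccs = ccs$seq[k],
      ccsQual = pmin(pmax(ccs$qual[[k]], 1L), 93L),
      subreads = subs$seq[idx], orientation = strand,
      ipd = ipd, pw = pw, snr = as.numeric(snr))
  }
  out
}

.scan_pacbio <- function(file, tags, qualities = FALSE) {
  if (grepl("\\.sam$", file)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  what <- c("qname", "flag", "seq", if (qualities) "qual")
  p <- Rsamtools::ScanBamParam(what = what, tag = tags)
  r <- Rsamtools::scanBam(file, param = p)[[1]]
  res <- list(qname = r$qname, flag = r$flag,
              seq = as.character(r$seq), tag = r$tag)
  if (qualities)
    res$qual <- lapply(as(r$qual, "IntegerList"), as.integer)
  res
}

#' Read a germline-variant mask from a VCF
#'
#' @param file path to a (plain or bgzipped) VCF.
#' @return data.frame with columns `pos` and `alt` (first ALT allele of
#'   each record), as consumed by [makeLabels()] and [mismatchTable()].
#' @export
readGermlineVcf <- function(file) {
  vcf <- VariantAnnotation::readVcf(file)
  alt <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                function(a) if (length(a)) a[[1]] else NA_character_,
                character(1))
  data.frame(pos = GenomicRanges::start(SummarizedExperiment::rowRanges(vcf)),
             alt = unname(alt), stringsAsFactors = FALSE)
}

#' Write polished reads as FASTQ
#'
#' Phred+33 qualities clamped to [1, 93]; deterministic input order.
#'
#' @param ids read identifiers.
#' @param sequences polished sequences.
#' @param qualities list of integer Phred vectors, one per read.
#' @param file output FASTQ path.
#' @param header optional comment lines describing tool version and
#'   configuration, written to `<file>.header.txt` alongside the FASTQ
#'   (FASTQ itself has no header record).
#' @return `file`, invisibly.
#' @export
writePolishedFastq <- function(ids, sequences, qualities, file,
                               header = NULL) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(qualities))
  qs <- vapply(qualities, function(q)
    rawToChar(as.raw(33L + pmin(pmax(as.integer(q), 1L), 93L))),
    character(1))
  bad <- nchar(sequences) != nchar(qs)
  if (any(bad)) stop("quality length must equal sequence length")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(sequences, ids)),
    Biostrings::PhredQuality(qs))
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, file),
    # cosmetic: the writer notes it drops (empty) mcols on the way out
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.null(header)) writeLines(header, paste0(file, ".header.txt"))
  invisible(file)
}

#' Read back a polished FASTQ
#'
#' @param file FASTQ path.
#' @return list with `ids`, `sequences`, `qualities` (integer lists).
#' @export
readPolishedFastq <- function(file) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(file),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(ids = names(x), sequences = as.character(x),
       qualities = lapply(as(Biostrings::quality(x), "IntegerList"),
                          as.integer))
}

#' Per-base labels for aligned reads in a BAM
#'
#' Walks each aligned read's 1:1-aligned (`M`/`=`/`X`) bases against the
#' reference and labels them with [makeLabels()]; insertions and clips
#' carry no reference base and are excluded.  Unaligned reads are skipped
#' with a message.
#'
#' @param bamFile coordinate-aligned BAM.
#' @param refFasta reference FASTA.
#' @param germline optional germline mask data.frame (`pos`, `alt`), e.g.
#'   from [readGermlineVcf()].
#' @return data.frame: `qname`, `queryPos`, `refPos`, `readBase`,
#'   `refBase`, `label`.
#' @export
labelsFromBam <- function(bamFile, refFasta, germline = NULL) {
  ref <- Biostrings::readDNAStringSet(refFasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq"))
  r <- Rsamtools::scanBam(bamFile, param = p)[[1]]
  out <- list()
  for (i in seq_along(r$qname)) {
    if (is.na(r$pos[i]) || bitwAnd(r$flag[i], 4L) > 0L) {
      message("read ", r$qname[i], " is unaligned; skipped")
      next
    }
    ops <- GenomicAlignments::explodeCigarOps(r$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(r$cigar[i])[[1]]
    qpos <- 1L; rpos <- r$pos[i]
    qidx <- integer(0); ridx <- integer(0)
    for (k in seq_along(ops)) {
      op <- ops[k]; ln <- lens[k]
      if (op %in% c("M", "=", "X")) {
        qidx <- c(qidx, qpos:(qpos + ln - 1L))
        ridx <- c(ridx, rpos:(rpos + ln - 1L))
        qpos <- qpos + ln; rpos <- rpos + ln
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + ln
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + ln
      }
    }
    rdB <- strsplit(as.character(r$seq[i]), "", fixed = TRUE)[[1]][qidx]
    rfB <- strsplit(as.character(ref[[as.character(r$rname[i])]]),
                    "", fixed = TRUE)[[1]][ridx]
    out[[length(out) + 1L]] <- data.frame(
      qname = r$qname[i], queryPos = qidx, refPos = ridx,
      readBase = rdB, refBase = rfB,
      label = makeLabels(rdB, rfB, ridx, germline),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(qname = character(), queryPos = integer(),
                      refPos = integer(), readBase = character(),
                      refBase = character(), label = integer()))
  do.call(rbind, out)
}
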