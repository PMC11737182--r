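.FEATURE_SYMS <- c("A", "C", "G", "T", "pad")

.one_hot <- function(sym) {
  m <- matrix(0, nrow = length(sym), ncol = 5L)
  m[cbind(seq_along(sym), match(sym, .FEATURE_SYMS))] <- 1
  m
}

#' Per-base feature schema
#'
#' Column names of the calibration feature matrix: one-hot trinucleotide
#' context (previous/current/next base, 5 symbols each including an end
#' pad), the original CCS quality, raw parallel-base counts plus their
#' total, the same counts as fractions of the total (depth invariance),
#' mean subread inter-pulse duration and pulse width with
#' presence-indicator bits (missing kinetics are encoded as 0 + indicator
#' 0), and the four per-read SNR channels.
#'
#' @return character vector of feature names.
#' @export
featureSchema <- function() {
  c(paste0("prev", .FEATURE_SYMS), paste0("cur", .FEATURE_SYMS),
    paste0("next", .FEATURE_SYMS), "ccsQual",
    paste0("cnt", c("A", "C", "G", "T", "Gap")), "cntTotal",
    paste0("frac", c("A", "C", "G", "T", "Gap")),
    "meanIpd", "ipdPresent", "meanPw", "pwPresent",
    paste0("snr", c("A", "C", "G", "T")))
}

#' Extract calibration features for a polished read
#'
#' One feature vector per polished base: trinucleotide context of the
#' polished sequence (ends padded), the original consensus quality of the
#' base, the parallel-base counts at its locus, subread kinetics averaged
#' over the subread bases whose node matches the base's backbone node
#' (matched bases only), and the per-read SNR.
#'
#' @param polished a [PolishedRead-class].
#' @param ccsQual integer Phred qualities of the original consensus read.
#' @param counts the [ParallelBases-class] used for polishing (indexed by
#'   original consensus position).
#' @param molecule the [CcsMolecule-class] providing subreads and kinetics.
#' @param graph the [PoaGraph-class] from [buildPoa()] (supplies the
#'   per-subread alignments and the backbone).
#' @return numeric matrix, one row per polished base, columns
#'   [featureSchema()].
#' @export
extractFeatures <- function(polished, ccsQual, counts, molecule, graph) {
  stopifnot(is(polished, "PolishedRead"), is(counts, "ParallelBases"),
            is(molecule, "CcsMolecule"), is(graph, "PoaGraph"))
  orig <- polished@originalPosition
  if (any(ccsQual < 1L | ccsQual > 93L))
    stop("consensus qualities must lie in [1, 93]")
  bb <- backbone(graph)
  if (length(bb) != length(ccsQual) || nrow(counts@counts) != length(ccsQual))
    stop("inputs are not indexed consistently with the consensus read")

  chars <- strsplit(polished@sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  prev <- c("pad", chars[-n]); nxt <- c(chars[-1], "pad")
  sym <- function(x) ifelse(x %in% .BASES, x, "pad")

  # per-node kinetic sums over matched subread bases
  nn <- numNodes(graph)
  ipdSum <- numeric(nn); ipdN <- numeric(nn)
  pwSum <- numeric(nn); pwN <- numeric(nn)
  for (i in seq_along(molecule@subreads)) {
    aln <- graph@alignments[[i + 1L]]
    ipd <- molecule@ipd[[i]]; pw <- molecule@pw[[i]]
    if (molecule@orientation[i] == "-") { ipd <- rev(ipd); pw <- rev(pw) }
    sel <- !is.na(aln[, 1]) & !is.na(aln[, 2])
    nodes <- aln[sel, 1]; poss <- aln[sel, 2]
    if (length(ipd)) {
      ipdSum[nodes] <- ipdSum[nodes] + ipd[poss]
      ipdN[nodes] <- ipdN[nodes] + 1
    }
    if (length(pw)) {
      pwSum[nodes] <- pwSum[nodes] + pw[poss]
      pwN[nodes] <- pwN[nodes] + 1
    }
  }

  node <- bb[orig]
  meanIpd <- ifelse(ipdN[node] > 0, ipdSum[node] / pmax(ipdN[node], 1), 0)
  meanPw <- ifelse(pwN[node] > 0, pwSum[node] / pmax(pwN[node], 1), 0)
  cmat <- counts@counts[orig, , drop = FALSE]
  tot <- rowSums(cmat)
  frac <- cmat / pmax(tot, 1)

  X <- cbind(.one_hot(sym(prev)), .one_hot(sym(chars)), .one_hot(sym(nxt)),
             ccsQual[orig], cmat, tot, frac,
             meanIpd, as.numeric(ipdN[node] > 0),
             meanPw, as.numeric(pwN[node] > 0),
             matrix(molecule@snr, nrow = n, ncol = 4L, byrow = TRUE))
  colnames(X) <- featureSchema()
  X
}

#' Label read bases against a reference
#'
#' Label 0 (error) for a base that differs from the reference and is not
#' explained by a germline variant; label 1 (correct) otherwise.  Only
#' 1:1-aligned bases can be labelled; insertions and clipped bases have no
#' reference base and must be excluded upstream.
#'
#' @param readBases,refBases character vectors of aligned bases (equal
#'   length).
#' @param refPos integer reference positions of the aligned pairs.
#' @param germline optional data.frame with columns `pos` and `alt`; a
#'   mismatch whose read base equals the germline ALT at that position is
#'   labelled 1.
#' @return integer vector of 0/1 labels.
#' @export
makeLabels <- function(readBases, refBases, refPos = seq_along(refBases),
                       germline = NULL) {
  stopifnot(length(readBases) == length(refBases),
            length(refPos) == length(readBases))
  mism <- readBases != refBases
  if (!is.null(germline) && nrow(germline) > 0) {
    idx <- match(refPos, germline$pos)
    masked <- !is.na(idx) & readBases == germline$alt[idx]
    mism <- mism & !masked
  }
  as.integer(!mism)
}

#' Train the base-quality calibration model
#'
#' Fits a feed-forward network (two ReLU hidden layers by default, sigmoid
#' output) or a logistic-regression baseline to 0/1 correctness labels,
#' minimising (optionally class-weighted) binary cross-entropy with Adam
#' and early stopping on a held-out split.  The held-out split is taken by
#' molecule when molecule ids are supplied, so bases of one read never
#' straddle the split.  When class weighting is used, predictions are
#' prior-corrected back to calibrated probabilities (see
#' [predictProbability()]).
#'
#' @param features numeric matrix with columns [featureSchema()] (or any
#'   fixed schema).
#' @param labels integer 0/1 vector (1 = correct); both classes must be
#'   present.
#' @param molecule optional molecule id per example, used for the held-out
#'   split.
#' @param architecture `"mlp"` or `"logistic"`.
#' @param hidden hidden-layer sizes for the network.
#' @param epochs,lr,batchSize training hyperparameters.
#' @param classWeights `"balanced"` (inverse class frequency), `NULL`
#'   (unweighted), or a numeric length-2 vector (class 0, class 1).
#' @param valFraction fraction held out for early stopping.
#' @param seed RNG seed; the fit is bit-reproducible given the seed.
#' @param patience early-stopping patience in epochs.
#' @param verbose print per-epoch held-out loss.
#' @return a [CalibrationModel-class]; `model@params$metrics` records the
#'   held-out binary cross-entropy and a predicted-vs-observed reliability
#'   table.
#' @export
trainCalibrationModel <- function(features, labels, molecule = NULL,
                                  architecture = c("mlp", "logistic"),
                                  hidden = c(64L, 32L), epochs = 40L,
                                  lr = 2e-3, batchSize = 512L,
                                  classWeights = "balanced",
                                  valFraction = 0.1, seed = 1L,
                                  patience = 5L, verbose = FALSE) {
  architecture <- match.arg(architecture)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("single-class training set")
  seed <- as.integer(seed)

  cw <- if (is.null(classWeights)) c(1, 1)
  else if (identical(classWeights, "balanced")) {
    n0 <- sum(y == 0L); n1 <- sum(y == 1L)
    c(length(y) / (2 * n0), length(y) / (2 * n1))
  } else as.numeric(classWeights)
  w <- ifelse(y == 1L, cw[2], cw[1])

  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  X <- sweep(sweep(features, 2, ctr), 2, scl, `/`)

  set.seed(seed)
  if (is.null(molecule)) {
    holdout <- sample.int(nrow(X)) <= valFraction * nrow(X)
  } else {
    ids <- unique(molecule)
    vi <- sample(ids, max(1L, round(valFraction * length(ids))))
    holdout <- molecule %in% vi
  }
  if (all(holdout) || !any(holdout)) stop("degenerate held-out split")

  if (architecture == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X[!holdout, , drop = FALSE]),
                                           y[!holdout],
                                           weights = w[!holdout],
                                           family = stats::binomial()))
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0          # aliased one-hot columns drop out
    params <- list(coef = coef)
    arch <- "logistic"
    pva <- as.numeric(1 / (1 + exp(-(cbind(1, X[holdout, , drop = FALSE]) %*%
                                       params$coef))))
  } else {
    attr(X, "hidden") <- as.integer(hidden)
    best <- .mlp_train(X, y, w, holdout, epochs = epochs, lr = lr,
                       batchSize = as.integer(batchSize), seed = seed,
                       patience = patience, verbose = verbose)
    params <- list(W = best$params$W, b = best$params$b)
    arch <- paste0("mlp:", paste(hidden, collapse = ","))
    pva <- .mlp_predict(best$params, X[holdout, , drop = FALSE])
  }
  heldLoss <- .bce(pva, y[holdout], w[holdout])
  pcorr <- .prior_correct(pva, cw)
  qpred <- .prob_to_q(pcorr)
  tb <- table(qpred)
  rel <- data.frame(predictedQ = as.integer(names(tb)), n = as.integer(tb))
  rel$mismatches <- vapply(rel$predictedQ, function(q)
    sum(y[holdout][qpred == q] == 0L), numeric(1))
  params$metrics <- list(heldOutLoss = heldLoss, reliability = rel)

  new("CalibrationModel", architecture = arch, params = params,
      featureNames = colnames(features), center = ctr, scale = scl,
      classWeights = cw, seed = seed, version = "ccspolish-calibration-1")
}

.prior_correct <- function(p, cw) {
  # invert the shift induced by class-weighted training so the output is a
  # calibrated probability again: p_w = w1*pi / (w1*pi + w0*(1-pi))
  a <- p / cw[2]; b <- (1 - p) / cw[1]
  a / (a + b)
}

.prob_to_q <- function(p) {
  perr <- pmax(1 - p, 1e-12)
  pmin(pmax(as.integer(round(-10 * log10(perr))), 1L), 93L)
}

#' Predict the probability that each base is correct
#'
#' @param model a [CalibrationModel-class].
#' @param features feature matrix with the schema the model was trained on.
#' @return numeric vector of calibrated probabilities in (0, 1).
#' @export
predictProbability <- function(model, features) {
  stopifnot(is(model, "CalibrationModel"))
  if (!identical(colnames(features), model@featureNames))
    stop("feature schema mismatch")
  X <- sweep(sweep(features, 2, model@center), 2, model@scale, `/`)
  p <- if (model@architecture == "logistic") {
    as.numeric(1 / (1 + exp(-(cbind(1, X) %*% model@params$coef))))
  } else {
    .mlp_predict(model@params, X)
  }
  .prior_correct(p, model@classWeights)
}

#' Predict per-base Phred qualities
#'
#' Converts the predicted correctness probability `p` to
#' `Q = round(-10 * log10(1 - p))`, clamped to the Phred range 1-93.
#'
#' @inheritParams predictProbability
#' @return integer vector of Phred qualities in `[1, 93]`.
#' @examples
#' \dontrun{predictQuality(model, features)}
#' @export
predictQuality <- function(model, features) {
  .prob_to_q(predictProbability(model, features))
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (%s): %d features, seed %d, version %s\n",
              object@architecture, length(object@featureNames),
              object@seed, object@version))
})

#' Serialise / load a calibration model
#'
#' The model is written as a single JSON file carrying the schema version,
#' feature names, normalisation statistics, class weights and weights.
#' Loading refuses files whose version or feature schema does not match.
#'
#' @param model a [CalibrationModel-class].
#' @param file path to write to / read from.
#' @return `saveCalibrationModel` returns `file` invisibly;
#'   `readCalibrationModel` returns the model.
#' @export
saveCalibrationModel <- function(model, file) {
  stopifnot(is(model, "CalibrationModel"))
  obj <- list(version = model@version, architecture = model@architecture,
              featureNames = model@featureNames,
              center = unname(model@center), scale = unname(model@scale),
              classWeights = model@classWeights, seed = model@seed)
  if (model@architecture == "logistic") {
    obj$coef <- unname(model@params$coef)
  } else {
    obj$W <- lapply(model@params$W, unname)
    obj$b <- lapply(model@params$b, unname)
  }
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname saveCalibrationModel
#' @export
readCalibrationModel <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$version, "ccspolish-calibration-1"))
    stop("unsupported calibration-model version: ", obj$version)
  params <- if (obj$architecture == "logistic") list(coef = obj$coef)
  else list(W = lapply(obj$W, as.matrix), b = obj$b)
  new("CalibrationModel", architecture = obj$architecture, params = params,
      featureNames = obj$featureNames,
      center = stats::setNames(obj$center, obj$featureNames),
      scale = stats::setNames(obj$scale, obj$featureNames),
      classWeights = obj$classWeights, seed = as.integer(obj$seed),
      version = obj$version)
}
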