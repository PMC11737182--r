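test_that("feature extraction pads read ends and averages constant kinetics", {
  truth <- "ACGTTGCA"
  mol <- new("CcsMolecule", id = "m/1", ccs = truth,
             ccsQual = rep(90L, 8), subreads = rep(truth, 3),
             orientation = rep("+", 3),
             ipd = rep(list(rep(10, 8)), 3), pw = rep(list(rep(8, 8)), 3),
             snr = c(9, 10, 11, 12))
  g <- buildPoa(mol@ccs, mol@subreads, mol@orientation)
  counts <- parallelBasesForRead(g)
  pr <- polishRead(mol@ccs, g, counts)
  X <- extractFeatures(pr, mol@ccsQual, counts, mol, g)
  expect_identical(dim(X), c(8L, length(featureSchema())))
  expect_identical(colnames(X), featureSchema())
  expect_identical(X[1, "prevpad"], c(prevpad = 1))
  expect_identical(X[8, "nextpad"], c(nextpad = 1))
  expect_true(all(X[, "meanIpd"] == 10))
  expect_true(all(X[, "meanPw"] == 8))
  expect_true(all(X[, "ipdPresent"] == 1))
  expect_true(all(X[, "snrA"] == 9 & X[, "snrT"] == 12))
})

test_that("kinetics averages match a position-tracking oracle", {
  set.seed(107)
  sm <- simulateMolecule(refLength = 40, nPasses = 5, seed = 17)
  mol <- sm$molecule
  g <- buildPoa(mol@ccs, mol@subreads, mol@orientation)
  counts <- parallelBasesForRead(g)
  pr <- polishRead(mol@ccs, g, counts)
  X <- extractFeatures(pr, mol@ccsQual, counts, mol, g)
  # oracle: walk each subread alignment and pool ipd values per backbone node
  bb <- backbone(g)
  for (j in sample(seq_len(nrow(X)), 10)) {
    node <- bb[pr@originalPosition[j]]
    vals <- c()
    for (i in seq_along(mol@subreads)) {
      aln <- g@alignments[[i + 1]]
      ipd <- mol@ipd[[i]]
      if (mol@orientation[i] == "-") ipd <- rev(ipd)
      hit <- which(!is.na(aln[, 1]) & !is.na(aln[, 2]) & aln[, 1] == node)
      if (length(hit)) vals <- c(vals, ipd[aln[hit, 2]])
    }
    expected <- if (length(vals)) mean(vals) else 0
    expect_equal(unname(X[j, "meanIpd"]), expected)
  }
})

test_that("missing kinetics produce sentinel features with presence bits off", {
  mol <- new("CcsMolecule", id = "m/2", ccs = "ACGTACGT",
             ccsQual = rep(80L, 8), subreads = rep("ACGTACGT", 2),
             orientation = c("+", "-"),
             ipd = list(numeric(0), numeric(0)),
             pw = list(numeric(0), numeric(0)), snr = rep(0, 4))
  mol@subreads[2] <- revComp(mol@subreads[2])
  g <- buildPoa(mol@ccs, mol@subreads, mol@orientation)
  counts <- parallelBasesForRead(g)
  pr <- polishRead(mol@ccs, g, counts)
  X <- extractFeatures(pr, mol@ccsQual, counts, mol, g)
  expect_true(all(X[, "meanIpd"] == 0))
  expect_true(all(X[, "ipdPresent"] == 0))
})

test_that("labels flag non-germline mismatches only", {
  rd <- c("A", "C", "G", "T")
  rf <- c("A", "C", "G", "T")
  expect_identical(makeLabels(rd, rf), rep(1L, 4))
  rd2 <- c("A", "T", "G", "T")
  germ <- data.frame(pos = 2L, alt = "T")
  expect_identical(makeLabels(rd2, rf, germline = germ), rep(1L, 4))
  expect_identical(makeLabels(rd2, rf), c(1L, 0L, 1L, 1L))
  germWrongAlt <- data.frame(pos = 2L, alt = "G")
  expect_identical(makeLabels(rd2, rf, germline = germWrongAlt),
                   c(1L, 0L, 1L, 1L))
})

test_that("training is reproducible and refuses degenerate input", {
  fs <- simulateFeatureSet(4000, seed = 9)
  m1 <- trainCalibrationModel(fs$features, fs$labels, epochs = 3, seed = 21)
  m2 <- trainCalibrationModel(fs$features, fs$labels, epochs = 3, seed = 21)
  expect_identical(m1@params$W, m2@params$W)
  expect_identical(m1@params$b, m2@params$b)
  expect_identical(predictQuality(m1, fs$features[1:50, ]),
                   predictQuality(m2, fs$features[1:50, ]))
  expect_error(trainCalibrationModel(fs$features, rep(1L, nrow(fs$features))),
               "single-class")
})

test_that("a separable problem is learned almost perfectly", {
  set.seed(113)
  fs <- simulateFeatureSet(6000, seed = 33)
  X <- fs$features
  score <- X[, "fracA"] + X[, "meanIpd"] / 20
  keep <- abs(score - 0.6) > 0.05            # margin-separated classes
  X <- X[keep, ]
  y <- as.integer(score[keep] > 0.6)
  m <- trainCalibrationModel(X, y, epochs = 40, seed = 3,
                             classWeights = NULL)
  p <- predictProbability(m, X)
  expect_gte(mean((p > 0.5) == (y == 1L)), 0.99)
})

test_that("probability-to-Phred conversion follows the closed form", {
  m <- new("CalibrationModel", architecture = "logistic",
           params = list(coef = c(0)), featureNames = "x",
           center = c(x = 0), scale = c(x = 1), classWeights = c(1, 1),
           seed = 1L, version = "ccspolish-calibration-1")
  expect_identical(ccspolish:::.prob_to_q(0.999), 30L)
  expect_identical(ccspolish:::.prob_to_q(1 - 10^-5.4), 54L)
  expect_identical(ccspolish:::.prob_to_q(1 - 10^-9.3), 93L)
  expect_identical(ccspolish:::.prob_to_q(1 - 1e-12), 93L)  # capped at 93
  expect_identical(ccspolish:::.prob_to_q(1e-6), 1L)        # floored at 1
})

test_that("predicted quality falls as the generator error rate rises", {
  fs <- simulateFeatureSet(3e4, seed = 42)
  m <- trainCalibrationModel(fs$features, fs$labels, molecule = fs$molecule,
                             epochs = 25, seed = 7)
  means <- vapply(c(0.5, 1, 2), function(es) {
    s <- simulateFeatureSet(8000, seed = 55, errorScale = es)
    mean(predictQuality(m, s$features))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("models round-trip through serialisation and reject schema drift", {
  fs <- simulateFeatureSet(3000, seed = 77)
  m <- trainCalibrationModel(fs$features, fs$labels, epochs = 3, seed = 5)
  f <- tempfile(fileext = ".json")
  saveCalibrationModel(m, f)
  m2 <- readCalibrationModel(f)
  expect_identical(m2@featureNames, m@featureNames)
  expect_equal(predictProbability(m2, fs$features[1:20, ]),
               predictProbability(m, fs$features[1:20, ]), tolerance = 1e-12)
  bad <- fs$features[1:5, ]
  colnames(bad)[1] <- "mystery"
  expect_error(predictProbability(m2, bad), "schema")
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$version <- "other-0"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, digits = NA, auto_unbox = TRUE)
  expect_error(readCalibrationModel(f2), "version")
})

test_that("the logistic baseline also trains and calibrates roughly", {
  fs <- simulateFeatureSet(2e4, seed = 88)
  m <- trainCalibrationModel(fs$features, fs$labels,
                             architecture = "logistic", seed = 2)
  p <- predictProbability(m, fs$features)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(mean(1 - p) - mean(fs$labels == 0L)), 0.02)
})
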