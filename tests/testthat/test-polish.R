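test_that("the strict-majority parallel rule corrects, keeps and ties as specified", {
  mk <- function(row) new("ParallelBases",
                          counts = matrix(as.integer(row), 1, 5,
                                          dimnames = list(NULL, c("A", "C", "G", "T", "-"))),
                          complete = sum(row) == 6L, direction = "forward",
                          numSequences = 6L)
  # helper graph whose consensus equals the read, so only the parallel rule fires
  g <- buildPoa("C", c("C", "C"))
  # original C outvotes A -> unchanged
  pr <- polishRead("C", g, mk(c(1, 5, 0, 0, 0)))
  expect_identical(polishedSequence(pr), "C")
  expect_identical(sum(correctionCounts(pr)), 0L)
  # alternative A with higher count -> PARALLEL correction
  pr <- polishRead("C", g, mk(c(4, 2, 0, 0, 0)))
  expect_identical(polishedSequence(pr), "A")
  expect_identical(correctionCounts(pr)[["PARALLEL"]], 1L)
  expect_identical(as.character(pr@perBaseOrigin), "PARALLEL")
  # tie -> strict inequality required, original kept
  pr <- polishRead("C", g, mk(c(3, 3, 0, 0, 0)))
  expect_identical(polishedSequence(pr), "C")
  # gap majority never deletes through the parallel rule
  pr <- polishRead("C", g, mk(c(0, 2, 0, 0, 4)))
  expect_identical(polishedSequence(pr), "C")
})

test_that("consensus substitutions and deletions are applied with disjoint origins", {
  # all subreads disagree at one base -> POA consensus substitutes
  g <- buildPoa("ACGT", c("AAGT", "AAGT", "AAGT"))
  pr <- polishRead("ACGT", g, parallelBasesForRead(g))
  expect_identical(polishedSequence(pr), "AAGT")
  expect_identical(correctionCounts(pr)[["POA_SUB"]], 1L)
  expect_identical(correctionCounts(pr)[["PARALLEL"]], 0L)
  # all subreads lack one base -> POA consensus deletes
  g <- buildPoa("ACGGT", c("ACGT", "ACGT", "ACGT"))
  pr <- polishRead("ACGGT", g, parallelBasesForRead(g))
  expect_identical(polishedSequence(pr), "ACGT")
  expect_identical(correctionCounts(pr)[["POA_DEL"]], 1L)
  expect_identical(length(pr@deletions), 1L)
  expect_identical(nchar(polishedSequence(pr)),
                   nchar("ACGGT") - length(pr@deletions))
})

test_that("polishing is idempotent on agreeing subreads", {
  set.seed(97)
  for (i in 1:5) {
    truth <- random_seq(30)
    g <- buildPoa(truth, rep(truth, 4))
    pr <- polishRead(truth, g, parallelBasesForRead(g))
    expect_identical(polishedSequence(pr), truth)
    expect_identical(sum(correctionCounts(pr)), 0L)
  }
})

test_that("error-free subreads correct an erroneous consensus base", {
  set.seed(101)
  for (i in 1:5) {
    truth <- random_seq(25)
    ccs <- mutate_seq(truth, 1)
    g <- buildPoa(ccs, rep(truth, 5))
    pr <- polishRead(ccs, g, parallelBasesForRead(g))
    expect_identical(polishedSequence(pr), truth)
  }
})

test_that("polishing never invents a base unseen at the locus", {
  set.seed(103)
  for (i in 1:10) {
    truth <- random_seq(20)
    subs <- vapply(1:5, function(k) mutate_seq(truth, sample(0:2, 1)),
                   character(1))
    ccs <- mutate_seq(truth, 1)
    g <- buildPoa(ccs, subs)
    counts <- parallelBasesForRead(g)
    pr <- polishRead(ccs, g, counts)
    pol <- strsplit(polishedSequence(pr), "")[[1]]
    cm <- parallelCounts(counts)
    ccsChars <- strsplit(ccs, "")[[1]]
    for (j in seq_along(pol)) {
      orig <- pr@originalPosition[j]
      seen <- colnames(cm)[cm[orig, ] > 0]
      expect_true(pol[j] %in% c(seen, ccsChars[orig]))
    }
  }
})

test_that("correction tallies and truth-based rates aggregate correctly", {
  g <- buildPoa("ACGT", c("ACGT", "ACGT"))
  clean <- polishRead("ACGT", g, parallelBasesForRead(g))
  out <- tallyCorrections(list(clean, clean))
  expect_identical(out$counts, c(POA_SUB = 0L, POA_DEL = 0L, PARALLEL = 0L))

  # zero-error simulation: specificity must be perfect
  reads <- list(); truth <- list()
  for (i in 1:5) {
    sm <- simulateMolecule(refLength = 60, nPasses = 5, subRate = 0,
                           insRate = 0, delRate = 0, ccsErrorRate = 0,
                           seed = i)
    res <- polishMolecule(sm$molecule)
    reads[[i]] <- res$polished
    truth[[i]] <- list(reference = strsplit(sm$reference, "")[[1]],
                       isError = sm$truthError)
  }
  out <- tallyCorrections(reads, truth)
  expect_identical(out$specificity, 1)
  expect_identical(out$counts, c(POA_SUB = 0L, POA_DEL = 0L, PARALLEL = 0L))
})

test_that("sensitivity grows with pass count on planted consensus errors", {
  sens <- function(npass, n = 12) {
    reads <- list(); truth <- list()
    for (i in seq_len(n)) {
      sm <- simulateMolecule(refLength = 120, nPasses = npass,
                             ccsErrorRate = 0.02, seed = 500 + i)
      res <- polishMolecule(sm$molecule)
      reads[[i]] <- res$polished
      truth[[i]] <- list(reference = strsplit(sm$reference, "")[[1]],
                         isError = sm$truthError)
    }
    tallyCorrections(reads, truth)
  }
  lo <- sens(3); hi <- sens(10)
  expect_gt(hi$sensitivity, lo$sensitivity)
  expect_gt(lo$sensitivity, 0)
  expect_gte(hi$specificity, 0.99)
})
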