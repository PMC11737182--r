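test_that("zero error rates reproduce the reference exactly", {
  sm <- simulateMolecule(refLength = 80, nPasses = 4, subRate = 0,
                         insRate = 0, delRate = 0, ccsErrorRate = 0,
                         seed = 3)
  expect_identical(sm$ccs, sm$reference)
  expect_false(any(sm$truthError))
  mol <- sm$molecule
  for (i in seq_along(mol@subreads)) {
    s <- mol@subreads[i]
    if (mol@orientation[i] == "-") s <- revComp(s)
    expect_identical(s, sm$reference)
  }
  expect_identical(mol@orientation, c("+", "-", "+", "-"))
})

test_that("the same seed reproduces the molecule bit for bit", {
  a <- simulateMolecule(refLength = 50, nPasses = 5, seed = 19)
  b <- simulateMolecule(refLength = 50, nPasses = 5, seed = 19)
  expect_identical(a$molecule@subreads, b$molecule@subreads)
  expect_identical(a$molecule@ipd, b$molecule@ipd)
  expect_identical(a$ccs, b$ccs)
  c <- simulateMolecule(refLength = 50, nPasses = 5, seed = 20)
  expect_false(identical(a$molecule@subreads, c$molecule@subreads))
})

test_that("per-pass mismatch rates concentrate around the nominal rate", {
  sm <- simulateMolecule(refLength = 1e4, nPasses = 8, subRate = 0.10,
                         insRate = 0, delRate = 0, ccsErrorRate = 0,
                         seed = 29)
  refChars <- strsplit(sm$reference, "")[[1]]
  mol <- sm$molecule
  mism <- vapply(seq_along(mol@subreads), function(i) {
    s <- mol@subreads[i]
    if (mol@orientation[i] == "-") s <- revComp(s)
    sum(strsplit(s, "")[[1]] != refChars)
  }, numeric(1))
  n <- 8 * 1e4
  expect_lt(abs(sum(mism) / n - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("pass errors are independent between passes", {
  sm <- simulateMolecule(refLength = 5e4, nPasses = 2, subRate = 0.05,
                         insRate = 0, delRate = 0, ccsErrorRate = 0,
                         seed = 31)
  refChars <- strsplit(sm$reference, "")[[1]]
  err <- sapply(1:2, function(i) {
    s <- sm$molecule@subreads[i]
    if (sm$molecule@orientation[i] == "-") s <- revComp(s)
    strsplit(s, "")[[1]] != refChars
  })
  expect_lt(abs(cor(err[, 1], err[, 2])), 0.02)
})

test_that("degenerate parameters are rejected with a message", {
  expect_error(simulateMolecule(refLength = 5), "refLength")
  expect_error(simulateMolecule(nPasses = 0), "nPasses")
  expect_error(simulateMolecule(subRate = 1.2), "rates")
})

test_that("cohorts plant germline and somatic variants as specified", {
  coh <- simulateCohort(6, refLength = 500, nPasses = 3,
                        germlineRate = 0.02, somaticRate = 0.002,
                        subRate = 0, insRate = 0, delRate = 0,
                        ccsErrorRate = 0, seed = 41)
  expect_gt(nrow(coh$germline), 0)
  refChars <- strsplit(coh$reference, "")[[1]]
  # somatic variants are single-molecule events at roughly rate * bases
  expect_lt(abs(nrow(coh$somatic) - 6 * 500 * 0.002),
            3 * sqrt(6 * 500 * 0.002) + 3)
  expect_false(any(duplicated(coh$somatic[c("molecule", "pos")])))
  # with no sequencing error, any ccs/ref difference is a planted variant
  for (i in seq_along(coh$molecules)) {
    cc <- strsplit(coh$molecules[[i]]$ccs, "")[[1]]
    diffs <- which(cc != refChars)
    planted <- sort(c(coh$germline$pos[coh$germline$alt == cc[coh$germline$pos]],
                      coh$somatic$pos[coh$somatic$molecule == i]))
    expect_true(all(diffs %in% planted))
  }
  # germline variants are labelled correct by the mask rule
  g1 <- coh$germline
  t1 <- coh$truth[coh$truth$molecule == 1, ]
  lab <- makeLabels(t1$ccsBase, refChars, t1$pos, g1)
  expect_true(all(lab == 1L))
})

test_that("somatic-free cohorts have no single-molecule-only variants", {
  coh <- simulateCohort(4, refLength = 300, nPasses = 3, germlineRate = 0,
                        somaticRate = 0, subRate = 0, insRate = 0,
                        delRate = 0, ccsErrorRate = 0, seed = 47)
  expect_identical(nrow(coh$somatic), 0L)
  refChars <- strsplit(coh$reference, "")[[1]]
  for (m in coh$molecules)
    expect_identical(strsplit(m$ccs, "")[[1]], refChars)
})

test_that("fixtures round-trip bit-exactly through the standard formats", {
  coh <- tiny_cohort()
  dir <- tempfile()
  writeFixture(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("subreads.bam", "ccs.bam",
                                               "ref.fasta", "germline.vcf",
                                               "truth.tsv")))))
  mols <- readMolecules(file.path(dir, "subreads.bam"),
                        file.path(dir, "ccs.bam"))
  expect_identical(length(mols), length(coh$molecules))
  for (i in seq_along(mols)) {
    a <- mols[[i]]; b <- coh$molecules[[i]]$molecule
    expect_identical(a@id, b@id)
    expect_identical(a@ccs, b@ccs)
    expect_identical(a@ccsQual, b@ccsQual)
    expect_identical(a@subreads, b@subreads)
    expect_identical(a@orientation, b@orientation)
    expect_identical(a@ipd, b@ipd)
    expect_identical(a@pw, b@pw)
    expect_equal(a@snr, b@snr, tolerance = 1e-6)
  }
  # reference and germline mask read back through the standard parsers
  ref <- Biostrings::readDNAStringSet(file.path(dir, "ref.fasta"))
  expect_identical(as.character(ref[[1]]), coh$reference)
  germ <- readGermlineVcf(file.path(dir, "germline.vcf"))
  expect_identical(germ$pos, coh$germline$pos)
  expect_identical(germ$alt, coh$germline$alt)
  # truth table has one row per consensus base
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth),
               sum(vapply(coh$molecules, function(m) nchar(m$ccs),
                          numeric(1))))
  # BAM parses cleanly with the standard toolchain
  expect_no_error(capture.output(
    Rsamtools::quickBamFlagSummary(file.path(dir, "subreads.bam"),
                                   main.groups.only = TRUE)))
})
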