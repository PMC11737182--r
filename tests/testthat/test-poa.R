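test_that("aligning a sequence to a matching linear graph scores all matches", {
  g <- addSequence(poaGraph(), "ACGT")
  aln <- alignToGraph(g, "ACGT")
  expect_s4_class(aln, "GraphAlignment")
  expect_identical(aln@score, 8L)
  expect_identical(aln@path[, 1], 1:4)
  expect_identical(aln@path[, 2], 1:4)
})

test_that("alignment against an empty graph is all insertions", {
  aln <- alignToGraph(poaGraph(), "ACGT")
  expect_identical(aln@score, -16L)
  expect_true(all(is.na(aln@path[, 1])))
})

test_that("non-nucleotide input is rejected", {
  g <- addSequence(poaGraph(), "ACGT")
  expect_error(alignToGraph(g, "ACXT"), "outside")
  expect_error(addSequence(g, ""), "non-empty")
})

test_that("linear-graph alignment equals Needleman-Wunsch (oracle)", {
  set.seed(11)
  for (i in 1:100) {
    a <- random_seq(sample(5:25, 1))
    b <- random_seq(sample(5:25, 1))
    g <- addSequence(poaGraph(), a)
    expect_identical(alignToGraph(g, b)@score, as.integer(nw_score(a, b)))
  }
})

test_that("graph alignment dominates per-path Needleman-Wunsch (oracle)", {
  set.seed(23)
  for (rep in 1:20) {
    g <- poaGraph()
    for (k in 1:3) g <- addSequence(g, random_seq(10))
    q <- random_seq(sample(6:14, 1))
    best <- max(vapply(enumerate_paths(g), function(p)
      nw_score(paste(nodeBases(g)[p], collapse = ""), q), numeric(1)))
    expect_gte(alignToGraph(g, q)@score, best)
  }
})

test_that("adding sequences builds the expected topology and weights", {
  g <- addSequence(poaGraph(), "ACGT")
  expect_identical(numNodes(g), 4L)
  expect_identical(numSequences(g), 1L)
  real <- edgeTable(g)[edgeTable(g)$from >= 1 & edgeTable(g)$to >= 1, ]
  expect_identical(nrow(real), 3L)
  expect_true(all(real$weight == 1L))

  g2 <- addSequence(g, "ACGT")
  expect_identical(numNodes(g2), 4L)   # idempotent topology
  expect_true(all(edgeTable(g2)$weight == 2L))
  expect_identical(numSequences(g2), 2L)
})

test_that("a disagreeing sequence creates exactly one parallel node", {
  g <- buildPoa("ACGT", c("ACGT", "ACGT", "ACGT", "ACGT", "AAGT"))
  expect_identical(numNodes(g), 5L)
  expect_identical(nodeBases(g)[5], "A")
  et <- edgeTable(g)
  expect_identical(et$weight[et$to == 2L], 5L)  # C keeps five sequences
  expect_identical(et$weight[et$to == 5L], 1L)  # parallel A carries one
})

test_that("buildPoa seeds with the consensus and counts sequences", {
  g <- buildPoa("ACGT", c("ACGT", "ACGT"))
  expect_identical(numSequences(g), 3L)
  expect_identical(backbone(g), 1:4)
  expect_identical(nodeRanks(g), 0:3)
  g0 <- buildPoa("ACGT", c("ACGT", "ACGT"), countCcs = FALSE)
  expect_identical(numSequences(g0), 2L)
  expect_error(buildPoa("ACGT", character(0)), "at least one subread")
})

test_that("reverse-orientation subreads are reverse-complemented first", {
  expect_identical(revComp(revComp("ACGTTG")), "ACGTTG")
  g <- buildPoa("ACGT", c("ACGT", revComp("ACGT")),
                orientation = c("+", "-"))
  expect_identical(numNodes(g), 4L)        # merges onto the backbone
  expect_true(all(edgeTable(g)$weight == 3L))
})

test_that("topological ranks respect every edge and are deterministic", {
  g <- worked_example_graph()
  et <- edgeTable(g)
  real <- et[et$from >= 1 & et$to >= 1, ]
  expect_true(all(nodeRanks(g)[real$from] < nodeRanks(g)[real$to]))
  expect_identical(nodeRanks(topoSort(g)), nodeRanks(g))
  set.seed(31)
  for (i in 1:20) {
    g <- poaGraph()
    for (k in 1:sample(2:5, 1)) g <- addSequence(g, random_seq(sample(8:15, 1)))
    g <- topoSort(g)
    expect_true(setequal(nodeRanks(g), 0:(numNodes(g) - 1)))
    et <- edgeTable(g)
    real <- et[et$from >= 1 & et$to >= 1, ]
    expect_true(all(nodeRanks(g)[real$from] < nodeRanks(g)[real$to]))
  }
})

test_that("heaviest consensus recovers identity and majority", {
  g <- buildPoa("ACGT", c("ACGT", "ACGT"))
  expect_identical(as.character(heaviestConsensus(g)), "ACGT")
  g <- buildPoa("ACGT", c("ACGT", "ACGT", "ACGT", "ACGT", "AAGT"))
  expect_identical(as.character(heaviestConsensus(g)), "ACGT")
  expect_identical(as.character(heaviestConsensus(poaGraph())), "")
})

test_that("heaviest consensus equals brute-force best path (oracle)", {
  set.seed(47)
  for (rep in 1:15) {
    truth <- random_seq(12)
    seqs <- c(rep(truth, 5), mutate_seq(truth, 1))
    g <- buildPoa(truth, seqs[-1])
    paths <- enumerate_paths(g)
    ws <- vapply(paths, function(p) path_weight(g, p), numeric(1))
    best <- paths[[which.max(ws)]]
    expect_identical(as.character(heaviestConsensus(g)),
                     paste(nodeBases(g)[best], collapse = ""))
    expect_identical(as.character(heaviestConsensus(g)), truth)
  }
})

test_that("graphs stay acyclic with valid weights through random growth", {
  set.seed(59)
  for (rep in 1:10) {
    g <- poaGraph()
    for (k in 1:4) {
      g <- addSequence(g, random_seq(sample(6:18, 1)))
      g <- topoSort(g)
      expect_true(validObject(g))
    }
    expect_identical(numSequences(g), 4L)
  }
})

test_that("every full cut carries total weight equal to the sequence count", {
  set.seed(61)
  for (rep in 1:10) {
    truth <- random_seq(15)
    subs <- vapply(1:5, function(i) mutate_seq(truth, sample(0:2, 1)),
                   character(1))
    g <- buildPoa(truth, subs)
    et <- edgeTable(g)
    rk <- function(v) {
      r <- integer(length(v))
      r[v == 0L] <- -1L
      r[v == -1L] <- numNodes(g)
      real <- v >= 1L
      r[real] <- nodeRanks(g)[v[real]]
      r
    }
    for (cut in 0:(numNodes(g) - 1)) {
      crossing <- rk(et$from) < cut & rk(et$to) >= cut
      expect_identical(sum(et$weight[crossing]), numSequences(g))
    }
  }
})

test_that("DOT dump names every node and edge", {
  g <- buildPoa("ACGT", c("ACGT", "AAGT"))
  dot <- graphToDot(g)
  expect_true(any(grepl("digraph", dot)))
  expect_identical(sum(grepl("->", dot)), length(g@edgeFrom))
})
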