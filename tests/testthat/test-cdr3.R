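test_that("anchor resolution: explicit override, gapped V, J motif scan", {
  # explicit anchor wins over everything
  g <- germlineGene("V", strrep("ACGT", 10), anchor = 12L)
  expect_identical(resolveAnchor(g, "five"), 12L)

  # gapped 5' sequence: anchor = ungapped position of the base at the
  # conventional gapped Cys104 offset
  core <- strrep("ACGT", 6)                       # 24 nt before the anchor
  tail <- "TGTGCCACC"
  gapped <- paste0(core, strrep(".", 309 - 24), tail)
  v <- germlineGene("V2", paste0(core, tail), gappedSequence = gapped)
  expect_identical(resolveAnchor(v, "five"), 24L)
  # oracle: strip the gaps before the target offset and count
  expect_identical(resolveAnchor(v, "five"),
                   nchar(gsub(".", "", substr(gapped, 1, 309), fixed = TRUE)))

  # degenerate gapped sequences resolve to nothing
  expect_identical(resolveAnchor(germlineGene("V3", "ACGTACGT"), "five"),
                   NA_integer_)

  # J motif: first [TTT|TTC|TGG] followed by G-X-G codon pattern
  j <- germlineGene("J", "ACAATCTTTGGAGCAGGAACCAGACT")
  expect_identical(resolveAnchor(j, "three"), 6L)
  expect_identical(substr(j@sequence, 7, 9), "TTT")
  # no motif, no anchor
  expect_identical(resolveAnchor(germlineGene("J2", "ACACACACACACACAC"),
                                 "three"), NA_integer_)
})

test_that("junction coordinates equal simulator truth on error-free reads", {
  w <- simWorld(seed = 61)
  sim <- simulateRepertoire(w$collection, nClones = 80, nReads = 80,
                            abundance = "uniform", errorRate = 0,
                            flipProb = 0, seed = 62)
  checked <- 0
  for (i in seq_len(80)) {
    tr <- sim$clones[i, ]
    if (is.na(tr$junctionStart)) next        # an anchor was deleted
    des <- designate(tr$sequence, w$set)
    c3 <- locateCDR3(tr$sequence, des, w$set)
    expect_identical(c3$junctionStart, as.integer(tr$junctionStart))
    expect_identical(c3$junctionEnd, as.integer(tr$junctionEnd))
    expect_identical(c3$productive, tr$productive)
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("frame and stop-codon rules drive productivity", {
  w <- simWorld(seed = 63)
  set <- w$set
  v <- set@fivePrime[[1]]
  j <- set@threePrime[[1]]
  aV <- v@anchor
  aJ <- j@anchor
  vLen <- nchar(v@sequence)

  mkRep <- function(nIns) paste0(v@sequence, nIns, j@sequence)
  junLen <- function(nIns) (vLen - aV) + nchar(nIns) + aJ + 3L

  # choose an insert making the junction in-frame and stop-free
  nIn <- "GGA"
  while (junLen(nIn) %% 3 != 0) nIn <- paste0(nIn, "G")
  des <- designate(mkRep(nIn), set)
  c3 <- locateCDR3(mkRep(nIn), des, set)
  expect_identical(c3$reason,
                   if (c3$productive) "IN_FRAME" else c3$reason)
  expect_identical((c3$junctionEnd - c3$junctionStart) %% 3L, 0L)
  if (c3$productive) {
    # translation invariant, against a hand-applied codon table
    junction <- substr(mkRep(nIn), c3$junctionStart + 1, c3$junctionEnd)
    inner <- substr(junction, 4, nchar(junction) - 3)
    expect_identical(c3$cdr3AA, oracleTranslate(inner))
    expect_identical(nchar(c3$cdr3AA),
                     as.integer((c3$junctionEnd - c3$junctionStart) / 3 - 2))
  }

  # force an in-frame TAA inside the insert: not productive, STOP_CODON
  pad <- (3 - (vLen - aV) %% 3) %% 3
  nStop <- paste0(strrep("G", pad), "TAA")
  while (junLen(nStop) %% 3 != 0) nStop <- paste0(nStop, "G")
  desS <- designate(mkRep(nStop), set)
  c3S <- locateCDR3(mkRep(nStop), desS, set)
  expect_false(c3S$productive)
  expect_identical(c3S$reason, "STOP_CODON")

  # out-of-frame junction
  nOof <- "GG"
  while (junLen(nOof) %% 3 != 1) nOof <- paste0(nOof, "C")
  desO <- designate(mkRep(nOof), set)
  c3O <- locateCDR3(mkRep(nOof), desO, set)
  expect_false(c3O$productive)
  expect_identical(c3O$reason, "OUT_OF_FRAME")
})

test_that("genes without anchors yield NO_ANCHOR, not an error", {
  set.seed(64)
  g <- simulateGermlineSet(locus = "DD", nFive = 2, nThree = 2,
                           fiveLength = c(60, 70), threeLength = c(60, 70),
                           anchors = FALSE, complete = FALSE)
  rep <- paste0(g$set@fivePrime[[1]]@sequence, "GATC",
                g$set@threePrime[[1]]@sequence)
  des <- designate(rep, g$set)
  c3 <- locateCDR3(rep, des, g$set)
  expect_false(c3$productive)
  expect_identical(c3$reason, "NO_ANCHOR")
})

test_that("productivity is stable when the read starts deeper in the gene", {
  w <- simWorld(seed = 65)
  sim <- simulateRepertoire(w$collection, nClones = 20, nReads = 20,
                            abundance = "uniform", errorRate = 0,
                            flipProb = 0, seed = 66)
  for (i in seq_len(10)) {
    tr <- sim$clones[i, ]
    if (is.na(tr$junctionStart)) next
    full <- tr$sequence
    clipped <- substr(full, 16, nchar(full))     # read starts 15 nt inside V
    c3a <- locateCDR3(full, designate(full, w$set), w$set)
    c3b <- locateCDR3(clipped, designate(clipped, w$set), w$set)
    expect_identical(c3a$productive, c3b$productive)
    expect_identical(c3a$reason, c3b$reason)
    if (!is.na(c3a$cdr3AA)) expect_identical(c3a$cdr3AA, c3b$cdr3AA)
  }
})
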