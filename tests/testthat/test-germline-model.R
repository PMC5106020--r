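test_that("a minimal configuration loads with the configured gene lists", {
  toy <- writeToyConfig()
  coll <- loadGermlineCollection(toy$config)
  expect_s4_class(coll, "GermlineCollection")
  expect_length(coll@sets, 1L)
  set <- coll@sets[[1]]
  expect_identical(set@locus, "TOY")
  expect_length(set@fivePrime, 2L)
  expect_length(set@threePrime, 1L)
  # header parsing keeps the first whitespace-delimited token only
  expect_identical(set@fivePrime[[1]]@name, "TOYV1*01")
})

test_that("configuration errors name the offending file or locus", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "g.json")
  jsonlite::write_json(list(systems = list(list(
    locus = "TRG", "5" = list("missing.fa"), "3" = list("missing.fa")))),
    cfg, auto_unbox = TRUE)
  expect_error(loadGermlineCollection(cfg), "missing.fa")

  toy <- writeToyConfig()
  twin <- jsonlite::read_json(toy$config)
  twin$systems <- c(twin$systems, twin$systems)   # duplicate TOY locus
  cfg2 <- file.path(toy$dir, "dup.json")
  jsonlite::write_json(twin, cfg2, auto_unbox = TRUE)
  expect_error(loadGermlineCollection(cfg2), "duplicate locus")

  expect_error(loadGermlineCollection(file.path(dir, "absent.json")),
               "absent.json")
})

test_that("non-ACGT germline records are rejected and named", {
  dir <- withr::local_tempdir()
  writeLines(c(">GOOD", "ACGTACGT", ">BAD1", "ACGRTACGT"),
             file.path(dir, "v.fa"))
  writeLines(c(">J", "ACGTACGT"), file.path(dir, "j.fa"))
  cfg <- file.path(dir, "g.json")
  jsonlite::write_json(list(systems = list(list(
    locus = "X", "5" = list("v.fa"), "3" = list("j.fa")))),
    cfg, auto_unbox = TRUE)
  expect_error(loadGermlineCollection(cfg), "BAD1")
})

test_that("gapped FASTA records keep both gapped and ungapped sequences", {
  dir <- withr::local_tempdir()
  writeLines(c(">V1", "ACG...TAC..GT"), file.path(dir, "v.fa"))
  writeLines(c(">J1", "ACGTACGTACGT"), file.path(dir, "j.fa"))
  cfg <- file.path(dir, "g.json")
  jsonlite::write_json(list(systems = list(list(
    locus = "X", complete = FALSE, "5" = list("v.fa"), "3" = list("j.fa")))),
    cfg, auto_unbox = TRUE)
  g <- loadGermlineCollection(cfg)@sets[[1]]@fivePrime[[1]]
  expect_identical(g@sequence, "ACGTACGT")
  expect_identical(g@gappedSequence, "ACG...TAC..GT")
})

test_that("neighbor pads concatenate, are recorded, and shift the anchor", {
  g <- germlineGene("TOYD1", "ACGT")
  p <- padWithNeighbors(g, "GG", "TT")
  expect_identical(p@sequence, "GGACGTTT")
  expect_identical(p@upstreamPad, 2L)
  expect_identical(p@downstreamPad, 2L)

  expect_identical(padWithNeighbors(g)@sequence, g@sequence)
  expect_identical(padWithNeighbors(g)@upstreamPad, 0L)

  a <- germlineGene("V", "ACGTACGTAC", anchor = 4L)
  expect_identical(padWithNeighbors(a, "GGG")@anchor, 7L)
})

test_that("padding a short D restores spaced-seed coverage", {
  d <- germlineGene("D1", strrep("ACGTT", 2))        # 10 nt < span 13
  p <- padWithNeighbors(d, strrep("GATC", 5), "")    # 20-nt upstream pad
  expect_identical(nchar(p@sequence), 30L)
  seed <- strrep("#", 13)
  # the padded gene now contributes k-mers where the bare gene cannot
  expect_length(masked_kmers <- vdjcluster:::masked_kmers_cpp(p@sequence, seed),
                30L - 13L + 1L)
  set <- germlineSet("D+", list(p), list(germlineGene("J", strrep("AC", 10))),
                     seedPattern = seed, complete = FALSE)
  idx <- buildKmerIndex(germlineCollection(list(set)), seed)
  expect_length(idx@indexWarnings, 0L)
  idxBare <- buildKmerIndex(germlineCollection(list(
    germlineSet("D+", list(d), list(germlineGene("J", strrep("AC", 10))),
                complete = FALSE))), seed)
  expect_match(idxBare@indexWarnings, "D1", all = FALSE)
})

test_that("a collection survives the config+FASTA round trip field-wise", {
  set.seed(11)
  g <- simulateGermlineSet(locus = "TRG", nFive = 3, nThree = 2)
  d <- simulateGermlineSet(locus = "DD", nFive = 2, nThree = 1,
                           fiveLength = c(12, 14), threeLength = c(12, 14),
                           anchors = FALSE, complete = FALSE)
  padded <- lapply(d$set@fivePrime, padWithNeighbors,
                   upstream = strrep("ACGT", 10))
  coll <- germlineCollection(
    list(g$set, germlineSet("DD", padded, d$set@threePrime,
                            complete = FALSE)),
    middleGenes = list(TRG = list(germlineGene("TRGD1*01",
                                               "ACGTACGTTACG"))))
  dir <- withr::local_tempdir()
  cfg <- writeGermlineCollection(coll, dir)
  coll2 <- loadGermlineCollection(cfg)
  expect_length(coll2@sets, 2L)
  for (k in seq_along(coll@sets)) {
    s1 <- coll@sets[[k]]; s2 <- coll2@sets[[k]]
    expect_identical(s1@locus, s2@locus)
    expect_identical(s1@complete, s2@complete)
    expect_identical(s1@seedPattern, s2@seedPattern)
    for (side in c("fivePrime", "threePrime")) {
      g1 <- slot(s1, side); g2 <- slot(s2, side)
      expect_identical(lapply(g1, function(x) x@name),
                       lapply(g2, function(x) x@name))
      expect_identical(lapply(g1, function(x) x@sequence),
                       lapply(g2, function(x) x@sequence))
      expect_identical(lapply(g1, function(x) x@gappedSequence),
                       lapply(g2, function(x) x@gappedSequence))
      expect_identical(lapply(g1, function(x) x@anchor),
                       lapply(g2, function(x) x@anchor))
      expect_identical(lapply(g1, function(x) x@upstreamPad),
                       lapply(g2, function(x) x@upstreamPad))
    }
  }
  expect_identical(coll2@middleGenes$TRG[[1]]@sequence, "ACGTACGTTACG")
})

test_that("invalid gene objects are rejected by validity checks", {
  expect_error(germlineGene("X", ""), "non-empty")
  expect_error(germlineGene("X", "ACGT", gappedSequence = "AC..GA"),
               "does not match")
  expect_error(germlineGene("X", "ACGTAC", anchor = 5L), "anchor")
  expect_error(germlineSet("L", list(), list(germlineGene("J", "ACGT"))),
               "empty")
  expect_error(
    germlineCollection(list(toySet("A"), toySet("A"))), "duplicate locus")
})
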