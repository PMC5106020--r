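test_that("semi-global alignment equals the exhaustive recursion oracle", {
  set.seed(51)
  for (i in seq_len(100)) {
    gene <- paste(sample(c("A", "C", "G", "T"), sample(1:20, 1),
                         replace = TRUE), collapse = "")
    seq <- paste(sample(c("A", "C", "G", "T"), sample(1:20, 1),
                        replace = TRUE), collapse = "")
    got <- alignFivePrime(gene, seq)
    expect_identical(got$score, as.integer(oracleAlignLeft(gene, seq)),
                     info = paste(gene, seq))
  }
})

test_that("alignment endpoints behave on canonical cases", {
  sc <- designationScoring()
  # exact prefix match
  a <- alignFivePrime("ACGTACGT", "ACGTACGTTTTTTTTT")
  expect_identical(a$score, 8L * sc$match)
  expect_identical(a$end, 8L)
  expect_identical(a$geneStart, 0L)
  expect_identical(a$geneEnd, 8L)

  # all-mismatch: nothing beats the empty alignment
  expect_lte(alignFivePrime("AAAA", "TTTT")$score, 0L)

  # an unrelated random 50-mer stays below the acceptance threshold
  set.seed(52)
  gene <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  probe <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
  expect_lt(alignFivePrime(gene, probe)$score, sc$minScore)

  # the 3' alignment is the mirror image
  b <- alignThreePrime("ACGTACGT", "TTTTTTTTACGTACGT")
  expect_identical(b$score, 8L * sc$match)
  expect_identical(b$start, 8L)
  expect_identical(b$end, 16L)
  expect_identical(b$geneStart, 0L)
})

test_that("designation recovers simulated V, J, deletions and N regions", {
  w <- simWorld(seed = 53)
  set <- w$set
  v <- set@fivePrime[[1]]
  j <- set@threePrime[[2]]
  vLen <- nchar(v@sequence)
  # choose N bases that never extend the V alignment into the junction
  # (junction micro-homology would legitimately shift the deletion split)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  tail3 <- strsplit(substr(v@sequence, vLen - 2, vLen), "")[[1]]
  nIns <- paste0(other(tail3[1]), other(tail3[2]), other(tail3[3]),
                 other(substr(j@sequence, 1, 1)), "C")
  rep <- paste0(substr(v@sequence, 1, vLen - 3),       # 3 nt deleted
                nIns, j@sequence)
  des <- designate(rep, set)
  expect_identical(des$status, "DESIGNATED")
  expect_identical(des$fiveGene, v@name)
  expect_identical(des$threeGene, j@name)
  expect_identical(des$fiveDel, 3L)
  expect_identical(des$threeDel, 0L)
  expect_identical(des$nRegions, nIns)
  expect_identical(des$text,
                   sprintf("%s 3/5/0 %s", v@name, j@name))

  # a pure V gene copy is not a recombination
  expect_identical(designate(v@sequence, set)$status, "UNSEGMENTED")
})

test_that("identical alleles tie to the lexicographically smallest name", {
  v <- germlineGene("TRGV1*02", strrep("ACGGT", 12))
  vTwin <- germlineGene("TRGV1*01", strrep("ACGGT", 12))
  j <- germlineGene("TRGJ1*01", strrep("CAGTT", 12))
  set <- germlineSet("TRG", list(v, vTwin), list(j))
  rep <- paste0(strrep("ACGGT", 12), "GGATC", strrep("CAGTT", 12))
  des <- designate(rep, set)
  expect_identical(des$fiveGene, "TRGV1*01")
  expect_identical(des$fiveTies, "TRGV1*02")
})

test_that("multi-D junctions are recovered in order on TRD-like cases", {
  set.seed(54)
  g <- simulateGermlineSet(locus = "TRD", nFive = 3, nThree = 2, nD = 3,
                           dLength = c(20, 37))
  coll <- germlineCollection(list(g$set), middleGenes = list(TRD = g$dGenes))
  sim <- simulateRepertoire(coll, nClones = 40, nReads = 40,
                            abundance = "uniform", errorRate = 0,
                            flipProb = 0, dPerClone = 2, dMinRemnant = 12,
                            seed = 55)
  ok <- 0
  for (i in seq_len(40)) {
    tr <- sim$clones[i, ]
    des <- designate(tr$sequence, g$set, dGenes = g$dGenes, maxD = 2)
    got <- paste(vapply(des$dGenes, function(d) d$name, character(1)),
                 collapse = ";")
    if (identical(got, tr$dGenes)) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)

  # VDDDJ with maxD = 3
  sim3 <- simulateRepertoire(coll, nClones = 20, nReads = 20,
                             abundance = "uniform", errorRate = 0,
                             flipProb = 0, dPerClone = 3, dMinRemnant = 14,
                             seed = 56)
  ok3 <- 0
  for (i in seq_len(20)) {
    tr <- sim3$clones[i, ]
    des <- designate(tr$sequence, g$set, dGenes = g$dGenes, maxD = 3)
    got <- paste(vapply(des$dGenes, function(d) d$name, character(1)),
                 collapse = ";")
    if (identical(got, tr$dGenes)) ok3 <- ok3 + 1
  }
  expect_gte(ok3 / 20, 0.9)
})

test_that("substitution-free designations reconstruct the representative", {
  w <- simWorld(seed = 57)
  sim <- simulateRepertoire(w$collection, nClones = 60, nReads = 60,
                            abundance = "uniform", errorRate = 0,
                            flipProb = 0, seed = 58)
  cleanCases <- 0
  for (i in seq_len(60)) {
    rep <- sim$clones$sequence[i]
    des <- designate(rep, w$set)
    expect_identical(des$status, "DESIGNATED")
    vG <- Filter(function(g) g@name == des$fiveGene, w$set@fivePrime)[[1]]
    jG <- Filter(function(g) g@name == des$threeGene, w$set@threePrime)[[1]]
    vRem <- substr(vG@sequence, des$fiveGeneStart + 1, des$fiveGeneEnd)
    jRem <- substr(jG@sequence, des$threeGeneStart + 1, des$threeGeneEnd)
    recon <- paste0(vRem, paste(des$nRegions, collapse = ""), jRem)
    subs <- sum(strsplit(vRem, "")[[1]] !=
                strsplit(substr(rep, 1, des$fiveSeqEnd), "")[[1]]) +
            sum(strsplit(jRem, "")[[1]] !=
                strsplit(substr(rep, des$threeSeqStart + 1,
                                nchar(rep)), "")[[1]])
    if (nchar(vRem) == des$fiveSeqEnd &&
        nchar(jRem) == nchar(rep) - des$threeSeqStart && subs == 0) {
      cleanCases <- cleanCases + 1
      expect_identical(recon, rep)
    }
  }
  # the vast majority of error-free cases align without any substitution
  expect_gte(cleanCases / 60, 0.8)
})
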