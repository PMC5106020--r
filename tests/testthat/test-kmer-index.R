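test_that("spaced seed patterns validate span and weight", {
  s <- spacedSeed("#####-#####-###")
  expect_identical(s$span, 15L)
  expect_identical(as.integer(s$weight), 13L)
  expect_error(spacedSeed("-####"), "start and end")
  expect_error(spacedSeed("##x##"), "over")
})

test_that("index keys are the masked characters and enumerate forward k-mers", {
  gene <- "ACGTACGTACGTA"                 # 13 nt
  set <- germlineSet("A", list(germlineGene("V1", gene)),
                     list(germlineGene("J1", "GGCCGGTTGGCCAA")))
  idx <- buildKmerIndex(germlineCollection(list(set)), "####")
  # oracle: enumerate all 13-4+1 forward windows and dedupe
  expected <- unique(substring(gene, 1:10, 4:13))
  lab5fwd <- which(idx@labelTable$locus == "A" & idx@labelTable$side == "5" &
                   idx@labelTable$strand == "+")
  gotForward <- idx@keys[idx@labels == lab5fwd]
  # keys shared with the reverse strand (palindromic k-mers) are AMBIGUOUS,
  # so compare against the oracle on the full key set of the gene
  expect_true(all(gotForward %in% expected))
  expect_setequal(union(gotForward, idx@keys[idx@labels == -1L &
                                             idx@keys %in% expected]),
                  expected)

  # masking: seed "##-##" over "ACGTA" keys on characters {0,1,3,4}
  set2 <- germlineSet("B", list(germlineGene("V1", "ACGTA")),
                      list(germlineGene("J1", "GGCCGGTTCC")))
  idx2 <- buildKmerIndex(germlineCollection(list(set2)), "##-##")
  expect_true("ACTA" %in% idx2@keys)
})

test_that("a k-mer shared by two labels becomes AMBIGUOUS", {
  shared <- "ACGTTACCA"                  # 9-mer present in both genes
  setA <- germlineSet("A", list(germlineGene("V1", paste0(shared, "GGGG"))),
                      list(germlineGene("J1", "CCTTCCTTCCTT")))
  setB <- germlineSet("B", list(germlineGene("V1", "CCTTGGCCTTGG")),
                      list(germlineGene("J1", paste0("TTTT", shared))))
  idx <- buildKmerIndex(germlineCollection(list(setA, setB)),
                        strrep("#", 9))
  expect_identical(idx@labels[idx@keys == shared], -1L)
})

test_that("affectation labels self, strand and N windows as specified", {
  w <- simWorld(seed = 31)
  idx <- buildKmerIndex(w$collection)
  gene <- w$set@fivePrime[[1]]

  # read shorter than the seed span
  expect_length(affectReads(idx, "ACGTACG")[[1]], 0L)

  # read = exact gene copy: all non-conflicting positions labelled (5', +)
  labs <- affectReads(idx, gene@sequence)[[1]]
  lt <- idx@labelTable
  hit <- labs[labs > 0]
  expect_true(length(hit) > 0)
  expect_true(all(lt$locus[hit] == "TRG" & lt$side[hit] == "5" &
                  lt$strand[hit] == "+"))

  # reverse complement: same positions reported on the minus strand
  labsRC <- affectReads(idx, rcChar(gene@sequence))[[1]]
  hitRC <- labsRC[labsRC > 0]
  expect_true(all(lt$side[hitRC] == "5" & lt$strand[hitRC] == "-"))

  # windows containing N never affect
  nRead <- paste0(substr(gene@sequence, 1, 20), "N",
                  substr(gene@sequence, 22, nchar(gene@sequence)))
  labsN <- affectReads(idx, nRead)[[1]]
  span <- idx@span
  expect_true(all(labsN[(21 - span + 1):21] == 0))
})

test_that("affectation equals a naive rescan of every germline gene", {
  w <- simWorld(seed = 32, nFive = 2, nThree = 2,
                fiveLength = c(25, 35), threeLength = c(25, 35))
  idx <- buildKmerIndex(w$collection)
  lt <- idx@labelTable
  set.seed(33)
  for (rep in seq_len(200)) {
    # mix random reads with mosaics of germline material
    read <- if (rep %% 2 == 0) {
      paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), replace = TRUE),
            collapse = "")
    } else {
      g <- w$set@fivePrime[[sample(2, 1)]]@sequence
      j <- w$set@threePrime[[sample(2, 1)]]@sequence
      paste0(substr(g, 1, sample(nchar(g), 1)),
             substr(j, sample(nchar(j), 1), nchar(j)))
    }
    got <- affectReads(idx, read)[[1]]
    want <- oracleAffect(w$collection, read, idx@pattern)
    expect_length(got, length(want))
    for (p in seq_along(want)) {
      if (length(want[[p]]) == 0) {
        expect_identical(got[p], 0L)
      } else if (length(want[[p]]) > 1) {
        expect_identical(got[p], -1L)
      } else {
        expect_gt(got[p], 0)
        expect_identical(paste(lt$locus[got[p]], lt$side[got[p]],
                               lt$strand[got[p]]), want[[p]])
      }
    }
  }
})

test_that("recombined reads are DETECTED with the junction in the N region", {
  w <- simWorld(seed = 34)
  idx <- buildKmerIndex(w$collection)
  v <- substr(w$set@fivePrime[[1]]@sequence, 1, 60)
  j <- substr(w$set@threePrime[[1]]@sequence, 1, 50)
  nIns <- "GATCCAGA"                     # 8 inserted nucleotides
  read <- paste0(v, nIns, j)
  call <- callRecombination(affectRead(idx, read), minAffects = 3)
  expect_identical(call$status, "DETECTED")
  expect_identical(call$locus, "TRG")
  expect_identical(call$strand, "+")
  span <- idx@span
  expect_gte(call$center, 60 - span)
  expect_lte(call$center, 68 + span)

  # pure V copy: one-sided evidence
  pureV <- callRecombination(affectRead(idx, w$set@fivePrime[[2]]@sequence),
                             minAffects = 3)
  expect_identical(pureV$status, "NO_THREE_PRIME")

  # no germline material at all
  set.seed(35)
  rand <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  expect_true(callRecombination(affectRead(idx, rand), 3)$status
              %in% c("NO_AFFECTS", "NO_FIVE_PRIME", "NO_THREE_PRIME"))
})

test_that("reads with comparable evidence for two loci abstain", {
  set.seed(36)
  a <- simulateGermlineSet(locus = "A", nFive = 2, nThree = 2)
  b <- simulateGermlineSet(locus = "B", nFive = 2, nThree = 2)
  coll <- germlineCollection(list(a$set, b$set))
  idx <- buildKmerIndex(coll)
  read <- paste0(substr(a$set@fivePrime[[1]]@sequence, 1, 40),
                 substr(b$set@fivePrime[[1]]@sequence, 1, 40))
  call <- callRecombination(affectRead(idx, read), minAffects = 3)
  expect_identical(call$status, "AMBIGUOUS_LOCUS")
})

test_that("calls are strand invariant and monotone in minAffects", {
  w <- simWorld(seed = 37)
  idx <- buildKmerIndex(w$collection)
  sim <- simulateRepertoire(w$collection, nClones = 20, nReads = 40,
                            flipProb = 0, errorRate = 0, seed = 38)
  for (i in seq_len(20)) {
    read <- sim$reads$sequence[i]
    fwdCall <- callRecombination(affectRead(idx, read), 3)
    rcCall <- callRecombination(affectRead(idx, rcChar(read)), 3)
    expect_identical(fwdCall$status, rcCall$status)
    expect_identical(fwdCall$locus, rcCall$locus)
    if (fwdCall$status == "DETECTED") {
      expect_identical(fwdCall$strand, "+")
      expect_identical(rcCall$strand, "-")
      # coordinates are reported on the forward-oriented read: identical
      expect_identical(fwdCall$center, rcCall$center)
    }
    # monotonicity: raising the threshold never creates a detection
    st <- vapply(1:8, function(m)
      callRecombination(affectRead(idx, read), m)$status, character(1))
    det <- st == "DETECTED"
    expect_true(all(diff(as.integer(det)) <= 0))
  }
})
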