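# Synthetic germline sets and recombined repertoires with full ground
# truth. Stands in for licensed germline databases: toy gene sets carry the
# same structural features the caller relies on (anchored conserved codons,
# short D genes, neighbor pads, spaced-seed-indexable sequences).

# uniform integer in [lo, hi]; safe for degenerate ranges
sampleRange <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# random genes with pairwise edit distance >= floor (rejection sampling)
randomGenes <- function(n, lenRange, floor, existing = character(0),
                        maxTries = 1000L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- randomDNA(sampleRange(lenRange[1], lenRange[2]))
    pool <- c(existing, out)
    if (!length(pool) ||
        all(utils::adist(cand, pool) >= floor)) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not generate genes at the requested distance floor",
           call. = FALSE)
  }
  out
}

#' Simulate a germline gene set
#'
#' Generates random 5' and 3' genes (and optionally D genes) with a
#' pairwise edit-distance floor, so gene identity is recoverable by
#' alignment. 5' genes receive a Cys codon (TGT) at a known anchor position
#' near their 3' end together with a consistent gapped sequence placing
#' that codon at the conventional gapped position; 3' genes carry a
#' Phe/Trp-Gly-X-Gly motif at a known position. All positions are recorded
#' in the gene anchors, so simulated rearrangements have exact CDR3 truth.
#'
#' @param locus locus label.
#' @param nFive,nThree,nD gene counts (D genes returned separately).
#' @param fiveLength,threeLength,dLength length ranges; D genes default to
#'   the short 8-37 nt range typical of D segments.
#' @param distanceFloor minimum pairwise edit distance between genes of the
#'   same list.
#' @param anchors embed conserved-codon anchors (disable for incomplete
#'   systems, which have no CDR3).
#' @param seedPattern spaced-seed pattern stored in the set.
#' @param complete completeness flag of the set.
#' @param seed optional RNG seed (\code{set.seed}) for reproducibility.
#' @return a list: \code{set} (a \linkS4class{GermlineSet}) and \code{dGenes}
#'   (list of \linkS4class{GermlineGene}, possibly empty).
#' @export
simulateGermlineSet <- function(locus = "SIM", nFive = 3L, nThree = 2L,
                                nD = 0L, fiveLength = c(90, 110),
                                threeLength = c(50, 70), dLength = c(8, 37),
                                distanceFloor = 10L, anchors = TRUE,
                                seedPattern = "##########", complete = TRUE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fiveSeqs <- randomGenes(nFive, fiveLength, distanceFloor)
  threeSeqs <- randomGenes(nThree, threeLength, distanceFloor,
                           existing = fiveSeqs)
  five <- vector("list", nFive)
  for (i in seq_len(nFive)) {
    s <- fiveSeqs[i]
    len <- nchar(s)
    if (anchors) {
      a <- len - 18L                       # Cys codon 18 nt from the 3' end
      a <- a - (a %% 3L)                   # keep the gene frame codon-aligned
      substr(s, a + 1L, a + 3L) <- "TGT"
      gapped <- paste0(substr(s, 1, a), strrep(".", 309L - a),
                       substr(s, a + 1L, len))
      five[[i]] <- germlineGene(sprintf("%sV%d*01", locus, i), s,
                                gappedSequence = gapped,
                                anchor = a)
    } else {
      five[[i]] <- germlineGene(sprintf("%sV%d*01", locus, i), s)
    }
  }
  three <- vector("list", nThree)
  for (i in seq_len(nThree)) {
    s <- threeSeqs[i]
    if (anchors) {
      a <- 12L                             # F/W codon at a fixed offset
      motif <- paste0(sample(c("TTT", "TTC", "TGG"), 1),
                      "GG", substr(s, a + 6L, a + 6L),
                      substr(s, a + 7L, a + 9L),
                      "GG", substr(s, a + 12L, a + 12L))
      substr(s, a + 1L, a + 12L) <- motif
      three[[i]] <- germlineGene(sprintf("%sJ%d*01", locus, i), s,
                                 anchor = a)
    } else {
      three[[i]] <- germlineGene(sprintf("%sJ%d*01", locus, i), s)
    }
  }
  dGenes <- list()
  if (nD > 0L) {
    dSeqs <- randomGenes(nD, dLength, min(distanceFloor, dLength[1]),
                         existing = c(fiveSeqs, threeSeqs))
    dGenes <- lapply(seq_len(nD), function(i)
      germlineGene(sprintf("%sD%d*01", locus, i), dSeqs[i]))
  }
  list(set = germlineSet(locus, five, three, seedPattern = seedPattern,
                         complete = complete),
       dGenes = dGenes)
}

#' Simulate a recombined repertoire with ground truth
#'
#' Builds \code{nClones} distinct rearrangements over the sets of a
#' collection — each a 5'-gene remnant, inserted N nucleotides, optional D
#' remnants with flanking N regions, and a 3'-gene remnant — then draws
#' reads per an abundance law, applies substitution errors and flips a
#' fraction of reads onto the minus strand. Every read and clone carries
#' complete truth (genes, deletions, N strings, junction coordinates when
#' both anchors survive the deletions, productivity by direct frame/stop
#' arithmetic, and the expected junction window).
#'
#' @param collection a \linkS4class{GermlineCollection} (typically from
#'   \code{\link{simulateGermlineSet}}).
#' @param nClones number of distinct rearrangements.
#' @param nReads total reads drawn.
#' @param abundance \code{"geometric"} (clone i proportional to
#'   \code{r^i}, giving a realistic major/minor clone structure) or
#'   \code{"uniform"}.
#' @param r geometric ratio (default 0.7).
#' @param errorRate per-base substitution probability.
#' @param delRange inclusive range of exonuclease deletions at each
#'   recombined gene end.
#' @param nRange inclusive range of inserted-N lengths.
#' @param dPerClone number of D segments per clone on loci that have middle
#'   genes (1 = VDJ, 2 = VDDJ, 3 = VDDDJ).
#' @param dMinRemnant minimum retained D length after deletions.
#' @param minRemnant minimum retained 5'/3' gene length after deletions.
#' @param flipProb probability a read is emitted on the minus strand.
#' @param w window length used for the truth window.
#' @param seed optional RNG seed.
#' @return a list: \code{reads} (data.frame id, sequence, quality, clone,
#'   flipped), \code{clones} (truth table: locus, genes, deletions,
#'   nStrings, junctionStart/End, productive, window, sequence) and
#'   \code{params}.
#' @export
simulateRepertoire <- function(collection, nClones = 10L, nReads = 1000L,
                               abundance = c("geometric", "uniform"),
                               r = 0.7, errorRate = 0, delRange = c(0, 8),
                               nRange = c(2, 10), dPerClone = 1L,
                               dMinRemnant = 12L, minRemnant = 40L,
                               flipProb = 0.2, w = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  abundance <- match.arg(abundance)
  stopifnot(is(collection, "GermlineCollection"))
  sets <- collection@sets

  clones <- vector("list", nClones)
  seen <- character(0)
  k <- 0L
  guard <- 0L
  while (k < nClones) {
    guard <- guard + 1L
    if (guard > 50L * nClones)
      stop("could not generate distinct clones; relax parameters",
           call. = FALSE)
    set <- sets[[sample.int(length(sets), 1)]]
    vG <- set@fivePrime[[sample.int(length(set@fivePrime), 1)]]
    jG <- set@threePrime[[sample.int(length(set@threePrime), 1)]]
    dList <- collection@middleGenes[[set@locus]]
    nD <- if (is.null(dList) || !length(dList)) 0L else dPerClone

    vLen <- nchar(vG@sequence)
    vDel <- min(sampleRange(delRange[1], delRange[2]),
                max(0L, vLen - minRemnant))
    vRem <- substr(vG@sequence, 1, vLen - vDel)

    jLen <- nchar(jG@sequence)
    jDel <- min(sampleRange(delRange[1], delRange[2]),
                max(0L, jLen - minRemnant))
    jRem <- substr(jG@sequence, jDel + 1L, jLen)

    dNames <- character(0); dDel5 <- integer(0); dDel3 <- integer(0)
    dRems <- character(0)
    if (nD > 0L) {
      nD <- min(nD, length(dList))
      picks <- sample.int(length(dList), nD, replace = FALSE)
      picks <- sort(picks)      # biological D order along the locus
      for (p in picks) {
        dg <- dList[[p]]
        dLen <- nchar(dg@sequence)
        room <- max(0L, dLen - dMinRemnant)
        d5 <- sampleRange(0L, min(delRange[2], room))
        d3 <- sampleRange(0L, min(delRange[2], room - d5))
        dNames <- c(dNames, dg@name)
        dDel5 <- c(dDel5, d5); dDel3 <- c(dDel3, d3)
        dRems <- c(dRems, substr(dg@sequence, d5 + 1L, dLen - d3))
      }
    }
    nStrings <- vapply(seq_len(nD + 1L), function(i) {
      len <- sampleRange(nRange[1], nRange[2])
      if (len == 0L) "" else randomDNA(len)
    }, character(1))

    middle <- character(0)
    for (i in seq_len(nD))
      middle <- c(middle, nStrings[i], dRems[i])
    middle <- c(middle, nStrings[nD + 1L])
    seqFull <- paste0(vRem, paste(middle, collapse = ""), jRem)
    if (seqFull %in% seen) next

    vRemLen <- nchar(vRem)
    insLen <- sum(nchar(middle))
    jRemLen <- nchar(jRem)
    # junction truth (codon 104 start .. codon 118 end) when both anchors
    # survive the deletions
    aV <- vG@anchor
    aJ <- jG@anchor
    anchorsKept <- !is.na(aV) && !is.na(aJ) &&
      (aV + 3L <= vRemLen) && (jDel <= aJ)
    jStart <- if (anchorsKept) aV else NA_integer_
    jEnd <- if (anchorsKept) vRemLen + insLen + (aJ - jDel) + 3L
            else NA_integer_
    productive <- NA
    if (anchorsKept) {
      jlen <- jEnd - jStart
      productive <- FALSE
      if (jlen %% 3L == 0L) {
        codons <- substring(substr(seqFull, jStart + 1L, jEnd),
                            seq(1, jlen - 2, by = 3),
                            seq(3, jlen, by = 3))
        productive <- !any(codons %in% c("TAA", "TAG", "TGA"))
      }
    }
    # expected caller window: the junction gap midpoint between the last
    # base of the 5' remnant and the first base of the 3' remnant
    center <- ((vRemLen - 1L) + (vRemLen + insLen)) %/% 2L
    window <- if (center - w %/% 2L >= 0L &&
                  center + w %/% 2L <= nchar(seqFull))
      substr(seqFull, center - w %/% 2L + 1L, center + w %/% 2L)
    else NA_character_

    k <- k + 1L
    seen <- c(seen, seqFull)
    clones[[k]] <- data.frame(
      clone = k, locus = set@locus, fiveGene = vG@name,
      threeGene = jG@name, dGenes = paste(dNames, collapse = ";"),
      fiveDel = vDel, threeDel = jDel,
      dDel5 = paste(dDel5, collapse = ";"),
      dDel3 = paste(dDel3, collapse = ";"),
      nStrings = paste(nStrings, collapse = ";"),
      junctionStart = jStart, junctionEnd = jEnd,
      productive = productive, window = window, sequence = seqFull,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, clones)

  prob <- switch(abundance,
                 uniform = rep(1, nClones),
                 geometric = r^(seq_len(nClones) - 1L))
  cloneOf <- sample.int(nClones, nReads, replace = TRUE,
                        prob = prob / sum(prob))
  flipped <- stats::runif(nReads) < flipProb
  seqs <- if (errorRate > 0) {
    vapply(truth$sequence[cloneOf], mutateSeq, character(1),
           rate = errorRate, USE.NAMES = FALSE)
  } else {
    truth$sequence[cloneOf]
  }
  if (any(flipped)) seqs[flipped] <- revcompChar(seqs[flipped])
  reads <- data.frame(
    id = sprintf("read%06d clone=%d", seq_len(nReads), cloneOf),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    clone = cloneOf, flipped = flipped, stringsAsFactors = FALSE)
  list(reads = reads, clones = truth,
       params = list(nClones = nClones, nReads = nReads,
                     abundance = abundance, r = r, errorRate = errorRate,
                     delRange = delRange, nRange = nRange,
                     dPerClone = dPerClone, flipProb = flipProb, w = w))
}

#' Simulate a small multi-locus germline universe
#'
#' The bundled benchmark configuration: two complete V-J systems (TRG-like
#' and IGH-like) plus one incomplete D-D system (Dd2/Dd3-like) whose short
#' D genes are extended with 40-nt genomic neighbor pads so that they carry
#' enough spaced k-mers to be detectable, and a TRD-like complete system
#' with three D genes for multi-D (VDDJ/VDDDJ) designation. All sequences
#' are synthetic with full truth; no licensed germline data is included.
#'
#' @param seed RNG seed.
#' @param withTRD include the TRD-like system with D genes.
#' @return a \linkS4class{GermlineCollection}.
#' @export
simulateStudyCollection <- function(seed = 1L, withTRD = TRUE) {
  set.seed(seed)
  trg <- simulateGermlineSet(locus = "TRG", nFive = 5L, nThree = 3L,
                             fiveLength = c(90, 110), threeLength = c(55, 70))
  igh <- simulateGermlineSet(locus = "IGH", nFive = 4L, nThree = 2L,
                             fiveLength = c(90, 110), threeLength = c(55, 70))
  # incomplete Dd2/Dd3-like system: short D genes, no CDR3 anchors; the
  # neighbor pads restore seed coverage and window context
  dd <- simulateGermlineSet(locus = "TRD+Dd3", nFive = 2L, nThree = 2L,
                            fiveLength = c(12, 16), threeLength = c(12, 16),
                            anchors = FALSE, complete = FALSE)
  padded5 <- lapply(dd$set@fivePrime, function(g)
    padWithNeighbors(g, upstream = randomDNA(40L)))
  padded3 <- lapply(dd$set@threePrime, function(g)
    padWithNeighbors(g, downstream = randomDNA(40L)))
  ddSet <- germlineSet("TRD+Dd3", padded5, padded3, complete = FALSE)
  sets <- list(trg$set, igh$set, ddSet)
  middle <- list()
  if (withTRD) {
    trd <- simulateGermlineSet(locus = "TRD", nFive = 4L, nThree = 3L,
                               nD = 3L, fiveLength = c(90, 110),
                               threeLength = c(55, 70), dLength = c(20, 37))
    sets <- c(sets, trd$set)
    middle <- list(TRD = trd$dGenes)
  }
  germlineCollection(sets, middleGenes = middle)
}

#' Write a simulated repertoire to FASTQ and its truth table to TSV
#'
#' @param sim result of \code{\link{simulateRepertoire}}.
#' @param fastqPath output FASTQ (qualities are constant \code{'I'}; the
#'   caller ignores them).
#' @param truthPath optional output TSV of the clone truth table.
#' @return \code{fastqPath}, invisibly.
#' @export
writeSimulatedFastq <- function(sim, fastqPath, truthPath = NULL) {
  lines <- as.vector(rbind(paste0("@", sim$reads$id),
                           sim$reads$sequence,
                           "+",
                           sim$reads$quality))
  writeLines(lines, fastqPath)
  if (!is.null(truthPath))
    utils::write.table(sim$clones, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fastqPath)
}
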