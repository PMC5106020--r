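# Detailed V(D)J designation of clonotype representatives by dynamic
# programming: semi-global 5'/3' gene alignment, greedy multi-D placement in
# the junction, deletion and N-region coordinates.

#' Default alignment scoring for gene designation
#'
#' Linear gap penalties; indels are penalized strongly because V(D)J
#' junction variation is substitution-dominated, and the acceptance
#' thresholds correspond to roughly 15 matched nucleotides for the 5'/3'
#' genes and 8 for the short D genes (D genes run 8-37 bp).
#'
#' @param match,mismatch,gap alignment scores.
#' @param minScore minimum 5'/3' alignment score to accept a designation.
#' @param dMinScore,dMinLen minimum local-alignment score and aligned gene
#'   length for a D gene to be placed in the junction.
#' @return a list of scoring parameters.
#' @export
designationScoring <- function(match = 2L, mismatch = -3L, gap = -7L,
                               minScore = 30L, dMinScore = 16L,
                               dMinLen = 8L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap), minScore = as.integer(minScore),
       dMinScore = as.integer(dMinScore), dMinLen = as.integer(dMinLen))
}

#' Semi-global gene-to-sequence alignments
#'
#' \code{alignFivePrime} aligns a 5' (V-side) gene against the left end of a
#' sequence: the aligned region of the sequence is a prefix of the sequence,
#' the gene may start anywhere (a read often begins inside the gene), and
#' both alignment ends are free (the gene's 3' end is typically deleted by
#' the recombination). \code{alignThreePrime} is the mirror image for 3'
#' (J-side) genes. Ties are broken deterministically (smallest end on the
#' sequence, then on the gene).
#'
#' @param gene a \linkS4class{GermlineGene} or a DNA string.
#' @param seq DNA string (forward-oriented representative).
#' @param scoring a \code{\link{designationScoring}} list.
#' @return a list with \code{score} and 0-based half-open intervals
#'   \code{start}/\code{end} on \code{seq} and \code{geneStart}/
#'   \code{geneEnd} on the gene.
#' @export
alignFivePrime <- function(gene, seq, scoring = designationScoring()) {
  g <- if (is(gene, "GermlineGene")) gene@sequence else gene
  r <- align_left_cpp(g, seq, scoring$match, scoring$mismatch, scoring$gap)
  list(score = r$score, start = 0L, end = r$seq_end,
       geneStart = r$gene_start, geneEnd = r$gene_end)
}

#' @rdname alignFivePrime
#' @export
alignThreePrime <- function(gene, seq, scoring = designationScoring()) {
  g <- if (is(gene, "GermlineGene")) gene@sequence else gene
  revStr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  m <- nchar(g); n <- nchar(seq)
  r <- align_left_cpp(revStr(g), revStr(seq),
                      scoring$match, scoring$mismatch, scoring$gap)
  list(score = r$score, start = n - r$seq_end, end = n,
       geneStart = m - r$gene_end, geneEnd = m - r$gene_start)
}

# Best gene of a list under an alignment function; score ties resolved to
# the lexicographically smallest allele name, with the tie list recorded.
bestGene <- function(genes, alignFun, seq, scoring) {
  res <- lapply(genes, alignFun, seq = seq, scoring = scoring)
  scores <- vapply(res, `[[`, numeric(1), "score")
  names <- vapply(genes, function(g) g@name, character(1))
  top <- which(scores == max(scores))
  pick <- top[order(names[top])][1]
  list(gene = genes[[pick]], aln = res[[pick]],
       ties = sort(names[setdiff(top, pick)]))
}

#' Compute the detailed V(D)J designation of a representative sequence
#'
#' The 5' gene maximizing the left-anchored semi-global score and the 3'
#' gene maximizing the right-anchored score are chosen; if either best
#' score is below the acceptance threshold the sequence is UNSEGMENTED.
#' The region between the two alignments is then scanned greedily for up to
#' \code{maxD} D genes by best local alignment (each accepted only above
#' the D score and length thresholds — relevant for TRD-like loci where
#' VDDJ and VDDDJ rearrangements occur); remaining segments become N
#' regions. Deletion counts derive from the unaligned gene ends.
#'
#' @param rep forward-oriented representative DNA string.
#' @param set the \linkS4class{GermlineSet} the clonotype was assigned to.
#' @param dGenes list of candidate D \linkS4class{GermlineGene} (may be
#'   empty).
#' @param maxD maximum number of D genes to place (1-3; 3 only makes sense
#'   for TRD-like systems).
#' @param scoring a \code{\link{designationScoring}} list.
#' @return a list with \code{status} ("DESIGNATED" or "UNSEGMENTED") and,
#'   when designated: \code{fiveGene}, \code{fiveDel}, \code{nRegions}
#'   (character vector), \code{dGenes} (list of (name, del5, del3)),
#'   \code{threeGene}, \code{threeDel}, alignment coordinates
#'   (\code{fiveGeneStart/End}, \code{fiveSeqEnd}, \code{threeGeneStart/End},
#'   \code{threeSeqStart}), scores, allele tie lists and \code{text}, the
#'   compact string form (e.g. \code{"TRGV2*01 0/7/0 TRGJP1*01"} = 5' gene,
#'   3'-deletion / N length / 5'-deletion, 3' gene).
#' @export
designate <- function(rep, set, dGenes = list(), maxD = 1L,
                      scoring = designationScoring()) {
  stopifnot(is(set, "GermlineSet"), maxD %in% 1:3)
  five <- bestGene(set@fivePrime, alignFivePrime, rep, scoring)
  three <- bestGene(set@threePrime, alignThreePrime, rep, scoring)
  if (five$aln$score < scoring$minScore || three$aln$score < scoring$minScore)
    return(list(status = "UNSEGMENTED"))

  fiveEnd <- five$aln$end
  threeStart <- three$aln$start
  fiveGeneEnd <- five$aln$geneEnd
  threeGeneStart <- three$aln$geneStart
  if (fiveEnd > threeStart) {
    # the two alignments overlap on the sequence (the junction coincidentally
    # extends a gene); trim the 5' side back, assuming a gapless tail
    ov <- fiveEnd - threeStart
    fiveEnd <- fiveEnd - ov
    fiveGeneEnd <- max(five$aln$geneStart, fiveGeneEnd - ov)
  }

  # greedy multi-D placement in the middle segments
  segs <- if (threeStart > fiveEnd)
    list(c(fiveEnd, threeStart)) else list()
  placedD <- list()
  if (length(dGenes) && maxD >= 1L) {
    while (length(placedD) < maxD && length(segs)) {
      best <- NULL
      for (si in seq_along(segs)) {
        seg <- segs[[si]]
        sub <- substr(rep, seg[1] + 1L, seg[2])
        for (g in dGenes) {
          loc <- align_local_cpp(g@sequence, sub, scoring$match,
                                 scoring$mismatch, scoring$gap)
          if (loc$score >= scoring$dMinScore &&
              (loc$gene_end - loc$gene_start) >= scoring$dMinLen &&
              (is.null(best) || loc$score > best$score ||
               (loc$score == best$score && g@name < best$gene@name))) {
            best <- list(score = loc$score, gene = g, seg = si,
                         seqStart = seg[1] + loc$seq_start,
                         seqEnd = seg[1] + loc$seq_end,
                         geneStart = loc$gene_start,
                         geneEnd = loc$gene_end)
          }
        }
      }
      if (is.null(best)) break
      placedD[[length(placedD) + 1L]] <- best
      seg <- segs[[best$seg]]
      newSegs <- list()
      if (best$seqStart > seg[1]) newSegs <- c(newSegs, list(c(seg[1], best$seqStart)))
      if (seg[2] > best$seqEnd) newSegs <- c(newSegs, list(c(best$seqEnd, seg[2])))
      segs <- c(segs[-best$seg], newSegs)
    }
  }
  placedD <- placedD[order(vapply(placedD, `[[`, numeric(1), "seqStart"))]

  # N regions are the unexplained middle segments, left to right
  bounds <- c(fiveEnd,
              unlist(lapply(placedD, function(d) c(d$seqStart, d$seqEnd))),
              threeStart)
  nRegions <- character(0)
  for (i in seq(1, length(bounds) - 1, by = 2))
    nRegions <- c(nRegions, substr(rep, bounds[i] + 1L, bounds[i + 1]))

  dOut <- lapply(placedD, function(d) {
    list(name = d$gene@name,
         del5 = d$geneStart,
         del3 = nchar(d$gene@sequence) - d$geneEnd,
         seqStart = d$seqStart, seqEnd = d$seqEnd)
  })
  des <- list(
    status = "DESIGNATED",
    locus = set@locus,
    fiveGene = five$gene@name,
    fiveDel = nchar(five$gene@sequence) - fiveGeneEnd,
    nRegions = nRegions,
    dGenes = dOut,
    threeGene = three$gene@name,
    threeDel = threeGeneStart,
    fiveGeneStart = five$aln$geneStart, fiveGeneEnd = fiveGeneEnd,
    fiveSeqEnd = fiveEnd,
    threeGeneStart = threeGeneStart, threeGeneEnd = three$aln$geneEnd,
    threeSeqStart = threeStart,
    fiveScore = five$aln$score, threeScore = three$aln$score,
    fiveTies = five$ties, threeTies = three$ties)
  des$text <- formatDesignation(des)
  des
}

#' Compact string form of a designation
#'
#' \code{"V a/n/b J"}: \code{a} nucleotides deleted at the V 3' end,
#' \code{n} inserted N nucleotides, \code{b} deleted at the J 5' end. With D
#' genes: \code{"V a/n1/c1 D c2/n2/b J"} where \code{c1}/\code{c2} are the
#' D gene's 5'/3' deletions.
#'
#' @param des a designation from \code{\link{designate}}.
#' @return a single string.
#' @export
formatDesignation <- function(des) {
  if (!identical(des$status, "DESIGNATED")) return(NA_character_)
  nl <- nchar(des$nRegions)
  parts <- des$fiveGene
  left <- des$fiveDel
  for (i in seq_along(des$dGenes)) {
    d <- des$dGenes[[i]]
    parts <- c(parts, sprintf("%d/%d/%d", left, nl[i], d$del5), d$name)
    left <- d$del3
  }
  parts <- c(parts, sprintf("%d/%d/%d", left, nl[length(nl)], des$threeDel),
             des$threeGene)
  paste(parts, collapse = " ")
}
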