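# CDR3/JUNCTION location via conserved-residue anchors (Cys104 on the V
# side, Phe/Trp118 on the J side) and productivity calling.

#' Resolve the conserved-codon anchor of a germline gene
#'
#' Resolution order: an explicit anchor (from the configuration) overrides
#' everything. For 5' genes with an IMGT-style gapped sequence, the anchor
#' is the ungapped position of the nucleotide at the conventional gapped
#' position of the Cys104 codon start (\code{gappedPos}, 1-based, default
#' 310). For 3' genes without gapped data, the first occurrence of a
#' Phe/Trp-Gly-X-Gly motif (codon \code{TTT|TTC|TGG}, then \code{GGN},
#' any codon, \code{GGN}) gives the position of the F/W codon.
#'
#' @param gene a \linkS4class{GermlineGene}.
#' @param side \code{"five"} or \code{"three"}.
#' @param gappedPos 1-based gapped nucleotide position of the first
#'   nucleotide of codon 104.
#' @return 0-based anchor position in the ungapped sequence, or
#'   \code{NA_integer_} when it cannot be resolved (downstream this yields a
#'   NO_ANCHOR CDR3 call; incomplete loci have no CDR3).
#' @export
resolveAnchor <- function(gene, side = c("five", "three"), gappedPos = 310L) {
  stopifnot(is(gene, "GermlineGene"))
  side <- match.arg(side)
  if (!is.na(gene@anchor)) return(gene@anchor)
  if (side == "five") {
    gs <- gene@gappedSequence
    if (is.na(gs) || nchar(gs) < gappedPos) return(NA_integer_)
    chars <- strsplit(gs, "")[[1]]
    if (chars[gappedPos] == ".") return(NA_integer_)
    a <- sum(chars[seq_len(gappedPos - 1L)] != ".")
    if (a > nchar(gene@sequence) - 3L) return(NA_integer_)
    return(as.integer(a))
  }
  # 3' side: F/W - G - X - G motif scan on the ungapped sequence
  s <- gene@sequence
  n <- nchar(s)
  if (n < 12L) return(NA_integer_)
  for (i in seq_len(n - 11L)) {
    if (substr(s, i, i + 2L) %in% c("TTT", "TTC", "TGG") &&
        substr(s, i + 3L, i + 4L) == "GG" &&
        substr(s, i + 9L, i + 10L) == "GG")
      return(as.integer(i - 1L))
  }
  NA_integer_
}

#' Locate the CDR3/JUNCTION on a designated sequence and call productivity
#'
#' The Cys104 codon start of the designated 5' gene is mapped through the V
#' alignment onto the representative (junction start) and the end of the
#' Phe/Trp118 codon of the 3' gene through the J alignment (junction end).
#' If either anchor codon falls in a deleted region of its gene the call is
#' NO_ANCHOR. A rearrangement is productive when the junction length is a
#' multiple of 3 and the junction reading frame contains no stop codon; the
#' CDR3 amino-acid string is the translation of the junction minus its two
#' anchor codons (positions 105-117).
#'
#' @param rep forward-oriented representative DNA string.
#' @param des a designation from \code{\link{designate}}.
#' @param set the \linkS4class{GermlineSet} carrying the designated genes.
#' @return a list: \code{junctionStart}, \code{junctionEnd} (0-based
#'   half-open on \code{rep}), \code{cdr3AA}, \code{productive},
#'   \code{reason} (IN_FRAME, OUT_OF_FRAME, STOP_CODON or NO_ANCHOR).
#' @export
locateCDR3 <- function(rep, des, set) {
  noAnchor <- list(junctionStart = NA_integer_, junctionEnd = NA_integer_,
                   cdr3AA = NA_character_, productive = FALSE,
                   reason = "NO_ANCHOR")
  if (!identical(des$status, "DESIGNATED")) return(noAnchor)
  vGene <- findGene(set, des$fiveGene)
  jGene <- findGene(set, des$threeGene)
  if (is.null(vGene) || is.null(jGene)) return(noAnchor)
  aV <- resolveAnchor(vGene, "five")
  aJ <- resolveAnchor(jGene, "three")
  if (is.na(aV) || is.na(aJ)) return(noAnchor)
  # anchor codons must be fully inside the aligned gene regions
  if (aV < des$fiveGeneStart || aV + 3L > des$fiveGeneEnd) return(noAnchor)
  if (aJ < des$threeGeneStart || aJ + 3L > des$threeGeneEnd) return(noAnchor)
  # map each anchor through the end of its alignment that lies in true
  # germline: the V anchor from the alignment's left (read start), the J
  # anchor from its right (read end); chance indels where an alignment
  # extends into the junction then cannot shift the mapping
  jStart <- aV - des$fiveGeneStart                     # V alignment starts at 0
  jEnd <- nchar(rep) - (des$threeGeneEnd - aJ - 3L)
  if (jEnd <= jStart) return(noAnchor)

  len <- jEnd - jStart
  if (len %% 3L != 0L)
    return(list(junctionStart = jStart, junctionEnd = jEnd,
                cdr3AA = NA_character_, productive = FALSE,
                reason = "OUT_OF_FRAME"))
  junction <- substr(rep, jStart + 1L, jEnd)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(junction),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  if (grepl("*", aa, fixed = TRUE))
    return(list(junctionStart = jStart, junctionEnd = jEnd,
                cdr3AA = NA_character_, productive = FALSE,
                reason = "STOP_CODON"))
  list(junctionStart = jStart, junctionEnd = jEnd,
       cdr3AA = substr(aa, 2L, nchar(aa) - 1L),
       productive = TRUE, reason = "IN_FRAME")
}
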