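# Spaced-seed index, per-read affectation, recombination calling.

validateSeedPattern <- function(pattern) {
  if (length(pattern) != 1L || !grepl("^[#-]+$", pattern))
    stop("seed pattern must be a string over '#' and '-'", call. = FALSE)
  if (!grepl("^#", pattern) || !grepl("#$", pattern))
    stop("seed pattern must start and end with '#'", call. = FALSE)
  invisible(pattern)
}

#' Spaced seed
#'
#' A seed pattern over \code{#} (match position) and \code{-} (don't-care).
#' The span is the pattern length, the weight the number of \code{#}
#' positions; lookup keys consist of the read characters under the \code{#}
#' positions only, so isolated substitutions under a \code{-} do not break
#' a match.
#'
#' @param pattern string over \code{#}/\code{-}, starting and ending with
#'   \code{#}.
#' @return a list with elements \code{pattern}, \code{span}, \code{weight}.
#' @examples
#' spacedSeed("#####-#####-###")
#' @export
spacedSeed <- function(pattern) {
  validateSeedPattern(pattern)
  list(pattern = pattern,
       span = nchar(pattern),
       weight = lengths(regmatches(pattern, gregexpr("#", pattern))))
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the spaced-seed k-mer index of a germline collection
#'
#' Every spaced k-mer of every 5' and 3' gene of every set, on both strands,
#' is entered under its (locus, side, strand) label. A masked k-mer seen
#' under two or more distinct labels becomes AMBIGUOUS and supports no
#' specific locus during affectation. Genes shorter than the seed span
#' contribute no k-mers; a warning is recorded per such gene.
#'
#' @param collection a validated \linkS4class{GermlineCollection}.
#' @param seed a seed pattern string or \code{\link{spacedSeed}} result;
#'   \code{NULL} uses the first set's configured pattern.
#' @return a \linkS4class{KmerIndex}.
#' @export
buildKmerIndex <- function(collection, seed = NULL) {
  stopifnot(is(collection, "GermlineCollection"))
  if (is.null(seed)) seed <- collection@sets[[1]]@seedPattern
  if (is.list(seed)) seed <- seed$pattern
  validateSeedPattern(seed)
  span <- nchar(seed)

  labelTable <- data.frame(locus = character(0), side = character(0),
                           strand = character(0),
                           stringsAsFactors = FALSE)
  labelId <- function(locus, side, strand) {
    hit <- which(labelTable$locus == locus & labelTable$side == side &
                 labelTable$strand == strand)
    if (length(hit)) return(hit)
    labelTable[nrow(labelTable) + 1L, ] <<- c(locus, side, strand)
    nrow(labelTable)
  }

  keyList <- list()
  labList <- list()
  warns <- character(0)
  for (set in collection@sets) {
    for (side in c("5", "3")) {
      genes <- if (side == "5") set@fivePrime else set@threePrime
      for (g in genes) {
        if (nchar(g@sequence) < span) {
          warns <- c(warns, sprintf(
            "gene %s (%s, %d nt) is shorter than the seed span %d; no k-mers",
            g@name, set@locus, nchar(g@sequence), span))
          next
        }
        fwd <- masked_kmers_cpp(g@sequence, seed)
        rev <- masked_kmers_cpp(revcompChar(g@sequence), seed)
        keyList[[length(keyList) + 1L]] <- fwd[!is.na(fwd)]
        labList[[length(labList) + 1L]] <-
          rep(labelId(set@locus, side, "+"), sum(!is.na(fwd)))
        keyList[[length(keyList) + 1L]] <- rev[!is.na(rev)]
        labList[[length(labList) + 1L]] <-
          rep(labelId(set@locus, side, "-"), sum(!is.na(rev)))
      }
    }
  }
  keys <- unlist(keyList, use.names = FALSE)
  labs <- unlist(labList, use.names = FALSE)
  if (is.null(keys)) keys <- character(0)
  if (is.null(labs)) labs <- integer(0)

  # collapse duplicates: same label -> keep; >= 2 distinct labels -> AMBIGUOUS
  if (length(keys)) {
    first <- !duplicated(keys)
    uk <- keys[first]
    ul <- labs[first]
    conflicting <- tapply(labs, keys, function(v) length(unique(v)) > 1L)
    ul[conflicting[uk]] <- -1L
    keys <- uk
    labs <- as.integer(ul)
  }
  new("KmerIndex", keys = keys, labels = labs, labelTable = labelTable,
      pattern = seed, span = as.integer(span),
      weight = as.integer(spacedSeed(seed)$weight),
      indexWarnings = warns)
}

#' Affect reads position-wise against a k-mer index
#'
#' For each position p of each read, the masked spaced k-mer starting at p
#' is looked up in the index. \code{affectReads} is the batch form returning
#' a list of integer label vectors (0 = no affect, -1 = AMBIGUOUS, otherwise
#' a row of the index label table); \code{affectRead} wraps a single read
#' into an affectation vector structure.
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param reads character vector of read sequences (A,C,G,T,N; any window
#'   containing a non-ACGT character yields no affect).
#' @param read a single read sequence.
#' @param readId identifier stored in the affectation vector.
#' @return \code{affectReads}: list of integer vectors of length
#'   \code{max(0, nchar(read) - span + 1)}. \code{affectRead}: a list with
#'   elements \code{readId}, \code{readLength}, \code{labels},
#'   \code{labelTable}, \code{span}.
#' @export
affectReads <- function(index, reads) {
  stopifnot(is(index, "KmerIndex"))
  affect_reads_cpp(toupper(as.character(reads)), index@keys, index@labels,
                   index@pattern)
}

#' @rdname affectReads
#' @export
affectRead <- function(index, read, readId = "read") {
  labs <- affectReads(index, read)[[1]]
  structure(list(readId = readId, readLength = nchar(read), labels = labs,
                 labelTable = index@labelTable, span = index@span),
            class = "AffectationVector")
}

# Statuses a read can take through detection and windowing.
READ_STATUSES <- c("DETECTED", "NO_FIVE_PRIME", "NO_THREE_PRIME",
                   "NO_AFFECTS", "AMBIGUOUS_LOCUS", "TOO_SHORT")

#' Decide whether a read carries a V(D)J recombination and locate the junction
#'
#' Counts non-ambiguous affects per (locus, strand) pair, requires at least
#' \code{minAffects} 5' affects and \code{minAffects} 3' affects of the
#' winning pair with the 5' evidence upstream of the 3' evidence (after
#' reverse-complement reorientation for minus-strand reads), and places the
#' junction between the end of the last 5'-labelled seed and the start of
#' the first 3'-labelled seed. If the runner-up (locus, strand) pair has at
#' least 90\% of the winner's affects the read is called AMBIGUOUS_LOCUS
#' rather than arbitrarily assigned.
#'
#' @param av an affectation vector from \code{\link{affectRead}}, or a bare
#'   integer label vector (then \code{labelTable} and \code{span} must be
#'   given).
#' @param minAffects minimum number of seed affects required on each side
#'   (default 5).
#' @param labelTable,span,readLength used when \code{av} is a bare vector.
#' @return a list: \code{status} (one of DETECTED, NO_FIVE_PRIME,
#'   NO_THREE_PRIME, NO_AFFECTS, AMBIGUOUS_LOCUS, TOO_SHORT), \code{locus},
#'   \code{strand}, and when DETECTED \code{junctionLeft} (0-based position
#'   of the rightmost 5'-labelled seed end), \code{junctionRight} (0-based
#'   position of the leftmost 3'-labelled seed start) and \code{center} =
#'   \code{floor((junctionLeft + junctionRight)/2)}, all on the
#'   forward-oriented read.
#' @export
callRecombination <- function(av, minAffects = 5L, labelTable = NULL,
                              span = NULL, readLength = NULL) {
  stopifnot(minAffects >= 1L)
  if (inherits(av, "AffectationVector")) {
    labels <- av$labels
    labelTable <- av$labelTable
    span <- av$span
    readLength <- av$readLength
  } else {
    labels <- av
  }
  none <- list(status = NA_character_, locus = NA_character_,
               strand = NA_character_, junctionLeft = NA_integer_,
               junctionRight = NA_integer_, center = NA_integer_)
  if (length(labels) == 0L) { none$status <- "TOO_SHORT"; return(none) }
  pos <- which(labels > 0L)
  if (length(pos) == 0L) { none$status <- "NO_AFFECTS"; return(none) }

  labs <- labels[pos]
  lt <- labelTable[labs, , drop = FALSE]
  pair <- paste(lt$locus, lt$strand, sep = "\r")
  tab <- sort(table(pair), decreasing = TRUE)
  # tie-break: two pairs within 10% of each other -> abstain
  if (length(tab) >= 2L && tab[2] >= 0.9 * tab[1]) {
    none$status <- "AMBIGUOUS_LOCUS"
    return(none)
  }
  bestPair <- names(tab)[1]
  bits <- strsplit(bestPair, "\r", fixed = TRUE)[[1]]
  locus <- bits[1]; strand <- bits[2]
  keep <- pair == bestPair
  p <- pos[keep] - 1L           # 0-based seed start on the read as given
  side <- lt$side[keep]
  if (strand == "-") p <- readLength - span - p   # forward-oriented coords
  p5 <- p[side == "5"]
  p3 <- p[side == "3"]
  none$locus <- locus; none$strand <- strand
  if (length(p5) < minAffects) { none$status <- "NO_FIVE_PRIME"; return(none) }
  if (length(p3) < minAffects) { none$status <- "NO_THREE_PRIME"; return(none) }
  # 5' evidence must sit upstream of 3' evidence; seed-span overlap of the
  # extreme seeds is tolerated (possible with spaced seeds), larger
  # inversions demote the weaker side
  if (max(p5) > min(p3)) {
    none$status <- if (length(p5) <= length(p3)) "NO_FIVE_PRIME"
                   else "NO_THREE_PRIME"
    return(none)
  }
  jl <- max(p5) + span - 1L
  jr <- min(p3)
  list(status = "DETECTED", locus = locus, strand = strand,
       junctionLeft = jl, junctionRight = jr,
       center = (jl + jr) %/% 2L)
}
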