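#' @useDynLib vdjcluster, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom S4Vectors mcols
#' @importFrom utils adist packageVersion write.table
#' @importFrom stats runif setNames na.omit
#' @importFrom tools file_ext
#' @import Biostrings
NULL

.ACGT_ONLY <- "^[ACGT]+$"

#' Germline gene
#'
#' A single germline gene or allele: its identifier, its ungapped DNA
#' sequence, an optional IMGT-style gapped sequence (with \code{.} gap
#' characters), an optional anchor (the 0-based position of the first
#' nucleotide of the conserved codon: Cys104 for 5' genes, Phe/Trp118 for 3'
#' genes), and the lengths of any neighbor regions concatenated onto the
#' gene (see \code{\link{padWithNeighbors}}).
#'
#' @slot name gene/allele identifier, e.g. \code{"TRGV2*01"}.
#' @slot sequence upper-case ungapped DNA string over A,C,G,T.
#' @slot gappedSequence gapped DNA string (\code{.} = gap) or \code{NA}.
#' @slot anchor 0-based anchor position in \code{sequence}, or \code{NA}.
#' @slot upstreamPad,downstreamPad lengths of included neighbor regions.
#' @exportClass GermlineGene
setClass("GermlineGene",
  representation(
    name = "character",
    sequence = "character",
    gappedSequence = "character",
    anchor = "integer",
    upstreamPad = "integer",
    downstreamPad = "integer"
  ),
  prototype(
    gappedSequence = NA_character_,
    anchor = NA_integer_,
    upstreamPad = 0L,
    downstreamPad = 0L
  )
)

setValidity("GermlineGene", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "'sequence' must be a single non-empty string")
  else if (!grepl(.ACGT_ONLY, object@sequence))
    msg <- c(msg, sprintf("gene '%s': sequence has non-ACGT characters",
                          object@name))
  if (!is.na(object@gappedSequence)) {
    ungapped <- gsub(".", "", object@gappedSequence, fixed = TRUE)
    if (!identical(ungapped, object@sequence))
      msg <- c(msg, sprintf(
        "gene '%s': gapped sequence does not match sequence after '.' removal",
        object@name))
  }
  if (!is.na(object@anchor)) {
    if (object@anchor < 0L || object@anchor > nchar(object@sequence) - 3L)
      msg <- c(msg, sprintf("gene '%s': anchor %d outside [0, len-3]",
                            object@name, object@anchor))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a germline gene
#'
#' @param name gene/allele identifier.
#' @param sequence DNA string (A,C,G,T; upper-cased on input).
#' @param gappedSequence optional gapped DNA string; removing \code{.}
#'   must yield \code{sequence}.
#' @param anchor optional 0-based position of the conserved codon's first
#'   nucleotide.
#' @param upstreamPad,downstreamPad neighbor-region lengths already included
#'   in \code{sequence}.
#' @return a \linkS4class{GermlineGene}.
#' @export
germlineGene <- function(name, sequence, gappedSequence = NA_character_,
                         anchor = NA_integer_, upstreamPad = 0L,
                         downstreamPad = 0L) {
  new("GermlineGene",
      name = as.character(name),
      sequence = toupper(as.character(sequence)),
      gappedSequence = if (is.na(gappedSequence)) NA_character_
                       else toupper(as.character(gappedSequence)),
      anchor = as.integer(anchor),
      upstreamPad = as.integer(upstreamPad),
      downstreamPad = as.integer(downstreamPad))
}

#' Germline gene set for one recombination system
#'
#' One locus (complete, e.g. TRG, or incomplete, e.g. Dd2/Dd3) with its 5'
#' ("left") and 3' ("right") gene lists and the spaced-seed pattern used to
#' index it.
#'
#' @slot locus locus label, e.g. \code{"TRG"}, \code{"TRD+"}.
#' @slot fivePrime,threePrime lists of \linkS4class{GermlineGene}.
#' @slot seedPattern spaced-seed pattern over \code{#}/\code{-}.
#' @slot complete \code{FALSE} for incomplete/unusual systems.
#' @exportClass GermlineSet
setClass("GermlineSet",
  representation(
    locus = "character",
    fivePrime = "list",
    threePrime = "list",
    seedPattern = "character",
    complete = "logical"
  ),
  prototype(seedPattern = "##########", complete = TRUE)
)

setValidity("GermlineSet", function(object) {
  msg <- character(0)
  if (length(object@fivePrime) == 0L)
    msg <- c(msg, "5' gene list is empty")
  if (length(object@threePrime) == 0L)
    msg <- c(msg, "3' gene list is empty")
  ok5 <- all(vapply(object@fivePrime, is, logical(1), "GermlineGene"))
  ok3 <- all(vapply(object@threePrime, is, logical(1), "GermlineGene"))
  if (!ok5 || !ok3)
    msg <- c(msg, "gene lists must contain GermlineGene objects")
  if (ok5 && ok3) {
    nm <- c(vapply(object@fivePrime, function(g) g@name, character(1)),
            vapply(object@threePrime, function(g) g@name, character(1)))
    if (anyDuplicated(nm))
      msg <- c(msg, sprintf("duplicate gene names in set '%s': %s",
                            object@locus,
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  tryCatch(validateSeedPattern(object@seedPattern),
           error = function(e) msg <<- c(msg, conditionMessage(e)))
  if (length(msg)) msg else TRUE
})

#' Construct a germline set
#'
#' @param locus locus label.
#' @param fivePrime,threePrime lists of \linkS4class{GermlineGene}.
#' @param seedPattern spaced-seed pattern (\code{#} = match position,
#'   \code{-} = don't care).
#' @param complete logical; \code{FALSE} for incomplete systems such as
#'   Dh/Jh or Dd2/Dd3 which have no CDR3.
#' @return a \linkS4class{GermlineSet}.
#' @export
germlineSet <- function(locus, fivePrime, threePrime,
                        seedPattern = "##########", complete = TRUE) {
  new("GermlineSet", locus = locus, fivePrime = fivePrime,
      threePrime = threePrime, seedPattern = seedPattern,
      complete = complete)
}

#' Multi-locus germline collection
#'
#' An ordered list of \linkS4class{GermlineSet} plus optional D (middle)
#' genes per locus. D genes are used only by the designation stage, never by
#' the k-mer index.
#'
#' @slot sets list of \linkS4class{GermlineSet}; locus labels unique.
#' @slot middleGenes named list, locus -> list of \linkS4class{GermlineGene}.
#' @exportClass GermlineCollection
setClass("GermlineCollection",
  representation(sets = "list", middleGenes = "list"),
  prototype(middleGenes = list())
)

setValidity("GermlineCollection", function(object) {
  msg <- character(0)
  if (!all(vapply(object@sets, is, logical(1), "GermlineSet")))
    msg <- c(msg, "'sets' must contain GermlineSet objects")
  else {
    loci <- vapply(object@sets, function(s) s@locus, character(1))
    if (anyDuplicated(loci))
      msg <- c(msg, sprintf("duplicate locus label: %s",
                            paste(unique(loci[duplicated(loci)]),
                                  collapse = ", ")))
    bad <- setdiff(names(object@middleGenes), loci)
    if (length(bad))
      msg <- c(msg, sprintf("middle genes reference unknown locus: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a germline collection
#'
#' @param sets list of \linkS4class{GermlineSet}.
#' @param middleGenes optional named list (locus -> list of D genes).
#' @return a \linkS4class{GermlineCollection}.
#' @export
germlineCollection <- function(sets, middleGenes = list()) {
  new("GermlineCollection", sets = sets, middleGenes = middleGenes)
}

#' Spaced-seed k-mer index
#'
#' Maps every masked spaced k-mer extracted from the 5'/3' genes of every
#' set of a collection, on both strands, to a (locus, side, strand) label,
#' or to AMBIGUOUS when the same masked k-mer occurs under two or more
#' distinct labels. Lookup keys are the characters at \code{#} positions of
#' the seed pattern only.
#'
#' @slot keys character vector of masked k-mer keys.
#' @slot labels integer vector parallel to \code{keys}: row number in
#'   \code{labelTable}, or \code{-1} for AMBIGUOUS.
#' @slot labelTable data.frame with columns locus, side
#'   (\code{"5"}/\code{"3"}) and strand (\code{"+"}/\code{"-"}).
#' @slot pattern,span,weight the seed pattern and its span/weight.
#' @slot indexWarnings per-gene warnings (genes shorter than the seed span
#'   contribute no k-mers).
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(
    keys = "character",
    labels = "integer",
    labelTable = "data.frame",
    pattern = "character",
    span = "integer",
    weight = "integer",
    indexWarnings = "character"
  )
)

#' Multi-sample clonotype result set
#'
#' The end product of the pipeline: per-sample metadata and read statistics,
#' a clonotype table, and a counts matrix (clonotypes x samples). Serialized
#' to/from the package's JSON result dialect by \code{\link{writeResult}}
#' and \code{\link{readResult}}.
#'
#' @slot samples data.frame with columns name, source, timestamp.
#' @slot stats list of per-sample statistics (read accounting, per-locus
#'   detected counts, diversity indices).
#' @slot clones data.frame with columns window, locus, representative, tag
#'   and list-columns designation, cdr3, mergedWindows.
#' @slot counts integer matrix, \code{nrow(clones)} x \code{nrow(samples)}.
#' @slot producer list: tool name, version, parameters, schema.
#' @exportClass ResultSet
setClass("ResultSet",
  representation(
    samples = "data.frame",
    stats = "list",
    clones = "data.frame",
    counts = "matrix",
    producer = "list"
  )
)

setValidity("ResultSet", function(object) {
  msg <- character(0)
  if (nrow(object@counts) != nrow(object@clones))
    msg <- c(msg, "counts rows must match clonotype rows")
  if (ncol(object@counts) != nrow(object@samples))
    msg <- c(msg, "counts columns must match samples")
  if (length(object@stats) != nrow(object@samples))
    msg <- c(msg, "one stats entry per sample required")
  if (nrow(object@clones) > 0 && any(rowSums(object@counts) < 1))
    msg <- c(msg, "every clonotype needs at least one read")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GermlineGene", function(object) {
  cat(sprintf("GermlineGene %s (%d nt%s%s)\n", object@name,
              nchar(object@sequence),
              if (!is.na(object@anchor))
                sprintf(", anchor %d", object@anchor) else "",
              if (object@upstreamPad > 0L || object@downstreamPad > 0L)
                sprintf(", pads %d/%d", object@upstreamPad,
                        object@downstreamPad) else ""))
})

setMethod("show", "GermlineSet", function(object) {
  cat(sprintf("GermlineSet %s (%s): %d five-prime, %d three-prime genes, seed %s\n",
              object@locus,
              if (object@complete) "complete" else "incomplete",
              length(object@fivePrime), length(object@threePrime),
              object@seedPattern))
})

setMethod("show", "GermlineCollection", function(object) {
  cat(sprintf("GermlineCollection with %d set(s):\n", length(object@sets)))
  for (s in object@sets) {
    nd <- length(object@middleGenes[[s@locus]])
    cat(sprintf("  %s: %d/%d genes%s\n", s@locus,
                length(s@fivePrime), length(s@threePrime),
                if (nd > 0) sprintf(" + %d D genes", nd) else ""))
  }
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: %d keys (%d ambiguous), seed %s (span %d, weight %d)\n",
              length(object@keys), sum(object@labels == -1L),
              object@pattern, object@span, object@weight))
})

setMethod("show", "ResultSet", function(object) {
  cat(sprintf("ResultSet: %d clonotype(s) x %d sample(s)\n",
              nrow(object@clones), nrow(object@samples)))
  if (nrow(object@samples)) {
    for (i in seq_len(nrow(object@samples))) {
      st <- object@stats[[i]]
      cat(sprintf("  %s: %d reads, %d detected\n",
                  object@samples$name[i], st$totalReads,
                  st$statusCounts[["DETECTED"]]))
    }
  }
})

#' Accessors for ResultSet
#'
#' \code{clonotypes} returns the clonotype table, \code{cloneCounts} the
#' clonotype x sample counts matrix, \code{sampleInfo} the sample
#' descriptors, \code{sampleStats} the per-sample statistics list and
#' \code{producerInfo} the producer metadata.
#'
#' @param object a \linkS4class{ResultSet}.
#' @return see description.
#' @export
setGeneric("clonotypes", function(object) standardGeneric("clonotypes"))

#' @rdname clonotypes
#' @export
setGeneric("cloneCounts", function(object) standardGeneric("cloneCounts"))

#' @rdname clonotypes
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname clonotypes
#' @export
setGeneric("sampleStats", function(object) standardGeneric("sampleStats"))

#' @rdname clonotypes
#' @export
setGeneric("producerInfo", function(object) standardGeneric("producerInfo"))

#' @rdname clonotypes
setMethod("clonotypes", "ResultSet", function(object) object@clones)

#' @rdname clonotypes
setMethod("cloneCounts", "ResultSet", function(object) object@counts)

#' @rdname clonotypes
setMethod("sampleInfo", "ResultSet", function(object) object@samples)

#' @rdname clonotypes
setMethod("sampleStats", "ResultSet", function(object) object@stats)

#' @rdname clonotypes
setMethod("producerInfo", "ResultSet", function(object) object@producer)
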