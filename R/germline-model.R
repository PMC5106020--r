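#' @importFrom jsonlite read_json write_json
NULL

# Read one germline FASTA file into a list of GermlineGene. '.' characters
# (IMGT gaps) are permitted: when present the record carries both the gapped
# and the ungapped sequence. Header = name token up to first whitespace.
readGeneFasta <- function(path) {
  if (!file.exists(path))
    stop("germline configuration error: file not found: ", path,
         call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  bad <- character(0)
  genes <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    raw <- seqs[[i]]
    ungapped <- gsub(".", "", raw, fixed = TRUE)
    if (!grepl(.ACGT_ONLY, ungapped)) {
      bad <- c(bad, nm[i])
      next
    }
    genes[[i]] <- germlineGene(
      name = nm[i], sequence = ungapped,
      gappedSequence = if (grepl(".", raw, fixed = TRUE)) raw
                       else NA_character_)
  }
  if (length(bad))
    stop("germline validation error in ", path,
         ": non-ACGT characters (after gap removal) in record(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  genes
}

#' Extend a germline gene with neighbor regions
#'
#' Short genes (notably D genes of 8-37 nt) may not carry enough k-mers to
#' seed detection; incomplete recombinations such as Dd2-Jd also retain
#' genomic sequence flanking the gene. Concatenating the genomic neighbor
#' regions onto the gene restores k-mer coverage. The pad lengths are
#' recorded and the anchor, when present, is shifted by the upstream pad.
#'
#' @param gene a \linkS4class{GermlineGene}.
#' @param upstream,downstream DNA strings (possibly empty) to prepend/append.
#' @return the padded \linkS4class{GermlineGene}.
#' @examples
#' g <- germlineGene("TOYD1", "ACGT")
#' padWithNeighbors(g, "GG", "TT")
#' @export
padWithNeighbors <- function(gene, upstream = "", downstream = "") {
  stopifnot(is(gene, "GermlineGene"))
  upstream <- toupper(upstream)
  downstream <- toupper(downstream)
  if ((nzchar(upstream) && !grepl(.ACGT_ONLY, upstream)) ||
      (nzchar(downstream) && !grepl(.ACGT_ONLY, downstream)))
    stop("neighbor pads must be ACGT strings", call. = FALSE)
  germlineGene(
    name = gene@name,
    sequence = paste0(upstream, gene@sequence, downstream),
    gappedSequence = NA_character_,
    anchor = if (is.na(gene@anchor)) NA_integer_
             else gene@anchor + nchar(upstream),
    upstreamPad = gene@upstreamPad + nchar(upstream),
    downstreamPad = gene@downstreamPad + nchar(downstream))
}

#' Load a multi-locus germline collection from a JSON configuration
#'
#' The configuration is a JSON document listing recombination systems, each
#' pointing to per-locus FASTA files of 5' and 3' germline genes (gapped
#' sequences permitted) and optionally D genes, a spaced-seed pattern,
#' explicit per-gene anchors, and explicit per-gene neighbor pads:
#'
#' \preformatted{
#' {
#'   "cys104_gapped_position": 310,
#'   "systems": [
#'     {"locus": "TRG", "complete": true,
#'      "5": ["TRGV.fa"], "3": ["TRGJ.fa"], "seed": "##########",
#'      "anchors": {"TRGJ1*01": 12},
#'      "pads": {"TRDD2*01": {"upstream": "ACGT...", "downstream": ""}}}
#'   ]
#' }
#' }
#'
#' Relative FASTA paths are resolved against the configuration file's
#' directory. After loading, anchors are resolved for genes of complete
#' sets: explicit anchors first, then gapped sequences (5' genes) or the
#' Phe/Trp-Gly-X-Gly motif (3' genes); see \code{\link{resolveAnchor}}.
#'
#' @param configPath path to the JSON configuration.
#' @return a validated \linkS4class{GermlineCollection}; set order follows
#'   the configuration.
#' @export
loadGermlineCollection <- function(configPath) {
  if (!file.exists(configPath))
    stop("germline configuration error: file not found: ", configPath,
         call. = FALSE)
  cfg <- jsonlite::read_json(configPath)
  if (is.null(cfg$systems) || !length(cfg$systems))
    stop("germline configuration error: no 'systems' entry in ", configPath,
         call. = FALSE)
  dir <- dirname(normalizePath(configPath))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
  gappedPos <- if (!is.null(cfg$cys104_gapped_position))
    as.integer(cfg$cys104_gapped_position) else 310L

  sets <- list()
  middle <- list()
  for (sys in cfg$systems) {
    locus <- as.character(sys$locus)
    complete <- if (is.null(sys$complete)) TRUE else isTRUE(sys$complete)
    seed <- if (is.null(sys$seed)) "##########" else as.character(sys$seed)
    readSide <- function(paths) {
      genes <- list()
      for (p in unlist(paths)) genes <- c(genes, readGeneFasta(resolve(p)))
      genes
    }
    five <- readSide(sys[["5"]])
    three <- readSide(sys[["3"]])
    dgen <- if (!is.null(sys[["4"]])) readSide(sys[["4"]]) else list()

    applyExtras <- function(genes, side) {
      lapply(genes, function(g) {
        pads <- sys$pads[[g@name]]
        if (!is.null(pads))
          g <- padWithNeighbors(g,
                                upstream = if (is.null(pads$upstream)) ""
                                           else pads$upstream,
                                downstream = if (is.null(pads$downstream)) ""
                                             else pads$downstream)
        pl <- sys$pad_lengths[[g@name]]
        if (!is.null(pl)) {   # informational pads already baked into sequence
          g@upstreamPad <- g@upstreamPad + as.integer(pl[[1]])
          g@downstreamPad <- g@downstreamPad + as.integer(pl[[2]])
        }
        expl <- sys$anchors[[g@name]]
        if (!is.null(expl)) {
          g@anchor <- as.integer(expl) +
            (if (is.null(pads) || is.null(pads$upstream)) 0L
             else nchar(pads$upstream))
          validObject(g)
        } else if (complete && is.na(g@anchor)) {
          a <- resolveAnchor(g, side = side, gappedPos = gappedPos)
          if (!is.na(a)) {
            g@anchor <- a
            validObject(g)
          }
        }
        g
      })
    }
    five <- applyExtras(five, "five")
    three <- applyExtras(three, "three")

    sets <- c(sets, germlineSet(locus, five, three, seedPattern = seed,
                                complete = complete))
    if (length(dgen)) middle[[locus]] <- dgen
  }
  loci <- vapply(sets, function(s) s@locus, character(1))
  if (anyDuplicated(loci))
    stop("germline validation error: duplicate locus label: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "),
         call. = FALSE)
  germlineCollection(sets, middle)
}

#' Write a germline collection back to a configuration + FASTA files
#'
#' Inverse of \code{\link{loadGermlineCollection}}: writes one FASTA per
#' side per locus (gapped sequences preserved when present), a D FASTA when
#' middle genes exist, explicit anchors for every anchored gene, and the
#' JSON configuration tying them together. Reloading the written
#' configuration reproduces the collection field-wise. Pads are written
#' already applied (sequences stored padded, pad lengths not re-applied on
#' reload), so the round trip is exact.
#'
#' @param collection a \linkS4class{GermlineCollection}.
#' @param dir output directory (created if needed).
#' @return the path of the written configuration file, invisibly.
#' @export
writeGermlineCollection <- function(collection, dir) {
  stopifnot(is(collection, "GermlineCollection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSide <- function(genes, file) {
    txt <- vapply(genes, function(g) {
      s <- if (!is.na(g@gappedSequence)) g@gappedSequence else g@sequence
      paste0(">", g@name, "\n", s)
    }, character(1))
    writeLines(txt, file.path(dir, file))
    file
  }
  systems <- lapply(collection@sets, function(set) {
    f5 <- writeSide(set@fivePrime, paste0(set@locus, "_5.fa"))
    f3 <- writeSide(set@threePrime, paste0(set@locus, "_3.fa"))
    anchors <- list()
    padLengths <- list()
    for (g in c(set@fivePrime, set@threePrime)) {
      if (!is.na(g@anchor)) anchors[[g@name]] <- g@anchor
      if (g@upstreamPad > 0L || g@downstreamPad > 0L)
        padLengths[[g@name]] <- c(g@upstreamPad, g@downstreamPad)
    }
    sys <- list(locus = set@locus, complete = set@complete,
                "5" = list(f5), "3" = list(f3), seed = set@seedPattern)
    dg <- collection@middleGenes[[set@locus]]
    if (!is.null(dg) && length(dg))
      sys[["4"]] <- list(writeSide(dg, paste0(set@locus, "_4.fa")))
    if (length(anchors)) sys$anchors <- anchors
    if (length(padLengths)) sys$pad_lengths <- padLengths
    sys
  })
  cfgPath <- file.path(dir, "germlines.json")
  jsonlite::write_json(list(systems = systems), cfgPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(cfgPath)
}

# Look up a gene by name across both sides of a set (and optionally a
# middle-gene list); NULL when absent.
findGene <- function(set, name, middleGenes = list()) {
  for (g in c(set@fivePrime, set@threePrime, middleGenes))
    if (g@name == name) return(g)
  NULL
}
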