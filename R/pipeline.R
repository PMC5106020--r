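# End-to-end driver: reads -> affectation -> recombination calls ->
# junction windows -> clonotypes -> statistics -> designation/CDR3 of the
# top clonotypes -> ResultSet.

#' Run the full clonotype-calling pipeline on one sample
#'
#' Two-phase design: phase one detects recombined reads with the
#' spaced-seed index and gathers them into clonotypes by exact junction
#' window — no alignment is performed, which is what makes high-throughput
#' processing fast. Phase two computes the detailed V(D)J designation (by
#' dynamic programming) and the CDR3/productivity call, but only for the
#' representatives of the \code{designateTop} most abundant clonotypes.
#'
#' @param reads a read file path (FASTA/FASTQ, optionally gzipped), a
#'   character vector of sequences, or a data.frame with columns \code{id},
#'   \code{sequence}.
#' @param collection a \linkS4class{GermlineCollection}.
#' @param w junction window length (default 50).
#' @param minAffects minimum seed affects per side (default 5).
#' @param seedPattern spaced-seed pattern overriding the collection's
#'   configured pattern; \code{NULL} keeps the configured one.
#' @param maxD maximum D genes per designation (raised to the configured
#'   value automatically only through this argument).
#' @param designateTop designate only the top N clonotypes by read count
#'   (\code{Inf} for all).
#' @param allowTruncated keep clipped windows at read borders.
#' @param sampleName,source sample descriptors stored in the result.
#' @return a \linkS4class{ResultSet} with one sample.
#' @examples
#' g <- simulateGermlineSet(locus = "TOY", seed = 7)
#' coll <- germlineCollection(list(g$set))
#' sim <- simulateRepertoire(coll, nClones = 4, nReads = 200, seed = 8)
#' rs <- runPipeline(sim$reads, coll)
#' rs
#' @export
runPipeline <- function(reads, collection, w = 50L, minAffects = 5L,
                        seedPattern = NULL, maxD = 1L, designateTop = 100L,
                        allowTruncated = FALSE, sampleName = "sample",
                        source = NA_character_) {
  stopifnot(is(collection, "GermlineCollection"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    source <- if (is.na(source)) reads else source
    reads <- readReads(reads)
  } else if (is.character(reads)) {
    reads <- data.frame(id = if (length(reads))
                          paste0("read", seq_along(reads)) else character(0),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)

  index <- buildKmerIndex(collection, seed = seedPattern)
  affs <- affectReads(index, reads$sequence)
  lens <- nchar(reads$sequence)

  statuses <- character(n)
  loci <- rep(NA_character_, n)
  strands <- rep(NA_character_, n)
  centers <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    call <- callRecombination(affs[[i]], minAffects = minAffects,
                              labelTable = index@labelTable,
                              span = index@span, readLength = lens[i])
    statuses[i] <- call$status
    loci[i] <- call$locus
    strands[i] <- call$strand
    centers[i] <- call$center
  }

  det <- which(statuses == "DETECTED")
  fwd <- reads$sequence[det]
  minus <- strands[det] == "-"
  if (any(minus)) fwd[minus] <- revcompChar(fwd[minus])
  lo <- centers[det] - w %/% 2L
  hi <- centers[det] + w %/% 2L
  inBounds <- lo >= 0L & hi <= lens[det]
  if (allowTruncated) {
    windows <- substr(fwd, pmax(lo, 0L) + 1L, pmin(hi, lens[det]))
    winOK <- rep(TRUE, length(det))
  } else {
    windows <- substr(fwd, lo + 1L, hi)
    winOK <- inBounds
  }
  # detected reads whose window would cross the read border are TOO_SHORT
  statuses[det[!winOK]] <- "TOO_SHORT"

  keep <- det[winOK]
  clu <- clusterClonotypes(data.frame(locus = loci[keep],
                                      window = windows[winOK],
                                      sequence = fwd[winOK],
                                      stringsAsFactors = FALSE))
  clones <- clu$clones
  counts <- matrix(clu$counts, ncol = 1L)

  # phase two: designation + CDR3 of the most abundant clonotypes
  setOf <- vapply(collection@sets, function(s) s@locus, character(1))
  nTop <- min(nrow(clones), designateTop)
  for (i in seq_len(nTop)) {
    set <- collection@sets[[match(clones$locus[i], setOf)]]
    dGenes <- collection@middleGenes[[clones$locus[i]]] %||% list()
    des <- designate(clones$representative[i], set, dGenes = dGenes,
                     maxD = maxD)
    clones$designation[[i]] <- des
    if (identical(des$status, "DESIGNATED") && set@complete)
      clones$cdr3[[i]] <- locateCDR3(clones$representative[i], des, set)
  }

  stats <- computeSampleStats(statuses, loci, clu$counts)
  producer <- list(
    name = "vdjcluster",
    version = as.character(utils::packageVersion("vdjcluster")),
    parameters = list(w = as.integer(w), minAffects = as.integer(minAffects),
                      seedPattern = index@pattern, maxD = as.integer(maxD),
                      designateTop = if (is.finite(designateTop))
                        as.integer(designateTop) else -1L,
                      allowTruncated = allowTruncated))
  new("ResultSet",
      samples = data.frame(name = sampleName, source = source,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                           stringsAsFactors = FALSE),
      stats = list(stats),
      clones = clones,
      counts = counts,
      producer = producer)
}
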