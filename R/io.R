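# Readers/writers: FASTA/FASTQ(.gz) reads, JSON result documents, TSV
# clonotype tables, curated test sets, multi-sample fusion.

SCHEMA_VERSION <- "vdjcluster-1.0"

fileFormat <- function(path) {
  p <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(p))
  if (ext %in% c("fa", "fasta", "fna")) "fasta"
  else if (ext %in% c("fq", "fastq")) "fastq"
  else stop("cannot infer read format from extension of ", path,
            call. = FALSE)
}

#' Read sequencing reads from FASTA or FASTQ, optionally gzip-compressed
#'
#' The format is inferred from the file extension (\code{.fa/.fasta} vs
#' \code{.fq/.fastq}, with an optional \code{.gz}); gzip is decompressed
#' transparently. Qualities are not used by the algorithm but are preserved.
#'
#' @param path input file.
#' @return a data.frame with columns \code{id}, \code{sequence} and
#'   \code{quality} (\code{NA} for FASTA).
#' @export
readReads <- function(path) {
  if (!file.exists(path))
    stop("read file not found: ", path, call. = FALSE)
  fmt <- fileFormat(path)
  if (fmt == "fasta") {
    ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    data.frame(id = sub("\\s.*$", "", names(ss)),
               sequence = toupper(as.character(ss)),
               quality = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    ss <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq"),
      error = function(e)
        stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
             call. = FALSE))
    seqs <- toupper(as.character(ss))
    # the quality line of each 4-line record, validated against the
    # sequence width (the fastq parser is lenient about short qualities)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con), add = TRUE)
    lines <- readLines(con, warn = FALSE)
    while (length(lines) && !nzchar(lines[length(lines)]))
      lines <- lines[-length(lines)]
    if (length(lines) != 4L * length(ss))
      stop("malformed FASTQ in ", path, ": expected ", 4L * length(ss),
           " lines for ", length(ss), " records", call. = FALSE)
    qual <- lines[seq_along(lines) %% 4L == 0L]
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad))
      stop("malformed FASTQ in ", path, ": quality length differs from ",
           "sequence length at record ", bad[1], call. = FALSE)
    data.frame(id = sub("\\s.*$", "", names(ss)),
               sequence = seqs, quality = qual, stringsAsFactors = FALSE)
  }
}

desToJSON <- function(des) {
  if (is.null(des) || !identical(des$status, "DESIGNATED")) return(NULL)
  des
}

cdr3ToJSON <- function(cdr3) {
  if (is.null(cdr3)) return(NULL)
  cdr3
}

#' Write / read a result document (JSON)
#'
#' The package's documented JSON result dialect: a top-level object with
#' \code{producer} (tool name, version, parameters, schema), \code{samples}
#' (name, source, timestamp, per-sample statistics) and \code{clones}
#' (\code{id} = junction window, locus, per-sample read counts,
#' representative, designation, cdr3, tag, merged windows).
#' \code{readResult(writeResult(rs))} reproduces the result field-wise; a
#' document with an unknown schema version is rejected.
#'
#' @param rs a \linkS4class{ResultSet}.
#' @param path output/input JSON file.
#' @param timestamp include sample timestamps (suppress for byte-identical
#'   reruns).
#' @return \code{writeResult}: \code{path}, invisibly. \code{readResult}:
#'   a \linkS4class{ResultSet}.
#' @export
writeResult <- function(rs, path, timestamp = TRUE) {
  stopifnot(is(rs, "ResultSet"))
  samples <- lapply(seq_len(nrow(rs@samples)), function(i) {
    st <- rs@stats[[i]]
    st$statusCounts <- as.list(st$statusCounts)  # keep names in JSON objects
    st$locusCounts <- as.list(st$locusCounts)
    list(name = rs@samples$name[i],
         source = rs@samples$source[i],
         timestamp = if (timestamp) rs@samples$timestamp[i] else NA,
         stats = st)
  })
  clones <- lapply(seq_len(nrow(rs@clones)), function(i) {
    list(id = rs@clones$window[i],
         locus = rs@clones$locus[i],
         reads = as.integer(rs@counts[i, ]),
         representative = rs@clones$representative[i],
         designation = desToJSON(rs@clones$designation[[i]]),
         cdr3 = cdr3ToJSON(rs@clones$cdr3[[i]]),
         tag = rs@clones$tag[i],
         merged_windows = rs@clones$mergedWindows[[i]])
  })
  doc <- list(producer = c(rs@producer, list(schema = SCHEMA_VERSION)),
              samples = samples, clones = clones)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeResult
#' @export
readResult <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$producer$schema) ||
      !identical(doc$producer$schema, SCHEMA_VERSION))
    stop("unknown result schema version: ",
         if (is.null(doc$producer$schema)) "<missing>"
         else doc$producer$schema, call. = FALSE)
  producer <- doc$producer
  producer$schema <- NULL
  nS <- length(doc$samples)
  samples <- data.frame(
    name = vapply(doc$samples, function(s) as.character(s$name), character(1)),
    source = vapply(doc$samples, function(s)
      if (is.null(s$source)) NA_character_ else as.character(s$source),
      character(1)),
    timestamp = vapply(doc$samples, function(s)
      if (is.null(s$timestamp)) NA_character_ else as.character(s$timestamp),
      character(1)),
    stringsAsFactors = FALSE)
  stats <- lapply(doc$samples, function(s) {
    st <- s$stats
    st$totalReads <- as.integer(st$totalReads)
    st$statusCounts <- unlist(st$statusCounts)
    st$locusCounts <- if (length(st$locusCounts))
      unlist(st$locusCounts) else integer(0)
    st$diversity <- lapply(st$diversity, function(x)
      if (is.null(x)) NA_real_ else x)
    st
  })
  nC <- length(doc$clones)
  clones <- emptyCloneTable()
  counts <- matrix(0L, nrow = nC, ncol = nS)
  if (nC) {
    clones <- data.frame(
      window = vapply(doc$clones, function(cl) as.character(cl$id),
                      character(1)),
      locus = vapply(doc$clones, function(cl) as.character(cl$locus),
                     character(1)),
      representative = vapply(doc$clones, function(cl)
        as.character(cl$representative), character(1)),
      tag = vapply(doc$clones, function(cl)
        if (is.null(cl$tag)) NA_character_ else as.character(cl$tag),
        character(1)),
      stringsAsFactors = FALSE)
    clones$designation <- lapply(doc$clones, function(cl)
      restoreDesignation(cl$designation))
    clones$cdr3 <- lapply(doc$clones, function(cl) restoreCDR3(cl$cdr3))
    clones$mergedWindows <- lapply(doc$clones, function(cl)
      as.character(unlist(cl$merged_windows)))
    counts <- do.call(rbind, lapply(doc$clones, function(cl)
      as.integer(unlist(cl$reads))))
  }
  new("ResultSet", samples = samples, stats = stats, clones = clones,
      counts = counts, producer = producer)
}

restoreDesignation <- function(x) {
  if (is.null(x)) return(NULL)
  x$nRegions <- as.character(unlist(x$nRegions))
  x$fiveTies <- as.character(unlist(x$fiveTies))
  x$threeTies <- as.character(unlist(x$threeTies))
  x$dGenes <- lapply(x$dGenes, function(d)
    list(name = d$name, del5 = as.integer(d$del5),
         del3 = as.integer(d$del3), seqStart = as.integer(d$seqStart),
         seqEnd = as.integer(d$seqEnd)))
  ints <- c("fiveDel", "threeDel", "fiveGeneStart", "fiveGeneEnd",
            "fiveSeqEnd", "threeGeneStart", "threeGeneEnd", "threeSeqStart",
            "fiveScore", "threeScore")
  for (f in ints) x[[f]] <- as.integer(x[[f]])
  x
}

restoreCDR3 <- function(x) {
  if (is.null(x)) return(NULL)
  list(junctionStart = if (is.null(x$junctionStart)) NA_integer_
                       else as.integer(x$junctionStart),
       junctionEnd = if (is.null(x$junctionEnd)) NA_integer_
                     else as.integer(x$junctionEnd),
       cdr3AA = if (is.null(x$cdr3AA)) NA_character_
                else as.character(x$cdr3AA),
       productive = isTRUE(x$productive),
       reason = as.character(x$reason))
}

#' Fuse single-sample results into a multi-sample result
#'
#' Clonotypes are matched across samples by exact (locus, window) identity;
#' counts vectors are assembled in input order with zeros for samples where
#' a clonotype is absent. Used to track clones of one patient across
#' follow-up time points. Producer parameters must be compatible (same
#' window length).
#'
#' @param results list of \linkS4class{ResultSet}.
#' @return a fused multi-sample \linkS4class{ResultSet}.
#' @export
fuseResults <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, logical(1), "ResultSet")))
  ws <- lapply(results, function(r) r@producer$parameters$w)
  if (length(unique(unlist(ws))) > 1L)
    stop("cannot fuse results with different window lengths: ",
         paste(unlist(ws), collapse = ", "), call. = FALSE)
  samples <- do.call(rbind, lapply(results, function(r) r@samples))
  rownames(samples) <- NULL
  stats <- do.call(c, lapply(results, function(r) r@stats))
  nS <- nrow(samples)

  keys <- character(0)
  clones <- emptyCloneTable()
  counts <- matrix(0L, nrow = 0L, ncol = nS)
  col0 <- 0L
  for (r in results) {
    nCol <- nrow(r@samples)
    k <- paste(r@clones$locus, r@clones$window, sep = "\r")
    newIdx <- which(!(k %in% keys))
    if (length(newIdx)) {
      add <- r@clones[newIdx, , drop = FALSE]
      clones <- rbind(clones, add)
      counts <- rbind(counts,
                      matrix(0L, nrow = length(newIdx), ncol = nS))
      keys <- c(keys, k[newIdx])
    }
    rowIdx <- match(k, keys)
    counts[rowIdx, col0 + seq_len(nCol)] <-
      counts[rowIdx, col0 + seq_len(nCol)] + r@counts
    col0 <- col0 + nCol
  }
  rownames(clones) <- NULL
  rs <- new("ResultSet", samples = samples, stats = stats, clones = clones,
            counts = counts, producer = results[[1]]@producer)
  sortClones(rs)
}

#' Export the clonotype table as TSV
#'
#' Columns: window, locus, one count column per sample, designation string,
#' CDR3 amino acids, productive flag.
#'
#' @param rs a \linkS4class{ResultSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeClonotypeTSV <- function(rs, path) {
  stopifnot(is(rs, "ResultSet"))
  tab <- data.frame(window = rs@clones$window, locus = rs@clones$locus,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rs@samples)))
    tab[[paste0("reads_", rs@samples$name[i])]] <- rs@counts[, i]
  tab$designation <- vapply(rs@clones$designation, function(d)
    if (is.null(d)) NA_character_ else d$text, character(1))
  tab$cdr3_aa <- vapply(rs@clones$cdr3, function(x)
    if (is.null(x)) NA_character_ else x$cdr3AA, character(1))
  tab$productive <- vapply(rs@clones$cdr3, function(x)
    if (is.null(x)) NA else x$productive, logical(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write curated test sequences
#'
#' Curated test sets are plain FASTA files whose headers carry the expected
#' call, in the dialect
#' \code{>name locus=TRG expected=TRGV2*01_0/7/0_TRGJP1*01}: the
#' \code{expected} designation string uses \code{_} as separator, its first
#' token is the expected 5' gene and its last token the expected 3' gene.
#'
#' @param path FASTA file of curated records.
#' @param records data.frame as returned by \code{readCuratedFasta}.
#' @return \code{readCuratedFasta}: data.frame with columns \code{name},
#'   \code{sequence}, \code{expectedLocus}, \code{expectedFive},
#'   \code{expectedThree}, \code{expectedString}.
#' @export
readCuratedFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  getField <- function(h, f) {
    m <- regmatches(h, regexpr(paste0(f, "=\\S+"), h))
    if (length(m)) sub(paste0("^", f, "="), "", m) else NA_character_
  }
  expected <- vapply(hdr, getField, character(1), f = "expected")
  toks <- strsplit(expected, "_", fixed = TRUE)
  data.frame(
    name = sub("\\s.*$", "", hdr),
    sequence = toupper(as.character(ss)),
    expectedLocus = vapply(hdr, getField, character(1), f = "locus"),
    expectedFive = vapply(toks, function(t)
      if (all(is.na(t))) NA_character_ else t[1], character(1)),
    expectedThree = vapply(toks, function(t)
      if (all(is.na(t))) NA_character_ else t[length(t)], character(1)),
    expectedString = gsub("_", " ", expected, fixed = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname readCuratedFasta
#' @param truth data.frame with columns \code{name}, \code{sequence},
#'   \code{locus}, \code{fiveGene}, \code{threeGene} (written as a curated
#'   FASTA).
#' @export
writeCuratedFasta <- function(truth, path) {
  lines <- character(0)
  for (i in seq_len(nrow(truth))) {
    lines <- c(lines,
               sprintf(">%s locus=%s expected=%s_%s", truth$name[i],
                       truth$locus[i], truth$fiveGene[i],
                       truth$threeGene[i]),
               truth$sequence[i])
  }
  writeLines(lines, path)
  invisible(path)
}

geneLevel <- function(name) sub("\\*.*$", "", name)

#' Evaluate the pipeline against curated records
#'
#' Runs the full detection + designation pipeline on each curated sequence
#' and reports the fraction with correct locus and correct 5'/3' gene, both
#' at allele level (exact name) and gene level (allele suffix \code{*NN}
#' ignored). Records whose expected locus is not in the collection are
#' counted as incorrect with a warning.
#'
#' @param records data.frame from \code{\link{readCuratedFasta}}.
#' @param collection a \linkS4class{GermlineCollection}.
#' @param minAffects,w,maxD pipeline parameters (see
#'   \code{\link{runPipeline}}).
#' @return a list: \code{n}, \code{locusAccuracy}, \code{fiveAccuracyAllele},
#'   \code{fiveAccuracyGene}, \code{threeAccuracyAllele},
#'   \code{threeAccuracyGene}, and the per-record table \code{detail}.
#' @export
evaluateCurated <- function(records, collection, minAffects = 5L, w = 50L,
                            maxD = 1L) {
  if (nrow(records) == 0L)
    stop("no curated records to evaluate", call. = FALSE)
  loci <- vapply(collection@sets, function(s) s@locus, character(1))
  unknown <- setdiff(stats::na.omit(unique(records$expectedLocus)), loci)
  if (length(unknown))
    warning("curated records reference unknown locus label(s): ",
            paste(unknown, collapse = ", "))
  index <- buildKmerIndex(collection)
  affs <- affectReads(index, records$sequence)
  okLocus <- okFiveA <- okFiveG <- okThreeA <- okThreeG <-
    logical(nrow(records))
  callLocus <- callFive <- callThree <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    call <- callRecombination(affs[[i]], minAffects = minAffects,
                              labelTable = index@labelTable,
                              span = index@span,
                              readLength = nchar(records$sequence[i]))
    if (!identical(call$status, "DETECTED")) next
    callLocus[i] <- call$locus
    okLocus[i] <- identical(call$locus, records$expectedLocus[i])
    set <- collection@sets[[match(call$locus, loci)]]
    seqFwd <- if (call$strand == "-") revcompChar(records$sequence[i])
              else records$sequence[i]
    des <- designate(seqFwd, set,
                     dGenes = collection@middleGenes[[call$locus]] %||% list(),
                     maxD = maxD)
    if (!identical(des$status, "DESIGNATED")) next
    callFive[i] <- des$fiveGene
    callThree[i] <- des$threeGene
    okFiveA[i] <- identical(des$fiveGene, records$expectedFive[i])
    okThreeA[i] <- identical(des$threeGene, records$expectedThree[i])
    okFiveG[i] <- identical(geneLevel(des$fiveGene),
                            geneLevel(records$expectedFive[i]))
    okThreeG[i] <- identical(geneLevel(des$threeGene),
                             geneLevel(records$expectedThree[i]))
  }
  list(n = nrow(records),
       locusAccuracy = mean(okLocus),
       fiveAccuracyAllele = mean(okFiveA),
       fiveAccuracyGene = mean(okFiveG),
       threeAccuracyAllele = mean(okThreeA),
       threeAccuracyGene = mean(okThreeG),
       detail = data.frame(name = records$name, calledLocus = callLocus,
                           calledFive = callFive, calledThree = callThree,
                           locusOK = okLocus, fiveOK = okFiveA,
                           threeOK = okThreeA, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
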