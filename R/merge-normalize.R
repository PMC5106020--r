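# Post-clustering clonotype merging (manual groups and DBSCAN-style
# automatic absorption of PCR/sequencing satellites) and spike-in
# normalization of abundances.

# minimal union-find over 1..n
unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  list(find = find, union = union)
}

# collapse the clonotype rows in `idx` of a ResultSet into the member with
# the largest total count (tie: lexicographically smallest window)
collapseGroup <- function(rs, idx) {
  tot <- rowSums(rs@counts[idx, , drop = FALSE])
  win <- rs@clones$window[idx]
  keep <- idx[order(-tot, win)][1]
  absorbed <- setdiff(idx, keep)
  rs@counts[keep, ] <- as.integer(colSums(rs@counts[idx, , drop = FALSE]))
  rs@clones$mergedWindows[[keep]] <- sort(unique(c(
    rs@clones$mergedWindows[[keep]],
    rs@clones$window[absorbed],
    unlist(rs@clones$mergedWindows[absorbed]))))
  list(rs = rs, drop = absorbed)
}

dropClones <- function(rs, drop) {
  if (!length(drop)) return(rs)
  keep <- setdiff(seq_len(nrow(rs@clones)), drop)
  rs@clones <- rs@clones[keep, , drop = FALSE]
  rownames(rs@clones) <- NULL
  rs@counts <- rs@counts[keep, , drop = FALSE]
  rs
}

sortClones <- function(rs) {
  o <- order(-rowSums(rs@counts), rs@clones$window)
  rs@clones <- rs@clones[o, , drop = FALSE]
  rownames(rs@clones) <- NULL
  rs@counts <- rs@counts[o, , drop = FALSE]
  rs
}

#' Merge clonotypes by explicit window groups
#'
#' Each group of windows collapses into its largest-count member; counts are
#' summed per sample and the absorbed windows are recorded in the surviving
#' clonotype's \code{mergedWindows}. Total read counts are conserved.
#'
#' @param rs a \linkS4class{ResultSet}.
#' @param groups list of character vectors of clonotype windows; groups must
#'   be disjoint and every window must exist in \code{rs}.
#' @return the merged \linkS4class{ResultSet}.
#' @export
mergeClonotypes <- function(rs, groups) {
  stopifnot(is(rs, "ResultSet"))
  if (!length(groups)) return(rs)
  allw <- unlist(groups)
  if (anyDuplicated(allw))
    stop("merge groups overlap on window(s): ",
         paste(unique(allw[duplicated(allw)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(allw, rs@clones$window)
  if (length(unknown))
    stop("unknown window(s) in merge groups: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  drop <- integer(0)
  for (grp in groups) {
    idx <- match(grp, rs@clones$window)
    if (length(idx) < 2L) next
    res <- collapseGroup(rs, idx)
    rs <- res$rs
    drop <- c(drop, res$drop)
  }
  sortClones(dropClones(rs, drop))
}

#' Automatically merge similar low-abundance clonotypes
#'
#' DBSCAN-style absorption of satellites: an edge joins two clonotypes when
#' the Levenshtein distance between their windows is at most \code{eps} and
#' the smaller count is at most \code{ratio} times the larger (PCR and
#' sequencing errors produce low-abundance neighbors of real clonotypes;
#' two genuinely distinct clones of comparable abundance are never merged).
#' Connected components with at least one edge collapse into the
#' component's largest clonotype. The operation is idempotent and conserves
#' total read counts.
#'
#' @param rs a \linkS4class{ResultSet}.
#' @param eps maximum edit distance between windows (default 1).
#' @param ratio maximum small/large total-count ratio (default 0.1).
#' @return the merged \linkS4class{ResultSet}.
#' @export
autoMerge <- function(rs, eps = 1, ratio = 0.1) {
  stopifnot(is(rs, "ResultSet"), eps >= 1, ratio > 0, ratio < 1)
  n <- nrow(rs@clones)
  if (n < 2L) return(rs)
  tot <- rowSums(rs@counts)
  d <- utils::adist(rs@clones$window)
  uf <- unionFind(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (rs@clones$locus[i] != rs@clones$locus[j]) next
      if (d[i, j] > eps) next
      if (min(tot[i], tot[j]) / max(tot[i], tot[j]) > ratio) next
      uf$union(i, j)
    }
  }
  comp <- vapply(seq_len(n), uf$find, integer(1))
  drop <- integer(0)
  for (root in unique(comp)) {
    idx <- which(comp == root)
    if (length(idx) < 2L) next
    res <- collapseGroup(rs, idx)
    rs <- res$rs
    drop <- c(drop, res$drop)
  }
  sortClones(dropClones(rs, drop))
}

#' Spike-in normalization of clonotype abundances
#'
#' Rescales abundances so that a control clonotype of known concentration
#' (a spike) takes exactly its expected fraction; the remaining abundance
#' mass is redistributed proportionally over the other clonotypes, so the
#' result still sums to 1. Used, e.g., to quantify minimal residual disease
#' against a spiked reference.
#'
#' @param rs a \linkS4class{ResultSet}.
#' @param targetWindow window of the spike clonotype.
#' @param expectedFraction its known concentration, in (0, 1).
#' @param sample sample index (column of the counts matrix).
#' @return numeric vector of normalized abundances, named by window,
#'   summing to 1.
#' @export
normalizeAbundances <- function(rs, targetWindow, expectedFraction,
                                sample = 1L) {
  stopifnot(is(rs, "ResultSet"),
            expectedFraction > 0, expectedFraction < 1)
  i <- match(targetWindow, rs@clones$window)
  if (is.na(i))
    stop("normalization target window not found: ", targetWindow,
         call. = FALSE)
  counts <- rs@counts[, sample]
  if (counts[i] == 0)
    stop("normalization target has zero count in sample ", sample,
         call. = FALSE)
  p <- counts / sum(counts)
  out <- p * (1 - expectedFraction) / (1 - p[i])
  out[i] <- expectedFraction
  stats::setNames(out, rs@clones$window)
}
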