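# Junction-window extraction and exact-window clustering into clonotypes.

#' Extract the fixed-width junction window from a detected read
#'
#' The clustering key is a \code{w}-nt subsequence centered on the junction
#' (default 50 bp): \code{read[center - w/2, center + w/2)} in 0-based
#' half-open coordinates. The read must already be forward-oriented
#' (reverse-complemented when the recombination was called on the minus
#' strand). When the interval exceeds the read, the read is TOO_SHORT unless
#' truncated windows are allowed, in which case the clipped interval is
#' returned and flagged.
#'
#' @param read forward-oriented read sequence.
#' @param call a DETECTED call from \code{\link{callRecombination}}.
#' @param w window length (even, >= 20; default 50).
#' @param allowTruncated return clipped windows instead of TOO_SHORT.
#' @return a list: \code{status} ("OK" or "TOO_SHORT"), \code{window},
#'   \code{truncated}.
#' @export
extractWindow <- function(read, call, w = 50L, allowTruncated = FALSE) {
  stopifnot(w %% 2L == 0L, w >= 20L)
  if (!identical(call$status, "DETECTED"))
    stop("extractWindow requires a DETECTED call", call. = FALSE)
  n <- nchar(read)
  lo <- call$center - w %/% 2L          # 0-based inclusive
  hi <- call$center + w %/% 2L          # 0-based exclusive
  if (lo < 0L || hi > n) {
    if (!allowTruncated)
      return(list(status = "TOO_SHORT", window = NA_character_,
                  truncated = FALSE))
    return(list(status = "OK",
                window = substr(read, max(lo, 0L) + 1L, min(hi, n)),
                truncated = TRUE))
  }
  list(status = "OK", window = substr(read, lo + 1L, hi), truncated = FALSE)
}

#' Gather windowed reads into clonotypes by exact window identity
#'
#' One clonotype per distinct (locus, window); its count is the number of
#' reads carrying that window and its representative is the longest read
#' carrying the window (ties: lexicographically smallest read). Output is
#' sorted by count descending, then window ascending. Exact matching only;
#' similarity-based merging is a separate, later step
#' (\code{\link{autoMerge}}).
#'
#' @param df data.frame with columns \code{locus}, \code{window},
#'   \code{sequence} (forward-oriented full read), one row per
#'   detected-and-windowed read of a single sample.
#' @return a list: \code{clones} (data.frame window, locus, representative,
#'   tag, and list-columns designation, cdr3, mergedWindows) and
#'   \code{counts} (integer vector of per-clonotype read counts).
#' @export
clusterClonotypes <- function(df) {
  stopifnot(all(c("locus", "window", "sequence") %in% names(df)))
  if (nrow(df) == 0L) {
    return(list(clones = emptyCloneTable(), counts = integer(0)))
  }
  key <- paste(df$locus, df$window, sep = "\r")
  # representative: longest read, ties broken by lexicographic order
  ord <- order(key, -nchar(df$sequence), df$sequence)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  firsts <- !duplicated(key)
  counts <- as.integer(table(key)[key[firsts]])
  clones <- data.frame(window = df$window[firsts],
                       locus = df$locus[firsts],
                       representative = df$sequence[firsts],
                       tag = NA_character_,
                       stringsAsFactors = FALSE)
  clones$designation <- vector("list", nrow(clones))
  clones$cdr3 <- vector("list", nrow(clones))
  clones$mergedWindows <- rep(list(character(0)), nrow(clones))
  o <- order(-counts, clones$window)
  clones <- clones[o, , drop = FALSE]
  rownames(clones) <- NULL
  list(clones = clones, counts = counts[o])
}

emptyCloneTable <- function() {
  clones <- data.frame(window = character(0), locus = character(0),
                       representative = character(0), tag = character(0),
                       stringsAsFactors = FALSE)
  clones$designation <- list()
  clones$cdr3 <- list()
  clones$mergedWindows <- list()
  clones
}
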