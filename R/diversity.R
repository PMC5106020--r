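# Clonality / diversity indices and per-sample read accounting.

#' Clonality and diversity indices of a clonotype abundance vector
#'
#' Shannon's diversity \eqn{H = -\sum p_i \ln p_i} (natural log), Shannon's
#' equitability \eqn{E = H / \ln S} (undefined for a single clonotype,
#' reported as \code{NA}), and Simpson's diversity in its unbiased
#' (Gini-Simpson) form \eqn{Ds = 1 - \sum c_i (c_i - 1) / (N (N - 1))}
#' (\code{0} when \eqn{N = 1}). A concentrated, clonal sample has low
#' \eqn{H} and \eqn{Ds}; a perfectly even repertoire has \eqn{E = 1}.
#'
#' @param counts vector of positive clonotype read counts.
#' @return a list with \code{H}, \code{E}, \code{Ds}, \code{S} (number of
#'   clonotypes) and \code{N} (total reads).
#' @examples
#' diversityIndices(c(10, 10, 10, 10))  # H = log(4), E = 1, Ds = 1 - 90/390
#' @export
diversityIndices <- function(counts) {
  if (length(counts) == 0L)
    stop("diversity of an empty count vector is undefined", call. = FALSE)
  if (any(counts < 1))
    stop("all counts must be positive", call. = FALSE)
  counts <- as.numeric(counts)
  N <- sum(counts)
  S <- length(counts)
  p <- counts / N
  H <- -sum(p * log(p))
  E <- if (S == 1L) NA_real_ else H / log(S)
  Ds <- if (N < 2) 0 else 1 - sum(counts * (counts - 1)) / (N * (N - 1))
  list(H = H, E = E, Ds = Ds, S = S, N = N)
}

# Assemble the per-sample statistics block: total reads, per-status read
# accounting, per-locus detected counts, diversity indices of the clonotype
# abundance vector.
computeSampleStats <- function(statuses, loci, cloneCounts) {
  statusCounts <- vapply(READ_STATUSES, function(s) sum(statuses == s),
                         integer(1))
  detLoci <- loci[statuses == "DETECTED"]
  locusCounts <- if (length(detLoci)) {
    tab <- table(detLoci)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  div <- if (length(cloneCounts))
    diversityIndices(cloneCounts)
  else
    list(H = NA_real_, E = NA_real_, Ds = NA_real_, S = 0L, N = 0L)
  list(totalReads = length(statuses),
       statusCounts = statusCounts,
       locusCounts = locusCounts,
       diversity = c(div,
                     list(H_base = "nats", Ds_form = "unbiased Gini-Simpson")))
}
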