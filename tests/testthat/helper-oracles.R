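# Independent oracles used by the tests. These are deliberately naive
# (exhaustive recursion, full rescans) and share no code with the package
# internals they check.

# Exhaustive recursion for the left-anchored semi-global alignment score:
# seq prefix [0, j) consumed, gene region [gs, i) with free gs, free ends.
oracleAlignLeft <- function(gene, seq, match = 2, mismatch = -3, gap = -7) {
  g <- strsplit(gene, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    best <- -Inf
    if (j == 0) best <- 0                         # free gene prefix
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (g[i] == s[j]) match else mismatch)
    if (i > 0 && j > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  # memoise on (i, j) to keep tiny instances fast while staying a direct
  # transcription of the recurrence
  memo <- array(NA_real_, dim = c(length(g) + 1, length(s) + 1))
  rec <- local({
    f <- function(i, j) {
      if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
      best <- -Inf
      if (j == 0) best <- 0
      if (i > 0 && j > 0)
        best <- max(best, f(i - 1, j - 1) +
                      if (g[i] == s[j]) match else mismatch)
      if (i > 0 && j > 0) best <- max(best, f(i - 1, j) + gap)
      if (j > 0) best <- max(best, f(i, j - 1) + gap)
      memo[i + 1, j + 1] <<- best
      best
    }
    f
  })
  best <- 0
  for (i in 0:length(g))
    for (j in 0:length(s))
      best <- max(best, rec(i, j))
  best
}

# Naive affectation: rescan every gene of every set at every read position
# and report the label set of the masked k-mer found there.
oracleAffect <- function(collection, read, pattern) {
  span <- nchar(pattern)
  hashAt <- which(strsplit(pattern, "")[[1]] == "#")
  maskOf <- function(s, p) {
    chars <- strsplit(substr(s, p, p + span - 1), "")[[1]]
    paste(chars[hashAt], collapse = "")
  }
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  n <- nchar(read)
  if (n < span) return(list())
  lapply(seq_len(n - span + 1), function(p) {
    key <- maskOf(read, p)
    if (grepl("[^ACGT]", substr(read, p, p + span - 1))) return(character(0))
    labels <- character(0)
    for (set in collection@sets) {
      for (side in c("5", "3")) {
        genes <- if (side == "5") set@fivePrime else set@threePrime
        for (g in genes) {
          for (strand in c("+", "-")) {
            gs <- if (strand == "+") g@sequence else rc(g@sequence)
            gl <- nchar(gs)
            if (gl < span) next
            for (q in seq_len(gl - span + 1)) {
              if (grepl("[^ACGT]", substr(gs, q, q + span - 1))) next
              if (maskOf(gs, q) == key) {
                labels <- c(labels, paste(set@locus, side, strand))
                break
              }
            }
          }
        }
      }
    }
    unique(labels)
  })
}

levDist <- function(a, b) as.integer(utils::adist(a, b))

# hand-applied standard genetic code (table from Biostrings, applied
# independently of the package's translation path)
oracleTranslate <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

rcChar <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
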