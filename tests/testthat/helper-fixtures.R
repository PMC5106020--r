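# Programmatic fixtures: tiny hand-built germline sets and an on-disk
# germline configuration, built fresh in a tempdir per call.

toyGene <- function(name, seq, ...) germlineGene(name, seq, ...)

# a deterministic toy V-J set with long distinct genes and known anchors
toySet <- function(locus = "TOY") {
  v1 <- paste0("ACGTACTGACTGCATGCTAGCTAGCATCGATCGTAGCTAGCTTCAGCTTG",
               "GATCCATGGAT", "TGT", "GCCACCTGGGACAGG")     # Cys at 61
  v2 <- paste0("TTGCAGCAGCCATGGCAGCTCGATCGATTTGCACCAGTTGCAAGCTAGCA",
               "ACCGGTTAGAT", "TGT", "GCTGCCTACAGGCCG")     # Cys at 61
  j1 <- paste0("CCAAGTGATTAT", "TTTGGCAGCGGA",
               "ACCAGACTGACCGTGCTCG")                       # F-G-X-G at 12
  j2 <- paste0("GGGACTCCAATC", "TGGGGAGGAGGT",
               "ACAAGTCTGATTGTCACAGG")                      # W-G-X-G at 12
  stopifnot(substr(v1, 62, 64) == "TGT", substr(v2, 62, 64) == "TGT",
            substr(j1, 13, 15) == "TTT", substr(j2, 13, 15) == "TGG")
  germlineSet(locus,
              list(toyGene(paste0(locus, "V1*01"), v1, anchor = 61L),
                   toyGene(paste0(locus, "V2*01"), v2, anchor = 61L)),
              list(toyGene(paste0(locus, "J1*01"), j1, anchor = 12L),
                   toyGene(paste0(locus, "J2*01"), j2, anchor = 12L)))
}

# write a loadable config: one TOY locus, 2 five-prime genes, 1 three-prime
writeToyConfig <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c(">TOYV1*01 first toy V",
               "ACGTACTGACTGCATGCTAGCTAGCATCGATCGTAGCTAGCT",
               ">TOYV2*01",
               "TTGCAGCAGCCATGGCAGCTCGATCGATTTGCACCAGTTGCA"),
             file.path(dir, "toyV.fa"))
  writeLines(c(">TOYJ1*01",
               "CCAAGTGATTATAAGTTTGGCAGCGGAACCAGACTGACCGTG"),
             file.path(dir, "toyJ.fa"))
  cfg <- list(systems = list(list(
    locus = "TOY", complete = TRUE,
    "5" = list("toyV.fa"), "3" = list("toyJ.fa"),
    seed = "##########")))
  path <- file.path(dir, "germlines.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  list(dir = dir, config = path)
}

# a small simulated world shared by several tests
simWorld <- function(seed = 101, nFive = 4, nThree = 3, ...) {
  set.seed(seed)
  g <- simulateGermlineSet(locus = "TRG", nFive = nFive, nThree = nThree, ...)
  list(set = g$set, dGenes = g$dGenes,
       collection = germlineCollection(list(g$set)))
}
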