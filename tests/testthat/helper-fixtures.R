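# shared fixtures, built in code

fixtureTarget <- function() {
  TargetSite(protospacer = "GACGCATAAAGATGAGACGCT", pam = "TTTA")
}

# brute-force oracle for the mismatch-library enumeration: enumerate all 4^L
# sequences and keep those whose mismatch positions span <= windowWidth
bruteForceSpanLibrary <- function(consensus, windowWidth) {
  L <- nchar(consensus)
  all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), L)
  cc <- strsplit(consensus, "")[[1]]
  keep <- vapply(strsplit(all, ""), function(b) {
    d <- which(b != cc)
    if (!length(d)) return(TRUE)
    length(d) <= windowWidth && (max(d) - min(d) + 1L) <= windowWidth
  }, logical(1))
  sort(all[keep])
}

# per-base substitution errors, independent of the package's own injector
addReadErrors <- function(reads, rate) {
  vapply(reads, function(s) {
    L <- nchar(s)
    hit <- which(stats::runif(L) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# 200-nt amplicon with a plus-strand Cas12a site at a known offset
fixtureAmplicon <- function(withDonor = FALSE) {
  set.seed(99)
  proto <- "GACGCATAAAGATGAGACGCT"
  left <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 95, TRUE), collapse = "")
  amp <- paste0(left, "TTTA", proto, right)
  if (!withDonor) return(AmpliconTarget(amp, proto, "TTTA", "Cas12a"))
  # EcoRI site inserted after protospacer position 12 (1-based), donor
  # interval flanks the insertion by 5 nt on each side
  ins <- 80L + 4L + 12L
  allele <- paste0(substr(amp, ins - 4L, ins), "GAATTC",
                   substr(amp, ins + 1L, ins + 5L))
  AmpliconTarget(amp, proto, "TTTA", "Cas12a",
                 hdrAllele = allele, hdrInterval = c(ins - 5L, ins + 5L))
}

# assemble a two-variant FractionCounts by hand
handCounts <- function(mat, fraction, replicate = 1L, alpha = 0.5) {
  FractionCounts(mat, fraction = fraction, replicate = replicate,
                 alpha = alpha)
}
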