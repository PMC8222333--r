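test_that("window geometry follows the enzyme-specific cut-site rules", {
  tgt <- fixtureAmplicon()
  # Cas12a plus strand: cut after protospacer position 18
  expect_equal(cutSite(tgt), 80L + 4L + 18L)
  expect_equal(editingWindow(tgt), c(cutSite(tgt) - 3L, cutSite(tgt) + 6L))
  expect_equal(diff(editingWindow(tgt)), 9L)
  # Cas9: cut 3 nt 5' of the PAM, symmetric 8-nt window
  set.seed(4)
  proto9 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  amp9 <- paste0(strrep("ACGT", 10), proto9, "TGGA", strrep("GATC", 10))
  tgt9 <- AmpliconTarget(amp9, proto9, "TGG", "Cas9")
  expect_equal(cutSite(tgt9), 40L + 20L - 3L)
  expect_equal(editingWindow(tgt9), c(cutSite(tgt9) - 4L, cutSite(tgt9) + 4L))
  # minus-strand placement is mirrored
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    ampliconSeq(tgt))))
  tgtM <- AmpliconTarget(rc, "GACGCATAAAGATGAGACGCT", "TTTA", "Cas12a")
  L <- nchar(rc)
  expect_equal(cutSite(tgtM), L - cutSite(tgt))
  expect_equal(editingWindow(tgtM), L - rev(editingWindow(tgt)))
  expect_error(AmpliconTarget(amp9, "AAACCCGGGTTTAAACCCGG", "TTTA"),
               "not found")
})

test_that("perfect, substituted and reverse-complement reads classify as unedited", {
  tgt <- fixtureAmplicon()
  ref <- ampliconSeq(tgt)
  subRead <- ref
  substr(subRead, cutSite(tgt), cutSite(tgt)) <-
    setdiff(c("A", "C", "G", "T"), substr(ref, cutSite(tgt), cutSite(tgt)))[1]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  alns <- alignReadToAmplicon(c(ref, subRead, rc), tgt)
  labels <- vapply(alns, classifyRead, "", target = tgt)
  expect_identical(labels, rep("unedited", 3))
  expect_equal(length(alns[[1]]$ops), 0L)
  expect_identical(alns[[3]]$strand, "-")
})

test_that("indels are slid to the score-equivalent placement nearest the cut", {
  # homopolymer straddling the cut: any of the 6 A's can be reported deleted
  proto <- "GACGCATAAAGATGAGACGCT"
  left <- strrep("CGTA", 20)
  amp <- paste0(left, "TTTA", proto, "AAAAAA", strrep("GTCA", 20))
  # protospacer ends at 80+4+21 = 105; homopolymer at [105,111); cut at 102
  tgt <- AmpliconTarget(amp, proto, "TTTA", "Cas12a")
  cut <- cutSite(tgt)
  # delete the LAST homopolymer A (furthest placement from the cut)
  read <- paste0(substr(amp, 1, 110), substr(amp, 112, nchar(amp)))
  aln <- alignReadToAmplicon(read, tgt)[[1]]
  expect_equal(length(aln$ops), 1L)
  op <- aln$ops[[1]]
  # oracle: equivalent placements delete any single A in [105,111); the
  # placement nearest cut=102 is [105,106)
  expect_identical(op$type, "D")
  expect_equal(op$start, 105L)
  expect_equal(op$end, 106L)
})

test_that("window overlap separates NHEJ from distal indels", {
  tgt <- fixtureAmplicon()
  ref <- ampliconSeq(tgt)
  cut <- cutSite(tgt)
  # 2-nt deletion centred on the cut -> NHEJ
  atCut <- paste0(substr(ref, 1, cut - 1), substr(ref, cut + 2, nchar(ref)))
  # same-size deletion far outside the window -> unedited
  far <- paste0(substr(ref, 1, 19), substr(ref, 22, nchar(ref)))
  res <- callEditing(c(atCut, far), tgt)
  expect_identical(unname(res$labels), c("NHEJ", "unedited"))
})

test_that("strict donor matching labels HDR before NHEJ", {
  tgt <- fixtureAmplicon(withDonor = TRUE)
  ref <- ampliconSeq(tgt)
  hi <- hdrInterval(tgt)
  hdrRead <- paste0(substr(ref, 1, hi[1]), hdrAllele(tgt),
                    substr(ref, hi[2] + 1, nchar(ref)))
  cut <- cutSite(tgt)
  nhejRead <- paste0(substr(ref, 1, cut - 1), substr(ref, cut + 3, nchar(ref)))
  res <- callEditing(c(hdrRead, nhejRead, ref), tgt)
  expect_identical(unname(res$labels), c("HDR", "NHEJ", "unedited"))
  # a donor-matching read seen in reverse complement still calls HDR
  rcHdr <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(hdrRead)))
  expect_identical(unname(callEditing(rcHdr, tgt)$labels), "HDR")
})

test_that("editing summaries tally and percentage correctly", {
  labels <- c(rep("NHEJ", 70), rep("HDR", 20), rep("unedited", 10))
  s <- summarizeEditing(labels)
  expect_equal(unname(editingPercent(s)), 90)
  expect_equal(unname(hdrPercent(s)), 20)
  expect_equal(sum(editingCounts(s)), 100)
  s0 <- summarizeEditing(rep("unedited", 5))
  expect_equal(unname(editingPercent(s0)), 0)
  sD <- summarizeEditing(c("unedited", "no alignment"))
  expect_equal(unname(discardedReads(sD)["no alignment"]), 1)
  expect_error(summarizeEditing(character()), "no classified")
})

test_that("classification is invariant to read order and matches simulated truth", {
  tgt <- fixtureAmplicon(withDonor = TRUE)
  tr <- simTruth(editingRate = 0.4, hdrRate = 0.15, errorRate = 0.001,
                 seed = 12)
  sim <- simulateAmpliconReads(tr, tgt, 800)
  res <- callEditing(sim$reads, tgt)
  expect_gte(mean(res$labels == sim$truthLabels), 0.99)
  perm <- sample(seq_along(sim$reads))
  res2 <- callEditing(sim$reads[perm], tgt)
  expect_identical(res2$labels, res$labels[perm])
})
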