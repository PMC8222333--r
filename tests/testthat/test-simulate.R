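test_that("every simulator is byte-reproducible under a fixed seed", {
  lib <- enumerateMismatchLibrary("ACGTAC", 3)
  tr <- simTruth(depth = 1e4, seed = 9)
  a <- SummarizedExperiment::assay(simulateSpecSeq(tr, lib), "counts")
  b <- SummarizedExperiment::assay(simulateSpecSeq(tr, lib), "counts")
  expect_identical(a, b)
  u <- SummarizedExperiment::assay(simulateSeamSeq(tr, lib), "counts")
  v <- SummarizedExperiment::assay(simulateSeamSeq(tr, lib), "counts")
  expect_identical(u, v)
  ref <- strrep("ACGT", 50)
  expect_identical(simulateMutantLibrary(tr, ref, 200)$sequences,
                   simulateMutantLibrary(tr, ref, 200)$sequences)
  tgt <- fixtureAmplicon(withDonor = TRUE)
  expect_identical(simulateAmpliconReads(tr, tgt, 100)$reads,
                   simulateAmpliconReads(tr, tgt, 100)$reads)
})

test_that("a null binding model gives statistically identical bound/unbound sorts", {
  lib <- enumerateMismatchLibrary("ACGTAC", 2)
  eps0 <- energyTruth(lib, 0)
  tr <- simTruth(bindingEnergy = eps0, fRef = 0.5, depth = 1e5, seed = 13)
  fc <- simulateSpecSeq(tr, lib)
  cts <- SummarizedExperiment::assay(fc, "counts")
  b <- cts[, "bound.1"]; u <- cts[, "unbound.1"]
  p <- suppressWarnings(stats::chisq.test(cbind(b, u))$p.value)
  expect_gt(p, 0.001)
  # and the measured lnKA is centred on zero
  m <- computeLnKA(fc)
  expect_lt(abs(mean(m$value)), 0.05)
})

test_that("single-variant partition arithmetic matches the closed forms", {
  lib <- enumerateMismatchLibrary("ACGTACGT", 1)
  eps <- energyTruth(lib, 1.25)   # alternatives at 1.0, 1.25, 1.5
  tr <- simTruth(bindingEnergy = eps, cleavageEnergy = eps,
                 exposureC = 2, fRef = 0.5, depth = 1e6, seed = 19)
  fc <- simulateSpecSeq(tr, lib)
  truth <- S4Vectors::metadata(fc)$truth
  # bound/unbound odds of a variant with energy E are exp(-E) relative to WT
  m <- computeLnKA(fc)
  expect_true(all(abs(m$value + truth$energies) <= 3 * m$se + 1e-9))
  sc <- simulateSeamSeq(tr, lib)
  truthC <- S4Vectors::metadata(sc)$truth
  d <- computeDeltaD(sc)
  pred <- 2 * (1 - exp(-truthC$energies))
  expect_true(all(abs(d$value - pred) <= 3 * d$se + 1e-9))
  # the 0.5-penalty single mismatch sits at C(1-e^-0.5) ~ 0.787 by the formula
  expect_equal(2 * (1 - exp(-0.5)), 0.787, tolerance = 1e-3)
})

test_that("error-prone PCR calibrates to its per-kb rate with uniform positions", {
  ref <- paste(rep("ACGT", 75), collapse = "")   # 300 nt
  tr0 <- simTruth(muPcr = 0, seed = 3)
  cl0 <- simulateMutantLibrary(tr0, ref, 50)
  expect_true(all(cl0$sequences == ref))
  tr <- simTruth(muPcr = 0.005, seed = 3)
  cl <- simulateMutantLibrary(tr, ref, 1e4)
  nm <- vapply(cl$mutations, nrow, 0L)
  perKb <- mean(nm) / nchar(ref) * 1000
  sigma <- sqrt(0.005 * 0.995 / (1e4 * nchar(ref))) * 1000
  expect_lt(abs(perKb - 5), 4 * sigma)
  # positions uniform across the region
  pos <- unlist(lapply(cl$mutations, `[[`, "pos"))
  bins <- table(cut(pos, breaks = seq(0, nchar(ref), by = 30)))
  p <- stats::chisq.test(bins)$p.value
  expect_gt(p, 0.001)
})

test_that("neutral selection drifts only by sampling while truth serializes", {
  set.seed(23)
  ref <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  tr <- simTruth(muPcr = 0.005, fitness = numeric(), baselineSurvival = 0.5,
                 depth = 2e4, errorRate = 0, seed = 23)
  cl <- simulateMutantLibrary(tr, ref, 5e3)
  sel <- simulateSelectionRounds(tr, cl, nRounds = 3, depth = 2e4)
  tabs <- lapply(names(sel$reads), function(r)
    mutationFrequencies(sel$reads[[r]], ref, round = as.integer(r)))
  traj <- enrichmentTrajectories(tabs)
  # aggregate mutation load is conserved under neutrality; individual rare
  # lineages drift (bottlenecks), so the check is on the distribution
  load0 <- sum(traj$freqs[, 1])
  load3 <- sum(traj$freqs[, ncol(traj$freqs)])
  expect_gt(load3 / load0, 0.6)
  expect_lt(load3 / load0, 1.6)
  common <- traj[traj$freqs[, 1] > 0.001, ]
  expect_gt(stats::median(common$fold), 0.3)
  expect_lt(stats::median(common$fold), 3)
  tf <- tempfile(fileext = ".json")
  writeSimTruthJSON(sel$truth, tf)
  back <- readSimTruthJSON(tf)
  expect_equal(back$baselineSurvival, 0.5)
  expect_equal(back$seed, 23)
  unlink(tf)
})

test_that("amplicon reads with zero editing are unedited up to sequencing error", {
  tgt <- fixtureAmplicon(withDonor = TRUE)
  tr <- simTruth(editingRate = 0, hdrRate = 0, errorRate = 0.001, seed = 31)
  sim <- simulateAmpliconReads(tr, tgt, 500)
  expect_true(all(sim$truthLabels == "unedited"))
  res <- callEditing(sim$reads, tgt)
  expect_equal(unname(editingPercent(res$summary)), 0)
  # off-window indels are labelled in truth and never classified as editing
  tr2 <- simTruth(editingRate = 1, hdrRate = 0, errorRate = 0, seed = 31)
  sim2 <- simulateAmpliconReads(tr2, tgt, 400, offWindowProb = 0.3)
  expect_gt(sum(sim2$truthLabels == "off-window"), 50)
  res2 <- callEditing(sim2$reads, tgt)
  off <- sim2$truthLabels == "off-window"
  expect_true(all(res2$labels[off] != "NHEJ" | FALSE))
  expect_true(all(res2$labels[!off] == "NHEJ"))
})

test_that("two simulated replicates at study-like depth agree per variant", {
  lib <- enumerateMismatchLibrary("ACGTAC", 4)
  tr <- simTruth(depth = 1e6, seed = 41)
  fc <- simulateSpecSeq(tr, lib, nReplicates = 2)
  m <- computeLnKA(fc)
  r1 <- m[m$replicate == "1", ]
  r2 <- m[m$replicate == "2", ]
  r2 <- r2[match(r1$variant_id, r2$variant_id), ]
  expect_gte(stats::cor(r1$value, r2$value), 0.95)
})

test_that("simulated FASTQ emission writes constant qualities and round-trips", {
  reads <- c("ACGTACGT", "GGGTTTCC")
  tf <- tempfile(fileext = ".fastq")
  writeSimFastq(reads, tf)
  back <- readReads(tf)
  expect_identical(unname(as.character(back)), reads)
  lines <- readLines(tf)
  expect_true(all(grepl("^\\?+$", lines[seq(4, length(lines), 4)])))
  unlink(tf)
})
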