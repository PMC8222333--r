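test_that("mutation frequencies count substitutions against the reference", {
  ref <- "ATGAAAGGGCCC"
  reads <- rep(ref, 100)
  t0 <- mutationFrequencies(reads, ref)
  expect_true(all(mutationFreqs(t0)[cbind(match(c("A","T","G","A"), c("A","C","G","T")), 1:4)] == 1))
  expect_equal(sum(mutationCounts(t0)) , 100 * nchar(ref))
  # 2 of 10 reads carry A->G at position 4
  mut <- ref; substr(mut, 4, 4) <- "G"
  t1 <- mutationFrequencies(c(rep(ref, 8), rep(mut, 2)), ref)
  expect_equal(unname(mutationFreqs(t1)["G", 4]), 0.2)
  expect_equal(unname(positionDepth(t1)[4]), 10)
  # indel-carrying reads add depth but never mutation calls
  del <- paste0(substr(ref, 1, 3), substr(ref, 5, nchar(ref)))
  t2 <- mutationFrequencies(c(rep(ref, 5), del), ref)
  expect_equal(unname(positionDepth(t2)[1]), 6)
  expect_equal(sum(mutationCounts(t2)["G", 4]), 0)
})

test_that("frequencies at simulated mutation rates match binomial expectation", {
  set.seed(17)
  ref <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  tr <- simTruth(muPcr = 0.005, seed = 17)
  cl <- simulateMutantLibrary(tr, ref, 1e4)
  t0 <- mutationFrequencies(cl$sequences, ref)
  refc <- strsplit(ref, "")[[1]]
  f <- mutationFreqs(t0)
  f[cbind(match(refc, c("A", "C", "G", "T")), seq_along(refc))] <- 0
  mfreq <- mean(colSums(f))
  sigma <- sqrt(0.005 * 0.995 / (1e4 * 200))
  expect_lt(abs(mfreq - 0.005), 4 * sigma)
})

test_that("zero-depth positions report missing, not zero", {
  ref <- "ACGTACGTA"
  tab <- new("MutationFrequencyTable", round = 0L, reference = ref,
             counts = matrix(0, 4, 9, dimnames = list(c("A","C","G","T"), NULL)),
             depth = rep(0, 9), codonOffset = 1L)
  expect_true(all(is.na(mutationFreqs(tab))))
})

test_that("trajectories compute folds with a depth floor and translate codons", {
  ref <- "ATGTTTAAA"                      # M F K
  mkTab <- function(round, freqG7) {
    counts <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
    depth <- rep(1000, 9)
    refc <- strsplit(ref, "")[[1]]
    counts[cbind(match(refc, c("A", "C", "G", "T")), 1:9)] <- 1000
    # A->G at position 7 (codon 3 AAA->GAA, K->E)
    counts["G", 7] <- freqG7 * 1000
    counts["A", 7] <- 1000 - counts["G", 7]
    new("MutationFrequencyTable", round = as.integer(round),
        reference = ref, counts = counts, depth = depth, codonOffset = 1L)
  }
  tabs <- list(mkTab(0, 0.01), mkTab(1, 0.1), mkTab(2, 0.5))
  traj <- enrichmentTrajectories(tabs)
  row <- traj[traj$label == "A7G", ]
  expect_equal(unname(row$fold), 50)
  expect_identical(unname(row$aaLabel), "K3E")
  # constant frequencies give fold 1
  flat <- enrichmentTrajectories(list(mkTab(0, 0.2), mkTab(1, 0.2),
                                      mkTab(2, 0.2)))
  expect_equal(unname(flat[flat$label == "A7G", ]$fold), 1)
  # unobserved-at-round-0 mutations use the 1/depth floor
  zero <- enrichmentTrajectories(list(mkTab(0, 0), mkTab(1, 0.5),
                                      mkTab(2, 0.5)))
  expect_equal(unname(zero[zero$label == "A7G", ]$fold), 0.5 / (1 / 1000))
  expect_error(enrichmentTrajectories(list(mkTab(1, 0.1), mkTab(2, 0.2))),
               "round 0")
  expect_error(enrichmentTrajectories(list(mkTab(0, 0.1), mkTab(2, 0.2))),
               "missing rounds: 1")
})

test_that("dominance calls honour the frequency and monotonicity thresholds", {
  ref <- "ATGTTTAAA"
  mkTraj <- function(series) {
    counts0 <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
    refc <- strsplit(ref, "")[[1]]
    tabs <- lapply(seq_along(series), function(i) {
      counts <- counts0
      counts[cbind(match(refc, c("A", "C", "G", "T")), 1:9)] <- 1000
      counts["G", 7] <- series[i] * 1000
      counts["A", 7] <- 1000 - counts["G", 7]
      new("MutationFrequencyTable", round = i - 1L, reference = ref,
          counts = counts, depth = rep(1000, 9), codonOffset = 1L)
    })
    enrichmentTrajectories(tabs)
  }
  rising <- mkTraj(c(0.01, 0.05, 0.2, 0.4, 0.6))
  expect_identical(unname(callDominantMutations(rising)), "A7G")
  flat <- mkTraj(rep(0.01, 5))
  expect_length(callDominantMutations(flat), 0)
  # a high-final but non-monotone trajectory fails the run requirement
  seesaw <- mkTraj(c(0.4, 0.1, 0.4, 0.1, 0.4))
  expect_length(callDominantMutations(seesaw, monotoneRoundsMin = 3), 0)
  # degenerate thresholds admit every observed mutation
  expect_gt(length(callDominantMutations(flat, finalFreqMin = 0,
                                         monotoneRoundsMin = 1)), 0)
})

test_that("an end-to-end selection calls exactly the planted mutations in fitness order", {
  set.seed(42)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  a1 <- setdiff(c("A", "C", "G", "T"), substr(ref, 100, 100))[1]
  a2 <- setdiff(c("A", "C", "G", "T"), substr(ref, 200, 200))[1]
  fitness <- stats::setNames(c(10, 8), c(paste0("100", a1), paste0("200", a2)))
  tr <- simTruth(muPcr = 0.005, fitness = fitness, baselineSurvival = 0.05,
                 depth = 1e5, errorRate = 0.001, seed = 5)
  clones <- simulateMutantLibrary(tr, ref, 1e5)
  sel <- simulateSelectionRounds(tr, clones, nRounds = 5, depth = 1e5)
  tabs <- lapply(names(sel$reads), function(r)
    mutationFrequencies(sel$reads[[r]], ref, round = as.integer(r)))
  dom <- callDominantMutations(enrichmentTrajectories(tabs))
  planted <- c(paste0(substr(ref, 100, 100), "100", a1),
               paste0(substr(ref, 200, 200), "200", a2))
  expect_identical(unname(dom), planted)
})
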