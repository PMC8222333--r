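#' @include AllClasses.R AllGenerics.R libraryDesign.R fractionCounts.R
NULL

#' Construct a SimTruth parameter object
#'
#' Defaults encode the study conditions the generators emulate: error-prone
#' PCR at 0.005 substitutions per base (5 mutations/kb), 83-nt reads,
#' 0.1 percent per-base sequencing error, a balanced reference sort
#' (consensus bound fraction 0.5) and a partial-digest cleavage exposure
#' C = k_ref * t = 1 (~63 percent consensus cleavage, maximizing log-ratio
#' dynamic range).
#'
#' @param bindingEnergy,cleavageEnergy 4 x P penalty matrices (rows A/C/G/T,
#'   columns position labels, consensus entries 0); see
#'   [defaultEnergyTruth()]
#' @param exposureC cleavage exposure C = k_ref * t
#' @param fRef consensus bound fraction in the binding sort
#' @param pamEnergy named 256-entry PAM energy table (optional)
#' @param muPcr error-prone-PCR per-base substitution rate
#' @param fitness named survival multipliers, keys "<position><altBase>"
#' @param baselineSurvival per-round survival of an unmutated clone
#' @param editingRate,hdrRate amplicon outcome probabilities (editing is
#'   total NHEJ + HDR; hdrRate must not exceed it)
#' @param depth reads per simulated column
#' @param readLength read length for FASTQ emission
#' @param errorRate per-base sequencing error rate
#' @param seed random seed recorded in all outputs
#' @return a [SimTruth-class]
#' @export
simTruth <- function(bindingEnergy = matrix(0, 4, 0,
                                            dimnames = list(.DNA_BASES, NULL)),
                     cleavageEnergy = bindingEnergy,
                     exposureC = 1, fRef = 0.5, pamEnergy = numeric(),
                     muPcr = 0.005, fitness = numeric(),
                     baselineSurvival = 0.05,
                     editingRate = 0.5, hdrRate = 0.1,
                     depth = 1e6, readLength = 83L, errorRate = 0.001,
                     seed = 1L) {
  stopifnot(hdrRate <= editingRate)
  new("SimTruth", bindingEnergy = bindingEnergy,
      cleavageEnergy = cleavageEnergy, exposureC = exposureC, fRef = fRef,
      pamEnergy = pamEnergy, muPcr = muPcr, fitness = fitness,
      baselineSurvival = baselineSurvival, editingRate = editingRate,
      hdrRate = hdrRate, depth = depth, readLength = as.integer(readLength),
      errorRate = errorRate, seed = as.integer(seed))
}

#' A realistic ground-truth penalty matrix for a Cas12a-like enzyme
#'
#' Deterministic per-position penalty profile shaped like the field's
#' consensus picture of Cas12a specificity: strong PAM recognition (weakest
#' at PAM positions 1 and 4), strong seed-region penalties (protospacer
#' positions 1-7), a characteristic dip in the centre (positions 9-11),
#' moderate penalties PAM-distal, and small deterministic per-base
#' variation.  Used as the generators' default energy truth.
#'
#' @param target a [TargetSite-class]
#' @param scale overall multiplier (default 1; e.g. 0.8 mimics an enzyme
#'   with uniformly reduced mismatch penalties)
#' @return 4 x P penalty matrix with consensus entries 0
#' @export
defaultEnergyTruth <- function(target, scale = 1) {
  labels <- positionLabels(target)
  refs <- strsplit(variableRegion(target), "")[[1]]
  base <- vapply(labels, function(p) {
    if (startsWith(p, "P")) {
      i <- as.integer(substring(p, 2L))
      if (i %in% c(1L, 4L)) 1.2 else 2.5
    } else {
      i <- as.integer(p)
      if (i <= 7L) 2.0
      else if (i >= 9L && i <= 11L) 0.3
      else if (i <= 19L) 1.0
      else 0.2
    }
  }, 0)
  eps <- matrix(0, 4L, length(labels), dimnames = list(.DNA_BASES, labels))
  for (j in seq_along(labels)) {
    alts <- setdiff(.DNA_BASES, refs[j])
    # fixed per-base offsets keep alternatives distinguishable
    eps[alts, j] <- scale * base[j] * c(0.8, 1.0, 1.2)
  }
  eps
}

#' Build a ground-truth penalty matrix for a library's coordinate frame
#'
#' Convenience for simulations over arbitrary frames: a per-position penalty
#' level (recycled over positions) spread over the three alternative bases
#' with fixed multipliers (0.8, 1.0, 1.2) so alternatives stay
#' distinguishable.
#'
#' @param library a [VariantLibrary-class]
#' @param perPosition per-position penalty level(s), recycled
#' @return 4 x P penalty matrix with consensus entries 0
#' @export
energyTruth <- function(library, perPosition = 1) {
  labels <- positionLabels(library)
  refs <- strsplit(variableRegion(library), "")[[1]]
  lvl <- rep_len(perPosition, length(labels))
  eps <- matrix(0, 4L, length(labels), dimnames = list(.DNA_BASES, labels))
  for (j in seq_along(labels)) {
    alts <- setdiff(.DNA_BASES, refs[j])
    eps[alts, j] <- lvl[j] * c(0.8, 1.0, 1.2)
  }
  eps
}

.defaultLibraryTruth <- function(library) {
  tg <- targetSite(library)
  if (!is.null(tg)) defaultEnergyTruth(tg)
  else energyTruth(library, 1)
}

# variant energies under an additive per-position truth matrix
.variantEnergies <- function(library, eps) {
  man <- variants(library)
  mm <- parseMismatches(man$mismatches)
  vapply(mm, function(d) {
    if (!nrow(d)) return(0)
    sum(eps[cbind(d$alt, d$position)])
  }, 0)
}

#' Simulate a Spec-seq binding sort
#'
#' Single-site Boltzmann partition with a global chemical potential: variant
#' i with energy E_i (sum of its mismatch penalties) is bound with
#' probability f_i = 1 / (1 + exp(E_i - mu)), mu = ln(fRef / (1 - fRef)).
#' Input, bound and unbound columns are multinomial draws of the configured
#' depth with weights proportional to n_i, n_i f_i and n_i (1 - f_i)
#' (equimolar n_i).  Deterministic given the seed.
#'
#' @param truth a [SimTruth-class]; its bindingEnergy must cover the
#'   library's coordinate frame (defaults to [defaultEnergyTruth()] when
#'   empty)
#' @param library a [VariantLibrary-class]
#' @param nReplicates number of independent bound/unbound replicate draws
#' @param seed override of the truth seed
#' @return a [FractionCounts-class] with the applied SimTruth in metadata
#' @export
simulateSpecSeq <- function(truth, library, nReplicates = 1L,
                            seed = truth@seed) {
  eps <- truth@bindingEnergy
  if (ncol(eps) == 0L) eps <- .defaultLibraryTruth(library)
  E <- .variantEnergies(library, eps)
  mu <- log(truth@fRef / (1 - truth@fRef))
  f <- 1 / (1 + exp(E - mu))
  n <- length(E)
  set.seed(seed)
  cols <- list()
  fraction <- character(); replicate <- character()
  for (r in seq_len(nReplicates)) {
    cols[[paste0("input", r)]] <-
      stats::rmultinom(1L, truth@depth, rep(1, n))[, 1L]
    cols[[paste0("bound", r)]] <- stats::rmultinom(1L, truth@depth, f)[, 1L]
    cols[[paste0("unbound", r)]] <-
      stats::rmultinom(1L, truth@depth, 1 - f)[, 1L]
    fraction <- c(fraction, "input", "bound", "unbound")
    replicate <- c(replicate, rep(as.character(r), 3L))
  }
  cts <- do.call(cbind, cols)
  rownames(cts) <- variantIds(library)
  fc <- FractionCounts(cts, fraction = fraction, replicate = replicate)
  metadata(fc)$truth <- list(energies = E, boundProb = f, seed = seed,
                             eps = eps, fRef = truth@fRef)
  fc
}

#' Simulate a SEAM-seq cleavage assay
#'
#' First-order cleavage kinetics with energy-scaled rates: variant i is
#' cleaved at rate k_i = k_ref * exp(-E^c_i), so after exposure C = k_ref*t
#' its uncut probability is q_i = exp(-C * exp(-E^c_i)).  The uncut column
#' is multinomial with weights proportional to n_i q_i, the input (mock
#' digest) column proportional to n_i.
#'
#' @inheritParams simulateSpecSeq
#' @return a [FractionCounts-class] with input and uncut columns
#' @export
simulateSeamSeq <- function(truth, library, nReplicates = 1L,
                            seed = truth@seed) {
  eps <- truth@cleavageEnergy
  if (ncol(eps) == 0L) eps <- .defaultLibraryTruth(library)
  E <- .variantEnergies(library, eps)
  q <- exp(-truth@exposureC * exp(-E))
  n <- length(E)
  set.seed(seed)
  cols <- list()
  fraction <- character(); replicate <- character()
  for (r in seq_len(nReplicates)) {
    cols[[paste0("input", r)]] <-
      stats::rmultinom(1L, truth@depth, rep(1, n))[, 1L]
    cols[[paste0("uncut", r)]] <- stats::rmultinom(1L, truth@depth, q)[, 1L]
    fraction <- c(fraction, "input", "uncut")
    replicate <- c(replicate, rep(as.character(r), 2L))
  }
  cts <- do.call(cbind, cols)
  rownames(cts) <- variantIds(library)
  fc <- FractionCounts(cts, fraction = fraction, replicate = replicate)
  metadata(fc)$truth <- list(energies = E, uncutProb = q, seed = seed,
                             eps = eps, exposureC = truth@exposureC)
  fc
}

# sparse per-base substitution-error injection into a character vector
.injectErrors <- function(seqs, errorRate) {
  if (errorRate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs)
  nTot <- stats::rbinom(1L, sum(L), errorRate)
  if (nTot == 0L) return(seqs)
  # place errors uniformly over (read, position) cells
  cum <- cumsum(as.numeric(L))
  cell <- sort(sample(sum(L), nTot))
  rd <- findInterval(cell - 1, cum) + 1L
  pos <- cell - c(0, cum)[rd]
  for (i in seq_len(nTot)) {
    cur <- substr(seqs[rd[i]], pos[i], pos[i])
    alt <- sample(setdiff(.DNA_BASES, cur), 1L)
    substr(seqs[rd[i]], pos[i], pos[i]) <- alt
  }
  seqs
}

#' Simulate an error-prone-PCR mutant library
#'
#' Each clone receives i.i.d. per-base substitutions at rate muPcr (default
#' 0.005, i.e. an average of 5 mutations per kb) with a uniform choice among
#' the three alternative bases.
#'
#' @param truth a [SimTruth-class]
#' @param region reference coding segment (character)
#' @param nClones number of clones
#' @param seed override of the truth seed
#' @return list: sequences (character vector), mutations (list of
#'   data.frames pos/ref/alt), truth (parameters applied, incl. seed)
#' @export
simulateMutantLibrary <- function(truth, region, nClones,
                                  seed = truth@seed) {
  region <- toupper(as.character(region))
  L <- nchar(region)
  refc <- strsplit(region, "")[[1]]
  set.seed(seed)
  nm <- stats::rbinom(nClones, L, truth@muPcr)
  seqs <- rep(region, nClones)
  mutations <- vector("list", nClones)
  empty <- data.frame(pos = integer(), ref = character(), alt = character())
  for (i in seq_len(nClones)) {
    if (nm[i] == 0L) { mutations[[i]] <- empty; next }
    pos <- sort(sample.int(L, nm[i]))
    alt <- vapply(pos, function(p)
      sample(setdiff(.DNA_BASES, refc[p]), 1L), "")
    s <- refc
    s[pos] <- alt
    seqs[i] <- paste(s, collapse = "")
    mutations[[i]] <- data.frame(pos = pos, ref = refc[pos], alt = alt)
  }
  list(sequences = seqs, mutations = mutations,
       truth = list(muPcr = truth@muPcr, region = region, seed = seed,
                    nClones = nClones))
}

#' Simulate rounds of survival selection
#'
#' Each round, clone i survives with probability sigma_i = baselineSurvival
#' times the product of the fitness multipliers of its mutations (capped at
#' 1); survivors are resampled with replacement back to the constant
#' population size, and reads are emitted from the post-selection population
#' at the configured depth and sequencing error rate.  Round 0 reads come
#' from the input library.
#'
#' @param truth a [SimTruth-class]; fitness keys are "<pos><altBase>"
#'   (e.g. "103G")
#' @param clones output of [simulateMutantLibrary()]
#' @param nRounds number of selection rounds (default 5)
#' @param depth reads emitted per round (default truth depth)
#' @param seed override of the truth seed
#' @return list: reads (list of character vectors, rounds 0..nRounds),
#'   truth (fitness map, per-clone survival, seed)
#' @export
simulateSelectionRounds <- function(truth, clones, nRounds = 5L,
                                    depth = truth@depth,
                                    seed = truth@seed) {
  seqs <- clones$sequences
  n <- length(seqs)
  sigma <- vapply(clones$mutations, function(m) {
    mult <- 1
    if (nrow(m)) {
      keys <- paste0(m$pos, m$alt)
      hit <- keys %in% names(truth@fitness)
      if (any(hit)) mult <- prod(truth@fitness[keys[hit]])
    }
    min(1, truth@baselineSurvival * mult)
  }, 0)
  set.seed(seed)
  pop <- seq_len(n)
  emit <- function(population) {
    idx <- sample(population, depth, replace = TRUE)
    .injectErrors(seqs[idx], truth@errorRate)
  }
  reads <- list(`0` = emit(pop))
  for (r in seq_len(nRounds)) {
    alive <- pop[stats::runif(length(pop)) < sigma[pop]]
    if (!length(alive)) stop("population went extinct at round ", r)
    pop <- sample(alive, n, replace = TRUE)
    reads[[as.character(r)]] <- emit(pop)
  }
  list(reads = reads,
       truth = list(fitness = as.list(truth@fitness),
                    baselineSurvival = truth@baselineSurvival,
                    survival = sigma, seed = seed, depth = depth,
                    errorRate = truth@errorRate))
}

#' Simulate edited amplicon reads with per-read truth labels
#'
#' Each read is drawn as HDR (probability hdrRate), NHEJ (probability
#' editingRate - hdrRate) or unedited, then hit by per-base sequencing
#' errors.  NHEJ indel sizes follow a truncated geometric distribution
#' (sizes 1..10, default mean ~2.5), deletions and insertions equally
#' likely, with the indel midpoint jittered by at most 1 nt around the cut.
#' A configurable fraction of indels is instead placed well outside the
#' scoring window and truth-labelled "off-window" — these should never be
#' counted as editing.
#'
#' @param truth a [SimTruth-class]
#' @param target an [AmpliconTarget-class] (supplies reference, cut and
#'   donor allele; HDR simulation requires a configured donor)
#' @param nReads number of reads
#' @param offWindowProb fraction of indel reads placed off-window (default 0)
#' @param seed override of the truth seed
#' @return list: reads (character vector), truthLabels, truth
#' @export
simulateAmpliconReads <- function(truth, target, nReads,
                                  offWindowProb = 0, seed = truth@seed) {
  ref <- ampliconSeq(target)
  L <- nchar(ref)
  cut <- cutSite(target)
  pNHEJ <- truth@editingRate - truth@hdrRate
  if (truth@hdrRate > 0 && is.na(hdrAllele(target)))
    stop("hdrRate > 0 requires a donor allele on the target")
  set.seed(seed)
  outcome <- sample(c("HDR", "NHEJ", "unedited"), nReads, replace = TRUE,
                    prob = c(truth@hdrRate, pNHEJ,
                             1 - truth@editingRate))
  hdrRead <- ref
  if (!is.na(hdrAllele(target))) {
    hi <- hdrInterval(target)
    hdrRead <- paste0(substr(ref, 1L, hi[1L]), hdrAllele(target),
                      substr(ref, hi[2L] + 1L, L))
  }
  w <- editingWindow(target)
  makeNhej <- function(off) {
    size <- sample(1:10, 1L, prob = 0.6^(1:10))
    mid <- if (off) {
      # far outside the scoring window, clear of the amplicon ends
      side <- sample(c(-1, 1), 1L)
      if (side < 0) max(15L, w[1L] - 25L) else min(L - 15L, w[2L] + 25L)
    } else cut + sample(-1:1, 1L)
    if (stats::runif(1L) < 0.5) {
      s <- max(1L, min(L - size, round(mid - size / 2)))   # deletion, 1-based
      paste0(substr(ref, 1L, s - 1L), substr(ref, s + size, L))
    } else {
      ins <- paste(sample(.DNA_BASES, size, replace = TRUE), collapse = "")
      paste0(substr(ref, 1L, mid), ins, substr(ref, mid + 1L, L))
    }
  }
  reads <- character(nReads)
  labels <- outcome
  for (i in seq_len(nReads)) {
    reads[i] <- switch(outcome[i],
      unedited = ref,
      HDR = hdrRead,
      NHEJ = {
        off <- stats::runif(1L) < offWindowProb
        if (off) labels[i] <- "off-window"
        makeNhej(off)
      })
  }
  reads <- .injectErrors(reads, truth@errorRate)
  list(reads = reads, truthLabels = labels,
       truth = list(editingRate = truth@editingRate,
                    hdrRate = truth@hdrRate, errorRate = truth@errorRate,
                    offWindowProb = offWindowProb, seed = seed))
}

#' Write simulated reads as FASTQ with constant qualities
#' @param reads character vector or DNAStringSet
#' @param file output path (".gz" gzips)
#' @param quality constant Phred quality (default 30)
#' @export
writeSimFastq <- function(reads, file, quality = 30L) {
  if (!is(reads, "DNAStringSet")) {
    nm <- paste0("read", seq_along(reads))
    reads <- Biostrings::DNAStringSet(reads)
    names(reads) <- nm
  } else if (is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    paste(rep(rawToChar(as.raw(quality + 33L)), w), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, filepath = file, format = "fastq",
                              qualities = q)
  invisible(file)
}

#' Serialize a simulation truth record as JSON
#'
#' Every simulator returns (or stores in metadata) a truth list; writing it
#' next to the data lets integration tests read ground truth only from the
#' serialized file.
#' @param truth list of truth parameters (from a simulator's $truth or a
#'   FractionCounts metadata)
#' @param file output path
#' @export
writeSimTruthJSON <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeSimTruthJSON
#' @export
readSimTruthJSON <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
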