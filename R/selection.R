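#' @include AllClasses.R AllGenerics.R fractionCounts.R
NULL

#' Per-position mutation frequencies from amplicon reads
#'
#' Compares merged amplicon reads against the reference coding segment and
#' tallies substitutions per position, normalized by per-position depth.
#' Only substitutions are scored: reads whose length differs from the
#' reference carry indels, which the selection assay purges (frameshifts are
#' lethal to the reporter), so such reads contribute to depth but never to
#' mutation counts.  Reads containing ambiguous bases contribute depth and
#' counts only at unambiguous positions.  When per-base qualities are
#' supplied, bases below \code{minBaseQuality} are masked out of both depth
#' and counts.
#'
#' @param reads DNAStringSet or character vector of merged amplicon reads
#'   spanning the mutagenized region
#' @param reference reference sequence of the region (character)
#' @param round selection round index (0 = input library)
#' @param codonOffset codon number of the first reference codon, used for
#'   residue-change labels (e.g. 503 for a region starting at codon I503)
#' @param qualities optional PhredQuality strings parallel to reads
#' @param minBaseQuality quality threshold when qualities are given
#' @return a [MutationFrequencyTable-class]
#' @export
mutationFrequencies <- function(reads, reference, round = 0L,
                                codonOffset = 1L, qualities = NULL,
                                minBaseQuality = 15L) {
  reference <- toupper(as.character(reference))
  L <- nchar(reference)
  if (L == 0L) stop("reference must be non-empty")
  if (!is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(as.character(reads))
  widths <- Biostrings::width(reads)
  if (any(widths < 1L)) stop("each read must span at least one position")
  even <- widths == L
  depth <- numeric(L)
  counts <- matrix(0, 4L, L, dimnames = list(.DNA_BASES, NULL))
  if (any(even)) {
    sub <- reads[even]
    if (!is.null(qualities)) {
      q <- as(Biostrings::PhredQuality(qualities[even]), "IntegerList")
      chars <- strsplit(as.character(sub), "")
      chars <- mapply(function(b, qq) {
        b[qq < minBaseQuality] <- "N"
        paste(b, collapse = "")
      }, chars, q, SIMPLIFY = TRUE)
      sub <- Biostrings::DNAStringSet(chars)
    }
    cm <- Biostrings::consensusMatrix(sub)[, seq_len(L), drop = FALSE]
    have <- intersect(.DNA_BASES, rownames(cm))
    counts[have, ] <- cm[have, ]
    depth <- depth + colSums(counts)
  }
  # indel-carrying reads: depth only
  depth <- depth + sum(!even)
  new("MutationFrequencyTable", round = as.integer(round),
      reference = reference, counts = counts, depth = depth,
      codonOffset = as.integer(codonOffset))
}

#' @describeIn mutationFrequencies 4 x L base count matrix
#' @param x a MutationFrequencyTable
#' @export
setMethod("mutationCounts", "MutationFrequencyTable", function(x) x@counts)
#' @describeIn mutationFrequencies per-position depth
#' @export
setMethod("positionDepth", "MutationFrequencyTable", function(x) x@depth)
#' @describeIn mutationFrequencies selection round index
#' @export
setMethod("roundIndex", "MutationFrequencyTable", function(x) x@round)

#' @describeIn mutationFrequencies 4 x L per-base frequency matrix
#'   (count / depth); NA, not 0, where depth is zero
#' @export
setMethod("mutationFreqs", "MutationFrequencyTable", function(x) {
  f <- sweep(x@counts, 2L, x@depth, "/")
  f[, x@depth == 0] <- NA_real_
  f
})

setMethod("show", "MutationFrequencyTable", function(object) {
  L <- nchar(object@reference)
  refIdx <- cbind(match(strsplit(object@reference, "")[[1]], .DNA_BASES),
                  seq_len(L))
  mut <- sum(object@counts) - sum(object@counts[refIdx])
  cat("MutationFrequencyTable round ", object@round, ": ", L,
      " positions, median depth ", stats::median(object@depth),
      ", total substitution calls ", mut, "\n", sep = "")
})

.aaChangeLabel <- function(reference, pos, alt, codonOffset) {
  ci <- (pos - 1L) %/% 3L
  cstart <- ci * 3L + 1L
  if (cstart + 2L > nchar(reference)) return(NA_character_)
  codon <- substr(reference, cstart, cstart + 2L)
  altCodon <- codon
  substr(altCodon, pos - cstart + 1L, pos - cstart + 1L) <- alt
  gc <- Biostrings::GENETIC_CODE
  paste0(gc[[codon]], codonOffset + ci, gc[[altCodon]])
}

#' Mutation enrichment trajectories across selection rounds
#'
#' For every (position, alternative base) substitution observed in any round,
#' builds the frequency series over rounds and the fold enrichment of the
#' final round relative to round 0, with a frequency floor of 1/depth at
#' round 0 so unobserved input mutations give finite folds.  Residue-change
#' labels (e.g. M537R) are derived by translating the single-base change in
#' its codon.
#'
#' @param tables list of [MutationFrequencyTable-class], one per round,
#'   containing round 0
#' @return DataFrame: position, ref, alt, label (e.g. "A112G"), aaLabel,
#'   one freq_<round> column per round, fold (final vs round 0)
#' @export
enrichmentTrajectories <- function(tables) {
  rounds <- vapply(tables, roundIndex, 0L)
  tables <- tables[order(rounds)]
  rounds <- sort(rounds)
  if (rounds[1L] != 0L) stop("round 0 (input library) is required")
  missing <- setdiff(seq.int(0L, max(rounds)), rounds)
  if (length(missing))
    stop("missing rounds: ", paste(missing, collapse = ", "))
  refs <- vapply(tables, function(t) t@reference, "")
  if (length(unique(refs)) != 1L)
    stop("all rounds must share one reference (coordinate frame)")
  reference <- refs[1L]
  L <- nchar(reference)
  refChars <- strsplit(reference, "")[[1]]
  freqs <- lapply(tables, mutationFreqs)
  # observed non-reference substitutions in any round
  anyObs <- Reduce(`+`, lapply(tables, mutationCounts)) > 0
  anyObs[cbind(match(refChars, .DNA_BASES), seq_len(L))] <- FALSE
  hits <- which(anyObs, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(DataFrame(position = integer(), ref = character(),
                     alt = character(), label = character(),
                     aaLabel = character()))
  }
  pos <- hits[, 2L]
  alt <- .DNA_BASES[hits[, 1L]]
  fm <- vapply(freqs, function(f) f[hits], numeric(nrow(hits)))
  fm <- matrix(fm, nrow = nrow(hits),
               dimnames = list(NULL, paste0("freq_", rounds)))
  floor0 <- 1 / pmax(positionDepth(tables[[1L]])[pos], 1)
  f0 <- pmax(fm[, 1L], floor0)
  fold <- fm[, ncol(fm)] / f0
  co <- tables[[1L]]@codonOffset
  aa <- vapply(seq_along(pos), function(i)
    .aaChangeLabel(reference, pos[i], alt[i], co), "")
  out <- DataFrame(position = pos, ref = refChars[pos], alt = alt,
                   label = paste0(refChars[pos], pos, alt), aaLabel = aa,
                   freqs = I(fm), fold = fold)
  out[order(-out$fold), , drop = FALSE]
}

#' Call dominant mutations from enrichment trajectories
#'
#' A mutation is dominant when its final-round frequency reaches
#' \code{finalFreqMin} and its frequency is non-decreasing over at least
#' \code{monotoneRoundsMin} consecutive rounds.  Results are sorted by final
#' frequency, most dominant first.  The thresholds are analysis defaults,
#' exposed because the underlying assay defines none.
#'
#' @param trajectories DataFrame from [enrichmentTrajectories()]
#' @param finalFreqMin final-round frequency threshold (default 0.1)
#' @param monotoneRoundsMin length of the required non-decreasing run, in
#'   rounds (default 3; values <= 1 disable the run requirement)
#' @return character vector of nucleotide-change labels (names give the
#'   residue-change labels), sorted by final frequency
#' @export
callDominantMutations <- function(trajectories, finalFreqMin = 0.1,
                                  monotoneRoundsMin = 3L) {
  if (!nrow(trajectories)) return(character())
  fm <- trajectories$freqs
  if (ncol(fm) < 2L) stop("need at least 2 rounds to call dominance")
  finalF <- fm[, ncol(fm)]
  monoRun <- apply(fm, 1L, function(f) {
    steps <- diff(f) >= -1e-12
    if (!length(steps)) return(1L)
    r <- rle(steps)
    best <- r$lengths[r$values]
    if (length(best)) max(best) + 1L else 1L
  })
  keep <- finalF >= finalFreqMin &
    (monotoneRoundsMin <= 1L | monoRun >= monotoneRoundsMin)
  sel <- trajectories[keep, , drop = FALSE]
  sel <- sel[order(-sel$freqs[, ncol(fm)]), , drop = FALSE]
  stats::setNames(sel$label, sel$aaLabel)
}

#' Write per-round frequency and trajectory tables
#' @param trajectories DataFrame from [enrichmentTrajectories()]
#' @param file path
#' @export
writeTrajectoriesTSV <- function(trajectories, file) {
  fm <- as.data.frame(trajectories$freqs)
  df <- cbind(as.data.frame(trajectories[, c("position", "ref", "alt",
                                             "label", "aaLabel")]),
              fm, fold = trajectories$fold)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
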