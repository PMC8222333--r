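#' @include AllClasses.R AllGenerics.R libraryDesign.R
NULL

#' Read sequencing reads from FASTQ or FASTA
#'
#' Thin wrapper over Biostrings that sniffs the format from the file name
#' (.fastq/.fq vs .fasta/.fa, optionally .gz).
#' @param file path
#' @return a DNAStringSet
#' @export
readReads <- function(file) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", file)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(file, format = fmt)
}

#' Extract the variable region from construct reads
#'
#' Locates the first occurrence of the 5' flank anchor and the following 3'
#' flank anchor (each allowed up to \code{maxFlankMismatches} substitutions)
#' and returns the substring between them.  Reads where either anchor is not
#' found yield NA ("no-match"); no-matches are a return state, not an error,
#' and are tallied into metadata by [tallyLibraryCounts()].  Reads containing
#' ambiguous bases in an anchor never match it.
#'
#' @param reads DNAStringSet or character vector of reads
#' @param target a [TargetSite-class] supplying the anchors
#' @param maxFlankMismatches substitutions tolerated per anchor (default 0)
#' @return character vector, NA where no match
#' @export
extractVariableRegion <- function(reads, target, maxFlankMismatches = 0L) {
  stopifnot(is(target, "TargetSite"))
  if (!is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(as.character(reads))
  m5 <- Biostrings::vmatchPattern(flank5(target), reads,
                                  max.mismatch = maxFlankMismatches)
  m3 <- Biostrings::vmatchPattern(flank3(target), reads,
                                  max.mismatch = maxFlankMismatches)
  rc <- as.character(reads)
  out <- rep(NA_character_, length(reads))
  s5 <- IRanges::start(m5); e5 <- IRanges::end(m5); s3 <- IRanges::start(m3)
  for (i in which(lengths(s5) > 0L & lengths(s3) > 0L)) {
    end5 <- e5[[i]][1L]
    starts3 <- s3[[i]]
    starts3 <- starts3[starts3 > end5]
    if (!length(starts3)) next
    out[i] <- substr(rc[i], end5 + 1L, starts3[1L] - 1L)
  }
  out
}

#' Tally a read stream against a variant library
#'
#' Extracted variable regions are assigned to library variants by exact
#' sequence match only — library members can differ by a single base, so
#' error-tolerant assignment would cross-assign; reads hit by sequencing
#' errors land in the unmatched tally instead.  Every library variant is
#' reported (possibly 0).
#'
#' @param reads DNAStringSet or character vector (one fraction's reads)
#' @param library a [VariantLibrary-class]
#' @param maxFlankMismatches passed to [extractVariableRegion()]
#' @return list with counts (named integer vector over variant IDs),
#'   unmatched, and total
#' @export
tallyLibraryCounts <- function(reads, library, maxFlankMismatches = 0L) {
  stopifnot(is(library, "VariantLibrary"))
  if (length(reads) == 0L)
    stop("empty read stream: no reads supplied for this fraction")
  vr <- extractVariableRegion(reads, targetSite(library),
                              maxFlankMismatches = maxFlankMismatches)
  seqs <- variantSequences(library)
  idx <- match(vr, seqs)
  counts <- tabulate(idx, nbins = length(seqs))
  names(counts) <- names(seqs)
  list(counts = counts,
       unmatched = sum(is.na(idx)),
       total = length(reads))
}

#' Assemble fraction tallies into a FractionCounts object
#'
#' @param counts integer matrix (variants x columns, rownames = variant IDs)
#'   or a list of tallies from [tallyLibraryCounts()]
#' @param fraction per-column fraction label (input/bound/unbound/uncut)
#' @param replicate per-column replicate identifier
#' @param unmatched per-column unmatched-read counts (taken from tallies when
#'   a tally list is given)
#' @param alpha pseudocount recorded for downstream normalization
#' @return a [FractionCounts-class]
#' @export
FractionCounts <- function(counts, fraction, replicate = 1L,
                           unmatched = 0L, alpha = 0.5) {
  if (is.list(counts) && !is.matrix(counts)) {
    unmatched <- vapply(counts, `[[`, 0L, "unmatched")
    counts <- do.call(cbind, lapply(counts, `[[`, "counts"))
  }
  counts <- as.matrix(counts)
  ncols <- ncol(counts)
  fraction <- rep_len(as.character(fraction), ncols)
  replicate <- rep_len(as.character(replicate), ncols)
  unmatched <- rep_len(as.integer(unmatched), ncols)
  colnames(counts) <- paste(fraction, replicate, sep = ".")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(fraction = fraction,
                                   replicate = replicate,
                                   unmatched = unmatched,
                                   total = colSums(counts) + unmatched,
                                   row.names = colnames(counts)))
  metadata(se)$alpha <- alpha
  new("FractionCounts", se)
}

#' Pseudocount-normalized variant frequencies
#'
#' Per column: f_i = (c_i + alpha) / sum_j (c_j + alpha), a Jeffreys-style
#' regularization applied at normalization time so raw counts stay auditable.
#' Frequencies sum to 1 per column.
#'
#' @param counts a [FractionCounts-class] or a count matrix
#' @param alpha pseudocount, > 0 (default 0.5, or the value stored in the
#'   FractionCounts metadata)
#' @return numeric matrix of frequencies
#' @export
normalizeFrequencies <- function(counts, alpha = NULL) {
  if (is(counts, "FractionCounts")) {
    if (is.null(alpha)) alpha <- metadata(counts)$alpha
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(alpha)) alpha <- 0.5
  stopifnot(alpha > 0)
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0))
    stop("all-zero count column: cannot normalize")
  sweep(counts + alpha, 2L, colSums(counts + alpha), "/")
}

#' Locate a (fraction, replicate) column in a FractionCounts object
#' @param fc a [FractionCounts-class]
#' @param fraction fraction label
#' @param replicate replicate identifier (default: first matching column)
#' @return column index
#' @export
fractionColumn <- function(fc, fraction, replicate = NULL) {
  cd <- colData(fc)
  sel <- cd$fraction == fraction
  if (!is.null(replicate)) sel <- sel & cd$replicate == as.character(replicate)
  i <- which(sel)
  if (!length(i))
    stop("no column for fraction '", fraction, "'",
         if (!is.null(replicate)) paste0(" replicate '", replicate, "'"))
  i[1L]
}

#' Write / read a fraction count table TSV
#'
#' Layout: variant_id column followed by one column per (fraction, replicate)
#' named "fraction.replicate".  A JSON sidecar (file + ".meta.json") stores
#' the unmatched tallies and pseudocount.
#' @param fc a [FractionCounts-class]
#' @param file path
#' @export
writeFractionCountsTSV <- function(fc, file) {
  cts <- SummarizedExperiment::assay(fc, "counts")
  df <- data.frame(variant_id = rownames(cts), cts, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(unmatched = as.list(stats::setNames(
                 colData(fc)$unmatched, colnames(cts))),
               alpha = metadata(fc)$alpha)
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeFractionCountsTSV
#' @export
readFractionCountsTSV <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  cts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cts) <- df$variant_id
  parts <- strsplit(colnames(cts), ".", fixed = TRUE)
  fraction <- vapply(parts, `[`, "", 1L)
  replicate <- vapply(parts, function(p)
    if (length(p) > 1L) paste(p[-1L], collapse = ".") else "1", "")
  unmatched <- 0L; alpha <- 0.5
  metaFile <- paste0(file, ".meta.json")
  if (file.exists(metaFile)) {
    meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
    if (!is.null(meta$unmatched))
      unmatched <- as.integer(meta$unmatched[colnames(cts)])
    if (!is.null(meta$alpha)) alpha <- meta$alpha
  }
  FractionCounts(cts, fraction = fraction, replicate = replicate,
                 unmatched = unmatched, alpha = alpha)
}
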