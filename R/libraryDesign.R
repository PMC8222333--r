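#' @include AllClasses.R AllGenerics.R targetSite.R
NULL

# mismatch annotation of sequences vs. a consensus, as "label:alt" strings
.annotateMismatches <- function(seqs, consensus, labels) {
  cs <- strsplit(consensus, "")[[1]]
  sm <- strsplit(seqs, "")
  ann <- vapply(sm, function(b) {
    d <- which(b != cs)
    if (!length(d)) return("")
    paste(labels[d], b[d], sep = ":", collapse = ",")
  }, character(1))
  ann
}

.idsFromAnnotation <- function(ann) {
  ifelse(ann == "", "WT",
         vapply(strsplit(ann, ","), function(m) {
           paste0("m", sub(":", "", m), collapse = "+")
         }, character(1)))
}

#' Parse encoded mismatch annotations
#'
#' Turns the "pos:alt,pos:alt" encoding used in library manifests into a
#' list of data.frames with columns position and alt.
#' @param ann character vector of encoded annotations ("" = consensus)
#' @return list of data.frames (zero rows for the consensus)
#' @export
parseMismatches <- function(ann) {
  lapply(strsplit(ann, ","), function(m) {
    m <- m[nzchar(m)]
    if (!length(m))
      return(data.frame(position = character(), alt = character()))
    parts <- strsplit(m, ":", fixed = TRUE)
    data.frame(position = vapply(parts, `[`, "", 1L),
               alt = vapply(parts, `[`, "", 2L))
  })
}

#' Enumerate a sliding-window mismatch library over a bare consensus
#'
#' Core enumeration behind [buildMismatchLibrary()], usable on any consensus
#' region (e.g. short frames for exhaustive cross-checks).  Emits every
#' sequence whose mismatched positions fit inside at least one contiguous
#' window of \code{windowWidth} positions, deduplicated by sequence, in
#' deterministic order (first window offset, then lexicographic).
#'
#' @param consensus consensus sequence of the variable region
#' @param windowWidth randomized window width
#' @param labels optional position labels (default "1".."L")
#' @param offsets window start offsets to tile (default: all)
#' @return a [VariantLibrary-class] (with no TargetSite attached)
#' @export
enumerateMismatchLibrary <- function(consensus, windowWidth = 4L,
                                     labels = NULL, offsets = NULL) {
  consensus <- toupper(as.character(consensus))
  v <- .validDna(consensus)
  if (!isTRUE(v)) stop(v)
  L <- nchar(consensus)
  w <- as.integer(windowWidth)
  if (w < 1L || w > L)
    stop("windowWidth must be between 1 and the region length (", L, ")")
  if (is.null(labels)) labels <- as.character(seq_len(L))
  stopifnot(length(labels) == L)
  if (is.null(offsets)) offsets <- seq_len(L - w + 1L)
  fills <- Biostrings::mkAllStrings(.DNA_BASES, w)   # lexicographic
  pre <- substring(consensus, 1L, offsets - 1L)
  post <- substring(consensus, offsets + w, L)
  seqs <- unlist(lapply(seq_along(offsets), function(i)
    paste0(pre[i], fills, post[i])), use.names = FALSE)
  seqs <- seqs[!duplicated(seqs)]
  ann <- .annotateMismatches(seqs, consensus, labels)
  nmm <- lengths(regmatches(ann, gregexpr(":", ann, fixed = TRUE)))
  nmm[ann == ""] <- 0L
  vdf <- DataFrame(variant_id = .idsFromAnnotation(ann),
                   sequence = seqs, n_mismatch = nmm, mismatches = ann)
  new("VariantLibrary", target = NULL, consensus = consensus,
      labels = labels, variants = vdf, type = "mismatch")
}

#' Build the sliding-window mismatch library
#'
#' Enumerates every sequence whose mismatched positions relative to the
#' consensus variable region (PAM + protospacer) all fit inside at least one
#' contiguous window of \code{windowWidth} positions — the in-silico
#' counterpart of pooling oligos with a randomized 4-nt window tiled across
#' the target.  Duplicates arising from overlapping windows are removed by
#' exact sequence identity; the consensus is kept exactly once.  Emission
#' order is deterministic: by first window offset, then lexicographically by
#' sequence.
#'
#' @param target a [TargetSite-class]
#' @param windowWidth width of the randomized window (default 4 nt)
#' @param region "both" to tile PAM and protospacer (default) or
#'   "protospacer" to restrict windows to protospacer positions
#' @return a [VariantLibrary-class]
#' @examples
#' ts <- TargetSite(protospacer = "GACGCATAAAGATGAGACGCT", pam = "TTTA")
#' lib <- buildMismatchLibrary(ts, windowWidth = 4)
#' length(lib)  # 4288 variants for the 25-nt variable region
#' @export
buildMismatchLibrary <- function(target, windowWidth = 4L,
                                 region = c("both", "protospacer")) {
  stopifnot(is(target, "TargetSite"))
  region <- match.arg(region)
  validObject(target)
  vr <- variableRegion(target)
  labels <- positionLabels(target)
  L <- nchar(vr)
  w <- as.integer(windowWidth)
  if (w < 1L || w > L)
    stop("windowWidth must be between 1 and the variable-region length (",
         L, ")")
  pamLen <- nchar(pamSeq(target))
  first <- if (region == "both") 1L else pamLen + 1L
  offsets <- seq.int(first, L - w + 1L)
  if (!length(offsets)) stop("window does not fit in the selected region")
  lib <- enumerateMismatchLibrary(vr, w, labels = labels, offsets = offsets)
  lib@target <- target
  lib
}

#' Build the exhaustive PAM library
#'
#' All 4^4 = 256 PAM 4-mers with the protospacer held at consensus, in
#' lexicographic PAM order.
#'
#' @param target a [TargetSite-class]
#' @return a [VariantLibrary-class] with a pam column in its manifest
#' @export
buildPamLibrary <- function(target) {
  stopifnot(is(target, "TargetSite"))
  validObject(target)
  if (nchar(pamSeq(target)) != 4L) stop("PAM must be 4 nt")
  pams <- Biostrings::mkAllStrings(.DNA_BASES, 4L)
  seqs <- paste0(pams, protospacer(target))
  ann <- .annotateMismatches(seqs, variableRegion(target),
                             positionLabels(target))
  nmm <- lengths(regmatches(ann, gregexpr(":", ann, fixed = TRUE)))
  nmm[ann == ""] <- 0L
  vdf <- DataFrame(variant_id = .idsFromAnnotation(ann),
                   sequence = seqs, n_mismatch = nmm, mismatches = ann,
                   pam = pams)
  new("VariantLibrary", target = target,
      consensus = variableRegion(target),
      labels = positionLabels(target), variants = vdf, type = "pam")
}

#' @describeIn buildMismatchLibrary variant manifest (DataFrame)
#' @param x a VariantLibrary
#' @export
setMethod("variants", "VariantLibrary", function(x) x@variants)

#' @describeIn buildMismatchLibrary variant identifiers
#' @export
setMethod("variantIds", "VariantLibrary", function(x) x@variants$variant_id)

#' @describeIn buildMismatchLibrary variant sequences (named by variant_id)
#' @export
setMethod("variantSequences", "VariantLibrary", function(x) {
  s <- x@variants$sequence
  names(s) <- x@variants$variant_id
  s
})

#' @describeIn buildMismatchLibrary library type ("mismatch" or "pam")
#' @export
setMethod("libraryType", "VariantLibrary", function(x) x@type)

#' @describeIn buildMismatchLibrary the TargetSite the library was built from
#'   (NULL for bare-consensus libraries)
#' @export
setMethod("targetSite", "VariantLibrary", function(x) x@target)

#' @describeIn buildMismatchLibrary consensus variable-region sequence
#' @export
setMethod("variableRegion", "VariantLibrary", function(x) x@consensus)

#' @describeIn buildMismatchLibrary variable-region position labels
#' @export
setMethod("positionLabels", "VariantLibrary", function(x) x@labels)

#' @export
setMethod("length", "VariantLibrary", function(x) nrow(x@variants))

setMethod("show", "VariantLibrary", function(object) {
  cat("VariantLibrary (", object@type, ") with ", nrow(object@variants),
      " variants\n", sep = "")
  cat("  variable region:", object@consensus, "\n")
  tab <- table(object@variants$n_mismatch)
  cat("  mismatch counts:",
      paste0(names(tab), "x:", as.integer(tab), collapse = "  "), "\n")
})

#' Write a variant library as FASTA
#'
#' One record per variant; record IDs are variant IDs.
#' @param library a [VariantLibrary-class]
#' @param file output path
#' @export
writeLibraryFasta <- function(library, file) {
  seqs <- Biostrings::DNAStringSet(variantSequences(library))
  Biostrings::writeXStringSet(seqs, filepath = file)
  invisible(file)
}

#' Write / read a library manifest TSV
#'
#' Columns: variant_id, sequence, n_mismatch, mismatches (encoded
#' "pos:alt,..."), plus pam for PAM libraries.
#' @param library a [VariantLibrary-class]
#' @param file path
#' @export
writeLibraryManifest <- function(library, file) {
  utils::write.table(as.data.frame(variants(library)), file = file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLibraryManifest
#' @export
readLibraryManifest <- function(file) {
  df <- utils::read.delim(file, colClasses = "character")
  df$n_mismatch <- as.integer(df$n_mismatch)
  df$mismatches[is.na(df$mismatches)] <- ""
  DataFrame(df)
}
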