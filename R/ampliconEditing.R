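#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an AmpliconTarget
#'
#' Locates the protospacer (with its PAM) inside the reference amplicon on
#' either strand and derives the cut coordinate and indel-scoring window.
#' All coordinates are 0-based, half-open on the displayed amplicon strand.
#'
#' Window geometry, following the standard cut-site rules: Cas9 cuts 3 nt 5'
#' of its (3') PAM and indels are scored over an 8-nt window centred on the
#' cut (cut +/- 4); Cas12a nominally cuts PAM-distal after protospacer
#' position 18 and indels are scored over a 9-nt window starting 3 nt
#' PAM-proximal of the cut and extending 9 nt PAM-distal-ward.  Both can be
#' overridden via \code{cutOffset} / \code{window} because reported cut
#' positions vary between systems.
#'
#' @param amplicon reference amplicon sequence
#' @param protospacer protospacer sequence as it reads 5'->3' next to its
#'   PAM (PAM 5' of protospacer for Cas12a, 3' for Cas9)
#' @param pam PAM sequence
#' @param enzyme "Cas12a" (default) or "Cas9"
#' @param hdrAllele optional expected post-edit sequence over hdrInterval
#' @param hdrInterval 0-based half-open interval on the reference amplicon
#'   that hdrAllele replaces
#' @param cutOffset override of the cut position, in protospacer coordinates
#'   (Cas12a: cut after this protospacer position, default 18; Cas9: cut
#'   this many nt 5' of the PAM, default 3)
#' @param window optional explicit window override, c(start, end) on the
#'   amplicon
#' @return an [AmpliconTarget-class]
#' @export
AmpliconTarget <- function(amplicon, protospacer, pam,
                           enzyme = c("Cas12a", "Cas9"),
                           hdrAllele = NULL, hdrInterval = NULL,
                           cutOffset = NULL, window = NULL) {
  enzyme <- match.arg(enzyme)
  amplicon <- toupper(as.character(amplicon))
  protospacer <- toupper(as.character(protospacer))
  pam <- toupper(as.character(pam))
  site <- if (enzyme == "Cas12a") paste0(pam, protospacer)
          else paste0(protospacer, pam)
  hit <- regexpr(site, amplicon, fixed = TRUE)
  strand <- "+"
  if (hit < 0L) {
    rcsite <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(site)))
    hit <- regexpr(rcsite, amplicon, fixed = TRUE)
    strand <- "-"
    if (hit < 0L) stop("protospacer+PAM not found in amplicon on either strand")
  }
  s0 <- as.integer(hit) - 1L                      # 0-based site start
  pLen <- nchar(protospacer)
  if (enzyme == "Cas12a") {
    off <- if (is.null(cutOffset)) 18L else as.integer(cutOffset)
    if (strand == "+") {
      protoStart <- s0 + 4L; protoEnd <- protoStart + pLen
      cut <- protoStart + off
      win <- c(cut - 3L, cut + 6L)                # PAM-proximal 3, distal 6
    } else {
      protoStart <- s0; protoEnd <- s0 + pLen     # PAM right of protospacer
      cut <- protoEnd - off
      win <- c(cut - 6L, cut + 3L)
    }
  } else {
    off <- if (is.null(cutOffset)) 3L else as.integer(cutOffset)
    if (strand == "+") {
      protoStart <- s0; protoEnd <- s0 + pLen     # PAM right of protospacer
      cut <- protoEnd - off
    } else {
      protoStart <- s0 + nchar(pam); protoEnd <- protoStart + pLen
      cut <- protoStart + off
    }
    win <- c(cut - 4L, cut + 4L)                  # symmetric 8-nt window
  }
  if (!is.null(window)) win <- as.integer(window)
  if (is.null(hdrAllele)) {
    hdrAllele <- NA_character_; hdrInterval <- c(NA_integer_, NA_integer_)
  } else {
    stopifnot(!is.null(hdrInterval), length(hdrInterval) == 2L)
    hdrAllele <- toupper(as.character(hdrAllele))
    hdrInterval <- as.integer(hdrInterval)
  }
  new("AmpliconTarget", amplicon = amplicon, enzyme = enzyme,
      protoStart = as.integer(protoStart), protoEnd = as.integer(protoEnd),
      strand = strand, cutSite = as.integer(cut),
      windowStart = as.integer(win[1L]), windowEnd = as.integer(win[2L]),
      hdrStart = hdrInterval[1L], hdrEnd = hdrInterval[2L],
      hdrAllele = hdrAllele)
}

#' @describeIn AmpliconTarget reference amplicon sequence
#' @param x an AmpliconTarget
#' @export
setMethod("ampliconSeq", "AmpliconTarget", function(x) x@amplicon)
#' @describeIn AmpliconTarget 0-based cut coordinate
#' @export
setMethod("cutSite", "AmpliconTarget", function(x) x@cutSite)
#' @describeIn AmpliconTarget indel-scoring window, c(start, end)
#' @export
setMethod("editingWindow", "AmpliconTarget", function(x)
  c(x@windowStart, x@windowEnd))
#' @describeIn AmpliconTarget expected donor allele (NA when unset)
#' @export
setMethod("hdrAllele", "AmpliconTarget", function(x) x@hdrAllele)
#' @describeIn AmpliconTarget donor interval, c(start, end)
#' @export
setMethod("hdrInterval", "AmpliconTarget", function(x)
  c(x@hdrStart, x@hdrEnd))

setMethod("show", "AmpliconTarget", function(object) {
  cat("AmpliconTarget (", object@enzyme, ", strand ", object@strand,
      ") on a ", nchar(object@amplicon), "-nt amplicon\n", sep = "")
  cat("  protospacer [", object@protoStart, ",", object@protoEnd,
      "), cut at ", object@cutSite, ", window [", object@windowStart, ",",
      object@windowEnd, ")\n", sep = "")
  if (!is.na(object@hdrAllele))
    cat("  HDR donor over [", object@hdrStart, ",", object@hdrEnd, ")\n",
        sep = "")
})

# slide an indel among score-equivalent placements (repeat context) to the
# one whose midpoint is nearest the cut; ties resolve to the leftmost
.slideIndel <- function(op, refc, cut) {
  if (op$type == "D") {
    k <- op$end - op$start
    cand <- op$start
    s <- op$start
    while (s > 0L && refc[s] == refc[s + k]) { s <- s - 1L; cand <- c(cand, s) }
    s <- op$start
    while (s + k + 1L <= length(refc) && refc[s + 1L] == refc[s + k + 1L]) {
      s <- s + 1L; cand <- c(cand, s)
    }
    mids <- cand + k / 2
    best <- cand[order(abs(mids - cut), cand)][1L]
    op$start <- best; op$end <- best + k
  } else {
    v <- strsplit(op$ins, "")[[1]]
    k <- length(v)
    cand <- list(list(b = op$start, v = v))
    b <- op$start; vv <- v
    while (b > 0L && vv[k] == refc[b]) {
      vv <- c(vv[k], vv[-k]); b <- b - 1L
      cand[[length(cand) + 1L]] <- list(b = b, v = vv)
    }
    b <- op$start; vv <- v
    while (b < length(refc) && vv[1L] == refc[b + 1L]) {
      vv <- c(vv[-1L], vv[1L]); b <- b + 1L
      cand[[length(cand) + 1L]] <- list(b = b, v = vv)
    }
    bs <- vapply(cand, `[[`, 0L, "b")
    best <- order(abs(bs - cut), bs)[1L]
    op$start <- cand[[best]]$b; op$end <- cand[[best]]$b
    op$ins <- paste(cand[[best]]$v, collapse = "")
  }
  op
}

# parse one gapped alignment into indel ops (0-based ref coordinates)
.alignmentOps <- function(pat, sub, refc, cut) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  refpos <- cumsum(s != "-")       # ref chars consumed up to each column
  ops <- list()
  r <- rle(ifelse(s == "-", "I", ifelse(p == "-", "D", "M")))
  endCol <- cumsum(r$lengths)
  startCol <- endCol - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "M") next
    if (r$values[i] == "D") {
      op <- list(type = "D", start = refpos[startCol[i]] - 1L,
                 end = refpos[endCol[i]], ins = "")
    } else {
      b <- if (startCol[i] == 1L) 0L else refpos[startCol[i] - 1L]
      op <- list(type = "I", start = b, end = b,
                 ins = paste(p[startCol[i]:endCol[i]], collapse = ""))
    }
    ops[[length(ops) + 1L]] <- .slideIndel(op, refc, cut)
  }
  ops
}

#' Globally align merged amplicon reads to the reference
#'
#' Needleman-Wunsch alignment with affine gaps (match +2, mismatch -2, gap
#' open -10, gap extend -1) of each read against the reference amplicon,
#' with strand rescue: the reverse complement is also aligned and the better
#' orientation kept.  Among score-equivalent indel placements (repeats), the
#' indel is slid to the placement whose midpoint is nearest the cut site —
#' the re-alignment convention that favours calling indels at the predicted
#' cut.  Reads scoring below \code{minScoreFrac} times the perfect score are
#' discarded as "no alignment".
#'
#' @param reads DNAStringSet or character vector of merged reads
#' @param target an [AmpliconTarget-class]
#' @param minScoreFrac score floor as a fraction of the perfect-match score
#'   (default 0.4)
#' @param minReadLength reads shorter than this are discarded (default 30)
#' @return list of per-read alignment records: score, strand, discarded,
#'   ops (indel operations with 0-based ref coordinates), pat/sub (gapped
#'   alignment strings), hasGaps
#' @export
alignReadToAmplicon <- function(reads, target, minScoreFrac = 0.4,
                                minReadLength = 30L) {
  stopifnot(is(target, "AmpliconTarget"))
  if (!is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(as.character(reads))
  ref <- ampliconSeq(target)
  refc <- strsplit(ref, "")[[1]]
  cut <- cutSite(target)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = FALSE)
  alnF <- Biostrings::pairwiseAlignment(reads, ref, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 10, gapExtension = 1)
  alnR <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(reads), ref, type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
  useR <- Biostrings::score(alnR) > Biostrings::score(alnF)
  scores <- ifelse(useR, Biostrings::score(alnR), Biostrings::score(alnF))
  patF <- as.character(Biostrings::pattern(alnF))
  subF <- as.character(Biostrings::subject(alnF))
  patR <- as.character(Biostrings::pattern(alnR))
  subR <- as.character(Biostrings::subject(alnR))
  pat <- ifelse(useR, patR, patF)
  sub <- ifelse(useR, subR, subF)
  widths <- Biostrings::width(reads)
  floorScore <- minScoreFrac * 2 * pmin(widths, nchar(ref))
  tooShort <- widths < minReadLength
  hasGaps <- grepl("-", pat, fixed = TRUE) | grepl("-", sub, fixed = TRUE)
  lapply(seq_along(reads), function(i) {
    if (tooShort[i] || scores[i] < floorScore[i])
      return(list(score = scores[i], strand = "*", discarded = TRUE,
                  ops = list(), pat = NA_character_, sub = NA_character_,
                  hasGaps = FALSE))
    ops <- if (hasGaps[i]) .alignmentOps(pat[i], sub[i], refc, cut)
           else list()
    list(score = scores[i], strand = if (useR[i]) "-" else "+",
         discarded = FALSE, ops = ops, pat = pat[i], sub = sub[i],
         hasGaps = hasGaps[i])
  })
}

# read-implied sequence over a reference interval [s, e): aligned read chars
# at interval columns plus insertions strictly inside the interval
.impliedSequence <- function(aln, s, e) {
  if (!aln$hasGaps) {
    # columns map 1:1 to reference positions
    return(substr(aln$pat, s + 1L, e))
  }
  p <- strsplit(aln$pat, "")[[1]]
  su <- strsplit(aln$sub, "")[[1]]
  refpos <- cumsum(su != "-")
  keep <- (su != "-" & refpos > s & refpos <= e) |
          (su == "-" & refpos > s & refpos < e)
  paste(p[keep][p[keep] != "-"], collapse = "")
}

#' Classify one aligned read as unedited / NHEJ / HDR
#'
#' When a donor is configured, the HDR check comes first and is strict: the
#' read's implied sequence over the full donor interval must equal the
#' expected allele exactly (donor-matching reads with extra indels elsewhere
#' in the window fall through to NHEJ).  Otherwise the read is NHEJ when any
#' indel operation overlaps the editing window, and unedited when not —
#' substitution-only reads are unedited, since editing is scored on indels.
#'
#' @param alignment one record from [alignReadToAmplicon()]
#' @param target an [AmpliconTarget-class]
#' @return "unedited", "NHEJ", "HDR", or "no alignment"
#' @export
classifyRead <- function(alignment, target) {
  if (alignment$discarded) return("no alignment")
  w <- editingWindow(target)
  if (!is.na(hdrAllele(target))) {
    hi <- hdrInterval(target)
    if (.impliedSequence(alignment, hi[1L], hi[2L]) == hdrAllele(target))
      return("HDR")
  }
  for (op in alignment$ops) {
    hit <- if (op$type == "D")
      op$start < w[2L] && op$end > w[1L]
    else
      op$start >= w[1L] && op$start <= w[2L]
    if (hit) return("NHEJ")
  }
  "unedited"
}

#' Align and classify a full read set
#'
#' @param reads DNAStringSet or character vector of merged reads
#' @param target an [AmpliconTarget-class]
#' @param ... passed to [alignReadToAmplicon()]
#' @return list: labels (per-read character vector) and summary
#'   (an [EditingSummary-class])
#' @export
callEditing <- function(reads, target, ...) {
  alns <- alignReadToAmplicon(reads, target, ...)
  labels <- vapply(alns, classifyRead, "", target = target)
  list(labels = labels, summary = summarizeEditing(labels))
}

#' Summarize per-read editing labels
#'
#' @param labels character vector of per-read labels; values other than
#'   unedited/NHEJ/HDR are counted as discarded with their label as reason
#' @return an [EditingSummary-class]
#' @export
summarizeEditing <- function(labels) {
  keep <- labels %in% c("unedited", "NHEJ", "HDR")
  if (!any(keep)) stop("no classified reads")
  counts <- vapply(c("unedited", "NHEJ", "HDR"),
                   function(l) sum(labels == l), 0)
  disc <- table(labels[!keep])
  new("EditingSummary", counts = counts,
      discarded = stats::setNames(as.numeric(disc), names(disc)))
}

#' @describeIn summarizeEditing classified read tallies
#' @param x an EditingSummary
#' @export
setMethod("editingCounts", "EditingSummary", function(x) x@counts)
#' @describeIn summarizeEditing total editing percentage (NHEJ + HDR)
#' @export
setMethod("editingPercent", "EditingSummary", function(x)
  100 * (x@counts[["NHEJ"]] + x@counts[["HDR"]]) / sum(x@counts))
#' @describeIn summarizeEditing HDR percentage
#' @export
setMethod("hdrPercent", "EditingSummary", function(x)
  100 * x@counts[["HDR"]] / sum(x@counts))
#' @describeIn summarizeEditing discarded-read tallies by reason
#' @export
setMethod("discardedReads", "EditingSummary", function(x) x@discarded)

setMethod("show", "EditingSummary", function(object) {
  tot <- sum(object@counts)
  cat("EditingSummary over", tot, "classified reads\n")
  cat(sprintf("  unedited %d | NHEJ %d | HDR %d\n",
              object@counts[["unedited"]], object@counts[["NHEJ"]],
              object@counts[["HDR"]]))
  cat(sprintf("  total editing %.1f%%, HDR %.1f%%\n",
              editingPercent(object), hdrPercent(object)))
  if (length(object@discarded))
    cat("  discarded:", paste(names(object@discarded), object@discarded,
                              sep = "=", collapse = ", "), "\n")
})

#' Write per-read classifications and the editing summary
#' @param labels per-read labels from [callEditing()]
#' @param summary an [EditingSummary-class]
#' @param file base path; writes <file>.tsv and <file>.json
#' @export
writeEditingResults <- function(labels, summary, file) {
  utils::write.table(
    data.frame(read = seq_along(labels), label = labels),
    paste0(file, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(editingCounts(summary)),
         totalEditingPercent = editingPercent(summary),
         hdrPercent = hdrPercent(summary),
         discarded = as.list(discardedReads(summary))),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
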