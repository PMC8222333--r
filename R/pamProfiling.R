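#' @include AllClasses.R AllGenerics.R specificity.R
NULL

#' PAM preference profile from relative measures
#'
#' Converts per-variant relative measures over the exhaustive PAM library
#' into a ranked activity profile.  Scores are oriented so that larger =
#' more active: lnKA measures are used as-is (affinity-positive), delta_d
#' measures are negated (penalty-signed).  The consensus PAM is anchored at
#' 0 by the estimators.  Ranks run 1 (most preferred) to 256, ties broken
#' lexicographically by PAM string so output is deterministic.  Replicates
#' are pooled by inverse-variance averaging.
#'
#' @param measures DataFrame from [computeLnKA()] or [computeDeltaD()]
#'   restricted to a PAM library's variants
#' @param library the PAM [VariantLibrary-class]
#' @param enzyme free-text enzyme label carried in the profile
#' @return a [PamProfile-class]
#' @export
pamRelativeActivity <- function(measures, library, enzyme = "") {
  stopifnot(is(library, "VariantLibrary"))
  if (libraryType(library) != "pam")
    stop("library must be a PAM library")
  man <- variants(library)
  if (anyDuplicated(man$pam)) stop("duplicate PAM rows in library")
  kind <- unique(measures$kind)
  if (length(kind) != 1L)
    stop("measures must all be of one kind")
  if (length(unique(measures$replicate)) > 1L)
    measures <- .preAverageMeasures(measures)
  idx <- match(man$variant_id, measures$variant_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " PAM variant(s) missing from measures; ",
            "flagged with NA scores and ranked last")
  value <- measures$value[idx]
  score <- if (kind == "lnKA") value else -value
  ord <- order(-score, man$pam, na.last = TRUE)
  rank <- integer(256L)
  rank[ord] <- seq_len(256L)
  prof <- DataFrame(pam = man$pam, score = score, rank = rank,
                    se = measures$se[idx])
  new("PamProfile", profile = prof, enzyme = enzyme,
      kind = if (kind == "lnKA") "binding" else "cleavage")
}

#' @describeIn pamRelativeActivity the 256-row profile DataFrame
#' @param x a PamProfile
#' @export
setMethod("pamTable", "PamProfile", function(x) x@profile)

#' @describeIn pamRelativeActivity enzyme label
#' @export
setMethod("enzymeLabel", "PamProfile", function(x) x@enzyme)

setMethod("show", "PamProfile", function(object) {
  cat("PamProfile (", object@kind, ") for ",
      if (nzchar(object@enzyme)) object@enzyme else "<unnamed enzyme>",
      "\n", sep = "")
  top <- topPams(object, 5L)
  cat("  top PAMs:", paste(top$pam, collapse = ", "), "\n")
})

#' Top-k preferred PAM sequences
#'
#' @param profile a [PamProfile-class]
#' @param k number of PAMs to return (default 10, the usual reporting depth)
#' @return the first k profile rows ordered by rank
#' @export
topPams <- function(profile, k = 10L) {
  stopifnot(is(profile, "PamProfile"), k >= 0L, k <= 256L)
  tab <- pamTable(profile)
  tab[order(tab$rank), , drop = FALSE][seq_len(k), , drop = FALSE]
}

#' Rank correlation with an external PAM activity table
#'
#' Spearman correlation between profile scores and an externally measured
#' activity table over the shared PAMs (ties handled by average ranks, the
#' default of the Spearman estimator).
#'
#' @param profile a [PamProfile-class]
#' @param external data.frame with columns pam and activity
#' @return list: rho, nShared
#' @export
correlateWithExternal <- function(profile, external) {
  stopifnot(all(c("pam", "activity") %in% colnames(external)))
  tab <- pamTable(profile)
  shared <- intersect(tab$pam, external$pam)
  if (!length(shared)) stop("no PAMs shared with the external table")
  if (length(shared) < 3L)
    stop("need at least 3 shared PAMs, got ", length(shared))
  x <- tab$score[match(shared, tab$pam)]
  y <- external$activity[match(shared, external$pam)]
  list(rho = stats::cor(x, y, method = "spearman"),
       nShared = length(shared))
}

#' Average profile scores over a degenerate PAM class
#'
#' Expands IUPAC degenerate bases (e.g. V = A/C/G) and averages the member
#' scores, matching how degenerate motifs like TTTV are summarized.
#' @param profile a [PamProfile-class]
#' @param pattern 4-character IUPAC string
#' @return mean score over member PAMs
#' @export
pamClassScore <- function(profile, pattern) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  stopifnot(length(chars) == 4L, all(chars %in% names(iupac)))
  members <- expand.grid(lapply(chars, function(ch)
    strsplit(iupac[[ch]], "")[[1]]), stringsAsFactors = FALSE)
  members <- do.call(paste0, members)
  tab <- pamTable(profile)
  mean(tab$score[match(members, tab$pam)], na.rm = TRUE)
}

#' Write a PAM profile / read an external activity table
#' @param profile a [PamProfile-class]
#' @param file path
#' @export
writePamProfileTSV <- function(profile, file) {
  utils::write.table(as.data.frame(pamTable(profile)), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePamProfileTSV
#' @export
readExternalActivities <- function(file) {
  df <- utils::read.delim(file)
  stopifnot(ncol(df) >= 2L)
  colnames(df)[1:2] <- c("pam", "activity")
  df
}
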