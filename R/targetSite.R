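#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TargetSite
#'
#' @param protospacer consensus protospacer, 5'->3' on the displayed strand,
#'   position 1 at the PAM-proximal end (default design length 21 nt)
#' @param pam consensus 4-nt PAM, written 5'->3' (P1..P4); the PAM sits 5'
#'   of the protospacer in the construct
#' @param flank5,flank3 fixed flanking sequences of the sequencing construct
#' @return a [TargetSite-class]
#' @examples
#' ts <- TargetSite(
#'   protospacer = "GACGCATAAAGATGAGACGCT",
#'   pam = "TTTA")
#' variableRegion(ts)
#' @export
TargetSite <- function(protospacer, pam = "TTTA",
                       flank5 = "ACACGACGCTCTTCCGATCT",
                       flank3 = "AGATCGGAAGAGCACACGTC") {
  up <- function(x) toupper(as.character(x))
  new("TargetSite", protospacer = up(protospacer), pam = up(pam),
      flank5 = up(flank5), flank3 = up(flank3))
}

#' @describeIn TargetSite consensus protospacer
#' @param x a TargetSite
#' @export
setMethod("protospacer", "TargetSite", function(x) x@protospacer)

#' @describeIn TargetSite consensus PAM
#' @export
setMethod("pamSeq", "TargetSite", function(x) x@pam)

#' @describeIn TargetSite 5' constant flank
#' @export
setMethod("flank5", "TargetSite", function(x) x@flank5)

#' @describeIn TargetSite 3' constant flank
#' @export
setMethod("flank3", "TargetSite", function(x) x@flank3)

#' @describeIn TargetSite the variable region of the construct:
#'   PAM then protospacer, in construct order
#' @export
setMethod("variableRegion", "TargetSite", function(x)
  paste0(x@pam, x@protospacer))

#' @describeIn TargetSite position labels of the variable region:
#'   P1..P4 for the PAM, then 1..L for the protospacer
#' @export
setMethod("positionLabels", "TargetSite", function(x)
  c(paste0("P", seq_len(nchar(x@pam))),
    as.character(seq_len(nchar(x@protospacer)))))

setMethod("show", "TargetSite", function(object) {
  cat("TargetSite\n")
  cat("  PAM (P1..P4):      ", object@pam, "\n")
  cat("  protospacer (1..", nchar(object@protospacer), "): ",
      object@protospacer, "\n", sep = "")
  cat("  flanks: 5'-", object@flank5, " ... ", object@flank3, "-3'\n",
      sep = "")
})
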