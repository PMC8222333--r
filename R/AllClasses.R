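#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.DNA_BASES <- c("A", "C", "G", "T")

.validDna <- function(x) {
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    return(sprintf("non-ACGT character at position %d of %s",
                   bad[i], substr(x[i], 1, 20)))
  }
  TRUE
}

#' TargetSite: a Cas12a target in its sequencing construct
#'
#' Holds the consensus protospacer and PAM together with the fixed flanking
#' sequences that bound the variable region in the sequencing construct.  The
#' construct is 5'-flank5-PAM-protospacer-flank3-3' on the displayed strand;
#' the PAM lies 5' of the protospacer as in Cas12a biology.  Protospacer
#' positions are numbered 1..L starting at the PAM-proximal base; PAM
#' positions are labelled P1..P4 in 5'->3' order.
#'
#' @slot protospacer consensus protospacer (>= 8 nt, default design 21 nt)
#' @slot pam consensus PAM, exactly 4 nt
#' @slot flank5,flank3 fixed constant flanks of the construct
#' @export
setClass("TargetSite",
  representation(protospacer = "character", pam = "character",
                 flank5 = "character", flank3 = "character"))

setValidity("TargetSite", function(object) {
  msgs <- character()
  for (f in c("protospacer", "pam", "flank5", "flank3")) {
    v <- .validDna(slot(object, f))
    if (!isTRUE(v)) msgs <- c(msgs, paste0(f, ": ", v))
  }
  if (nchar(object@protospacer) < 8L)
    msgs <- c(msgs, "protospacer must be at least 8 nt")
  if (nchar(object@pam) != 4L)
    msgs <- c(msgs, "pam must be exactly 4 nt")
  if (length(msgs)) msgs else TRUE
})

#' VariantLibrary: a designed set of sequence variants
#'
#' One row per variant of the variable region (PAM + protospacer in construct
#' order).  The zero-mismatch consensus appears exactly once, with
#' variant_id "WT".  Mismatch variant IDs are "m<pos><alt>" terms joined by
#' "+" (e.g. "mP2A+m5C"), giving stable join keys across modules.
#'
#' @slot target the [TargetSite-class] the library was designed against, or
#'   NULL for libraries enumerated over a bare consensus region
#' @slot consensus the consensus variable-region sequence
#' @slot labels position labels of the variable region
#' @slot variants DataFrame with columns variant_id, sequence, n_mismatch,
#'   mismatches (encoded "pos:alt,pos:alt"), and for PAM libraries a pam column
#' @slot type "mismatch" or "pam"
#' @export
setClass("VariantLibrary",
  representation(target = "ANY", consensus = "character",
                 labels = "character", variants = "DataFrame",
                 type = "character"))

setValidity("VariantLibrary", function(object) {
  v <- object@variants
  if (length(object@labels) != nchar(object@consensus))
    return("labels must have one entry per consensus position")
  need <- c("variant_id", "sequence", "n_mismatch", "mismatches")
  if (!all(need %in% colnames(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(v$variant_id)) return("variant_id values must be unique")
  if (anyDuplicated(v$sequence)) return("variant sequences must be unique")
  if (sum(v$variant_id == "WT") != 1L)
    return("the consensus variant WT must appear exactly once")
  if (!object@type %in% c("mismatch", "pam"))
    return("type must be 'mismatch' or 'pam'")
  TRUE
})

#' FractionCounts: variant x (fraction, replicate) read counts
#'
#' Extends SummarizedExperiment: one assay "counts" of non-negative integer
#' read counts, rows keyed by variant_id, columns annotated with fraction
#' (input / bound / unbound / uncut) and replicate.  Per-column unmatched-read
#' tallies live in colData; the pseudocount used downstream is in metadata.
#'
#' @export
setClass("FractionCounts", contains = "SummarizedExperiment")

setValidity("FractionCounts", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("counts must be non-negative")
  cd <- colData(object)
  if (!all(c("fraction", "replicate", "unmatched") %in% colnames(cd)))
    return("colData must have fraction, replicate, unmatched")
  ok <- cd$fraction %in% c("input", "bound", "unbound", "uncut")
  if (!all(ok)) return("fraction must be one of input/bound/unbound/uncut")
  TRUE
})

#' EnergyMatrix: per-position, per-base mismatch penalties
#'
#' Additive penalty model in natural-log units with the consensus base
#' anchored at zero per position (epsilon(p, ref) = 0).  Positive penalties
#' mean a mismatch is disfavoured.  Cleavage matrices carry the shared
#' saturation scale C = k_ref * t (one value per replicate).
#'
#' @slot positions ordered position labels (P1..P4 then 1..21 by default)
#' @slot refBases named consensus base per position
#' @slot eps 4 x P penalty matrix, rows A/C/G/T
#' @slot se standard errors, same shape
#' @slot flags per-entry status: "ok", "ref", "unidentifiable", "saturated"
#' @slot kind "binding" or "cleavage"
#' @slot C saturation scale(s); NA for binding matrices
#' @slot diagnostics list: residual SD, n observations, convergence info
#' @export
setClass("EnergyMatrix",
  representation(positions = "character", refBases = "character",
                 eps = "matrix", se = "matrix", flags = "matrix",
                 kind = "character", exposureC = "numeric", diagnostics = "list"))

setValidity("EnergyMatrix", function(object) {
  P <- length(object@positions)
  for (m in c("eps", "se", "flags")) {
    mm <- slot(object, m)
    if (!identical(dim(mm), c(4L, P)))
      return(sprintf("%s must be 4 x %d", m, P))
  }
  if (!object@kind %in% c("binding", "cleavage"))
    return("kind must be 'binding' or 'cleavage'")
  ref <- object@eps[cbind(match(object@refBases, .DNA_BASES), seq_len(P))]
  if (any(ref != 0, na.rm = TRUE))
    return("reference-base penalties must be exactly 0")
  if (object@kind == "cleavage" && any(!is.na(object@exposureC) & object@exposureC <= 0))
    return("cleavage saturation scale C must be > 0")
  TRUE
})

#' PamProfile: ranked PAM preference profile
#'
#' All 256 4-mer PAMs with a reference-anchored relative activity score
#' (larger = more active; consensus PAM scores 0) and a rank permutation
#' (1 = most preferred; ties broken lexicographically).
#'
#' @slot profile DataFrame with columns pam, score, rank
#' @slot enzyme free-text enzyme label
#' @slot kind measure the scores derive from ("binding" or "cleavage")
#' @export
setClass("PamProfile",
  representation(profile = "DataFrame", enzyme = "character",
                 kind = "character"))

setValidity("PamProfile", function(object) {
  p <- object@profile
  if (!all(c("pam", "score", "rank") %in% colnames(p)))
    return("profile needs columns pam, score, rank")
  if (nrow(p) != 256L || anyDuplicated(p$pam))
    return("profile must contain 256 unique PAM strings")
  if (!identical(sort(p$rank), 1:256))
    return("ranks must be a permutation of 1..256")
  TRUE
})

#' MutationFrequencyTable: per-position substitution tallies for one round
#'
#' @slot round selection round index (0 = input library)
#' @slot reference reference sequence of the mutagenized region
#' @slot counts 4 x L matrix of base counts (rows A/C/G/T)
#' @slot depth per-position sequencing depth (reads covering the position)
#' @slot codonOffset codon number of the first full codon (for residue labels)
#' @export
setClass("MutationFrequencyTable",
  representation(round = "integer", reference = "character",
                 counts = "matrix", depth = "numeric",
                 codonOffset = "integer"))

setValidity("MutationFrequencyTable", function(object) {
  L <- nchar(object@reference)
  if (!identical(dim(object@counts), c(4L, L)))
    return(sprintf("counts must be 4 x %d", L))
  if (length(object@depth) != L) return("depth must have one entry per position")
  if (any(colSums(object@counts) > object@depth + 1e-9))
    return("per-position base counts cannot exceed depth")
  TRUE
})

#' AmpliconTarget: an editing target within a sequencing amplicon
#'
#' Coordinates are 0-based, half-open on the amplicon.  The cut site and the
#' indel-scoring window are derived from enzyme class and protospacer
#' placement: Cas9 cuts between protospacer positions 17/18 (3 nt 5' of the
#' PAM) and is scored over an 8-nt window centred on the cut; Cas12a nominally
#' cuts PAM-distal after protospacer position 18 and is scored over a 9-nt
#' window starting 3 nt PAM-proximal of that cut.
#'
#' @slot amplicon reference amplicon sequence
#' @slot enzyme "Cas9" or "Cas12a"
#' @slot protoStart,protoEnd protospacer interval on the amplicon
#' @slot strand "+" if the protospacer is on the displayed amplicon strand
#' @slot cutSite cut coordinate (between bases cutSite-1 and cutSite)
#' @slot windowStart,windowEnd indel-scoring window
#' @slot hdrStart,hdrEnd,hdrAllele optional donor interval and expected
#'   post-edit sequence over it (NA when no donor is configured)
#' @export
setClass("AmpliconTarget",
  representation(amplicon = "character", enzyme = "character",
                 protoStart = "integer", protoEnd = "integer",
                 strand = "character", cutSite = "integer",
                 windowStart = "integer", windowEnd = "integer",
                 hdrStart = "integer", hdrEnd = "integer",
                 hdrAllele = "character"))

setValidity("AmpliconTarget", function(object) {
  if (!object@enzyme %in% c("Cas9", "Cas12a"))
    return("enzyme must be 'Cas9' or 'Cas12a'")
  L <- nchar(object@amplicon)
  w <- object@windowEnd - object@windowStart
  expw <- if (object@enzyme == "Cas9") 8L else 9L
  if (w != expw)
    return(sprintf("window length must be %d for %s", expw, object@enzyme))
  if (object@windowStart < 0L || object@windowEnd > L)
    return("editing window must lie within the amplicon")
  if (!is.na(object@hdrAllele)) {
    if (object@hdrEnd <= object@windowStart || object@hdrStart >= object@windowEnd)
      return("HDR interval must overlap the editing window")
  }
  TRUE
})

#' EditingSummary: classified amplicon read tallies
#'
#' @slot counts named tallies: unedited, NHEJ, HDR
#' @slot discarded named tallies of discarded reads by reason
#' @export
setClass("EditingSummary",
  representation(counts = "numeric", discarded = "numeric"))

setValidity("EditingSummary", function(object) {
  if (!identical(names(object@counts), c("unedited", "NHEJ", "HDR")))
    return("counts must be named unedited, NHEJ, HDR (in order)")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' DoseResponseFit: four-parameter logistic concentration-response fit
#' @slot estimate named: EC50, hill, top, bottom
#' @slot se matching standard errors
#' @slot residualSD residual standard deviation
#' @slot flags character vector of fit warnings (e.g. "no transition")
#' @export
setClass("DoseResponseFit",
  representation(estimate = "numeric", se = "numeric",
                 residualSD = "numeric", flags = "character"))

#' KineticsFit: single-exponential cleavage kinetics fit F(t) = A(1 - e^{-kt})
#' @slot estimate named: k (per minute), A (plateau fraction)
#' @slot se matching standard errors
#' @slot residualSD residual standard deviation
#' @slot flags fit warnings
#' @export
setClass("KineticsFit",
  representation(estimate = "numeric", se = "numeric",
                 residualSD = "numeric", flags = "character"))

#' SimTruth: ground-truth parameters for the synthetic-data generators
#'
#' Serialized alongside every simulated dataset so that integration tests can
#' read truth only from the file.
#'
#' @slot bindingEnergy 4 x P penalty matrix for the binding simulator
#' @slot cleavageEnergy 4 x P penalty matrix for the cleavage simulator
#' @slot exposureC cleavage exposure C = k_ref * t
#' @slot fRef reference (consensus) bound fraction in the binding sort
#' @slot pamEnergy named 256-entry energy table for PAM simulations
#' @slot muPcr per-base substitution rate of the error-prone PCR
#'   (default 0.005, i.e. 5 mutations per kb)
#' @slot fitness named survival multipliers, keys "<pos><altBase>"
#' @slot baselineSurvival per-round survival of an unmutated clone
#' @slot editingRate,hdrRate amplicon simulation outcome probabilities
#' @slot depth sequencing depth per simulated column
#' @slot readLength simulated read length (default 83 nt)
#' @slot errorRate per-base sequencing error rate
#' @slot seed random seed recorded in every output
#' @export
setClass("SimTruth",
  representation(bindingEnergy = "matrix", cleavageEnergy = "matrix",
                 exposureC = "numeric", fRef = "numeric",
                 pamEnergy = "numeric", muPcr = "numeric",
                 fitness = "numeric", baselineSurvival = "numeric",
                 editingRate = "numeric", hdrRate = "numeric",
                 depth = "numeric", readLength = "integer",
                 errorRate = "numeric", seed = "integer"))

setValidity("SimTruth", function(object) {
  rates <- c(fRef = object@fRef, muPcr = object@muPcr,
             baselineSurvival = object@baselineSurvival,
             editingRate = object@editingRate, hdrRate = object@hdrRate,
             errorRate = object@errorRate)
  if (any(rates < 0 | rates > 1))
    return("all rates must lie in [0, 1]")
  if (object@exposureC < 0) return("exposureC must be non-negative")
  TRUE
})
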