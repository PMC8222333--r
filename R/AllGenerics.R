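#' @include AllClasses.R
NULL

#' @export
setGeneric("protospacer", function(x) standardGeneric("protospacer"))
#' @export
setGeneric("pamSeq", function(x) standardGeneric("pamSeq"))
#' @export
setGeneric("flank5", function(x) standardGeneric("flank5"))
#' @export
setGeneric("flank3", function(x) standardGeneric("flank3"))
#' @export
setGeneric("variableRegion", function(x) standardGeneric("variableRegion"))
#' @export
setGeneric("positionLabels", function(x) standardGeneric("positionLabels"))

#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @export
setGeneric("variantSequences", function(x) standardGeneric("variantSequences"))
#' @export
setGeneric("libraryType", function(x) standardGeneric("libraryType"))
#' @export
setGeneric("targetSite", function(x) standardGeneric("targetSite"))

#' @export
setGeneric("penalties", function(x) standardGeneric("penalties"))
#' @export
setGeneric("penaltySE", function(x) standardGeneric("penaltySE"))
#' @export
setGeneric("penaltyFlags", function(x) standardGeneric("penaltyFlags"))
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))
#' @export
setGeneric("saturationScale", function(x) standardGeneric("saturationScale"))
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))

#' @export
setGeneric("pamTable", function(x) standardGeneric("pamTable"))
#' @export
setGeneric("enzymeLabel", function(x) standardGeneric("enzymeLabel"))

#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))
#' @export
setGeneric("positionDepth", function(x) standardGeneric("positionDepth"))
#' @export
setGeneric("mutationFreqs", function(x) standardGeneric("mutationFreqs"))
#' @export
setGeneric("roundIndex", function(x) standardGeneric("roundIndex"))

#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))
#' @export
setGeneric("editingWindow", function(x) standardGeneric("editingWindow"))
#' @export
setGeneric("hdrAllele", function(x) standardGeneric("hdrAllele"))
#' @export
setGeneric("hdrInterval", function(x) standardGeneric("hdrInterval"))

#' @export
setGeneric("editingCounts", function(x) standardGeneric("editingCounts"))
#' @export
setGeneric("editingPercent", function(x) standardGeneric("editingPercent"))
#' @export
setGeneric("hdrPercent", function(x) standardGeneric("hdrPercent"))
#' @export
setGeneric("discardedReads", function(x) standardGeneric("discardedReads"))

#' @export
setGeneric("fitEstimates", function(x) standardGeneric("fitEstimates"))
#' @export
setGeneric("fitSE", function(x) standardGeneric("fitSE"))
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
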