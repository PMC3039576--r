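#' @rdname LocDataset-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname LocDataset-accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname LocDataset-accessors
#' @export
setGeneric("goAnnotations", function(x) standardGeneric("goAnnotations"))

#' @rdname LocDataset-accessors
#' @export
setGeneric("locations", function(x) standardGeneric("locations"))

#' @rdname LocDataset-accessors
#' @export
setGeneric("locationClasses", function(x) standardGeneric("locationClasses"))

#' @rdname LocDataset-accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname GoTlmModel-accessors
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))

#' @rdname GoTlmModel-accessors
#' @export
setGeneric("channelScores", function(x) standardGeneric("channelScores"))

#' @rdname GoTlmModel-accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname GoTlmModel-accessors
#' @export
setGeneric("goVocabularies", function(x) standardGeneric("goVocabularies"))

#' Accessors for LocDataset
#'
#' @param x A [LocDataset-class] object (for `locationClasses`, also a
#'   [GoTlmModel-class]).
#'
#' @return `proteinIds`: character ids; `proteinSequences`: the
#'   [Biostrings::AAStringSet]; `goAnnotations`: the annotation
#'   `data.frame`; `locations`: named character labels (`NA` =
#'   unlabeled); `locationClasses`: sorted class names; `nProteins`:
#'   integer count.
#'
#' @name LocDataset-accessors
NULL

#' @rdname LocDataset-accessors
setMethod("proteinIds", "LocDataset", function(x) names(x@sequences))

#' @rdname LocDataset-accessors
setMethod("proteinSequences", "LocDataset", function(x) x@sequences)

#' @rdname LocDataset-accessors
setMethod("goAnnotations", "LocDataset", function(x) x@annotations)

#' @rdname LocDataset-accessors
setMethod("locations", "LocDataset", function(x) {
  stats::setNames(x@labels, names(x@sequences))
})

#' @rdname LocDataset-accessors
setMethod("locationClasses", "LocDataset", function(x) x@classes)

#' @rdname LocDataset-accessors
setMethod("nProteins", "LocDataset", function(x) length(x@sequences))

#' Accessors for GoTlmModel
#'
#' @param x A [GoTlmModel-class] object.
#'
#' @return `kernelWeights`: named numeric weights over the five channels
#'   (non-negative, summing to 1); `channelScores`: per-channel SE, MCC,
#'   SE×MCC product and weight; `modelParams`: list with the selected
#'   `cvK`, `gamma` and `C`; `goVocabularies`: named list of the frozen
#'   per-aspect GO vocabularies; `locationClasses`: class order used for
#'   prediction and tie-breaking.
#'
#' @name GoTlmModel-accessors
NULL

#' @rdname GoTlmModel-accessors
setMethod("kernelWeights", "GoTlmModel", function(x) x@weights[channelNames()])

#' @rdname GoTlmModel-accessors
setMethod("channelScores", "GoTlmModel", function(x) x@channelScores)

#' @rdname GoTlmModel-accessors
setMethod("modelParams", "GoTlmModel", function(x) x@params)

#' @rdname GoTlmModel-accessors
setMethod("goVocabularies", "GoTlmModel", function(x) x@vocabularies)

#' @rdname GoTlmModel-accessors
setMethod("locationClasses", "GoTlmModel", function(x) x@classes)

setMethod("show", "LocDataset", function(object) {
  lab <- sum(!is.na(object@labels))
  cat("LocDataset with", length(object@sequences), "proteins\n")
  cat("  annotations:", nrow(object@annotations), "GO rows (",
      paste(sprintf("%s=%d", GO_ASPECTS,
                    vapply(GO_ASPECTS, function(a)
                      sum(object@annotations$aspect == a), 0L)),
            collapse = ", "), ")\n")
  cat("  labeled:", lab, "of", length(object@sequences),
      "| classes:", length(object@classes), "\n")
  if (length(object@classes)) {
    cat("  ", paste(utils::head(object@classes, 8), collapse = ", "),
        if (length(object@classes) > 8) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "GoTlmModel", function(object) {
  cat("GoTlmModel:", length(object@trainIds), "training proteins,",
      length(object@classes), "classes\n")
  w <- round(object@weights[channelNames()], 4)
  cat("  kernel weights:",
      paste(sprintf("%s=%.3f", names(w), w), collapse = " "), "\n")
  p <- object@params
  cat(sprintf("  selected: cvK=%d gamma=%g C=%g\n", p$cvK, p$gamma, p$C))
})
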