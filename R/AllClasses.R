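#' @import methods
NULL

#' LocDataset: proteins, GO annotations and location labels
#'
#' The central data container: an ordered set of protein sequences
#' (a [Biostrings::AAStringSet] named by protein id), a table of
#' per-protein gene-ontology annotations with their aspect, and an
#' optional location label per protein.  Location classes are the
#' sorted set of distinct labels.
#'
#' @slot sequences [Biostrings::AAStringSet] named by unique protein ids.
#' @slot annotations `data.frame` with columns `protein_id`, `term`
#'   (GO accession, `GO:` + 7 digits) and `aspect` (one of `P`, `F`, `C`).
#' @slot labels Character vector parallel to `sequences`; `NA` where a
#'   protein is unlabeled.
#' @slot classes Character vector: sorted distinct non-`NA` labels.
#'
#' @seealso [LocDataset()] for construction, [readDataset()] to load one
#'   from files, [generateDataset()] to simulate one.
#' @aliases LocDataset-class
#' @exportClass LocDataset
setClass("LocDataset",
  representation(
    sequences = "AAStringSet",
    annotations = "data.frame",
    labels = "character",
    classes = "character"
  )
)

setValidity("LocDataset", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    msgs <- c(msgs, "all proteins must have non-empty ids")
  } else if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msgs <- c(msgs, paste0("duplicate protein id(s): ",
                           paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (any(Biostrings::width(object@sequences) < 1)) {
    msgs <- c(msgs, "all sequences must have length >= 1")
  }
  ann <- object@annotations
  need <- c("protein_id", "term", "aspect")
  if (!all(need %in% colnames(ann))) {
    msgs <- c(msgs, "annotations must have columns protein_id, term, aspect")
  } else if (nrow(ann) > 0) {
    if (!all(ann$aspect %in% GO_ASPECTS)) {
      msgs <- c(msgs, "annotation aspect must be one of P, F, C")
    }
    if (!all(grepl(GO_ACCESSION_PATTERN, ann$term))) {
      msgs <- c(msgs, "annotation terms must match GO:[0-9]{7}")
    }
    if (!all(ann$protein_id %in% ids)) {
      miss <- setdiff(unique(ann$protein_id), ids)
      msgs <- c(msgs, paste0("annotation protein id(s) absent from dataset: ",
                             paste(utils::head(miss, 5), collapse = ", ")))
    }
  }
  if (length(object@labels) != length(object@sequences)) {
    msgs <- c(msgs, "labels must be parallel to sequences")
  }
  have <- !is.na(object@labels)
  expected <- sort(unique(object@labels[have]))
  if (!identical(object@classes, expected)) {
    msgs <- c(msgs, "classes must be the sorted set of labels present")
  }
  if (length(msgs)) msgs else TRUE
})

#' GoTlmModel: a fitted weighted multi-kernel localization predictor
#'
#' Holds everything needed to predict new proteins: the location class
#' order, per-aspect GO vocabularies frozen from the training set, the
#' training feature channels (needed to compute rectangular test-vs-train
#' kernels), the estimated channel weights, the selected
#' hyper-parameters, and the one-vs-one SVM state.
#'
#' @slot classes Ordered location classes (sorted training labels).
#' @slot vocabularies Named list `P`/`F`/`C` of sorted GO-term vocabularies.
#' @slot channels Named list of the five training feature matrices.
#' @slot trainIds Protein ids of the training rows, in channel row order.
#' @slot weights Named numeric channel weights (non-negative, sum 1).
#' @slot channelScores `data.frame` with per-channel SE, MCC, product and
#'   weight from the inner cross-validation.
#' @slot params Named list: selected `cvK`, `gamma`, `C`.
#' @slot config The [modelConfig()] the model was trained with.
#' @slot svm One-vs-one SVM state (class-pair structure and binary fits).
#' @slot version Model format tag used by [saveModel()]/[loadModel()].
#'
#' @aliases GoTlmModel-class
#' @exportClass GoTlmModel
setClass("GoTlmModel",
  representation(
    classes = "character",
    vocabularies = "list",
    channels = "list",
    trainIds = "character",
    weights = "numeric",
    channelScores = "data.frame",
    params = "list",
    config = "list",
    svm = "list",
    version = "character"
  )
)

setValidity("GoTlmModel", function(object) {
  msgs <- character()
  if (length(object@classes) < 1) msgs <- c(msgs, "model must have classes")
  if (!setequal(names(object@weights), channelNames())) {
    msgs <- c(msgs, "weights must cover the five channels")
  } else {
    w <- object@weights[channelNames()]
    if (any(w < -1e-12)) msgs <- c(msgs, "weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-8) msgs <- c(msgs, "weights must sum to 1")
  }
  if (!all(GO_ASPECTS %in% names(object@vocabularies))) {
    msgs <- c(msgs, "vocabularies must cover aspects P, F, C")
  }
  if (!all(channelNames() %in% names(object@channels))) {
    msgs <- c(msgs, "training channels must cover the five channels")
  }
  need <- c("cvK", "gamma", "C")
  if (!all(need %in% names(object@params))) {
    msgs <- c(msgs, "params must contain cvK, gamma, C")
  }
  if (length(msgs)) msgs else TRUE
})
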