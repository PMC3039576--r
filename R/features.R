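# The five feature channels: amino-acid composition (AA, 20-dim),
# di-peptide composition (diAA, 400-dim), and three binary GO-term
# vectors (P, F, C) over vocabularies frozen from the training set.

#' Amino-acid composition of one sequence
#'
#' Relative frequency of each of the 20 standard residues, in fixed
#' alphabetical order `ACDEFGHIKLMNPQRSTVWY`.  Positions holding
#' ambiguity letters (B, Z, X, U, O, J) are excluded from both numerator
#' and denominator, so the retained components still sum to 1.
#'
#' @param sequence Amino-acid string, length >= 1.
#' @return Named numeric vector of 20 frequencies; all-zero (with a
#'   warning) when no standard residue is present.
#' @export
#' @examples
#' aaComposition("AAG")
aaComposition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  total <- sum(counts)
  v <- stats::setNames(numeric(length(AA_ALPHABET)), AA_ALPHABET)
  if (total == 0) {
    warning("sequence has no standard residue; all-zero composition")
    return(v)
  }
  v[] <- as.numeric(counts) / total
  v
}

#' Di-peptide composition of one sequence
#'
#' Relative frequency of each of the 400 ordered residue pairs over a
#' sliding window of width 2.  Dimers containing an ambiguity letter are
#' skipped; the remainder are normalized by the count of retained
#' dimers.  A length-1 sequence yields the all-zero vector.
#'
#' @inheritParams aaComposition
#' @return Named numeric vector of 400 frequencies.
#' @export
#' @examples
#' diaaComposition("AAA")[["AA"]]
diaaComposition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  s <- toupper(sequence)
  n <- nchar(s)
  v <- stats::setNames(numeric(length(DIAA_ALPHABET)), DIAA_ALPHABET)
  if (n < 2) return(v)
  dimers <- substring(s, 1:(n - 1), 2:n)
  counts <- table(factor(dimers, levels = DIAA_ALPHABET))
  total <- sum(counts)
  if (total == 0) return(v)
  v[] <- as.numeric(counts) / total
  v
}

#' GO vocabulary for one aspect
#'
#' The sorted unique accessions of one aspect, to be built from
#' *training* annotations only; test-time terms outside it are dropped.
#'
#' @param annotations Annotation `data.frame` (`protein_id`, `term`,
#'   `aspect`).
#' @param aspect One of `"P"`, `"F"`, `"C"`.
#' @return Character vector of sorted unique GO accessions (possibly
#'   empty).
#' @export
buildGoVocabulary <- function(annotations, aspect) {
  aspect <- match.arg(aspect, GO_ASPECTS)
  ann <- normalizeAnnotations(annotations)
  sort(unique(ann$term[ann$aspect == aspect]))
}

#' Binary GO-term matrix over a fixed vocabulary
#'
#' Entry (i, j) is 1 iff protein i carries vocabulary term j for this
#' aspect.  Terms absent from the vocabulary (out-of-vocabulary test
#' terms) are silently dropped; the count of dropped (protein, term)
#' pairs is attached as attribute `"dropped"` and logged.
#'
#' @param ids Protein ids, defining row order.
#' @param annotations Annotation `data.frame`.
#' @param vocabulary Character vector from [buildGoVocabulary()].
#' @param aspect One of `"P"`, `"F"`, `"C"`.
#' @return Binary matrix `length(ids)` x `length(vocabulary)` with
#'   dimnames, attribute `dropped` = number of out-of-vocabulary pairs.
#' @export
goBinaryMatrix <- function(ids, annotations, vocabulary, aspect) {
  aspect <- match.arg(aspect, GO_ASPECTS)
  ann <- normalizeAnnotations(annotations)
  ann <- ann[ann$aspect == aspect & ann$protein_id %in% ids, , drop = FALSE]
  m <- matrix(0, nrow = length(ids), ncol = length(vocabulary),
              dimnames = list(ids, vocabulary))
  inVocab <- ann$term %in% vocabulary
  dropped <- sum(!inVocab)
  if (dropped > 0) {
    gotlmLog("aspect %s: dropped %d out-of-vocabulary term assignment(s)",
             aspect, dropped)
  }
  ann <- ann[inVocab, , drop = FALSE]
  if (nrow(ann)) {
    m[cbind(match(ann$protein_id, ids), match(ann$term, vocabulary))] <- 1
  }
  attr(m, "dropped") <- dropped
  m
}

#' Build all five feature channels for a dataset
#'
#' With `vocabularies = NULL` (training) the per-aspect vocabularies are
#' built from the dataset's own annotations; otherwise (test) the given
#' frozen vocabularies are used and out-of-vocabulary terms are dropped.
#'
#' @param dataset A [LocDataset-class].
#' @param vocabularies `NULL`, or a named list `P`/`F`/`C` of
#'   vocabularies from a trained model.
#' @return Named list of five matrices (`P`, `F`, `C`, `AA`, `diAA`)
#'   with protein ids as rownames; attribute `vocabularies` holds the
#'   vocabularies used.
#' @export
buildChannels <- function(dataset, vocabularies = NULL) {
  stopifnot(is(dataset, "LocDataset"))
  ids <- proteinIds(dataset)
  ann <- goAnnotations(dataset)
  if (is.null(vocabularies)) {
    vocabularies <- lapply(stats::setNames(GO_ASPECTS, GO_ASPECTS),
                           function(a) buildGoVocabulary(ann, a))
  }
  stopifnot(all(GO_ASPECTS %in% names(vocabularies)))
  seqs <- as.character(proteinSequences(dataset))
  aa <- t(vapply(seqs, aaComposition, numeric(20)))
  di <- t(vapply(seqs, diaaComposition, numeric(400)))
  rownames(aa) <- rownames(di) <- ids
  channels <- list(
    P = goBinaryMatrix(ids, ann, vocabularies$P, "P"),
    F = goBinaryMatrix(ids, ann, vocabularies$F, "F"),
    C = goBinaryMatrix(ids, ann, vocabularies$C, "C"),
    AA = aa,
    diAA = di
  )
  attr(channels, "vocabularies") <- vocabularies
  channels
}
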