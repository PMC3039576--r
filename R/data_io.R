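# Reading and writing the external formats: FASTA sequences, GO
# annotation TSV, location label TSV, and the trained-model archive.

#' Construct a LocDataset from in-memory parts
#'
#' @param sequences A named [Biostrings::AAStringSet], or a named
#'   character vector of amino-acid sequences.
#' @param annotations `data.frame` with columns `protein_id`, `term`,
#'   `aspect`; duplicated rows are collapsed.  Proteins without
#'   annotations are legal and receive all-zero GO vectors downstream.
#' @param labels Named character vector mapping protein ids to location
#'   names; proteins absent from it are unlabeled (`NA`).
#' @param dropUnmatched If `TRUE`, annotation rows whose `protein_id` is
#'   not in `sequences` are dropped with a warning; if `FALSE` (default)
#'   they are an error.
#'
#' @return A validated [LocDataset-class].
#' @export
#' @examples
#' d <- LocDataset(c(p1 = "MKVLA", p2 = "GGHHE"),
#'                 data.frame(protein_id = "p1", term = "GO:0005634",
#'                            aspect = "C"),
#'                 labels = c(p1 = "nucleus", p2 = "cytoplasm"))
#' locationClasses(d)
LocDataset <- function(sequences,
                       annotations = emptyAnnotations(),
                       labels = character(),
                       dropUnmatched = FALSE) {
  if (is.character(sequences)) {
    sequences <- Biostrings::AAStringSet(sequences)
  }
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by protein id")
  annotations <- normalizeAnnotations(annotations)
  bad <- !(annotations$protein_id %in% ids)
  if (any(bad)) {
    if (dropUnmatched) {
      warning(sum(bad), " annotation row(s) dropped: protein id not in dataset")
      annotations <- annotations[!bad, , drop = FALSE]
      rownames(annotations) <- NULL
    } else {
      stop("annotation protein id(s) not in dataset: ",
           paste(utils::head(unique(annotations$protein_id[bad]), 5),
                 collapse = ", "))
    }
  }
  labvec <- rep(NA_character_, length(ids))
  if (length(labels)) {
    if (is.null(names(labels))) stop("labels must be named by protein id")
    unknown <- setdiff(names(labels), ids)
    if (length(unknown)) {
      stop("label(s) for unknown protein id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    labvec[match(names(labels), ids)] <- unname(labels)
  }
  new("LocDataset",
      sequences = sequences,
      annotations = annotations,
      labels = labvec,
      classes = sort(unique(labvec[!is.na(labvec)])))
}

emptyAnnotations <- function() {
  data.frame(protein_id = character(), term = character(),
             aspect = character(), stringsAsFactors = FALSE)
}

normalizeAnnotations <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  need <- c("protein_id", "term", "aspect")
  if (!all(need %in% colnames(ann))) {
    stop("annotations need columns protein_id, term, aspect")
  }
  ann <- ann[need]
  for (cl in need) ann[[cl]] <- as.character(ann[[cl]])
  ann <- unique(ann)
  rownames(ann) <- NULL
  ann
}

#' Read protein sequences from a FASTA file
#'
#' The record id is the first whitespace-delimited token of the header.
#' Sequences are uppercased; `*` and gap characters (`-`, `.`) are
#' stripped.
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::AAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  chr <- gsub("[*.-]", "", chr)
  empty <- !nzchar(chr)
  if (any(empty)) {
    stop("FASTA record(s) with empty sequence: ",
         paste(ids[empty], collapse = ", "))
  }
  out <- Biostrings::AAStringSet(chr)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A [LocDataset-class] or named [Biostrings::AAStringSet].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
  seqs <- if (is(x, "LocDataset")) proteinSequences(x) else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read GO annotations from a 3-column TSV
#'
#' Expected columns: protein id, GO accession (`GO:` + 7 digits), aspect
#' (`P`, `F` or `C`).  Lines starting with `#` are ignored; duplicated
#' rows collapse to one.
#'
#' @param path TSV file path.
#' @return `data.frame` with columns `protein_id`, `term`, `aspect`.
#' @export
readGoAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (!length(keep)) return(emptyAnnotations())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("annotation line ", keep[which(nf < 3)[1]],
         ": expected >= 3 tab-separated columns")
  }
  ann <- data.frame(
    protein_id = vapply(parts, `[[`, "", 1),
    term = vapply(parts, `[[`, "", 2),
    aspect = vapply(parts, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  badAspect <- !(ann$aspect %in% GO_ASPECTS)
  if (any(badAspect)) {
    i <- which(badAspect)[1]
    stop("annotation line ", keep[i], ": aspect '", ann$aspect[i],
         "' not one of P, F, C")
  }
  badTerm <- !grepl(GO_ACCESSION_PATTERN, ann$term)
  if (any(badTerm)) {
    i <- which(badTerm)[1]
    stop("annotation line ", keep[i], ": malformed GO accession '",
         ann$term[i], "'")
  }
  ann <- unique(ann)
  rownames(ann) <- NULL
  ann
}

#' Write GO annotations to TSV
#'
#' @param annotations `data.frame` with `protein_id`, `term`, `aspect`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeGoAnnotations <- function(annotations, path) {
  ann <- normalizeAnnotations(annotations)
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read location labels from a 2-column TSV
#'
#' @param path TSV file path (protein id, location name).
#' @return Named character vector mapping protein id to location.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (!length(keep)) return(stats::setNames(character(), character()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("label line ", keep[which(nf < 2)[1]], ": expected 2 columns")
  }
  ids <- vapply(parts, `[[`, "", 1)
  labs <- vapply(parts, `[[`, "", 2)
  pairs <- unique(data.frame(id = ids, lab = labs, stringsAsFactors = FALSE))
  if (anyDuplicated(pairs$id)) {
    dup <- unique(pairs$id[duplicated(pairs$id)])
    stop("conflicting labels for protein id(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  stats::setNames(pairs$lab, pairs$id)
}

#' Write location labels to TSV
#'
#' @param labels Named character vector (protein id -> location).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeLabels <- function(labels, path) {
  labels <- labels[!is.na(labels)]
  utils::write.table(
    data.frame(names(labels), unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a LocDataset from FASTA, annotation and label files
#'
#' @param fasta FASTA path (required).
#' @param go Optional GO annotation TSV path.
#' @param labels Optional label TSV path.
#' @inheritParams LocDataset
#' @return A [LocDataset-class].
#' @export
readDataset <- function(fasta, go = NULL, labels = NULL,
                        dropUnmatched = FALSE) {
  seqs <- readFasta(fasta)
  ann <- if (is.null(go)) emptyAnnotations() else readGoAnnotations(go)
  lab <- if (is.null(labels)) character() else readLabels(labels)
  lab <- lab[names(lab) %in% names(seqs)]
  LocDataset(seqs, ann, lab, dropUnmatched = dropUnmatched)
}

#' Write a LocDataset to a directory
#'
#' Writes `dataset.fasta`, `annotations.tsv` and (when labels exist)
#' `labels.tsv` under `dir`.
#'
#' @param dataset A [LocDataset-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "dataset.fasta"),
             go = file.path(dir, "annotations.tsv"),
             labels = file.path(dir, "labels.tsv"))
  writeFasta(dataset, paths["fasta"])
  writeGoAnnotations(goAnnotations(dataset), paths["go"])
  lab <- locations(dataset)
  if (any(!is.na(lab))) writeLabels(lab, paths["labels"]) else
    paths <- paths[c("fasta", "go")]
  invisible(paths)
}

#' Save a trained model to a single-file archive
#'
#' The archive records a format version and a payload checksum so that
#' truncated or corrupted files are detected at load time.
#'
#' @param model A fitted [GoTlmModel-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [loadModel()]
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "GoTlmModel"))
  validObject(model)
  payload <- serialize(model, NULL)
  saveRDS(list(format = MODEL_FORMAT,
               checksum = rawChecksum(payload),
               payload = payload),
          path)
  invisible(path)
}

#' Load a trained model archive
#'
#' @param path Archive written by [saveModel()].
#' @return The [GoTlmModel-class]; predictions are identical to those of
#'   the model that was saved.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  arc <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable model archive: ",
                                           conditionMessage(e)))
  if (!is.list(arc) || !identical(arc$format, MODEL_FORMAT)) {
    stop("model archive format mismatch (expected ", MODEL_FORMAT, ")")
  }
  if (!identical(unname(rawChecksum(arc$payload)), unname(arc$checksum))) {
    stop("model archive integrity check failed (corrupted payload)")
  }
  model <- unserialize(arc$payload)
  validObject(model)
  model
}
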