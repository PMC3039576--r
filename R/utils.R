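# Internal constants and helpers shared across modules.

#' Channel names used throughout the package
#'
#' The five feature channels, in canonical order: the three gene-ontology
#' aspects (biological process `P`, molecular function `F`, cellular
#' component `C`) and the two sequence-composition channels (`AA`,
#' amino-acid composition; `diAA`, di-peptide composition).
#'
#' @return Character vector of the five channel names.
#' @export
#' @examples
#' channelNames()
channelNames <- function() c("P", "F", "C", "AA", "diAA")

GO_ASPECTS <- c("P", "F", "C")

# Fixed alphabetical order of the 20 standard residues; frozen so that
# serialized models are portable across sessions.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# All 400 ordered dimers, first residue varying slowest: AA, AC, ..., YY.
DIAA_ALPHABET <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))

AMBIGUITY_LETTERS <- c("B", "Z", "X", "U", "O", "J")

GO_ACCESSION_PATTERN <- "^GO:[0-9]{7}$"

MODEL_FORMAT <- "goTLM-model-1"

#' @importFrom withr with_seed
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic derived seed, kept below 2^31 so it stays a valid R integer.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

gotlmLog <- function(...) {
  if (isTRUE(getOption("goTLM.verbose", TRUE))) {
    message("[goTLM] ", sprintf(...))
  }
  invisible(NULL)
}

# Cheap content checksum used for model-archive integrity (not security).
rawChecksum <- function(x) {
  stopifnot(is.raw(x))
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(x, tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
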