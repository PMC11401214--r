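# Shared small helpers: logging, Phred handling, residue checks.

#' Control nanomatch logging verbosity
#'
#' Messages go to stderr. Levels: 0 silent, 1 info (default), 2 debug.
#'
#' @param level integer verbosity level.
#' @return the previous level, invisibly.
#' @export
nm_verbosity <- function(level) {
  old <- getOption("nanomatch.verbose", 1L)
  options(nanomatch.verbose = as.integer(level))
  invisible(old)
}

nm_log <- function(..., level = 1L) {
  if (getOption("nanomatch.verbose", 1L) >= level)
    message("[nanomatch] ", ...)
  invisible(NULL)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @return a list of integer vectors.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Reverse-complement DNA strings
#'
#' IUPAC degenerate codes are complemented code-wise (e.g. Y -> R);
#' characters outside the IUPAC alphabet become N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) .cpp_revcomp(as.character(x))

is_standard_aa <- function(x) {
  !grepl(sprintf("[^%s]", paste(.AA20, collapse = "")), x)
}

is_dna <- function(x) {
  !grepl("[^ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]", x)
}

# I/L-collapsed form used for all isobaric-equivalent containment tests.
il_collapse <- function(x, il_equivalent = TRUE) {
  if (il_equivalent) chartr("L", "I", x) else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stable_id <- function(protein) paste0("vhh_", .cpp_fnv1a64(protein))
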