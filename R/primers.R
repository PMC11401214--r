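# Primer definitions and IUPAC-aware fuzzy (Hamming) primer location.

#' Define a PCR primer
#'
#' `seq` is the full synthesized oligo 5'->3'; the first `tail_len` bases
#' (e.g. an NNNNNN diversity hexamer) are non-annealing and are excluded
#' from all matching and length accounting. The annealing sequence may
#' contain IUPAC degenerate codes (a target base matches a code if it
#' belongs to the code's base set).
#'
#' @param name primer name.
#' @param seq oligo sequence, 5'->3', IUPAC codes allowed.
#' @param orientation `"forward"` or `"reverse"`.
#' @param tail_len number of 5' non-annealing bases to strip.
#' @param hinge hinge class this primer implies when it identifies a
#'   sequence (reverse primers only), one of `"long_hinge_IgG2"`,
#'   `"short_hinge_IgG3"`, or `NA`.
#' @return an object of class `primer_def`.
#' @export
primer_def <- function(name, seq, orientation = c("forward", "reverse"),
                       tail_len = 0L, hinge = NA_character_) {
  orientation <- match.arg(orientation)
  seq <- toupper(seq)
  stopifnot(nchar(seq) > tail_len)
  if (!is_dna(seq)) stop("primer ", name, ": non-IUPAC characters in sequence")
  annealing <- substr(seq, tail_len + 1L, nchar(seq))
  structure(list(name = name, annealing_seq = annealing,
                 orientation = orientation, tail_len = as.integer(tail_len),
                 hinge = hinge),
            class = "primer_def")
}

#' @export
print.primer_def <- function(x, ...) {
  cat(sprintf("<primer %s> %s (%s, %d nt annealing%s)\n", x$name,
              x$annealing_seq, x$orientation, nchar(x$annealing_seq),
              if (x$tail_len > 0) sprintf(", %dN tail", x$tail_len) else ""))
  invisible(x)
}

#' Allowed mismatch budget for a primer at a fractional tolerance
#'
#' The budget is `ceiling(frac * annealing length)`: a 23-nt annealing
#' region at 20% tolerance allows 5 mismatches.
#'
#' @param primer a [primer_def()].
#' @param max_mismatch_frac fractional mismatch tolerance.
#' @return integer mismatch budget.
#' @export
mismatch_budget <- function(primer, max_mismatch_frac = 0.2) {
  as.integer(ceiling(max_mismatch_frac * nchar(primer$annealing_seq) - 1e-9))
}

#' Locate a primer annealing site in a DNA target
#'
#' Substitution-only (Hamming) search of the annealing sequence against the
#' target; reverse primers are searched against the reverse complement and
#' the hit is reported in plus-strand coordinates. Returns the hit with the
#' fewest mismatches (ties broken by smallest position), or `NULL` when no
#' position is within the mismatch budget.
#'
#' @param target DNA string.
#' @param primer a [primer_def()].
#' @param max_mismatch_frac fractional mismatch tolerance (default 0.2).
#' @return a list with `primer_name`, `position` (1-based start of the site
#'   on the plus strand), `strand`, `mismatches`, `max_allowed`, `length`;
#'   or `NULL` for no hit.
#' @export
find_primer <- function(target, primer, max_mismatch_frac = 0.2) {
  stopifnot(inherits(primer, "primer_def"))
  target <- toupper(target)
  subject <- if (primer$orientation == "reverse") revcomp(target) else target
  budget <- mismatch_budget(primer, max_mismatch_frac)
  hit <- .cpp_scan_best(subject, primer$annealing_seq, budget)
  if (is.na(hit$pos)) return(NULL)
  plen <- nchar(primer$annealing_seq)
  pos <- hit$pos
  strand <- "+"
  if (primer$orientation == "reverse") {
    # map the reverse-complement coordinate back to the plus strand
    pos <- nchar(target) - (hit$pos + plen - 1L) + 1L
    strand <- "-"
  }
  list(primer_name = primer$name, position = pos, strand = strand,
       mismatches = hit$mismatches, max_allowed = budget, length = plen)
}

# Vectorised best-hit scan over many targets (used by the database builder
# and the survey). Returns data.frame(pos, mismatches) in the coordinates
# of `targets` as given (no strand handling here).
scan_targets <- function(targets, annealing_seq, max_mm) {
  hit <- .cpp_scan_best(targets, annealing_seq, max_mm)
  data.frame(pos = hit$pos, mismatches = hit$mismatches)
}

#' Built-in hinge-targeted VHH amplification primers
#'
#' The leader-region forward primer (CALL001-style, with a degenerate Y) and
#' the long-hinge / short-hinge reverse primers, each synthesized with a 6N
#' diversity tail. Reverse-primer identity encodes the IgG2 (long hinge) or
#' IgG3 (short hinge) subclass of the amplified transcript.
#'
#' @return named list of [primer_def()] objects
#'   (`call001`, `lh_rev`, `sh_rev`).
#' @export
builtin_primers <- function() {
  list(
    call001 = primer_def("6N-CALL001", "NNNNNNGTCCTGGCTGCTCTTYTACAAGG",
                         "forward", tail_len = 6L),
    lh_rev = primer_def("6N-LH-rev", "NNNNNNGTGGTTGTGGTTTTGGTGTCTTGGG",
                        "reverse", tail_len = 6L, hinge = "long_hinge_IgG2"),
    sh_rev = primer_def("6N-SH-rev", "NNNNNNCTGGGGTCTTCGCTGTGGTGC",
                        "reverse", tail_len = 6L, hinge = "short_hinge_IgG3")
  )
}
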