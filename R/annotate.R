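# Framework/CDR annotation by conserved anchor motifs and an IMGT-style
# position map pinned at the canonical immunoglobulin anchors:
# first Cys (IMGT 23), post-CDR1 Trp (41), second Cys (104), FR4 Trp (118).

#' Anchor motif configuration for CDR annotation
#'
#' Each anchor has one or more amino-acid patterns (`.` = wildcard) with the
#' offset of the anchor residue inside the pattern, a search window for the
#' anchor position (negative values count from the sequence end, -1 = last
#' residue), and the IMGT position the anchor pins. Defaults are the
#' canonical immunoglobulin anchors; all are overridable.
#'
#' @param anchors named list of anchor definitions (see Details).
#' @param max_mismatch allowed pattern mismatches at non-wildcard positions
#'   (default 0: exact matching; ties are broken towards fewer mismatches,
#'   then the leftmost position, then earlier patterns).
#' @param min_gap named integer vector: minimum residue spacing enforced
#'   between consecutive anchors (an anchor violating it is discarded).
#' @return an object of class `anchor_config`.
#' @export
anchor_config <- function(anchors = NULL, max_mismatch = 0L,
                          min_gap = c(trp41 = 7L, cys104 = 54L, fr4_trp = 2L)) {
  if (is.null(anchors)) {
    anchors <- list(
      cys23 = list(patterns = list(list(pat = "C", offset = 1L)),
                   window = c(18L, 30L), imgt = 23L),
      trp41 = list(patterns = list(list(pat = "W", offset = 1L)),
                   window = c(36L, 46L), imgt = 41L),
      cys104 = list(patterns = list(list(pat = "Y.C", offset = 3L)),
                    window = c(95L, 110L), imgt = 104L),
      fr4_trp = list(patterns = list(list(pat = "WG.G", offset = 1L)),
                     window = c(-15L, -1L), imgt = 118L)
    )
  }
  stopifnot(all(c("cys23", "trp41", "cys104", "fr4_trp") %in% names(anchors)))
  structure(list(anchors = anchors, max_mismatch = as.integer(max_mismatch),
                 min_gap = min_gap),
            class = "anchor_config")
}

# Vectorised anchor search: best anchor position per protein for one anchor
# definition (NA when nothing matches within the mismatch budget).
find_anchor <- function(proteins, anchor, max_mismatch) {
  n <- length(proteins)
  L <- nchar(proteins)
  best_mm <- rep(NA_integer_, n)
  best_pos <- rep(NA_integer_, n)
  w <- anchor$window
  lo <- if (w[1] < 0) L + w[1] + 1L else rep(w[1], n)
  hi <- if (w[2] < 0) L + w[2] + 1L else rep(w[2], n)
  width <- max(0L, max(hi - lo, na.rm = TRUE)) + 1L
  for (pi in seq_along(anchor$patterns)) {
    pat <- anchor$patterns[[pi]]
    chars <- strsplit(pat$pat, "", fixed = TRUE)[[1]]
    plen <- length(chars)
    fixed_j <- which(chars != ".")
    for (k in seq_len(width) - 1L) {
      apos <- lo + k
      start <- apos - pat$offset + 1L
      valid <- apos <= hi & start >= 1L & (start + plen - 1L) <= L
      if (!any(valid)) next
      mm <- integer(n)
      for (j in fixed_j) {
        mm <- mm + (substr(proteins, start + j - 1L, start + j - 1L) != chars[j])
      }
      ok <- valid & mm <= max_mismatch &
        (is.na(best_mm) | mm < best_mm |
           (mm == best_mm & apos < best_pos))
      best_mm[ok] <- mm[ok]
      best_pos[ok] <- apos[ok]
    }
  }
  best_pos
}

#' Annotate framework and CDR regions of VHH proteins
#'
#' Locates the four anchor motifs of `cfg` and derives FR1-FR4 / CDR1-3
#' boundaries (1-based, inclusive) by linear pinning: CDR1 spans the
#' residues between IMGT 26 and 39, CDR2 between IMGT 55 and 66, CDR3
#' strictly between the second Cys and the FR4 Trp motif. Anchors that
#' fail, or violate the minimum spacing to the previous anchor, leave their
#' dependent regions unresolved (NA) rather than guessed; confidence is
#' `"full"` (all anchors), `"partial"` (some), or `"failed"` (fewer than
#' two).
#'
#' @param proteins character vector of amino-acid sequences.
#' @param cfg an [anchor_config()].
#' @return a data.frame of class `cdr_annotation`, one row per protein,
#'   with anchor positions (`cys23`, `trp41`, `cys104`, `fr4_trp`), region
#'   boundaries (`fr1_start` ... `fr4_end`), `length` and `confidence`.
#' @export
annotate_regions <- function(proteins, cfg = anchor_config()) {
  stopifnot(inherits(cfg, "anchor_config"))
  n <- length(proteins)
  L <- nchar(proteins)
  a <- lapply(cfg$anchors, find_anchor, proteins = proteins,
              max_mismatch = cfg$max_mismatch)

  # enforce minimum spacing against the previous retained anchor
  gap <- cfg$min_gap
  prev <- a$cys23
  bad <- !is.na(a$trp41) & !is.na(prev) & a$trp41 < prev + gap[["trp41"]]
  a$trp41[bad] <- NA_integer_
  prev <- ifelse(is.na(a$trp41), prev, a$trp41)
  need <- ifelse(is.na(a$trp41), gap[["trp41"]] + gap[["cys104"]], gap[["cys104"]])
  bad <- !is.na(a$cys104) & !is.na(prev) & a$cys104 < prev + need
  a$cys104[bad] <- NA_integer_
  prev <- ifelse(is.na(a$cys104), prev, a$cys104)
  need <- ifelse(is.na(a$cys104), gap[["cys104"]] + gap[["fr4_trp"]], gap[["fr4_trp"]])
  bad <- !is.na(a$fr4_trp) & !is.na(prev) & a$fr4_trp < prev + need
  a$fr4_trp[bad] <- NA_integer_

  n_found <- (!is.na(a$cys23)) + (!is.na(a$trp41)) + (!is.na(a$cys104)) +
    (!is.na(a$fr4_trp))
  confidence <- ifelse(n_found == 4L, "full",
                       ifelse(n_found >= 2L, "partial", "failed"))

  na <- rep(NA_integer_, n)
  out <- data.frame(
    cys23 = a$cys23, trp41 = a$trp41, cys104 = a$cys104, fr4_trp = a$fr4_trp,
    fr1_start = ifelse(!is.na(a$cys23), 1L, na),
    fr1_end = a$cys23 + 3L,
    cdr1_start = a$cys23 + 4L,
    cdr1_end = a$trp41 - 3L,
    fr2_start = a$trp41 - 2L,
    fr2_end = a$trp41 + 14L,
    cdr2_start = a$trp41 + 15L,
    cdr2_end = a$cys104 - 39L,
    fr3_start = a$cys104 - 38L,
    fr3_end = a$cys104,
    cdr3_start = a$cys104 + 1L,
    cdr3_end = a$fr4_trp - 1L,
    fr4_start = a$fr4_trp,
    fr4_end = ifelse(!is.na(a$fr4_trp), L, na),
    length = L,
    confidence = confidence,
    stringsAsFactors = FALSE
  )
  # paired-boundary regions need both anchors
  out$cdr1_start[is.na(out$cdr1_end)] <- NA_integer_
  out$cdr1_end[is.na(out$cdr1_start)] <- NA_integer_
  out$cdr2_start[is.na(out$cdr2_end)] <- NA_integer_
  out$cdr2_end[is.na(out$cdr2_start)] <- NA_integer_
  out$cdr3_start[is.na(out$cdr3_end)] <- NA_integer_
  out$cdr3_end[is.na(out$cdr3_start)] <- NA_integer_
  # fr2/fr3 boundaries that run past the ends are unresolved
  bad_fr2 <- !is.na(out$fr2_start) & (out$fr2_start < 1L | out$fr2_end > L)
  out$fr2_start[bad_fr2] <- out$fr2_end[bad_fr2] <- NA_integer_
  bad_fr3 <- !is.na(out$fr3_start) & out$fr3_start < 1L
  out$fr3_start[bad_fr3] <- out$fr3_end[bad_fr3] <- NA_integer_
  bad_fr1 <- !is.na(out$fr1_end) & out$fr1_end > L
  out$fr1_start[bad_fr1] <- out$fr1_end[bad_fr1] <- NA_integer_
  class(out) <- c("cdr_annotation", "data.frame")
  out
}

#' Extract the CDR3 sequences from an annotation
#'
#' @param proteins character vector of proteins.
#' @param ann matching [annotate_regions()] result.
#' @return character vector of CDR3 strings (`NA` where unresolved).
#' @export
cdr3_seq <- function(proteins, ann) {
  ifelse(is.na(ann$cdr3_start), NA_character_,
         substr(proteins, ann$cdr3_start, ann$cdr3_end))
}

# IMGT loop-gapping labels for a loop of length L filling slots s..e:
# positions fill from both ends towards the middle; loops longer than the
# slot count get insertion codes extending from the loop middle
# (e.g. 111.1, 111.2, ..., 112.2, 112.1 for CDR3).
imgt_gap_labels <- function(L, s, e) {
  if (L == 0) return(character(0))
  n <- e - s + 1L
  if (L <= n) {
    front <- ceiling(L / 2)
    back <- L - front
    c(as.character(seq(s, s + front - 1L)),
      if (back > 0) as.character(seq(e - back + 1L, e)))
  } else {
    extra <- L - n
    k1 <- ceiling(extra / 2)
    k2 <- extra - k1
    mid1 <- s + ceiling(n / 2) - 1L
    mid2 <- mid1 + 1L
    c(as.character(seq(s, mid1)),
      if (k1 > 0) paste0(mid1, ".", seq_len(k1)),
      if (k2 > 0) paste0(mid2, ".", rev(seq_len(k2))),
      as.character(seq(mid2, e)))
  }
}

#' IMGT-style position map for an annotated protein
#'
#' Framework residues are numbered by linear assignment pinned at the
#' anchors (first Cys = 23, post-CDR1 Trp = 41, second Cys = 104, FR4
#' Trp = 118); CDR residues follow the IMGT loop-gapping convention for
#' variable-length loops. Residues unreachable from a resolved anchor
#' (including any hinge stub past IMGT 128) are `NA`.
#'
#' @param protein one amino-acid sequence.
#' @param ann a one-row [annotate_regions()] result for it.
#' @return character vector of IMGT position labels, one per residue.
#' @export
imgt_positions <- function(protein, ann) {
  if (nrow(ann) != 1L) stop("imgt_positions() expects a one-row annotation")
  if (ann$confidence == "failed")
    stop("annotation failed for this sequence; import an external numbering ",
         "with import_external_numbering()")
  L <- nchar(protein)
  map <- rep(NA_character_, L)
  put <- function(idx, labels) {
    keep <- idx >= 1L & idx <= L
    map[idx[keep]] <<- labels[keep]
  }
  if (!is.na(ann$cys23)) {
    idx <- seq(ann$cys23 - 22L, ann$cys23 + 3L)
    put(idx, as.character(1:26))
  }
  if (!is.na(ann$cdr1_start) && ann$cdr1_end >= ann$cdr1_start) {
    idx <- seq(ann$cdr1_start, ann$cdr1_end)
    put(idx, imgt_gap_labels(length(idx), 27L, 38L))
  }
  if (!is.na(ann$fr2_start)) {
    put(seq(ann$fr2_start, ann$fr2_end), as.character(39:55))
  }
  if (!is.na(ann$cdr2_start) && ann$cdr2_end >= ann$cdr2_start) {
    idx <- seq(ann$cdr2_start, ann$cdr2_end)
    put(idx, imgt_gap_labels(length(idx), 56L, 65L))
  }
  if (!is.na(ann$fr3_start)) {
    put(seq(ann$fr3_start, ann$fr3_end), as.character(66:104))
  }
  if (!is.na(ann$cdr3_start) && ann$cdr3_end >= ann$cdr3_start) {
    idx <- seq(ann$cdr3_start, ann$cdr3_end)
    put(idx, imgt_gap_labels(length(idx), 105L, 117L))
  }
  if (!is.na(ann$fr4_start)) {
    idx <- seq(ann$fr4_start, min(L, ann$fr4_start + 10L))
    put(idx, as.character(seq(118L, length.out = length(idx))))
  }
  map
}

#' Test for the VH-hallmark GLEW motif at IMGT 49-52
#'
#' Conventional-VH contaminants carry Gly-Leu-Glu-Trp at IMGT positions
#' 49-52; true VHH frameworks do not. Returns `NA` (indeterminate, logged)
#' when any of positions 49-52 is absent from the map -- an unannotatable
#' sequence is reported, not condemned.
#'
#' @param protein one amino-acid sequence.
#' @param position_map its IMGT map from [imgt_positions()].
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
has_vh_hallmark <- function(protein, position_map) {
  idx <- match(as.character(49:52), position_map)
  if (anyNA(idx)) {
    nm_log("GLEW check indeterminate: IMGT 49-52 not fully mapped", level = 2L)
    return(NA)
  }
  identical(substring(protein, idx, idx), c("G", "L", "E", "W"))
}

#' Rebuild an annotation from an external (e.g. ANARCI-style) numbering
#'
#' Region boundaries are derived from the IMGT region definitions
#' (FR1 <= 26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
#' FR4 >= 118; insertion codes such as 111.1 sort into their loop).
#'
#' @param protein one amino-acid sequence.
#' @param numbering data.frame with columns `index` (1-based residue index)
#'   and `imgt` (IMGT label), monotone in both.
#' @return a one-row `cdr_annotation` data.frame.
#' @export
import_external_numbering <- function(protein, numbering) {
  if (is.null(numbering) || nrow(numbering) == 0)
    stop("empty numbering table")
  idx <- as.integer(numbering$index)
  val <- as.numeric(numbering$imgt)
  if (anyNA(idx) || anyNA(val))
    stop("numbering table has unparseable entries")
  if (is.unsorted(idx, strictly = TRUE) || is.unsorted(val, strictly = TRUE))
    stop("numbering table must be strictly monotone in index and IMGT position")
  L <- nchar(protein)
  region_rng <- function(lo, hi) {
    i <- idx[val >= lo & val <= hi]
    if (length(i) == 0) c(NA_integer_, NA_integer_) else range(i)
  }
  b <- list(fr1 = region_rng(-Inf, 26.5), cdr1 = region_rng(26.5, 38.5),
            fr2 = region_rng(38.5, 55.5), cdr2 = region_rng(55.5, 65.5),
            fr3 = region_rng(65.5, 104.5), cdr3 = region_rng(104.5, 117.5),
            fr4 = region_rng(117.5, Inf))
  anchor_at <- function(p) {
    i <- idx[val == p]
    if (length(i) == 1) i else NA_integer_
  }
  cdrs <- !is.na(c(b$cdr1[1], b$cdr2[1], b$cdr3[1]))
  out <- data.frame(
    cys23 = anchor_at(23), trp41 = anchor_at(41), cys104 = anchor_at(104),
    fr4_trp = anchor_at(118),
    fr1_start = b$fr1[1], fr1_end = b$fr1[2],
    cdr1_start = b$cdr1[1], cdr1_end = b$cdr1[2],
    fr2_start = b$fr2[1], fr2_end = b$fr2[2],
    cdr2_start = b$cdr2[1], cdr2_end = b$cdr2[2],
    fr3_start = b$fr3[1], fr3_end = b$fr3[2],
    cdr3_start = b$cdr3[1], cdr3_end = b$cdr3[2],
    fr4_start = b$fr4[1], fr4_end = if (!is.na(b$fr4[1])) L else NA_integer_,
    length = L,
    confidence = if (all(cdrs)) "full" else if (any(cdrs)) "partial" else "failed",
    stringsAsFactors = FALSE
  )
  class(out) <- c("cdr_annotation", "data.frame")
  out
}
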