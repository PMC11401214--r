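# ORF extraction by primer position, translation, deduplication.

translate_dna <- function(dna) {
  dna <- substr(dna, 1L, 3L * (nchar(dna) %/% 3L))
  out <- character(length(dna))
  ok <- nchar(dna) >= 3L
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(dna[ok]),
                                if.fuzzy.codon = "X")
    out[ok] <- as.character(aa)
  }
  out
}

#' Extract and translate the VHH coding region of merged amplicons
#'
#' The reading frame is set by primer position: translation starts at the
#' end of the best forward-primer hit plus `frame_offset`, and runs to the
#' start of the best reverse-primer hit (plus-strand coordinates), truncated
#' to whole codons. The identity of the matching reverse primer assigns the
#' hinge class; amplicons matching neither reverse primer are retried with
#' `fallback_rev` (hinge `"unknown"`) when supplied. Sequences with an
#' in-frame stop codon or a translated length outside `len_range` are
#' rejected, with per-reason tallies.
#'
#' @param amplicons character vector of merged amplicon sequences (or a
#'   data.frame from [merge_pairs()], in which case only `status == "ok"`
#'   rows are used).
#' @param fwd_primers,rev_primers lists of [primer_def()] objects.
#' @param frame_offset bases between forward-primer end and codon 1.
#' @param max_mismatch_frac primer mismatch tolerance (default 0.2).
#' @param len_range acceptable translated length window in residues.
#' @param fallback_rev optional [primer_def()] used as a reverse anchor when
#'   no hinge-specific reverse primer hits.
#' @return a list with `drafts` (data.frame `protein`, `dna`, `hinge`,
#'   `count` all 1) and `rejects` (named integer tally of reject reasons).
#' @export
extract_and_translate <- function(amplicons, fwd_primers, rev_primers,
                                  frame_offset = 0L, max_mismatch_frac = 0.2,
                                  len_range = c(90L, 180L),
                                  fallback_rev = NULL) {
  if (is.data.frame(amplicons)) amplicons <- amplicons$seq[amplicons$status == "ok"]
  amplicons <- toupper(amplicons)
  n <- length(amplicons)
  if (is.null(names(fwd_primers))) names(fwd_primers) <- vapply(fwd_primers, `[[`, "", "name")
  if (is.null(names(rev_primers))) names(rev_primers) <- vapply(rev_primers, `[[`, "", "name")

  # best forward hit across forward primers
  fwd_end <- rep(NA_integer_, n)
  fwd_mm <- rep(NA_integer_, n)
  for (p in fwd_primers) {
    hits <- scan_targets(amplicons, p$annealing_seq,
                         mismatch_budget(p, max_mismatch_frac))
    better <- !is.na(hits$pos) & (is.na(fwd_mm) | hits$mismatches < fwd_mm)
    fwd_end[better] <- hits$pos[better] + nchar(p$annealing_seq) - 1L
    fwd_mm[better] <- hits$mismatches[better]
  }

  # best reverse hit: scan the reverse complement, convert to plus strand
  rc <- revcomp(amplicons)
  rev_start <- rep(NA_integer_, n)
  rev_mm <- rep(NA_integer_, n)
  hinge <- rep(NA_character_, n)
  scan_rev <- function(p, allow_update) {
    hits <- scan_targets(rc, p$annealing_seq,
                         mismatch_budget(p, max_mismatch_frac))
    plen <- nchar(p$annealing_seq)
    pos_plus <- nchar(amplicons) - (hits$pos + plen - 1L) + 1L
    better <- allow_update & !is.na(hits$pos) &
      (is.na(rev_mm) | hits$mismatches < rev_mm)
    rev_start[better] <<- pos_plus[better]
    rev_mm[better] <<- hits$mismatches[better]
    hinge[better] <<- if (is.na(p$hinge)) "unknown" else p$hinge
  }
  for (p in rev_primers) scan_rev(p, rep(TRUE, n))
  if (!is.null(fallback_rev)) scan_rev(fallback_rev, is.na(rev_start))

  rejects <- c(no_forward = 0L, no_reverse = 0L, internal_stop = 0L,
               length_out_of_range = 0L)
  rejects["no_forward"] <- sum(is.na(fwd_end))
  usable <- !is.na(fwd_end)
  rejects["no_reverse"] <- sum(usable & is.na(rev_start))
  usable <- usable & !is.na(rev_start)
  start <- fwd_end + 1L + as.integer(frame_offset)
  usable <- usable & start < rev_start
  coding <- ifelse(usable, substr(amplicons, start, rev_start - 1L), "")
  protein <- character(n)
  protein[usable] <- translate_dna(coding[usable])
  has_stop <- usable & grepl("*", protein, fixed = TRUE)
  rejects["internal_stop"] <- sum(has_stop)
  usable <- usable & !has_stop
  plen <- nchar(protein)
  bad_len <- usable & (plen < len_range[1] | plen > len_range[2])
  rejects["length_out_of_range"] <- rejects["length_out_of_range"] + sum(bad_len)
  usable <- usable & !bad_len

  drafts <- data.frame(
    protein = protein[usable],
    dna = substr(coding[usable], 1L, 3L * nchar(protein[usable])),
    hinge = hinge[usable],
    count = rep(1L, sum(usable)),
    stringsAsFactors = FALSE
  )
  list(drafts = drafts, rejects = rejects)
}

#' Deduplicate translated drafts into a counted VHH database
#'
#' Collapses records by exact protein identity; read counts are summed
#' (total support is conserved). The representative DNA is the most
#' frequent exact DNA variant of the protein (ties: lexicographically
#' smallest); the hinge class is the majority call. Output is sorted by
#' count descending, then protein ascending, and each record gets a stable
#' id derived from a hash of the protein sequence.
#'
#' @param drafts data.frame with `protein`, `dna`, `hinge`, `count` (all 1).
#' @return a `vhh_db` data.frame with columns `id`, `protein`, `dna`,
#'   `count`, `hinge`.
#' @export
dedup_and_count <- function(drafts) {
  stopifnot(all(c("protein", "dna", "hinge") %in% names(drafts)))
  if (is.null(drafts$count)) drafts$count <- 1L
  if (nrow(drafts) == 0) {
    out <- data.frame(id = character(), protein = character(),
                      dna = character(), count = integer(),
                      hinge = character(), stringsAsFactors = FALSE)
    class(out) <- c("vhh_db", "data.frame")
    return(out)
  }
  sp <- split(seq_len(nrow(drafts)), drafts$protein)
  rec <- lapply(names(sp), function(p) {
    i <- sp[[p]]
    dna_tab <- tapply(drafts$count[i], drafts$dna[i], sum)
    dna_tab <- dna_tab[order(-dna_tab, names(dna_tab))]
    hinge_tab <- sort(table(drafts$hinge[i]), decreasing = TRUE)
    data.frame(protein = p, dna = names(dna_tab)[1],
               count = sum(drafts$count[i]),
               hinge = names(hinge_tab)[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out <- out[order(-out$count, out$protein), , drop = FALSE]
  out <- data.frame(id = stable_id(out$protein), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("vhh_db", "data.frame")
  out
}

#' @export
print.vhh_db <- function(x, ...) {
  cat(sprintf("<vhh_db> %d unique proteins, %d supporting reads\n",
              nrow(x), sum(x$count)))
  if (nrow(x) > 0) {
    tab <- table(x$hinge)
    cat("  hinge classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  top: %s (count %d, %d aa)\n", x$id[1], x$count[1],
                nchar(x$protein[1])))
  }
  invisible(x)
}

#' Build a VHH protein database from merged amplicons
#'
#' Convenience wrapper: [extract_and_translate()] then [dedup_and_count()].
#'
#' @inheritParams extract_and_translate
#' @return a list with `db` (a `vhh_db`) and `rejects` (reason tally).
#' @export
build_vhh_db <- function(amplicons, fwd_primers, rev_primers,
                         frame_offset = 0L, max_mismatch_frac = 0.2,
                         len_range = c(90L, 180L), fallback_rev = NULL) {
  ex <- extract_and_translate(amplicons, fwd_primers, rev_primers,
                              frame_offset, max_mismatch_frac, len_range,
                              fallback_rev)
  nm_log("translated ", nrow(ex$drafts), " amplicons; rejects: ",
         paste(sprintf("%s=%d", names(ex$rejects), ex$rejects), collapse = ", "))
  list(db = dedup_and_count(ex$drafts), rejects = ex$rejects)
}

#' Write a VHH database as FASTA
#'
#' Protein FASTA headers follow `>vhh_<hash> count=<n> hinge=<class>`; a DNA
#' sidecar with identical headers can be written alongside.
#'
#' @param db a `vhh_db`.
#' @param path protein FASTA path.
#' @param dna_path optional DNA sidecar FASTA path.
#' @export
write_vhh_fasta <- function(db, path, dna_path = NULL) {
  hdr <- sprintf("%s count=%d hinge=%s", db$id, db$count, db$hinge)
  write_fasta(data.frame(desc = hdr, seq = db$protein), path)
  if (!is.null(dna_path))
    write_fasta(data.frame(desc = hdr, seq = db$dna), dna_path)
  invisible(path)
}

#' Read a VHH database from FASTA written by [write_vhh_fasta()]
#'
#' @param path protein FASTA path.
#' @param dna_path optional DNA sidecar path.
#' @return a `vhh_db` data.frame.
#' @export
read_vhh_fasta <- function(path, dna_path = NULL) {
  x <- read_fasta(path, alphabet = "aa")
  count <- as.integer(sub("^count=", "",
                          regmatches(x$desc, regexpr("count=\\d+", x$desc))))
  hinge <- sub("^hinge=", "",
               regmatches(x$desc, regexpr("hinge=\\S+", x$desc)))
  out <- data.frame(id = x$id, protein = x$seq,
                    dna = NA_character_, count = count, hinge = hinge,
                    stringsAsFactors = FALSE)
  if (!is.null(dna_path)) {
    d <- read_fasta(dna_path, alphabet = "dna")
    out$dna <- d$seq[match(out$id, d$id)]
  }
  class(out) <- c("vhh_db", "data.frame")
  out
}
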