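# Paired-end overlap merging (substitution-only, quality-aware consensus).

#' Merge one paired-end read into an amplicon consensus
#'
#' Read 2 is reverse-complemented, then the longest ungapped overlap whose
#' mismatch fraction is at most `max_overlap_mismatch_frac` is taken.
#' Conflicting overlap positions are resolved by the higher Phred quality
#' (ties keep the read-1 base); every disagreeing position increments
#' `conflict_count`.
#'
#' @param seq1,qual1 read 1 sequence and Phred+33 quality string.
#' @param seq2,qual2 read 2 (as sequenced, i.e. reverse strand) and quality.
#' @param min_overlap minimum acceptable overlap length (default 20).
#' @param max_overlap_mismatch_frac maximum mismatch fraction inside the
#'   overlap (default 0.1).
#' @return a list with `seq`, `overlap_len`, `conflict_count`, `status`
#'   (`"ok"` or `"no_overlap"`); `seq` is `NA` on failure.
#' @export
merge_read_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 20L,
                            max_overlap_mismatch_frac = 0.1) {
  m <- merge_pairs(data.frame(id = "r", seq1 = seq1, qual1 = qual1,
                              seq2 = seq2, qual2 = qual2,
                              stringsAsFactors = FALSE),
                   min_overlap = min_overlap,
                   max_overlap_mismatch_frac = max_overlap_mismatch_frac)
  list(seq = m$seq[1], overlap_len = m$overlap_len[1],
       conflict_count = m$conflict_count[1], status = m$status[1])
}

#' Merge many read pairs
#'
#' Vectorised form of [merge_read_pair()] over a pair table as returned by
#' [read_fastq_pairs()].
#'
#' @param pairs data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @inheritParams merge_read_pair
#' @return data.frame with `id`, `seq`, `overlap_len`, `conflict_count`,
#'   `status`. The merged-length identity
#'   `nchar(seq) == nchar(seq1) + nchar(seq2) - overlap_len` holds for
#'   every successful row.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L,
                        max_overlap_mismatch_frac = 0.1) {
  s2rc <- revcomp(pairs$seq2)
  q2rc <- vapply(pairs$qual2, function(q) {
    paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = "")
  }, FUN.VALUE = "", USE.NAMES = FALSE)
  res <- .cpp_merge_pairs(toupper(pairs$seq1), pairs$qual1, s2rc, q2rc,
                          as.integer(min_overlap), max_overlap_mismatch_frac)
  n_fail <- sum(res$status != "ok")
  if (n_fail > 0)
    nm_log(n_fail, "/", nrow(pairs), " read pairs failed to merge")
  data.frame(id = pairs$id, seq = res$seq, overlap_len = res$overlap_len,
             conflict_count = res$conflict_count, status = res$status,
             stringsAsFactors = FALSE)
}
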