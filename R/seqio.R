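# Readers/writers for the external plain-text formats. Everything
# downstream works on plain data.frames produced here.

#' Read a FASTA file
#'
#' Wrapped sequence lines are joined; record order is preserved. The full
#' header line (minus `>`) is kept in `desc`, its first word in `id`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"`, `"aa"`, or `NULL` to skip alphabet checking.
#' @return a data.frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(grepl("^\\s*$", lines)))
    return(data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE))
  first <- which(!grepl("^\\s*$", lines))[1]
  hdr <- grepl("^>", lines)
  if (!hdr[first])
    stop("FASTA parse error at line ", first, ": expected '>' header, got: ",
         substr(lines[first], 1, 40))
  idx <- cumsum(hdr)
  descs <- sub("^>", "", lines[hdr])
  hdr_lines <- which(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, collapse = "",
                 FUN.VALUE = "")
  # records with no body at all are absent from `seqs`
  out_seq <- character(length(descs))
  out_seq[as.integer(names(seqs))] <- seqs
  empty <- which(!nzchar(gsub("\\s", "", out_seq)))
  if (length(empty))
    stop("FASTA parse error: empty sequence for record at line ",
         hdr_lines[empty[1]], " ('", substr(descs[empty[1]], 1, 40), "')")
  out_seq <- gsub("\\s", "", out_seq)
  if (!is.null(alphabet)) {
    bad <- if (alphabet == "dna") !is_dna(out_seq) else !is_standard_aa(out_seq)
    if (any(bad))
      stop("FASTA record '", descs[which(bad)[1]], "' contains characters ",
           "outside the ", alphabet, " alphabet")
  }
  data.frame(id = vapply(strsplit(descs, "\\s+"), `[`, 1, FUN.VALUE = ""),
             desc = descs, seq = unname(out_seq), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data.frame with `seq` and either `desc` or `id` columns.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  hdr <- if (!is.null(x$desc)) x$desc else x$id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    s <- x$seq[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", hdr[i]), substring(s, starts,
                                                pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

strip_read_suffix <- function(id) sub("/[12]$", "", sub("\\s.*$", "", id))

read_fastq_one <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0)
    stop("FASTQ file ", path, " is truncated (line count not a multiple of 4)")
  id <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  seq <- lines[seq(2, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  if (any(nchar(seq) != nchar(qual)))
    stop("FASTQ file ", path, ": sequence/quality length mismatch at record ",
         which(nchar(seq) != nchar(qual))[1])
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Read a FASTQ read pair
#'
#' Files must be record-aligned (same order and count); read ids are
#' compared after stripping any `/1`/`/2` suffix and description.
#' Qualities are kept as Phred+33 strings (see [phred_to_int()]).
#'
#' @param path_r1,path_r2 paths to the two FASTQ files.
#' @return a data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2))
    stop("FASTQ pair record counts differ: ", nrow(r1), " vs ", nrow(r2))
  id1 <- strip_read_suffix(r1$id)
  id2 <- strip_read_suffix(r2$id)
  bad <- which(id1 != id2)
  if (length(bad))
    stop("FASTQ pair id mismatch at record ", bad[1], ": '", id1[bad[1]],
         "' vs '", id2[bad[1]], "'")
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param x data.frame with `id`, `seq`, `qual` columns (Phred+33 strings).
#' @param path output path.
#' @export
write_fastq <- function(x, path) {
  out <- character(4L * nrow(x))
  out[seq(1, length(out), by = 4)] <- paste0("@", x$id)
  out[seq(2, length(out), by = 4)] <- x$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- x$qual
  writeLines(out, path)
  invisible(path)
}

#' Read an MS peptide observation table
#'
#' Expects a TSV with header columns `peptide`, `protease`, `sample_id` and
#' optionally `score`. Peptides shorter than `min_peptide_len` are dropped
#' with a logged count (never silently). Protease labels must be one of
#' `trypsin`, `chymotrypsin_high`, `chymotrypsin_low`.
#'
#' @param path path to the TSV.
#' @param min_peptide_len minimum peptide length retained (default 6, the
#'   usual MS identifiability floor).
#' @return data.frame with columns `peptide`, `protease`, `sample_id`, `score`.
#' @export
read_peptide_table <- function(path, min_peptide_len = 6L) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("peptide", "protease", "sample_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("peptide table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(x$score)) x$score <- NA_real_
  x <- x[, c("peptide", "protease", "sample_id", "score")]
  bad_prot <- setdiff(unique(x$protease), .PROTEASES)
  if (length(bad_prot))
    stop("unknown protease label(s) ", paste(sQuote(bad_prot), collapse = ", "),
         "; allowed: ", paste(.PROTEASES, collapse = ", "))
  bad_aa <- !is_standard_aa(x$peptide)
  if (any(bad_aa))
    stop("peptide table row ", which(bad_aa)[1],
         ": peptide contains non-standard residues: ", x$peptide[which(bad_aa)[1]])
  short <- nchar(x$peptide) < min_peptide_len
  if (any(short)) {
    warning(sum(short), " peptide(s) shorter than ", min_peptide_len,
            " residues dropped")
    nm_log("dropped ", sum(short), " sub-threshold peptides from ", path)
    x <- x[!short, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' Write peptide observations as TSV
#'
#' @param x peptide observation data.frame.
#' @param path output path.
#' @export
write_peptide_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer definition table
#'
#' TSV with columns `name`, `seq`, `orientation` (`forward`/`reverse`) and
#' optional `tail_len` (count of 5' non-annealing bases, e.g. an NNNNNN
#' diversity hexamer) and `hinge` (hinge class assigned by a reverse primer).
#'
#' @param path path to the TSV.
#' @return a list of [primer_def()] objects.
#' @export
read_primer_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "seq", "orientation")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("primer table missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(x)), function(i) {
    primer_def(x$name[i], x$seq[i], x$orientation[i],
               tail_len = if (is.null(x$tail_len)) 0L else x$tail_len[i],
               hinge = if (is.null(x$hinge)) NA_character_ else x$hinge[i])
  })
}
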