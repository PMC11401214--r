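# In silico protease digestion under Expasy-style rules, unique-peptide
# lists, and the cleavage-site-by-IMGT-position histogram.

#' Protease cleavage rule
#'
#' Expasy-style rules: cleavage C-terminal of `cleave_after` residues
#' unless the next residue is in `blocked_before`. Built-ins:
#' trypsin (after K/R, not before P), chymotrypsin high specificity
#' (after F/Y/W, not before P), chymotrypsin low specificity (additionally
#' after M/L/H).
#'
#' @param name `"trypsin"`, `"chymotrypsin_high"`, or `"chymotrypsin_low"`;
#'   or any label when `cleave_after` is supplied explicitly.
#' @param cleave_after,blocked_before optional residue sets overriding the
#'   built-in rule.
#' @return an object of class `protease_rule`.
#' @export
protease_rule <- function(name, cleave_after = NULL, blocked_before = NULL) {
  if (is.null(cleave_after)) {
    builtin <- list(
      trypsin = list(after = c("K", "R"), blocked = "P"),
      chymotrypsin_high = list(after = c("F", "Y", "W"), blocked = "P"),
      chymotrypsin_low = list(after = c("F", "Y", "W", "M", "L", "H"),
                              blocked = "P")
    )
    if (!name %in% names(builtin))
      stop("unknown protease '", name, "'; allowed: ",
           paste(names(builtin), collapse = ", "))
    cleave_after <- builtin[[name]]$after
    blocked_before <- builtin[[name]]$blocked
  }
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_before = blocked_before %||% character(0)),
            class = "protease_rule")
}

# Cleavage sites of `rule` in one protein: positions i such that cleavage
# occurs between residues i and i+1.
cleavage_sites <- function(protein, rule) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(aa)
  if (L < 2) return(integer(0))
  i <- seq_len(L - 1L)
  i[aa[i] %in% rule$cleave_after & !(aa[i + 1L] %in% rule$blocked_before)]
}

#' Digest a protein in silico
#'
#' Fully-specific digestion: peptides are the maximal spans between
#' cleavage sites; with `missed_cleavages = k`, all unions of up to `k + 1`
#' adjacent spans are additionally emitted. At 0 missed cleavages the
#' peptides concatenate exactly to the protein.
#'
#' @param protein amino-acid string.
#' @param rule a [protease_rule()].
#' @param missed_cleavages maximum missed cleavages (default 0, as used for
#'   VHH database digestion).
#' @return data.frame with `peptide`, `start`, `end` (1-based, inclusive)
#'   and `missed`.
#' @export
digest_protein <- function(protein, rule, missed_cleavages = 0L) {
  stopifnot(nchar(protein) > 0, is_standard_aa(protein))
  sites <- cleavage_sites(protein, rule)
  bounds <- c(0L, sites, nchar(protein))
  n_span <- length(bounds) - 1L
  out <- list()
  for (k in 0:missed_cleavages) {
    if (n_span - k < 1L) break
    i <- seq_len(n_span - k)
    out[[k + 1L]] <- data.frame(
      start = bounds[i] + 1L,
      end = bounds[i + 1L + k],
      missed = k
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  data.frame(peptide = substring(protein, res$start, res$end),
             start = res$start, end = res$end, missed = res$missed,
             stringsAsFactors = FALSE)
}

#' Unique peptides of a VHH database under one protease
#'
#' Digests every database protein (deduplicated input required) and pools
#' peptides of at least `min_len` residues, each with its complete set of
#' source sequence ids; output sorted lexicographically by peptide.
#'
#' @param db a `vhh_db` data.frame (`id`, `protein`).
#' @param rule a [protease_rule()].
#' @param min_len minimum peptide length (default 6).
#' @param missed_cleavages maximum missed cleavages (default 0).
#' @return data.frame with `peptide`, `n_sources` and a list-column
#'   `sources` of id vectors.
#' @export
unique_peptides <- function(db, rule, min_len = 6L, missed_cleavages = 0L) {
  if (anyDuplicated(db$protein))
    stop("database contains duplicate proteins; run dedup_and_count() first")
  per <- lapply(seq_len(nrow(db)), function(i) {
    d <- digest_protein(db$protein[i], rule, missed_cleavages)
    d <- d[nchar(d$peptide) >= min_len, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(peptide = unique(d$peptide), id = db$id[i],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per)
  if (is.null(long))
    return(data.frame(peptide = character(), n_sources = integer(),
                      sources = I(list())))
  sp <- split(long$id, long$peptide)
  sp <- sp[order(names(sp))]
  data.frame(peptide = names(sp), n_sources = lengths(sp),
             sources = I(unname(sp)), stringsAsFactors = FALSE)
}

#' Write a unique-peptide list as FASTA
#'
#' Headers follow `>pep_<i> sources=<n>`.
#'
#' @param peps result of [unique_peptides()].
#' @param path output path.
#' @export
write_peptide_fasta <- function(peps, path) {
  hdr <- sprintf("pep_%d sources=%d", seq_len(nrow(peps)), peps$n_sources)
  write_fasta(data.frame(desc = hdr, seq = peps$peptide), path)
}

#' Histogram of cleavage events by IMGT position
#'
#' For every cleavage site in every database sequence, increments the IMGT
#' position of the residue after which cleavage occurs; sites at residues
#' without an IMGT assignment are tallied separately, so that
#' `sum(counts) + unmapped` equals the total number of cleavage events.
#'
#' @param db a `vhh_db` (or data.frame with `protein`).
#' @param rule a [protease_rule()].
#' @param ann a [annotate_regions()] result for `db$protein`.
#' @return a list with `counts` (named integer vector, IMGT label ->
#'   count), `unmapped` and `total` (mapped + unmapped events).
#' @export
cleavage_histogram <- function(db, rule, ann) {
  counts <- list()
  unmapped <- 0L
  total <- 0L
  for (i in seq_len(nrow(db))) {
    sites <- cleavage_sites(db$protein[i], rule)
    total <- total + length(sites)
    if (length(sites) == 0) next
    if (ann$confidence[i] == "failed") {
      unmapped <- unmapped + length(sites)
      next
    }
    map <- imgt_positions(db$protein[i], ann[i, , drop = FALSE])
    lab <- map[sites]
    unmapped <- unmapped + sum(is.na(lab))
    lab <- lab[!is.na(lab)]
    for (l in lab) counts[[l]] <- (counts[[l]] %||% 0L) + 1L
  }
  cv <- unlist(counts) %||% integer(0)
  cv <- cv[order(as.numeric(names(cv)))]
  list(counts = cv, unmapped = unmapped, total = total)
}
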