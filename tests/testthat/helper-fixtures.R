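# Shared fixtures and independent reference (oracle) implementations.
# Oracles are deliberately naive/quadratic and never call package internals.

# -- oracle: exhaustive IUPAC Hamming scan ---------------------------------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_mismatches <- function(target, pattern, start) {
  tc <- strsplit(target, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  mm <- 0L
  for (j in seq_along(pc)) {
    tb <- tc[start + j - 1L]
    allowed <- iupac_sets[[pc[j]]]
    if (!(tb %in% c("A", "C", "G", "T")) || !(tb %in% allowed)) mm <- mm + 1L
  }
  mm
}

oracle_best_hit <- function(target, pattern, max_mm) {
  n <- nchar(target); p <- nchar(pattern)
  if (n < p) return(NULL)
  best <- NULL
  for (s in seq_len(n - p + 1L)) {
    mm <- oracle_mismatches(target, pattern, s)
    if (mm <= max_mm && (is.null(best) || mm < best$mm)) best <- list(pos = s, mm = mm)
  }
  best
}

# -- oracle: quadratic digestion reference ---------------------------------

oracle_digest <- function(protein, cleave_after, blocked_before) {
  aa <- strsplit(protein, "")[[1]]
  peps <- character(0)
  cur <- ""
  for (i in seq_along(aa)) {
    cur <- paste0(cur, aa[i])
    nxt <- if (i < length(aa)) aa[i + 1L] else NA
    if (aa[i] %in% cleave_after && (is.na(nxt) || !(nxt %in% blocked_before))) {
      if (!is.na(nxt)) { peps <- c(peps, cur); cur <- "" }
    }
  }
  c(peps, cur)
}

# -- oracle: brute-force peptide containment (I/L equivalent) --------------

oracle_contains <- function(peptide, protein, il = TRUE) {
  if (il) { peptide <- chartr("L", "I", peptide); protein <- chartr("L", "I", protein) }
  grepl(peptide, protein, fixed = TRUE)
}

oracle_match_table <- function(peptides, db, il = TRUE) {
  out <- list()
  for (p in peptides) for (i in seq_len(nrow(db))) {
    if (oracle_contains(p, db$protein[i], il))
      out[[length(out) + 1L]] <- data.frame(peptide = p, id = db$id[i])
  }
  if (length(out) == 0) return(data.frame(peptide = character(), id = character()))
  do.call(rbind, out)
}

# -- small constructed fixtures --------------------------------------------

random_dna_str <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
random_aa_str <- function(len) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# a protein built from the default framework template with chosen CDRs;
# region boundaries are known by construction
template_protein <- function(cdr1 = "GRTFSSYA", cdr2 = "INSGGGST",
                             cdr3 = "AKDPSYYRGSY", hinge = "short_hinge_IgG3",
                             tpl = vhh_template()) {
  protein <- paste0(tpl$leader, tpl$fr1, cdr1, tpl$fr2, cdr2, tpl$fr3,
                    cdr3, tpl$fr4, tpl$hinge_stub[[hinge]])
  off <- nchar(tpl$leader) + nchar(tpl$fr1)
  list(protein = protein,
       cdr1 = c(off + 1L, off + nchar(cdr1)),
       cdr2 = c(off + nchar(cdr1) + nchar(tpl$fr2) + 1L,
                off + nchar(cdr1) + nchar(tpl$fr2) + nchar(cdr2)),
       cdr3 = c(off + nchar(cdr1) + nchar(tpl$fr2) + nchar(cdr2) + nchar(tpl$fr3) + 1L,
                off + nchar(cdr1) + nchar(tpl$fr2) + nchar(cdr2) + nchar(tpl$fr3) + nchar(cdr3)))
}

# a minimal deduplicated database from protein strings
tiny_db <- function(proteins, counts = NULL, hinge = "short_hinge_IgG3") {
  counts <- counts %||% rep(1L, length(proteins))
  expanded <- rep(proteins, counts)
  drafts <- data.frame(protein = expanded,
                       dna = nanomatch:::reverse_translate(expanded),
                       hinge = rep(hinge, length.out = length(expanded)),
                       count = rep(1L, length(expanded)),
                       stringsAsFactors = FALSE)
  dedup_and_count(drafts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
options(nanomatch.verbose = 0)
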