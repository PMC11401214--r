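# Peptide-to-sequence mapping, CDR-weighted coverage, CDR3 clonotype
# grouping, uniqueness scores, ranking and selection filters.

#' Map observed peptides back to database sequences
#'
#' Substring containment with Ile and Leu treated as identical when
#' `il_equivalent` (they are isobaric and indistinguishable by standard MS
#' fragmentation). All match spans are reported; peptides matching nothing
#' are retained in `unmatched`.
#'
#' @param observations peptide observation data.frame
#'   (see [read_peptide_table()]), or a character vector of peptides.
#' @param db a `vhh_db` data.frame.
#' @param il_equivalent treat I and L as identical (default `TRUE`).
#' @return a list with `matches` (data.frame `peptide`, `id`, `start`,
#'   `end`) and `unmatched` (character vector of peptides).
#' @export
map_peptides <- function(observations, db, il_equivalent = TRUE) {
  peptides <- if (is.data.frame(observations)) observations$peptide else observations
  peptides <- unique(peptides)
  seqs_c <- il_collapse(db$protein, il_equivalent)
  res <- vector("list", length(peptides))
  for (k in seq_along(peptides)) {
    pep_c <- il_collapse(peptides[k], il_equivalent)
    hit <- grep(pep_c, seqs_c, fixed = TRUE)
    if (length(hit) == 0) next
    spans <- gregexpr(pep_c, seqs_c[hit], fixed = TRUE)
    n_per <- lengths(spans)
    res[[k]] <- data.frame(
      peptide = peptides[k],
      id = rep(db$id[hit], n_per),
      start = unlist(spans),
      end = unlist(spans) + nchar(peptides[k]) - 1L,
      stringsAsFactors = FALSE
    )
  }
  matches <- do.call(rbind, res)
  if (is.null(matches))
    matches <- data.frame(peptide = character(), id = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched = setdiff(peptides, unique(matches$peptide)))
}

#' Per-residue region weights for coverage scoring
#'
#' Defaults give CDR3 coverage the most weight (FR = 1, CDR1 = CDR2 = 3,
#' CDR3 = 10).
#'
#' @param fr,cdr1,cdr2,cdr3 per-residue weights.
#' @return named numeric vector over the seven regions.
#' @export
coverage_weights <- function(fr = 1, cdr1 = 3, cdr2 = 3, cdr3 = 10) {
  c(fr1 = fr, cdr1 = cdr1, fr2 = fr, cdr2 = cdr2, fr3 = fr, cdr3 = cdr3,
    fr4 = fr)
}

.REGIONS <- c("fr1", "cdr1", "fr2", "cdr2", "fr3", "cdr3", "fr4")

region_matrix <- function(ann) {
  cols <- as.vector(rbind(paste0(.REGIONS, "_start"), paste0(.REGIONS, "_end")))
  as.matrix(ann[, cols])
}

#' CDR-weighted peptide coverage scores
#'
#' For each sequence, the score is `100 * sum_r(w_r * c_r) / sum_r(w_r *
#' n_r)` over its resolved regions, where `c_r` is the number of residues
#' of region `r` covered by at least one matched peptide and `n_r` the
#' region length. Unresolved regions carry zero weight; sequences whose
#' annotation failed are scored with uniform weights over the whole
#' sequence and flagged.
#'
#' @param db a `vhh_db`.
#' @param ann matching [annotate_regions()] result.
#' @param matches match table from [map_peptides()].
#' @param weights per-residue region weights ([coverage_weights()]).
#' @return data.frame with `id`, `score` (0-100), `cdr3_covered`,
#'   `uniform_fallback`, and per-region covered counts `cov_fr1` ...
#'   `cov_fr4`.
#' @export
coverage_score <- function(db, ann, matches, weights = coverage_weights()) {
  n <- nrow(db)
  reg <- region_matrix(ann)
  mode(reg) <- "integer"
  sidx <- match(matches$id, db$id)
  keep <- !is.na(sidx)
  cov <- .cpp_region_cover(sidx[keep], as.integer(matches$start[keep]),
                           as.integer(matches$end[keep]), reg,
                           as.integer(nchar(db$protein)))
  colnames(cov) <- .REGIONS
  rlen <- reg[, seq(2, 14, by = 2), drop = FALSE] -
    reg[, seq(1, 13, by = 2), drop = FALSE] + 1L
  colnames(rlen) <- .REGIONS
  w <- matrix(weights[.REGIONS], n, 7, byrow = TRUE)
  w[is.na(rlen)] <- 0
  num <- rowSums(w * ifelse(is.na(cov), 0L, cov))
  den <- rowSums(w * ifelse(is.na(rlen), 0L, rlen))
  score <- ifelse(den > 0, 100 * num / den, 0)

  # failed annotations: uniform weights over the whole sequence
  failed <- ann$confidence == "failed"
  if (any(failed)) {
    L <- nchar(db$protein)
    full <- cbind(rep(1L, n), L)
    covf <- .cpp_region_cover(sidx[keep], as.integer(matches$start[keep]),
                              as.integer(matches$end[keep]), full,
                              as.integer(L))
    score[failed] <- 100 * covf[failed, 1] / L[failed]
  }
  data.frame(id = db$id, score = score,
             cdr3_covered = !is.na(cov[, "cdr3"]) & cov[, "cdr3"] > 0,
             uniform_fallback = failed,
             cov_fr1 = cov[, 1], cov_cdr1 = cov[, 2], cov_fr2 = cov[, 3],
             cov_cdr2 = cov[, 4], cov_fr3 = cov[, 5], cov_cdr3 = cov[, 6],
             cov_fr4 = cov[, 7], stringsAsFactors = FALSE)
}

#' Partition a database into CDR3 clonotype groups
#'
#' Exact mode keys groups on the I/L-collapsed CDR3 string. Cluster mode
#' additionally single-linkage-merges exact groups whose CDR3s differ in
#' length by at most one and have identity (1 - edit distance / longer
#' length) at least `similarity_threshold`. Sequences with unresolved CDR3
#' become flagged singleton groups.
#'
#' @param db a `vhh_db`.
#' @param ann matching annotation.
#' @param mode `"exact"` (default) or `"cluster"`.
#' @param similarity_threshold cluster-mode identity threshold (default 0.8).
#' @param il_equivalent collapse I/L in group keys (default `TRUE`).
#' @return data.frame with `id`, `group_id`, `cdr3` (group key),
#'   `unresolved_cdr3`.
#' @export
group_by_cdr3 <- function(db, ann, mode = c("exact", "cluster"),
                          similarity_threshold = 0.8, il_equivalent = TRUE) {
  mode <- match.arg(mode)
  cdr3 <- cdr3_seq(db$protein, ann)
  key <- il_collapse(cdr3, il_equivalent)
  unresolved <- is.na(key)
  key[unresolved] <- paste0("unresolved_", db$id[unresolved])
  if (mode == "cluster") {
    uk <- unique(key[!unresolved])
    if (length(uk) > 1) {
      parent <- seq_along(uk)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      lens <- nchar(uk)
      for (i in seq_along(uk)) {
        cand <- which(abs(lens - lens[i]) <= 1L & seq_along(uk) > i)
        if (length(cand) == 0) next
        d <- utils::adist(uk[i], uk[cand])[1, ]
        sim <- 1 - d / pmax(lens[i], lens[cand])
        for (j in cand[sim >= similarity_threshold]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      root <- vapply(seq_along(uk), find, 1L)
      # representative key: the root's own key
      remap <- setNames(uk[root], uk)
      key[!unresolved] <- remap[key[!unresolved]]
    }
  }
  grp <- match(key, unique(key))
  data.frame(id = db$id, group_id = sprintf("g%04d", grp), cdr3 = key,
             unresolved_cdr3 = unresolved, stringsAsFactors = FALSE)
}

#' Peptide uniqueness score within a CDR3 group
#'
#' `100 * (number of group sequences containing the peptide) / (number of
#' database sequences containing it)`, containment under the same I/L
#' equivalence as [map_peptides()]. The score is the probability that the
#' peptide originated from an antibody with the group's CDR3; 100 means
#' every database occurrence lies inside the group.
#'
#' @param peptide one peptide string.
#' @param group_ids ids of the group members.
#' @param db a `vhh_db`.
#' @param il_equivalent I/L equivalence flag.
#' @return the score, a real in (0, 100].
#' @export
uniqueness_score <- function(peptide, group_ids, db, il_equivalent = TRUE) {
  pep <- il_collapse(peptide, il_equivalent)
  seqs <- il_collapse(db$protein, il_equivalent)
  in_db <- grepl(pep, seqs, fixed = TRUE)
  if (!any(in_db)) stop("peptide matches no database sequence: ", peptide)
  100 * sum(in_db & db$id %in% group_ids) / sum(in_db)
}

# Vectorised uniqueness over all (peptide, group) pairs present in the
# match table; derived purely from containment counts.
uniqueness_table <- function(matches, groups) {
  hits <- unique(matches[, c("peptide", "id")])
  hits$group_id <- groups$group_id[match(hits$id, groups$id)]
  n_db <- tapply(hits$id, hits$peptide, function(x) length(unique(x)))
  pg <- unique(hits[, c("peptide", "group_id")])
  n_grp <- tapply(hits$id, paste(hits$peptide, hits$group_id, sep = "\r"),
                  function(x) length(unique(x)))
  pg$n_group <- as.integer(n_grp[paste(pg$peptide, pg$group_id, sep = "\r")])
  pg$n_db <- as.integer(n_db[pg$peptide])
  pg$uniqueness <- 100 * pg$n_group / pg$n_db
  rownames(pg) <- NULL
  pg
}

#' Rank CDR3 groups and their members
#'
#' Groups are ranked by their top-scoring member (descending maximum
#' coverage score; ties by total group read count, then group id); within
#' each group, members are ranked by read count (descending; ties by
#' score, then id). The ordering is total and deterministic.
#'
#' @param groups result of [group_by_cdr3()].
#' @param scores result of [coverage_score()].
#' @param db a `vhh_db` (read counts).
#' @param ann matching annotation (CDR3 intervals carried into the report).
#' @return a `candidate_report` skeleton: list with ranked `groups` and
#'   `members` data.frames (filters not yet applied).
#' @export
rank_candidates <- function(groups, scores, db, ann) {
  m <- data.frame(
    id = db$id, count = db$count,
    group_id = groups$group_id[match(db$id, groups$id)],
    cdr3 = groups$cdr3[match(db$id, groups$id)],
    unresolved_cdr3 = groups$unresolved_cdr3[match(db$id, groups$id)],
    score = scores$score[match(db$id, scores$id)],
    cdr3_covered = scores$cdr3_covered[match(db$id, scores$id)],
    cdr3_start = ann$cdr3_start, cdr3_end = ann$cdr3_end,
    stringsAsFactors = FALSE
  )
  g <- do.call(rbind, lapply(split(m, m$group_id), function(x) {
    data.frame(group_id = x$group_id[1], cdr3 = x$cdr3[1],
               group_score = max(x$score), total_count = sum(x$count),
               n_members = nrow(x),
               unresolved_cdr3 = any(x$unresolved_cdr3),
               stringsAsFactors = FALSE)
  }))
  # groups keyed by an unresolved CDR3 are not reviewable clonotypes:
  # they stay in the report (flagged) but rank after all resolved groups
  g <- g[order(g$unresolved_cdr3, -g$group_score, -g$total_count, g$group_id), ,
         drop = FALSE]
  g$rank <- seq_len(nrow(g))
  rownames(g) <- NULL
  m <- m[order(match(m$group_id, g$group_id), -m$count, -m$score, m$id), ,
         drop = FALSE]
  m$rank_in_group <- unlist(lapply(split(seq_len(nrow(m)),
                                         match(m$group_id, g$group_id)),
                                   seq_along), use.names = FALSE)
  rownames(m) <- NULL
  structure(list(groups = g, members = m), class = "candidate_report")
}

#' Apply selection filters to a ranked report
#'
#' Flags each member: `glew_hit` (VH-hallmark GLEW at IMGT 49-52),
#' `cross_antigen_hit` (a CDR3-covering matched peptide with uniqueness
#' above the threshold also observed in an unrelated antigen's peptide
#' set), and `no_unique_peptide` (no matched peptide with uniqueness
#' strictly above the threshold, default 80). `selected` is true iff no
#' flag is set.
#'
#' @param report skeleton from [rank_candidates()].
#' @param matches match table from [map_peptides()].
#' @param groups result of [group_by_cdr3()].
#' @param cross_antigen_peptides named list of peptide character vectors,
#'   one per unrelated antigen (may be empty).
#' @param uniqueness_threshold strict lower bound for a "high" uniqueness
#'   score (default 80).
#' @param glew_flags logical vector aligned with the database
#'   (`NA` = indeterminate, which does not remove a candidate).
#' @param il_equivalent I/L equivalence flag (must match the mapping).
#' @return the `candidate_report` with per-member flags, `max_uniqueness`,
#'   `selected`, and a `uniqueness` evidence table attached.
#' @export
apply_filters <- function(report, matches, groups,
                          cross_antigen_peptides = list(),
                          uniqueness_threshold = 80,
                          glew_flags = NULL, il_equivalent = TRUE) {
  m <- report$members
  uniq <- uniqueness_table(matches, groups)

  # per-member max uniqueness over its matched peptides (scored against
  # the member's own group)
  mt <- matches
  mt$group_id <- groups$group_id[match(mt$id, groups$id)]
  mt$uniqueness <- uniq$uniqueness[match(paste(mt$peptide, mt$group_id),
                                         paste(uniq$peptide, uniq$group_id))]
  mu <- tapply(mt$uniqueness, mt$id, max)
  m$max_uniqueness <- as.numeric(mu[m$id])
  m$no_unique_peptide <- is.na(m$max_uniqueness) |
    !(m$max_uniqueness > uniqueness_threshold)

  # cross-antigen: CDR3-covering high-uniqueness peptides shared with an
  # unrelated antigen's observed set
  cross_set <- unique(il_collapse(unlist(cross_antigen_peptides,
                                         use.names = FALSE) %||% character(0),
                                  il_equivalent))
  m$cross_antigen_hit <- FALSE
  if (length(cross_set) > 0 && nrow(mt) > 0) {
    c3s <- m$cdr3_start[match(mt$id, m$id)]
    c3e <- m$cdr3_end[match(mt$id, m$id)]
    spans_cdr3 <- !is.na(c3s) & mt$start <= c3e & mt$end >= c3s
    bad <- spans_cdr3 & mt$uniqueness > uniqueness_threshold &
      il_collapse(mt$peptide, il_equivalent) %in% cross_set
    m$cross_antigen_hit <- m$id %in% unique(mt$id[bad])
  }

  if (is.null(glew_flags)) glew_flags <- setNames(rep(NA, nrow(m)), m$id)
  if (is.null(names(glew_flags)))
    stop("glew_flags must be a named logical vector keyed by sequence id")
  gf <- glew_flags[m$id]
  m$glew_hit <- !is.na(gf) & gf           # indeterminate never removes
  m$glew_indeterminate <- is.na(gf)
  m$selected <- !m$glew_hit & !m$cross_antigen_hit & !m$no_unique_peptide
  report$members <- m
  report$uniqueness <- uniq
  report$matches <- mt
  report$params <- list(uniqueness_threshold = uniqueness_threshold,
                        il_equivalent = il_equivalent)
  report
}

#' Evidence table for manual spectral review
#'
#' For each selected candidate, lists its CDR3-spanning matched peptides
#' with uniqueness scores and spans, ordered for MS/MS fragmentation
#' review (the spectra themselves are not inspected here).
#'
#' @param report a filtered `candidate_report`.
#' @return data.frame with `id`, `group_id`, `peptide`, `start`, `end`,
#'   `uniqueness`; candidates with no CDR3-spanning peptide are reported
#'   with a warning.
#' @export
evidence_summary <- function(report) {
  if (is.null(report$matches))
    stop("run apply_filters() before evidence_summary()")
  m <- report$members
  sel <- m$id[m$selected]
  mt <- report$matches
  c3s <- m$cdr3_start[match(mt$id, m$id)]
  c3e <- m$cdr3_end[match(mt$id, m$id)]
  keep <- mt$id %in% sel & !is.na(c3s) & mt$start <= c3e & mt$end >= c3s
  ev <- mt[keep, c("id", "group_id", "peptide", "start", "end", "uniqueness")]
  ev <- ev[order(match(ev$id, m$id), -ev$uniqueness, ev$peptide), , drop = FALSE]
  rownames(ev) <- NULL
  none <- setdiff(sel, unique(ev$id))
  if (length(none) > 0)
    warning(length(none), " selected candidate(s) have no CDR3-spanning ",
            "peptide evidence: ", paste(head(none, 3), collapse = ", "))
  ev
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report> %d CDR3 groups, %d sequences\n",
              nrow(x$groups), nrow(x$members)))
  if (!is.null(x$members$selected))
    cat(sprintf("  selected candidates: %d (uniqueness > %s)\n",
                sum(x$members$selected), x$params$uniqueness_threshold))
  top <- utils::head(x$groups, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  #%d %s score=%.1f reads=%d cdr3=%s\n", top$rank[i],
                top$group_id[i], top$group_score[i], top$total_count[i],
                top$cdr3[i]))
  invisible(x)
}
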