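# Candidate report serialization (TSV and JSON dialects).

.REPORT_COLS <- c("group_rank", "group_id", "cdr3", "group_score",
                  "rank_in_group", "id", "count", "score", "cdr3_covered",
                  "max_uniqueness", "glew_hit", "cross_antigen_hit",
                  "no_unique_peptide", "selected")

flatten_report <- function(report) {
  m <- report$members
  g <- report$groups
  for (col in c("max_uniqueness", "glew_hit", "cross_antigen_hit",
                "no_unique_peptide", "selected"))
    if (is.null(m[[col]])) m[[col]] <- NA
  out <- data.frame(
    group_rank = g$rank[match(m$group_id, g$group_id)],
    group_id = m$group_id, cdr3 = m$cdr3,
    group_score = g$group_score[match(m$group_id, g$group_id)],
    rank_in_group = m$rank_in_group, id = m$id, count = m$count,
    score = m$score, cdr3_covered = m$cdr3_covered,
    max_uniqueness = m$max_uniqueness, glew_hit = m$glew_hit,
    cross_antigen_hit = m$cross_antigen_hit,
    no_unique_peptide = m$no_unique_peptide, selected = m$selected,
    stringsAsFactors = FALSE
  )
  out[order(out$group_rank, out$rank_in_group), .REPORT_COLS]
}

#' Write a candidate report to TSV or JSON
#'
#' Column order is fixed and rows follow group rank then within-group rank,
#' so output is byte-stable for identical input. The JSON dialect nests
#' members and per-peptide uniqueness evidence inside each group and
#' round-trips through [read_candidate_report()].
#'
#' @param report a `candidate_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- flatten_report(report)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    write.table(format(flat, digits = 6, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- report$groups
  groups <- lapply(seq_len(nrow(g)), function(i) {
    gm <- flat[flat$group_id == g$group_id[i], , drop = FALSE]
    members <- lapply(seq_len(nrow(gm)), function(j) as.list(gm[j, setdiff(names(gm), c("group_rank", "group_id", "cdr3", "group_score"))]))
    u <- report$uniqueness
    ev <- if (!is.null(u)) {
      ug <- u[u$group_id == g$group_id[i], c("peptide", "n_group", "n_db", "uniqueness"), drop = FALSE]
      lapply(seq_len(nrow(ug)), function(j) as.list(ug[j, ]))
    } else list()
    list(rank = g$rank[i], group_id = g$group_id[i], cdr3 = g$cdr3[i],
         group_score = g$group_score[i], total_count = g$total_count[i],
         members = members, uniqueness = ev)
  })
  jsonlite::write_json(list(groups = groups,
                            params = report$params %||% NULL),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read back a JSON candidate report
#'
#' @param path path written by [write_candidate_report()] with
#'   `format = "json"`.
#' @return a `candidate_report` (groups, members, uniqueness tables).
#' @export
read_candidate_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  g <- x$groups
  groups <- data.frame(group_id = g$group_id, cdr3 = g$cdr3,
                       group_score = g$group_score,
                       total_count = g$total_count, rank = g$rank,
                       stringsAsFactors = FALSE)
  members <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    m <- g$members[[i]]
    m$group_id <- g$group_id[i]
    m$cdr3 <- g$cdr3[i]
    m
  }))
  uniq <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    u <- g$uniqueness[[i]]
    if (is.null(u) || length(u) == 0 || NROW(u) == 0) return(NULL)
    u$group_id <- g$group_id[i]
    u
  }))
  structure(list(groups = groups, members = members, uniqueness = uniq,
                 params = x$params),
            class = "candidate_report")
}
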