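# End-to-end orchestration: reads -> database -> annotation -> mapping ->
# ranked, filtered candidate report; plus the recovery experiment used to
# validate the whole pipeline on simulated ground truth.

#' Run the candidate-identification pipeline on in-memory inputs
#'
#' Merges pairs (unless pre-merged amplicons are given), builds the
#' deduplicated translated database, annotates CDRs, maps the observed
#' peptides, scores, groups by CDR3, ranks, and applies the selection
#' filters.
#'
#' @param pairs read-pair data.frame ([read_fastq_pairs()]), or `NULL`.
#' @param merged pre-merged amplicon sequences (character), or `NULL`.
#' @param observations peptide observation data.frame.
#' @param cross_antigen named list of peptide observation data.frames (or
#'   peptide character vectors) from unrelated antigens.
#' @param fwd_primers,rev_primers primer lists (default [builtin_primers()]).
#' @param cfg_anchors an [anchor_config()].
#' @param weights coverage weights ([coverage_weights()]).
#' @param uniqueness_threshold strict selection threshold (default 80).
#' @param group_mode `"exact"` or `"cluster"`.
#' @param il_equivalent I/L equivalence flag (default `TRUE`).
#' @param min_overlap,max_overlap_mismatch_frac pair-merging parameters.
#' @param max_mismatch_frac primer mismatch tolerance.
#' @param frame_offset bases between forward-primer end and codon 1.
#' @return a list of class `nanomatch_result`: `report`
#'   (`candidate_report`), `db`, `ann`, `evidence`, `rejects`,
#'   `merge_stats`.
#' @export
run_pipeline <- function(pairs = NULL, merged = NULL, observations,
                         cross_antigen = list(),
                         fwd_primers = NULL, rev_primers = NULL,
                         cfg_anchors = anchor_config(),
                         weights = coverage_weights(),
                         uniqueness_threshold = 80,
                         group_mode = "exact", il_equivalent = TRUE,
                         min_overlap = 20L, max_overlap_mismatch_frac = 0.1,
                         max_mismatch_frac = 0.2, frame_offset = 0L) {
  p <- builtin_primers()
  if (is.null(fwd_primers)) fwd_primers <- list(p$call001)
  if (is.null(rev_primers)) rev_primers <- list(p$lh_rev, p$sh_rev)

  merge_stats <- NULL
  if (is.null(merged)) {
    if (is.null(pairs)) stop("supply either read pairs or merged amplicons")
    mg <- merge_pairs(pairs, min_overlap, max_overlap_mismatch_frac)
    merge_stats <- table(mg$status)
    merged <- mg$seq[mg$status == "ok"]
  }
  built <- build_vhh_db(merged, fwd_primers, rev_primers, frame_offset,
                        max_mismatch_frac)
  db <- built$db
  if (nrow(db) == 0) stop("no amplicon yielded a usable VHH sequence")
  ann <- annotate_regions(db$protein, cfg_anchors)
  mp <- map_peptides(observations, db, il_equivalent)
  scores <- coverage_score(db, ann, mp$matches, weights)
  groups <- group_by_cdr3(db, ann, group_mode, il_equivalent = il_equivalent)
  report <- rank_candidates(groups, scores, db, ann)
  glew <- vapply(seq_len(nrow(db)), function(i) {
    if (ann$confidence[i] == "failed") return(NA)
    has_vh_hallmark(db$protein[i], imgt_positions(db$protein[i],
                                                  ann[i, , drop = FALSE]))
  }, FUN.VALUE = NA)
  names(glew) <- db$id
  cross_peps <- lapply(cross_antigen, function(x) {
    if (is.data.frame(x)) x$peptide else x
  })
  report <- apply_filters(report, mp$matches, groups, cross_peps,
                          uniqueness_threshold, glew, il_equivalent)
  evidence <- suppressWarnings(evidence_summary(report))
  structure(list(report = report, db = db, ann = ann, evidence = evidence,
                 rejects = built$rejects, merge_stats = merge_stats,
                 unmatched = mp$unmatched),
            class = "nanomatch_result")
}

#' @export
print.nanomatch_result <- function(x, ...) {
  cat("== nanomatch pipeline result ==\n")
  print(x$db)
  print(x$report)
  invisible(x)
}

#' Run the full simulated-study pipeline for one seed
#'
#' Simulates a repertoire, reads and peptide observations under `cfg`,
#' runs [run_pipeline()] on them, and reports where the true binder
#' clonotypes ranked.
#'
#' @param cfg a [sim_config()].
#' @param ... passed to [run_pipeline()].
#' @return list with `result` (`nanomatch_result`), `truth`, `binder_ranks`
#'   (group rank of each true binder CDR3; `NA` if absent), and
#'   `selected_ids`.
#' @export
run_simulated_study <- function(cfg, ...) {
  truth <- simulate_repertoire(cfg)
  reads <- simulate_reads(truth, cfg)
  ms <- simulate_peptides(truth, cfg)
  res <- run_pipeline(pairs = reads$pairs, observations = ms$observations,
                      cross_antigen = list(unrelated = ms$cross_antigen),
                      ...)
  bi <- match(truth$binder_ids, truth$clones$clone_id)
  bkey <- il_collapse(substr(truth$clones$protein[bi],
                             truth$clones$cdr3_start[bi],
                             truth$clones$cdr3_end[bi]))
  # locate each binder group via its exact protein when present in the
  # database (robust to cluster-mode representative keys), falling back
  # to the CDR3 key
  bid <- res$db$id[match(truth$clones$protein[bi], res$db$protein)]
  bgrp <- res$report$members$group_id[match(bid, res$report$members$id)]
  ranks <- res$report$groups$rank[match(bgrp, res$report$groups$group_id)]
  miss <- is.na(ranks)
  if (any(miss))
    ranks[miss] <- res$report$groups$rank[match(bkey[miss],
                                                res$report$groups$cdr3)]
  list(result = res, truth = truth, ms = ms,
       binder_cdr3 = bkey, binder_ranks = ranks,
       selected_ids = res$report$members$id[res$report$members$selected])
}

#' Binder-recovery experiment over many seeds
#'
#' The validation workhorse: for each seed, a full simulated study is run
#' and the experiment records whether every true binder CDR3 group ranked
#' within the top `top_k` groups. Grouping defaults to similarity
#' clustering here (the pipeline's own way of pooling sequencing-error
#' CDR3 variants with their parent clonotype).
#'
#' @param n_seeds number of independent runs (default 20).
#' @param base_seed first seed; run `i` uses `base_seed + i - 1`.
#' @param top_k rank cutoff (default 5).
#' @param cfg_fn function(seed) returning the [sim_config()] for one run;
#'   defaults to the standard study conditions.
#' @param group_mode CDR3 grouping mode for the runs (default `"cluster"`).
#' @return data.frame with `seed`, `all_in_top_k`, `worst_rank`,
#'   `n_groups`, `n_selected`.
#' @export
recovery_experiment <- function(n_seeds = 20L, base_seed = 1L, top_k = 5L,
                                cfg_fn = function(seed) sim_config(seed = seed),
                                group_mode = "cluster") {
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i - 1L
    st <- run_simulated_study(cfg_fn(seed), group_mode = group_mode)
    data.frame(seed = seed,
               all_in_top_k = !anyNA(st$binder_ranks) &&
                 all(st$binder_ranks <= top_k),
               worst_rank = if (anyNA(st$binder_ranks)) NA_integer_
                            else max(st$binder_ranks),
               n_groups = nrow(st$result$report$groups),
               n_selected = length(st$selected_ids))
  })
  do.call(rbind, rows)
}

file_digest <- function(paths) {
  vapply(paths, function(p) {
    if (!file.exists(p)) return(NA_character_)
    unname(tools::md5sum(p))
  }, FUN.VALUE = "")
}

#' Build a machine-readable run manifest
#'
#' @param params fully resolved parameter list.
#' @param inputs named character vector of input file paths.
#' @param seed the run seed (or `NA`).
#' @return a list (`tool`, `version`, `timestamp`, `seed`, `params`,
#'   `inputs` with md5 digests).
#' @export
run_manifest <- function(params, inputs = character(0), seed = NA_integer_) {
  list(tool = "nanomatch",
       version = as.character(utils::packageVersion("nanomatch")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       params = params,
       inputs = if (length(inputs)) {
         data.frame(path = unname(inputs), md5 = unname(file_digest(inputs)),
                    stringsAsFactors = FALSE)
       } else NULL)
}

#' Run the whole pipeline from a configuration file
#'
#' The YAML configuration has per-stage sections (`inputs`, `merge`,
#' `primers`, `rank`); unknown keys are rejected. Outputs (report TSV +
#' JSON, manifest JSON) are written under `outdir`. Any stage failure
#' aborts with the failing stage named and leaves a `FAILED` marker file.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outdir output directory (created if needed).
#' @param seed optional integer seed recorded in the manifest.
#' @return the `nanomatch_result`, invisibly.
#' @export
run_all <- function(config, outdir = ".", seed = NA_integer_) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  allowed <- c("inputs", "merge", "primers", "rank")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("config schema violation; unknown section(s): ",
         paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outdir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inp <- cfg$inputs %||% list()
  pairs <- NULL; merged <- NULL
  if (!is.null(inp$r1)) {
    pairs <- stage("read-input", read_fastq_pairs(inp$r1, inp$r2))
  } else if (!is.null(inp$merged)) {
    merged <- stage("read-input", read_fasta(inp$merged, alphabet = "dna")$seq)
  } else stop("pipeline stage 'read-input' failed: config gives neither ",
              "inputs$r1/r2 nor inputs$merged", call. = FALSE)
  obs <- stage("rank", {
    if (is.null(inp$peptides))
      stop("inputs$peptides is required")
    do.call(rbind, lapply(inp$peptides, read_peptide_table))
  })
  cross <- stage("rank", {
    ca <- inp$cross_antigen %||% list()
    setNames(lapply(ca, read_peptide_table), names(ca) %||% NULL)
  })
  primers <- if (!is.null(cfg$primers$file)) {
    stage("primers", read_primer_table(cfg$primers$file))
  } else NULL
  fwd <- rev <- NULL
  if (!is.null(primers)) {
    ori <- vapply(primers, `[[`, "", "orientation")
    fwd <- primers[ori == "forward"]
    rev <- primers[ori == "reverse"]
  }
  mrg <- cfg$merge %||% list()
  rnk <- cfg$rank %||% list()
  res <- stage("pipeline", run_pipeline(
    pairs = pairs, merged = merged, observations = obs,
    cross_antigen = cross, fwd_primers = fwd, rev_primers = rev,
    uniqueness_threshold = rnk$uniqueness_threshold %||% 80,
    group_mode = rnk$group_mode %||% "exact",
    min_overlap = mrg$min_overlap %||% 20L,
    max_overlap_mismatch_frac = mrg$max_overlap_mismatch_frac %||% 0.1,
    max_mismatch_frac = cfg$primers$max_mismatch_frac %||% 0.2,
    frame_offset = cfg$primers$frame_offset %||% 0L))
  stage("write-output", {
    write_candidate_report(res$report, file.path(outdir, "report.tsv"), "tsv")
    write_candidate_report(res$report, file.path(outdir, "report.json"), "json")
    manifest <- run_manifest(cfg, inputs = unlist(inp, use.names = FALSE),
                             seed = seed)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(res)
}
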