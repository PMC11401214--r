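# Repertoire-wide primer-coverage survey and flanking-region diversity.

#' Survey how well a primer covers a sequence population
#'
#' For each target the best annealing-site match within the mismatch
#' tolerance is extracted as that target's site variant. Variants are
#' tallied and then greedily merged in descending abundance: each variant
#' is absorbed into the most abundant already-kept variant within Hamming
#' distance `merge_radius`, otherwise kept as a new variant until `top_n`
#' variants are kept (later unmergeable variants are dropped). Coverage is
#' the merged abundance of the kept variants divided by the number of
#' targets with any within-tolerance site.
#'
#' @param targets character vector of DNA sequences (e.g. cDNA reads).
#' @param probe a [primer_def()]; reverse probes are searched on the
#'   reverse complement of each target.
#' @param max_mismatch_frac fractional mismatch tolerance (default 0.2).
#' @param top_n number of site variants to keep (default 10).
#' @param merge_radius Hamming radius for absorbing minor variants
#'   (default 1).
#' @return a list of class `primer_survey`: `variants` (data.frame
#'   `variant`, `abundance`, `mean_mismatch`), `coverage` (percent, `NA`
#'   when no target has a site), `n_with_site`, `n_targets`, `flagged`.
#' @export
primer_coverage_survey <- function(targets, probe, max_mismatch_frac = 0.2,
                                   top_n = 10L, merge_radius = 1L) {
  stopifnot(top_n >= 1L, merge_radius >= 0L)
  targets <- toupper(targets)
  subject <- if (probe$orientation == "reverse") revcomp(targets) else targets
  budget <- mismatch_budget(probe, max_mismatch_frac)
  hits <- scan_targets(subject, probe$annealing_seq, budget)
  has_site <- !is.na(hits$pos)
  n_with_site <- sum(has_site)
  if (n_with_site == 0) {
    out <- list(variants = data.frame(variant = character(),
                                      abundance = integer(),
                                      mean_mismatch = numeric()),
                coverage = NA_real_, n_with_site = 0L,
                n_targets = length(targets), flagged = TRUE)
    class(out) <- "primer_survey"
    return(out)
  }
  plen <- nchar(probe$annealing_seq)
  site <- substr(subject[has_site], hits$pos[has_site],
                 hits$pos[has_site] + plen - 1L)
  mm <- hits$mismatches[has_site]
  tab <- tapply(rep(1L, length(site)), site, sum)
  mm_tab <- tapply(mm, site, sum)
  ord <- order(-tab, names(tab))
  variants <- names(tab)[ord]
  abund <- as.integer(tab[ord])
  mm_sum <- as.numeric(mm_tab[ord])

  kept <- integer(0)          # indices into `variants`
  kept_ab <- integer(0)
  kept_mm <- numeric(0)
  for (i in seq_along(variants)) {
    merged <- FALSE
    if (length(kept) > 0 && merge_radius >= 0) {
      d <- .cpp_hamming(variants[kept], variants[i])
      ok <- which(!is.na(d) & d <= merge_radius)
      if (length(ok) > 0) {
        j <- ok[which.max(kept_ab[ok])]   # most abundant kept variant
        kept_ab[j] <- kept_ab[j] + abund[i]
        kept_mm[j] <- kept_mm[j] + mm_sum[i]
        merged <- TRUE
      }
    }
    if (!merged && length(kept) < top_n) {
      kept <- c(kept, i)
      kept_ab <- c(kept_ab, abund[i])
      kept_mm <- c(kept_mm, mm_sum[i])
    }
  }
  vdf <- data.frame(variant = variants[kept], abundance = kept_ab,
                    mean_mismatch = kept_mm / kept_ab,
                    stringsAsFactors = FALSE)
  vdf <- vdf[order(-vdf$abundance, vdf$variant), , drop = FALSE]
  rownames(vdf) <- NULL
  out <- list(variants = vdf,
              coverage = 100 * sum(kept_ab) / n_with_site,
              n_with_site = n_with_site, n_targets = length(targets),
              flagged = FALSE)
  class(out) <- "primer_survey"
  out
}

#' @export
print.primer_survey <- function(x, ...) {
  if (x$flagged) {
    cat("<primer_survey> no within-tolerance site in any of", x$n_targets,
        "targets (coverage undefined)\n")
    return(invisible(x))
  }
  cat(sprintf("<primer_survey> coverage %.1f%% (%d kept variants; %d/%d targets with a site)\n",
              x$coverage, nrow(x$variants), x$n_with_site, x$n_targets))
  print(utils::head(x$variants, 10))
  invisible(x)
}

#' Unique flanking sequences adjacent to a primer anchor
#'
#' Extracts a fixed-width window next to each target's anchor hit (e.g. the
#' FR4 region adjacent to a hinge primer site) and tallies the unique
#' strings, supporting diversity comparisons between primer sets.
#'
#' @param targets character vector of DNA sequences.
#' @param positions integer vector: 1-based start of the anchor site in each
#'   target.
#' @param anchor_len length of the anchor site.
#' @param window width of the flank to extract.
#' @param side `"left"` (5' of the anchor) or `"right"` (3' of it).
#' @return a list with `flanks` (data.frame `flank`, `count`) and
#'   `n_skipped` (targets whose window exceeded the sequence bounds).
#' @export
flanking_region_diversity <- function(targets, positions, anchor_len,
                                      window, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(length(targets) == length(positions), window >= 0L)
  if (side == "left") {
    start <- positions - window
    end <- positions - 1L
  } else {
    start <- positions + anchor_len
    end <- positions + anchor_len + window - 1L
  }
  ok <- start >= 1L & end <= nchar(targets) & !is.na(positions)
  if (window == 0L) {
    start <- pmin(pmax(start, 1L), nchar(targets) + 1L)
    end <- start - 1L
    ok <- !is.na(positions)
  }
  flank <- substr(targets[ok], start[ok], end[ok])
  tab <- sort(table(flank), decreasing = TRUE)
  list(flanks = data.frame(flank = names(tab), count = as.integer(tab),
                           stringsAsFactors = FALSE),
       n_skipped = sum(!ok))
}
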