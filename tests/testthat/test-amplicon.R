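# Pair merging, fuzzy primer location, ORF extraction, dedup, survey.

test_that("merge_read_pair obeys the length identity and consensus rules", {
  # r1 of length 8; r2's reverse complement shares its last 4 bases
  r1 <- "AACCGGTT"
  r2rc <- "GGTTACGT"      # overlap 4 with r1 suffix "GGTT"
  r2 <- revcomp(r2rc)
  m <- merge_read_pair(r1, strrep("I", 8), r2, strrep("I", 8), min_overlap = 4)
  expect_equal(m$status, "ok")
  expect_equal(m$overlap_len, 4L)
  expect_equal(nchar(m$seq), 8L + 8L - 4L)
  expect_equal(m$seq, "AACCGGTTACGT")
  expect_equal(m$conflict_count, 0L)

  # identical full-length reads merge to themselves
  m2 <- merge_read_pair(r1, strrep("I", 8), revcomp(r1), strrep("I", 8),
                        min_overlap = 4)
  expect_equal(m2$seq, r1)
  expect_equal(m2$overlap_len, nchar(r1))

  # failure is a value
  m3 <- merge_read_pair("AAAAAAAA", strrep("I", 8), "AAAAAAAA", strrep("I", 8),
                        min_overlap = 20)
  expect_equal(m3$status, "no_overlap")
  expect_true(is.na(m3$seq))
})

test_that("overlap conflicts resolve by quality, ties to read 1", {
  base <- random_dna_str(40)
  r1 <- substr(base, 1, 30)
  r2rc_true <- substr(base, 11, 40)
  # introduce a conflict at overlap position: r2 disagrees at base 15
  r2rc_chars <- strsplit(r2rc_true, "")[[1]]
  pos_in_r2 <- 5L  # corresponds to base 15 of the merged sequence
  r2rc_chars[pos_in_r2] <- setdiff(c("A", "C", "G", "T"), r2rc_chars[pos_in_r2])[1]
  r2rc <- paste(r2rc_chars, collapse = "")

  hiq <- strrep("I", 30); loq <- strrep("5", 30)
  # r2 higher quality -> r2's base wins
  m <- merge_read_pair(r1, loq, revcomp(r2rc), hiq, min_overlap = 10)
  expect_equal(m$conflict_count, 1L)
  expect_equal(substr(m$seq, 15, 15), r2rc_chars[pos_in_r2])
  # equal quality -> r1 base kept
  m2 <- merge_read_pair(r1, hiq, revcomp(r2rc), hiq, min_overlap = 10)
  expect_equal(substr(m2$seq, 15, 15), substr(base, 15, 15))
})

test_that("chosen overlap maximizes length within the mismatch budget", {
  set.seed(42)
  for (rep in 1:25) {
    amp <- random_dna_str(60)
    r1 <- substr(amp, 1, 40)
    r2rc <- substr(amp, 21, 60)
    m <- merge_read_pair(r1, strrep("I", 40), revcomp(r2rc), strrep("I", 40),
                         min_overlap = 5, max_overlap_mismatch_frac = 0)
    # oracle: enumerate all ungapped offsets, keep longest exact overlap
    best <- 0L
    for (ov in 5:40) {
      if (substr(r1, 41 - ov, 40) == substr(r2rc, 1, ov)) best <- max(best, ov)
    }
    expect_equal(m$overlap_len, best)
    expect_equal(nchar(m$seq), 40L + 40L - m$overlap_len)
  }
})

test_that("a 23-base primer at 20% tolerance allows exactly 5 mismatches", {
  p <- builtin_primers()
  expect_equal(nchar(p$call001$annealing_seq), 23L)
  expect_equal(mismatch_budget(p$call001, 0.2), 5L)
})

test_that("find_primer locates exact, degenerate and reverse-strand sites", {
  p <- primer_def("p", "ACGT", "forward")
  h <- find_primer("TTACGTTT", p)
  expect_equal(h$position, 3L)  # 1-based
  expect_equal(h$mismatches, 0L)

  # Y matches both C and T with zero mismatches
  py <- primer_def("py", "AYGT", "forward")
  expect_equal(find_primer("TTACGTTT", py)$mismatches, 0L)
  expect_equal(find_primer("TTATGTTT", py)$mismatches, 0L)

  # reverse primer reported in plus-strand coordinates
  pr <- primer_def("pr", "ACGT", "reverse")
  target <- paste0("GGG", revcomp("ACGT"), "TT")
  h <- find_primer(target, pr)
  expect_equal(h$position, 4L)
  expect_equal(h$strand, "-")

  expect_null(find_primer("AAAAAAAA", p, max_mismatch_frac = 0))
})

test_that("find_primer equals the exhaustive Hamming scan oracle", {
  set.seed(7)
  codes <- c("A", "C", "G", "T", "Y", "R", "N", "W")
  for (i in 1:200) {
    target <- random_dna_str(sample(25:200, 1))
    plen <- sample(5:23, 1)
    pattern <- paste(sample(codes, plen, replace = TRUE, prob = c(rep(5, 4), 1, 1, 1, 1)),
                     collapse = "")
    frac <- sample(c(0, 0.1, 0.2), 1)
    p <- primer_def("p", pattern, "forward")
    got <- find_primer(target, p, frac)
    want <- oracle_best_hit(target, pattern, ceiling(frac * plen - 1e-9))
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$position, want$pos)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("extract_and_translate picks the ORF between the primer sites", {
  p <- builtin_primers()
  # hand-checkable codons: GTG CAG CTG CAG GAG -> VQLQE (plus padding to
  # pass the length window via a template protein)
  tp <- template_protein()
  dna <- nanomatch:::reverse_translate(tp$protein)
  site_f <- sub("Y", "C", p$call001$annealing_seq)
  amp <- paste0("ACGTAC", site_f, dna, revcomp(p$sh_rev$annealing_seq), "TTACGA")
  res <- extract_and_translate(amp, list(p$call001), list(p$lh_rev, p$sh_rev))
  expect_equal(nrow(res$drafts), 1L)
  expect_equal(res$drafts$protein, tp$protein)
  expect_equal(res$drafts$hinge, "short_hinge_IgG3")
  # emitted record re-translates exactly
  expect_equal(nanomatch:::translate_dna(res$drafts$dna), res$drafts$protein)

  # standard-code translation spot check
  expect_equal(nanomatch:::translate_dna("GTGCAGCTGCAGGAG"), "VQLQE")

  # internal stop codon -> tallied rejection (replace codon 10 in frame)
  bad_dna <- paste0(substr(dna, 1, 27), "TAA", substr(dna, 31, nchar(dna)))
  amp2 <- paste0("ACGTAC", site_f, bad_dna, revcomp(p$sh_rev$annealing_seq), "TT")
  res2 <- extract_and_translate(amp2, list(p$call001), list(p$sh_rev))
  expect_equal(nrow(res2$drafts), 0L)
  expect_equal(unname(res2$rejects["internal_stop"]), 1L)

  # no forward primer site
  res3 <- extract_and_translate(random_dna_str(400), list(p$call001),
                                list(p$sh_rev), max_mismatch_frac = 0)
  expect_equal(unname(res3$rejects["no_forward"]), 1L)

  # unknown hinge via fallback reverse anchor
  fb <- primer_def("fallback", "GGCCGGAATTCCGGAA", "reverse")
  amp3 <- paste0("ACGTAC", site_f, dna, revcomp("GGCCGGAATTCCGGAA"), "TT")
  res4 <- extract_and_translate(amp3, list(p$call001), list(p$sh_rev),
                                fallback_rev = fb)
  expect_equal(res4$drafts$hinge, "unknown")
})

test_that("dedup_and_count conserves support and picks majority DNA", {
  tp1 <- template_protein(cdr3 = "ARDAYWGQS")$protein
  tp2 <- template_protein(cdr3 = "ARHPYYEDS")$protein
  dna1a <- nanomatch:::reverse_translate(tp1)
  # synonymous variant of the same protein (wobble base of codon 3, Val)
  dna1b <- paste0(substr(dna1a, 1, 8), "C", substr(dna1a, 10, nchar(dna1a)))
  stopifnot(dna1a != dna1b,
            nanomatch:::translate_dna(dna1b) == tp1)
  drafts <- data.frame(
    protein = c(tp1, tp1, tp1, tp2),
    dna = c(dna1a, dna1a, dna1b, nanomatch:::reverse_translate(tp2)),
    hinge = "short_hinge_IgG3", count = 1L)
  db <- dedup_and_count(drafts)
  expect_equal(nrow(db), 2L)
  expect_equal(sum(db$count), 4L)          # conservation
  expect_equal(db$count, c(3L, 1L))        # sorted by count desc
  expect_equal(db$dna[db$protein == tp1], dna1a)  # majority variant
  expect_match(db$id, "^vhh_[0-9a-f]{16}$")

  # all distinct -> all counts 1
  dd <- data.frame(protein = c(tp1, tp2), dna = c(dna1a, dna1b),
                   hinge = "unknown", count = 1L)
  expect_equal(dedup_and_count(dd)$count, c(1L, 1L))
})

test_that("primer survey tallies, merges and computes coverage", {
  probe <- primer_def("probe", "ACGTACGTACGTACG", "forward")  # budget 3
  site <- "ACGTACGTACGTACG"
  flank <- function(core) paste0(random_dna_str(10), core, random_dna_str(10))
  set.seed(1)
  # 9 targets share the exact site, 1 differs by 3 bases (within tolerance,
  # outside the merge radius)
  off3 <- "ACCTACATACGTACT"
  stopifnot(sum(strsplit(site, "")[[1]] != strsplit(off3, "")[[1]]) == 3)
  targets <- c(replicate(9, flank(site)), flank(off3))
  sv <- primer_coverage_survey(targets, probe, top_n = 1, merge_radius = 1)
  expect_equal(sv$coverage, 90)            # 9/10
  expect_equal(sv$n_with_site, 10L)

  # all identical -> one variant, 100%
  sv2 <- primer_coverage_survey(replicate(5, flank(site)), probe)
  expect_equal(sv2$coverage, 100)
  expect_equal(nrow(sv2$variants), 1L)

  # one-mismatch variant merges into the top variant (radius 1)
  off1 <- "ACCTACGTACGTACG"
  sv3 <- primer_coverage_survey(c(replicate(6, flank(site)), flank(off1)),
                                probe, top_n = 1, merge_radius = 1)
  expect_equal(sv3$coverage, 100)
  expect_equal(sv3$variants$abundance, 7L)
  expect_gt(sv3$variants$mean_mismatch, 0)

  # no site anywhere -> flagged, coverage undefined
  sv4 <- primer_coverage_survey(replicate(3, random_dna_str(30)), probe,
                                max_mismatch_frac = 0)
  expect_true(sv4$flagged)
  expect_true(is.na(sv4$coverage))
})

test_that("survey coverage is monotone in top_n and merge_radius", {
  probe <- primer_def("probe", "ACGTACGTACGT", "forward")
  set.seed(9)
  targets <- vapply(1:60, function(i) {
    core <- strsplit("ACGTACGTACGT", "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) { pos <- sample(12, k); core[pos] <- sample(c("A","C","G","T"), k, replace = TRUE) }
    paste0(random_dna_str(8), paste(core, collapse = ""), random_dna_str(8))
  }, "")
  cov <- function(tn, mr) primer_coverage_survey(targets, probe, top_n = tn,
                                                 merge_radius = mr)$coverage
  for (mr in 0:2) {
    covs <- vapply(1:6, cov, 0, mr = mr)
    expect_true(all(diff(covs) >= -1e-9))
  }
  for (tn in c(1L, 3L)) {
    covs <- vapply(0:3, function(mr) cov(tn, mr), 0)
    expect_true(all(diff(covs) >= -1e-9))
  }
})

test_that("flanking diversity matches set operations on constructed data", {
  targets <- c(rep("AAACCCGGGTTT", 3))
  fr <- flanking_region_diversity(targets, positions = rep(7L, 3),
                                  anchor_len = 3L, window = 3L, side = "left")
  expect_equal(fr$flanks$flank, "CCC")
  expect_equal(fr$flanks$count, 3L)

  # window 0 -> single empty flank
  fr0 <- flanking_region_diversity(targets, rep(7L, 3), 3L, 0L, "left")
  expect_equal(fr0$flanks$flank, "")
  expect_equal(fr0$flanks$count, 3L)

  # out-of-bounds windows are skipped and tallied
  fr2 <- flanking_region_diversity(c("AAGGT", "CCCCCCAAGGT"), c(3L, 9L), 2L,
                                   4L, "left")
  expect_equal(fr2$n_skipped, 1L)
  expect_equal(fr2$flanks$flank, "CCAA")

  # two primer sets on one repertoire: overlap equals set intersection
  set.seed(5)
  reps <- vapply(1:30, function(i) random_dna_str(40), "")
  fA <- flanking_region_diversity(reps, rep(11L, 30), 5L, 6L, "left")
  fB <- flanking_region_diversity(reps, rep(13L, 30), 5L, 6L, "left")
  manualA <- unique(substr(reps, 5, 10))
  manualB <- unique(substr(reps, 7, 12))
  expect_setequal(fA$flanks$flank, manualA)
  expect_setequal(fB$flanks$flank, manualB)
  expect_setequal(intersect(fA$flanks$flank, fB$flanks$flank),
                  intersect(manualA, manualB))
})
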