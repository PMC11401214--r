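# Peptide mapping, coverage scoring, CDR3 grouping, uniqueness, ranking,
# filters.

make_scored_db <- function(cdr3s, counts = NULL) {
  prots <- vapply(cdr3s, function(c3) template_protein(cdr3 = c3)$protein, "")
  db <- tiny_db(prots, counts = counts)
  ann <- annotate_regions(db$protein)
  list(db = db, ann = ann)
}

test_that("map_peptides handles I/L equivalence and reports spans", {
  x <- make_scored_db(c("ARNIKDYWS", "ARNLKDYWS", "GGHDSTWYE"))
  db <- x$db
  # NIK vs NLK: match only under I/L equivalence
  hits_il <- map_peptides("ARNIK", db, il_equivalent = TRUE)
  hits_exact <- map_peptides("ARNIK", db, il_equivalent = FALSE)
  expect_equal(length(unique(hits_il$matches$id)), 2L)
  expect_equal(length(unique(hits_exact$matches$id)), 1L)
  # spans point at the real occurrence
  m <- hits_exact$matches
  expect_equal(substr(db$protein[db$id == m$id[1]], m$start[1], m$end[1]),
               "ARNIK")
  # unmatched peptides are retained
  res <- map_peptides(c("WWWWWW", "ARNIK"), db)
  expect_equal(res$unmatched, "WWWWWW")
})

test_that("map_peptides equals the brute-force double loop on random data", {
  set.seed(21)
  prots <- vapply(1:30, function(i) random_aa_str(sample(40:90, 1)), "")
  db <- tiny_db(unique(prots))
  peptides <- unique(c(
    vapply(1:25, function(i) {
      p <- sample(db$protein, 1)
      s <- sample(nchar(p) - 8, 1)
      substr(p, s, s + sample(5:8, 1))
    }, ""),
    vapply(1:10, function(i) random_aa_str(7), "")))
  for (il in c(TRUE, FALSE)) {
    got <- unique(map_peptides(peptides, db, il)$matches[, c("peptide", "id")])
    want <- oracle_match_table(peptides, db, il)
    got_key <- sort(paste(got$peptide, got$id))
    want_key <- sort(paste(want$peptide, want$id))
    expect_identical(got_key, want_key)
  }
})

test_that("coverage score normalizes to 0-100 and weights CDR3 most", {
  x <- make_scored_db("ARDPSYYRGSY")
  db <- x$db; ann <- x$ann
  L <- nchar(db$protein)
  # every residue covered -> 100 regardless of weights
  full <- data.frame(peptide = "full", id = db$id, start = 1L, end = L)
  expect_equal(coverage_score(db, ann, full)$score, 100)
  # no residue covered -> 0
  none <- full[0, ]
  expect_equal(coverage_score(db, ann, none)$score, 0)
  # only CDR3 covered -> hand-computed weighted fraction
  c3 <- data.frame(peptide = "c3", id = db$id,
                   start = ann$cdr3_start, end = ann$cdr3_end)
  sc <- coverage_score(db, ann, c3)
  w <- coverage_weights()
  rlen <- c(fr1 = ann$fr1_end - ann$fr1_start + 1L,
            cdr1 = ann$cdr1_end - ann$cdr1_start + 1L,
            fr2 = ann$fr2_end - ann$fr2_start + 1L,
            cdr2 = ann$cdr2_end - ann$cdr2_start + 1L,
            fr3 = ann$fr3_end - ann$fr3_start + 1L,
            cdr3 = ann$cdr3_end - ann$cdr3_start + 1L,
            fr4 = ann$fr4_end - ann$fr4_start + 1L)
  hand <- 100 * (w["cdr3"] * rlen["cdr3"]) / sum(w[names(rlen)] * rlen)
  expect_equal(sc$score, unname(hand))
  expect_true(sc$cdr3_covered)
})

test_that("adding a peptide match never decreases a coverage score", {
  set.seed(22)
  x <- make_scored_db(c("ARDPSYYRGSY", "GGHDSTWYE"))
  db <- x$db; ann <- x$ann
  spans <- lapply(1:20, function(i) {
    id <- sample(db$id, 1)
    L <- nchar(db$protein[db$id == id])
    s <- sample(L - 6, 1)
    data.frame(peptide = paste0("p", i), id = id, start = s, end = s + 6L)
  })
  prev <- coverage_score(db, ann, do.call(rbind, spans[0]))$score
  for (k in 1:20) {
    cur <- coverage_score(db, ann, do.call(rbind, spans[seq_len(k)]))$score
    expect_true(all(cur - prev >= -1e-9))
    prev <- cur
  }
})

test_that("exact CDR3 grouping collapses I/L and partitions the database", {
  x <- make_scored_db(c("ARNIKDYWS", "ARNLKDYWS", "GGHDSTWYE"))
  g <- group_by_cdr3(x$db, x$ann)
  expect_equal(length(unique(g$group_id)), 2L)  # I/L-collapsed key
  expect_equal(nrow(g), nrow(x$db))             # partition covers all
  # identical CDR3 on different frameworks lands in one group
  p1 <- template_protein(cdr1 = "GRTFSSYA", cdr3 = "ARDDYWGQS")$protein
  p2 <- template_protein(cdr1 = "GSIFSINT", cdr3 = "ARDDYWGQS")$protein
  db2 <- tiny_db(c(p1, p2))
  g2 <- group_by_cdr3(db2, annotate_regions(db2$protein))
  expect_equal(length(unique(g2$group_id)), 1L)
})

test_that("cluster mode single-links similar CDR3s like the exhaustive oracle", {
  # constructed trio: A~B 0.9, B~C 0.9, A~C 0.8 -> one group at 0.8
  a <- "AAAAAAAAAA"
  b <- "AAAAAAAAAB"; b <- chartr("B", "C", b)
  cc <- "AAAAAAAACC"
  trio <- make_scored_db(c(a, b, cc))
  g <- group_by_cdr3(trio$db, trio$ann, mode = "cluster",
                     similarity_threshold = 0.8)
  expect_equal(length(unique(g$group_id)), 1L)
  # at 0.95 nothing merges
  g2 <- group_by_cdr3(trio$db, trio$ann, mode = "cluster",
                      similarity_threshold = 0.95)
  expect_equal(length(unique(g2$group_id)), 3L)

  # randomized oracle comparison via igraph connected components
  skip_if_not_installed("igraph")
  set.seed(23)
  cdr3s <- unique(vapply(1:25, function(i) {
    base <- "ARDSSYWGQDT"
    k <- sample(0:3, 1)
    ch <- strsplit(base, "")[[1]]
    if (k > 0) { pos <- sample(length(ch), k); ch[pos] <- sample(LETTERS[LETTERS %in% c("A","D","E","G","S","T","W","Y")], k, replace = TRUE) }
    paste(ch, collapse = "")
  }, ""))
  x <- make_scored_db(cdr3s)
  thr <- 0.8
  g <- group_by_cdr3(x$db, x$ann, mode = "cluster", similarity_threshold = thr)
  keys <- chartr("L", "I", cdr3_seq(x$db$protein, x$ann))
  uk <- unique(keys)
  adj <- outer(seq_along(uk), seq_along(uk), Vectorize(function(i, j) {
    if (abs(nchar(uk[i]) - nchar(uk[j])) > 1) return(FALSE)
    d <- utils::adist(uk[i], uk[j])
    1 - d / max(nchar(uk[i]), nchar(uk[j])) >= thr
  }))
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  oracle_groups <- split(uk, comp)
  got_groups <- split(keys, g$group_id[match(x$db$id, g$id)])
  norm <- function(gs) sort(vapply(gs, function(s) paste(sort(unique(s)), collapse = "|"), ""))
  expect_setequal(unname(norm(got_groups)), unname(norm(oracle_groups)))
})

test_that("uniqueness score reproduces hand-counted ratios", {
  # database of 4 sequences sharing a framework; peptide placement known
  x <- make_scored_db(c("ARAAAAPEPA", "ARCCCCPEPA", "ARGGGGPEPA", "ARSSSSDDDD"))
  db <- x$db
  g <- group_by_cdr3(db, x$ann)
  # "peptide only in group members" -> 100
  grp_a <- db$id[grepl("ARAAAAPEPA", db$protein)]
  expect_equal(uniqueness_score("AAAAPEP", grp_a, db), 100)
  # 2 of group, 4 of database -> 50.0 ; 2 of group, 3 of db -> 66.67
  db2 <- tiny_db(c(template_protein(cdr3 = "WWAAKEYDS")$protein,
                   template_protein(cdr3 = "WWAAKEYDT")$protein,
                   template_protein(cdr3 = "HHAAKEYGG")$protein,
                   template_protein(cdr3 = "HHAAKEYGW")$protein))
  pep <- "AAKEY"
  grp <- db2$id[grepl("WWAAKEY", db2$protein)]
  expect_equal(uniqueness_score(pep, grp, db2), 50)
  # 2 of group, 3 of db -> 66.67 (drop one non-group sequence)
  db3 <- db2[db2$id %in% c(grp, db2$id[grepl("HHAAKEYGG", db2$protein)]), ]
  expect_equal(round(uniqueness_score(pep, grp, db3), 2), 66.67)
  # peptide matching nothing is an error
  expect_error(uniqueness_score("WWWWWWWW", grp, db2), "no database")
})

test_that("uniqueness is bounded and monotone under group merging", {
  set.seed(24)
  x <- make_scored_db(vapply(1:12, function(i) random_aa_str(9), ""))
  db <- x$db
  obs <- unlist(lapply(db$protein[1:6], function(p) {
    s <- sample(20, 2)
    substring(p, s, s + 7)
  }))
  mp <- map_peptides(obs, db)
  g <- group_by_cdr3(db, x$ann)
  u <- nanomatch:::uniqueness_table(mp$matches, g)
  expect_true(all(u$uniqueness > 0 & u$uniqueness <= 100))
  # merging two groups never decreases uniqueness relative to the merge
  gids <- unique(g$group_id)
  if (length(gids) >= 2) {
    for (pep in unique(u$peptide)[1:5]) {
      merged_ids <- g$id[g$group_id %in% gids[1:2]]
      merged_val <- uniqueness_score(pep, merged_ids, db)
      for (k in 1:2) {
        single <- u$uniqueness[u$peptide == pep & u$group_id == gids[k]]
        if (length(single)) expect_gte(merged_val + 1e-9, single)
      }
    }
  }
})

test_that("ranking follows top-score-then-count rules deterministically", {
  # two members of one CDR3 group differ in CDR1 so they stay distinct
  prots <- c(template_protein(cdr3 = "ARAAAAAAAA")$protein,
             template_protein(cdr1 = "GRTFSSYA", cdr3 = "ARCCCCCCCC")$protein,
             template_protein(cdr1 = "GSIFDINH", cdr3 = "ARCCCCCCCC")$protein)
  db <- tiny_db(prots, counts = c(7L, 120L, 7L))
  ann <- annotate_regions(db$protein)
  # cover group A fully (score 100), group C partially
  mA <- data.frame(peptide = "a", id = db$id[db$count == 7 & grepl("ARAAAA", db$protein)],
                   start = 1L, end = nchar(db$protein[1]))
  idC <- db$id[grepl("ARCCCC", db$protein)]
  mC <- data.frame(peptide = "c", id = idC, start = 1L, end = 40L)
  sc <- coverage_score(db, ann, rbind(mA, mC))
  g <- group_by_cdr3(db, ann)
  rep0 <- rank_candidates(g, sc, db, ann)
  # group with top score 100 ranks first
  top_group <- rep0$groups$group_id[1]
  expect_equal(rep0$groups$group_score[1], 100)
  # within the CCCC group, count 120 ranks before count 7
  ccc <- rep0$members[rep0$members$cdr3 == "ARCCCCCCCC", ]
  expect_equal(ccc$count, c(120L, 7L))

  # permutation invariance
  perm <- sample(nrow(db))
  db_p <- db[perm, ]; ann_p <- ann[perm, ]
  sc_p <- coverage_score(db_p, ann_p, rbind(mA, mC))
  g_p <- group_by_cdr3(db_p, ann_p)
  rep_p <- rank_candidates(g_p, sc_p, db_p, ann_p)
  expect_equal(rep_p$groups$cdr3, rep0$groups$cdr3)
  expect_equal(rep_p$members$id, rep0$members$id)
})

test_that("groups partition all scored sequences", {
  set.seed(25)
  x <- make_scored_db(vapply(1:40, function(i) random_aa_str(sample(5:15, 1)), ""))
  g <- group_by_cdr3(x$db, x$ann)
  rep0 <- rank_candidates(g, coverage_score(x$db, x$ann,
                                            data.frame(peptide = character(),
                                                       id = character(),
                                                       start = integer(),
                                                       end = integer())),
                          x$db, x$ann)
  expect_equal(sum(rep0$groups$n_members), nrow(x$db))
  expect_setequal(rep0$members$id, x$db$id)
})

test_that("selection filters implement the strict >80 rule and flags", {
  x <- make_scored_db(c("WWAADDEEYS", "HHGGSSTTYD"), counts = c(5L, 5L))
  db <- x$db; ann <- x$ann
  g <- group_by_cdr3(db, ann)
  id1 <- db$id[grepl("WWAADDEEYS", db$protein)]
  id2 <- db$id[grepl("HHGGSSTTYD", db$protein)]
  ann1 <- ann[match(id1, db$id), ]
  # a CDR3-spanning peptide unique to sequence 1 (uniqueness 100)
  pep1 <- substr(db$protein[db$id == id1], ann1$cdr3_start - 2, ann1$cdr3_end)
  mp <- map_peptides(pep1, db)
  sc <- coverage_score(db, ann, mp$matches)
  rep0 <- rank_candidates(g, sc, db, ann)
  rep1 <- apply_filters(rep0, mp$matches, g)
  m1 <- rep1$members[rep1$members$id == id1, ]
  expect_equal(m1$max_uniqueness, 100)
  expect_true(m1$selected)
  # the unmatched sequence has no unique peptide
  m2 <- rep1$members[rep1$members$id == id2, ]
  expect_true(m2$no_unique_peptide)
  expect_false(m2$selected)

  # cross-antigen collision on the high-uniqueness CDR3 peptide
  rep2 <- apply_filters(rep0, mp$matches, g,
                        cross_antigen_peptides = list(other = pep1))
  expect_true(rep2$members$cross_antigen_hit[rep2$members$id == id1])
  expect_false(rep2$members$selected[rep2$members$id == id1])

  # uniqueness exactly 80 fails the strict bound
  # build: peptide in 4 of 5 database sequences, all 4 in one group
  p_shared <- "AADDEEGGKK"
  grp_prots <- vapply(1:4, function(i)
    template_protein(cdr3 = paste0("AR", p_shared))$protein, "")
  # make the four group members distinct outside the CDR3
  grp_prots <- vapply(seq_along(grp_prots), function(i) {
    sub("GRTFSSYA", paste0("GRTFSSY", LETTERS[i]), grp_prots[i])
  }, "")
  grp_prots <- vapply(1:4, function(i)
    template_protein(cdr1 = paste0("GRTFSSY", c("A", "C", "D", "E")[i]),
                     cdr3 = paste0("AR", p_shared))$protein, "")
  out_prot <- template_protein(cdr3 = paste0("GG", p_shared))$protein
  db8 <- tiny_db(c(grp_prots, out_prot))
  ann8 <- annotate_regions(db8$protein)
  g8 <- group_by_cdr3(db8, ann8)
  mp8 <- map_peptides(p_shared, db8)
  sc8 <- coverage_score(db8, ann8, mp8$matches)
  rep8 <- apply_filters(rank_candidates(g8, sc8, db8, ann8), mp8$matches, g8)
  big_ids <- db8$id[grepl(paste0("AR", p_shared), db8$protein)]
  mbig <- rep8$members[rep8$members$id %in% big_ids, ]
  expect_equal(unique(mbig$max_uniqueness), 80)
  expect_true(all(mbig$no_unique_peptide))   # strict > 80

  # GLEW flag removes, indeterminate does not
  glew <- setNames(c(TRUE, NA), c(id1, id2))
  rep3 <- apply_filters(rep0, mp$matches, g, glew_flags = glew)
  expect_true(rep3$members$glew_hit[rep3$members$id == id1])
  expect_false(rep3$members$selected[rep3$members$id == id1])
  expect_false(rep3$members$glew_hit[rep3$members$id == id2])
  expect_true(rep3$members$glew_indeterminate[rep3$members$id == id2])
})

test_that("selected candidates satisfy the report invariant by re-check", {
  set.seed(26)
  st <- run_simulated_study(sim_config(n_clones = 40, n_binders = 3,
                                       seed = 31, n_read_pairs = 800))
  m <- st$result$report$members
  sel <- m[m$selected, ]
  expect_true(all(!sel$glew_hit & !sel$cross_antigen_hit &
                    !sel$no_unique_peptide))
  expect_true(all(sel$max_uniqueness > 80))
})

test_that("evidence rows span the CDR3 interval of their candidate", {
  st <- run_simulated_study(sim_config(n_clones = 30, n_binders = 2,
                                       seed = 33, n_read_pairs = 600))
  ev <- st$result$evidence
  m <- st$result$report$members
  expect_gt(nrow(ev), 0)
  c3s <- m$cdr3_start[match(ev$id, m$id)]
  c3e <- m$cdr3_end[match(ev$id, m$id)]
  expect_true(all(ev$start <= c3e & ev$end >= c3s))
  expect_true(all(ev$id %in% m$id[m$selected]))
})
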