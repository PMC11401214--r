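# Seeded generation of synthetic VHH repertoires, paired-end amplicon
# reads, and noisy dual-protease peptide observations with ground truth.

# one fixed codon per amino acid (reverse translation of clone proteins)
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(protein) {
  vapply(strsplit(protein, "", fixed = TRUE), function(aa) {
    paste(.CODON[aa], collapse = "")
  }, FUN.VALUE = "")
}

#' Default VHH framework template
#'
#' A canonical camelid VHH scaffold: one leader residue retained from the
#' amplicon 5' end, FR1 ending in the first conserved Cys (position 23 of
#' the translated sequence), a 17-residue FR2 whose conserved Trp sits at
#' IMGT 41 with the VHH-hallmark tetrad (IMGT 49-52) at `hallmark`, a
#' 39-residue FR3 ending in the second conserved Cys, and a W-G-x-G FR4.
#' CDR1/CDR2 defaults are neutral placeholders replaced per clone.
#'
#' @param hallmark residues placed at IMGT 49-52 (default `"EREF"`, a VHH
#'   tetrad; use `"GLEW"` to build a conventional-VH contaminant).
#' @return named list of framework segment strings.
#' @export
vhh_template <- function(hallmark = "EREF") {
  stopifnot(nchar(hallmark) == 4)
  list(
    leader = "S",
    fr1 = "QVQLQESGGGLVQAGGSLRLSCAAS",
    fr2 = paste0("MGWFRQAPGK", hallmark, "VAG"),
    fr3 = "TYYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC",
    fr4 = "WGQGTQVTVSS",
    hinge_stub = c(long_hinge_IgG2 = "AHH", short_hinge_IgG3 = "EPK")
  )
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic repertoire: clone count,
#' CDR length laws, log-normal clone abundances, 2 x 300-class paired-end
#' reads with a per-base substitution error rate, and a serum-MS arm in
#' which the peptides of `n_binders` abundance-weighted clones are observed
#' with a per-peptide detection probability plus background contaminants.
#'
#' @param n_clones number of distinct clones (default 500).
#' @param n_binders number of antigen-binding clones whose peptides are
#'   observed (default 5).
#' @param seed integer seed; mandatory, drives every stochastic step.
#' @param cdr1_len,cdr2_len fixed CDR1/CDR2 lengths (default 8).
#' @param cdr3_len_range CDR3 length range, uniform draw (default 5-22).
#' @param abundance_sdlog log-normal clone abundance spread (default 1).
#' @param n_read_pairs read pairs to simulate (default 20000).
#' @param read_len read length (default 300).
#' @param error_rate per-base substitution error rate (default 0.003).
#' @param detection_prob per-peptide MS detection probability (default 0.6).
#' @param contaminant_rate expected contaminant observations per detected
#'   peptide (default 0.05).
#' @param min_peptide_len MS identifiability floor (default 6).
#' @param proteases protease rules under which observed peptides are
#'   generated; the default emits all three search lists (tryptic plus
#'   chymotryptic under both specificities), matching how dual-protease
#'   MS data are searched.
#' @param template framework template from [vhh_template()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 500L, n_binders = 5L, seed,
                       cdr1_len = 8L, cdr2_len = 8L,
                       cdr3_len_range = c(5L, 22L),
                       abundance_sdlog = 1,
                       n_read_pairs = 20000L, read_len = 300L,
                       error_rate = 0.003,
                       detection_prob = 0.6, contaminant_rate = 0.05,
                       min_peptide_len = 6L,
                       proteases = c("trypsin", "chymotrypsin_high",
                                     "chymotrypsin_low"),
                       template = vhh_template()) {
  if (missing(seed)) stop("sim_config() requires an explicit seed")
  stopifnot(n_clones >= 1L,
            error_rate >= 0, error_rate <= 1,
            detection_prob >= 0, detection_prob <= 1,
            contaminant_rate >= 0)
  structure(list(n_clones = as.integer(n_clones),
                 n_binders = as.integer(n_binders), seed = as.integer(seed),
                 cdr1_len = cdr1_len, cdr2_len = cdr2_len,
                 cdr3_len_range = cdr3_len_range,
                 abundance_sdlog = abundance_sdlog,
                 n_read_pairs = as.integer(n_read_pairs),
                 read_len = as.integer(read_len), error_rate = error_rate,
                 detection_prob = detection_prob,
                 contaminant_rate = contaminant_rate,
                 min_peptide_len = min_peptide_len,
                 proteases = proteases,
                 template = template),
            class = "sim_config")
}

# derive independent sub-seeds for the pipeline stages from the main seed
stage_seeds <- function(seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(.AA20, len[i], replace = TRUE), collapse = "")
  }, FUN.VALUE = "")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, FUN.VALUE = "")
}

#' Simulate a VHH repertoire with ground truth
#'
#' Clones share the framework template and carry random CDRs; each clone
#' gets a hinge variant (long = IgG2, short = IgG3, equiprobable), a
#' log-normal abundance, and an amplicon carrying the built-in primer
#' annealing sites (degenerate CALL001 position resolved per clone).
#' Binders are drawn with probability proportional to abundance, matching
#' the serum-dominant clonotypes the MS arm observes. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `ground_truth`: `clones` (data.frame with
#'   `clone_id`, `protein`, `dna`, `amplicon`, `hinge`, `abundance`, CDR
#'   boundary columns), `binder_ids`, and `cfg`.
#' @export
simulate_repertoire <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seeds(cfg$seed)[1])
  n <- cfg$n_clones
  tpl <- cfg$template
  cdr1 <- random_aa(n, rep(cfg$cdr1_len, n))
  cdr2 <- random_aa(n, rep(cfg$cdr2_len, n))
  l3 <- sample(seq(cfg$cdr3_len_range[1], cfg$cdr3_len_range[2]), n,
               replace = TRUE)
  cdr3 <- random_aa(n, l3)
  hinge <- sample(names(tpl$hinge_stub), n, replace = TRUE)
  protein <- paste0(tpl$leader, tpl$fr1, cdr1, tpl$fr2, cdr2, tpl$fr3,
                    cdr3, tpl$fr4, tpl$hinge_stub[hinge])
  dna <- reverse_translate(protein)

  p <- builtin_primers()
  fwd_sites <- vapply(seq_len(n), function(i) {
    sub("Y", sample(c("C", "T"), 1), p$call001$annealing_seq)
  }, FUN.VALUE = "")
  rev_site <- ifelse(hinge == "long_hinge_IgG2",
                     revcomp(p$lh_rev$annealing_seq),
                     revcomp(p$sh_rev$annealing_seq))
  amplicon <- paste0(random_dna(n, rep(6L, n)), fwd_sites, dna, rev_site,
                     random_dna(n, rep(6L, n)))

  ab <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
  ab <- ab / sum(ab)
  binders <- sample(seq_len(n), min(cfg$n_binders, n), prob = ab)

  off <- nchar(tpl$leader) + nchar(tpl$fr1)
  clones <- data.frame(
    clone_id = sprintf("clone_%04d", seq_len(n)),
    protein = protein, dna = dna, amplicon = amplicon, hinge = hinge,
    abundance = ab,
    cdr1_start = off + 1L, cdr1_end = off + cfg$cdr1_len,
    cdr2_start = off + cfg$cdr1_len + nchar(tpl$fr2) + 1L,
    cdr2_end = off + cfg$cdr1_len + nchar(tpl$fr2) + cfg$cdr2_len,
    cdr3_start = off + cfg$cdr1_len + nchar(tpl$fr2) + cfg$cdr2_len +
      nchar(tpl$fr3) + 1L,
    cdr3_end = off + cfg$cdr1_len + nchar(tpl$fr2) + cfg$cdr2_len +
      nchar(tpl$fr3) + l3,
    stringsAsFactors = FALSE
  )
  structure(list(clones = clones,
                 binder_ids = clones$clone_id[sort(binders)], cfg = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d clones (%d binders), seed %d\n",
              nrow(x$clones), length(x$binder_ids), x$cfg$seed))
  invisible(x)
}

add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    L <- nchar(s)
    k <- rbinom(1, L, rate)
    if (k == 0) return(s)
    pos <- sample.int(L, k)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
    paste(chars, collapse = "")
  }, FUN.VALUE = "", USE.NAMES = FALSE)
}

#' Simulate 2 x 300-class paired-end reads from a repertoire
#'
#' Reads are drawn per clone abundance (multinomial); read 1 is the
#' amplicon 5' prefix, read 2 the reverse complement of its 3' suffix, so
#' default amplicon lengths guarantee overlapping pair geometry.
#' Substitution errors are added at `cfg$error_rate` and every base gets
#' the Phred quality consistent with that rate. Deterministic under
#' `cfg$seed`.
#'
#' @param truth a [simulate_repertoire()] result.
#' @param cfg the same [sim_config()].
#' @return list with `pairs` (data.frame `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `read_clone` (source clone id per read pair).
#' @export
simulate_reads <- function(truth, cfg = truth$cfg) {
  set.seed(stage_seeds(cfg$seed)[2])
  amp <- truth$clones$amplicon
  if (any(nchar(amp) < cfg$read_len))
    stop("read length ", cfg$read_len, " exceeds an amplicon length (",
         min(nchar(amp)), ")")
  counts <- as.integer(rmultinom(1, cfg$n_read_pairs, truth$clones$abundance))
  src <- rep(seq_along(amp), counts)
  src <- src[sample.int(length(src))]
  a <- amp[src]
  r1 <- substr(a, 1L, cfg$read_len)
  r2 <- revcomp(substr(a, nchar(a) - cfg$read_len + 1L, nchar(a)))
  r1 <- add_substitution_errors(r1, cfg$error_rate)
  r2 <- add_substitution_errors(r2, cfg$error_rate)
  q <- if (cfg$error_rate > 0) {
    min(40L, as.integer(round(-10 * log10(cfg$error_rate))))
  } else 40L
  qs <- strrep(intToUtf8(q + 33L), cfg$read_len)
  list(pairs = data.frame(id = sprintf("read_%06d", seq_along(src)),
                          seq1 = r1, qual1 = qs, seq2 = r2, qual2 = qs,
                          stringsAsFactors = FALSE),
       read_clone = truth$clones$clone_id[src])
}

#' Simulate dual-protease MS peptide observations
#'
#' Binder clones are digested in silico (trypsin and chymotrypsin high
#' specificity, no missed cleavages); each peptide of at least
#' `cfg$min_peptide_len` residues is observed with probability
#' `cfg$detection_prob`. Contaminant observations (peptides of random
#' non-binder clones, and random amino-acid strings) are added at
#' `cfg$contaminant_rate` per detected peptide. A decoy "unrelated
#' antigen" observation set is built the same way from a disjoint set of
#' non-binder clones. Deterministic under `cfg$seed`.
#'
#' @param truth a [simulate_repertoire()] result.
#' @param cfg the same [sim_config()].
#' @return list with `observations`, `cross_antigen` (peptide observation
#'   data.frames), `provenance` (clone of origin per non-contaminant
#'   observation row, `NA` for contaminants), `decoy_binder_ids`.
#' @export
simulate_peptides <- function(truth, cfg = truth$cfg) {
  if (length(truth$binder_ids) == 0) stop("binder set is empty")
  set.seed(stage_seeds(cfg$seed)[3])
  rules <- setNames(lapply(cfg$proteases, protease_rule), cfg$proteases)

  digest_set <- function(clone_ids, sample_id, detect) {
    rows <- list()
    prov <- character(0)
    for (cid in clone_ids) {
      prot <- truth$clones$protein[truth$clones$clone_id == cid]
      for (rn in names(rules)) {
        d <- digest_protein(prot, rules[[rn]], 0L)
        pep <- unique(d$peptide[nchar(d$peptide) >= cfg$min_peptide_len])
        seen <- pep[runif(length(pep)) < detect]
        if (length(seen) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = seen, protease = rn, sample_id = sample_id,
          score = NA_real_, stringsAsFactors = FALSE)
        prov <- c(prov, rep(cid, length(seen)))
      }
    }
    obs <- do.call(rbind, rows) %||%
      data.frame(peptide = character(), protease = character(),
                 sample_id = character(), score = numeric(),
                 stringsAsFactors = FALSE)
    list(obs = obs, prov = prov)
  }

  main <- digest_set(truth$binder_ids, "antigen_A", cfg$detection_prob)

  non_binders <- setdiff(truth$clones$clone_id, truth$binder_ids)
  n_cont <- rpois(1, cfg$contaminant_rate * nrow(main$obs))
  cont <- NULL
  if (n_cont > 0 && length(non_binders) > 0) {
    cont_rows <- lapply(seq_len(n_cont), function(i) {
      if (runif(1) < 0.5) {
        cid <- sample(non_binders, 1)
        prot <- truth$clones$protein[truth$clones$clone_id == cid]
        rn <- sample(names(rules), 1)
        d <- digest_protein(prot, rules[[rn]], 0L)
        pep <- d$peptide[nchar(d$peptide) >= cfg$min_peptide_len]
        if (length(pep) == 0) return(NULL)
        data.frame(peptide = sample(pep, 1), protease = rn,
                   sample_id = "antigen_A", score = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(peptide = random_aa(1, sample(8:15, 1)),
                   protease = sample(names(rules), 1),
                   sample_id = "antigen_A", score = NA_real_,
                   stringsAsFactors = FALSE)
      }
    })
    cont <- do.call(rbind, cont_rows)
  }
  observations <- rbind(main$obs, cont)
  provenance <- c(main$prov, rep(NA_character_, nrow(observations) - length(main$prov)))

  decoys <- character(0)
  if (length(non_binders) > 0)
    decoys <- sample(non_binders, min(cfg$n_binders, length(non_binders)))
  decoy <- digest_set(decoys, "unrelated_antigen", cfg$detection_prob)

  list(observations = observations, cross_antigen = decoy$obs,
       provenance = provenance, decoy_binder_ids = decoys)
}
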