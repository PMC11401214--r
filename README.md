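# nanomatch

Identify nanobody (VHH) candidates by combining high-throughput amplicon
sequencing of a camelid heavy-chain-only antibody repertoire with
mass-spectrometry peptide identifications from antigen-purified serum.

Camelid HCAb circulating in serum carry the antigen specificity of the
immune response; affinity purification plus LC-MS/MS yields peptides from
the binding clones, while amplicon sequencing of lymphocyte cDNA yields
the repertoire of candidate VHH sequences. `nanomatch` joins the two:

1. **Database construction** — paired-end reads are merged by ungapped
   overlap, the leader forward primer and hinge reverse primers are
   located with a fractional mismatch tolerance (Hamming, IUPAC-aware; a
   23-nt primer at 20% tolerance allows ⌈0.2·23⌉ = 5 mismatches), the
   reading frame is set by the primer positions, and translated sequences
   are deduplicated with read-count tracking. Reverse-primer identity
   assigns the IgG2 (long hinge) / IgG3 (short hinge) subclass.
2. **Annotation** — FR/CDR boundaries from conserved anchor motifs
   (Cys-23, Trp-41, Y-x-C for Cys-104, W-G-x-G for FR4) plus an
   IMGT-style position map; conventional-VH contaminants are flagged by
   the GLEW tetrad at IMGT 49–52.
3. **In silico digestion** — Expasy rules for trypsin and chymotrypsin
   (high/low specificity), unique-peptide FASTA lists, and a
   cleavage-site histogram in IMGT coordinates.
4. **Matching and ranking** — observed peptides are mapped back under
   Ile/Leu equivalence; each sequence is scored by CDR-weighted coverage

   score = 100 · Σ<sub>r</sub> w<sub>r</sub> c<sub>r</sub> / Σ<sub>r</sub> w<sub>r</sub> n<sub>r</sub>,  w = (FR 1, CDR1 3, CDR2 3, CDR3 10)

   sequences are grouped into CDR3 clonotypes (exact or
   similarity-clustered), groups are ranked by their top-scoring member
   and members by sequencing counts, and each peptide gets a
   **uniqueness score** = 100 · (group sequences containing it) /
   (database sequences containing it). Selection requires a peptide with
   uniqueness > 80, no GLEW hallmark, and no cross-antigen evidence.
5. **Simulation** — a fully seeded generator of repertoires, 2×300-class
   reads, and noisy dual-protease peptide observations with ground truth,
   so the complete pipeline is testable without external data.

See `vignettes/nanomatch-methods.Rmd` for the model, parameter
definitions, and design rationale.

## Worked example

A simulated study: 80 clones, 3 serum binders, 4000 read pairs, peptide
detection probability 0.6 per search list.

```r
library(nanomatch)
cfg   <- sim_config(n_clones = 80, n_binders = 3, seed = 42, n_read_pairs = 4000)
truth <- simulate_repertoire(cfg)
reads <- simulate_reads(truth, cfg)
ms    <- simulate_peptides(truth, cfg)
res   <- run_pipeline(pairs = reads$pairs, observations = ms$observations,
                      cross_antigen = list(unrelated = ms$cross_antigen),
                      group_mode = "cluster")
res
#> == nanomatch pipeline result ==
#> <vhh_db> 2138 unique proteins, 3805 supporting reads
#>   hinge classes: long_hinge_IgG2=1067, short_hinge_IgG3=1071
#>   top: vhh_333a9b05ba1c0d0c (count 106, 123 aa)
#> <candidate_report> 196 CDR3 groups, 2138 sequences
#>   selected candidates: 71 (uniqueness > 80)
#>   #1 g0049 score=97.3 reads=24 cdr3=NKCPAIHHHCTIPIQ
#>   #2 g0028 score=94.3 reads=43 cdr3=WIWFKYWQAAIGHIDSRPQ
#>   #3 g0025 score=93.5 reads=40 cdr3=TPPHTEQCNCQFWIIFRQ
#>   #4 g0027 score=46.7 reads=43 cdr3=PQMKYTGYMTKKF
#>   #5 g0048 score=44.3 reads=19 cdr3=TRSRN
```

The three groups at the top are exactly the three simulated binder
clonotypes (report CDR3 keys are I/L-collapsed, since MS cannot tell the
isobaric residues apart). The score gap to rank 4 separates clonotypes
with CDR-specific peptide evidence from the framework-coverage baseline
that every clone shares. Per-candidate evidence for manual MS/MS review:

```r
head(res$evidence, 3)
#>                     id group_id                     peptide start end uniqueness
#> 1 vhh_d212287c1fa3cf7d    g0049                    CNKCPAIH    98 105        100
#> 2 vhh_d212287c1fa3cf7d    g0049 CPAIHHHCTLPLQWGQGTQVTVSSAHH   101 127        100
#> 3 vhh_d212287c1fa3cf7d    g0049      NTVYLQMNSLKPEDTAVYYCNK    79 100        100
```

Each row is a CDR3-spanning peptide of a selected candidate with its
match span and uniqueness — uniqueness 100 means every database sequence
containing that peptide belongs to this clonotype.

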