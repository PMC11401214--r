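---
title: "Identifying nanobody candidates from serum proteomics and VHH amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying nanobody candidates from serum proteomics and VHH amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomatch)
options(nanomatch.verbose = 0)
```

## The problem

Camelids make heavy-chain-only antibodies (HCAb) whose single variable
domain (VHH) can be expressed alone as a nanobody. After immunization,
antigen-specific HCAb circulate in serum; affinity-purifying them against
the antigen and analysing the digest by LC-MS/MS yields peptides from the
binding clones. Those peptides alone cannot reconstruct a VHH, but the
animal's expressed VHH repertoire can be read out by amplicon sequencing of
lymphocyte cDNA. `nanomatch` joins the two measurements: it builds a
translated candidate database from the sequencing reads, maps the
MS-identified peptides back onto it, and ranks CDR3 clonotypes by
CDR-weighted peptide coverage, so that the clones actually secreted against
the antigen rise to the top.

The package covers the computational arms of that workflow:

1. **Amplicon processing** — merge 2×300-class paired-end reads, locate the
   leader-region forward primer and the hinge-region reverse primers with a
   fractional mismatch tolerance, pick the reading frame from the primer
   positions, translate, reject defective sequences, and deduplicate with
   read-count tracking. Reverse-primer identity classifies each transcript
   as long-hinge IgG2 or short-hinge IgG3.
2. **Annotation** — find framework anchor motifs and derive FR1–FR4 and
   CDR1–3 boundaries plus an IMGT-style position map.
3. **In silico digestion** — trypsin and chymotrypsin (high/low
   specificity) under Expasy rules, unique-peptide lists, and a
   cleavage-site-by-IMGT-position histogram.
4. **Matching and ranking** — peptide-to-sequence mapping under I/L
   equivalence, CDR-weighted coverage scores, CDR3 clonotype grouping,
   peptide uniqueness scores, ranking, and the selection filters
   (cross-antigen, GLEW, uniqueness threshold).
5. **Simulation** — a seeded generator of repertoires, reads and peptide
   observations with ground truth, so every stage is testable end to end.

## Primer search and database construction

Primer matching is substitution-only (Hamming) with IUPAC degenerate codes
matched by set membership; the mismatch budget for a primer of annealing
length $L$ at tolerance $f$ is $\lceil fL \rceil$, so the 23-nt leader
primer at 20% tolerance allows 5 mismatches. The built-in primers are the
leader forward primer and the long/short hinge reverse primers, each
synthesized with a 6N diversity tail that is excluded from matching:

```{r primers}
builtin_primers()
```

Pair merging takes the longest ungapped overlap whose mismatch fraction is
at most 0.1 (default; the separate 0.2 default tolerance applies to primer
sites). Overlap conflicts resolve to the higher-quality base, quality ties
to read 1. Translation runs from the forward-primer end (plus a
configurable frame offset, 0 for the built-in leader primer) to the
reverse-site boundary, truncated to whole codons; sequences with in-frame
stops or a translated length outside 90–180 residues are rejected with
tallied reasons. Deduplication is at the protein level — read counts
measure transcript support for a candidate protein — with the majority DNA
variant kept as representative.

## Anchor-based annotation

Annotation uses the canonical immunoglobulin anchors: the first conserved
Cys near IMGT 23 (searched at positions 18–30), the post-CDR1 Trp (IMGT
41; 36–46), the second conserved Cys (IMGT 104) found via a `Y-x-C` motif
at 95–110, and a `W-G-x-G` FR4 motif in the final 15 residues. Boundaries
follow by linear pinning (e.g. CDR3 is exactly the span between the second
Cys and the FR4 Trp). Anchors that fail leave their dependent regions
*unresolved* rather than guessed; confidence degrades from `full` through
`partial` to `failed`.

Two deliberate choices:

* **No lone-Cys fallback for the second Cys.** A bare "any Cys in the
  window" fallback looks harmless but is confidently wrong on sequencing
  errors: when the conserved Cys codon is hit by a substitution, the
  fallback re-anchors on any Cys inside the CDR3 and manufactures a
  plausible-looking clonotype keyed by a CDR3 suffix. Such artifacts
  scored high enough to displace genuine clonotypes in ranking
  experiments, so the default config requires the `Y-x-C` context; the
  fallback remains available through `anchor_config()`.
* **Linear pinning assumes ungapped FR2 (17 residues) and FR3 (39).**
  True for the simulator's scaffold and for most VHH; germlines with
  IMGT framework gaps would shift CDR2 bounds by one or two positions.
  External numberings (e.g. ANARCI output) can be imported with
  `import_external_numbering()` to bypass the internal anchors entirely.

The IMGT map numbers framework residues by linear assignment pinned at the
anchors and gaps CDR loops by the IMGT convention (filling from both ends,
gaps in the middle; loops longer than the slot count get `111.1`-style
insertion codes). The map supports the VH-contaminant filter: a sequence
with Gly-Leu-Glu-Trp at IMGT 49–52 is flagged as a conventional-VH
contaminant. An unmappable 49–52 yields an *indeterminate* flag, which is
reported but never removes a candidate — the filter exists to discard known
contaminants, not unannotatable sequences.

## Digestion

Cleavage rules are the Expasy defaults: trypsin after K/R not before P;
chymotrypsin high specificity after F/Y/W not before P; low specificity
additionally after M/L/H. The simple `[KR]` trypsin rule is used without
the extended Keil exceptions, matching the named defaults of standard
digestion software; exceptions can be configured. Database digestion uses
no missed cleavages (peptides then tile each protein exactly — a tested
invariant); up to two missed cleavages are supported for matching
robustness. Mass-spectrometric I/L ambiguity is *not* handled at digestion
time: digestion is sequence-exact, and isobaric equivalence is applied at
match time where it belongs.

On the default scaffold the Tyr-rich FR3 end (`...TAVYYC`) places a
chymotryptic site within two residues of the CDR3 start, while the nearest
constitutive tryptic site sits ~20 residues upstream — the practical reason
the workflow digests with both proteases in parallel: chymotryptic peptides
release the CDR3 cleanly while trypsin provides long spanning coverage.

## Scoring, grouping and selection

A matched peptide covers the residues of its span(s); sequence scores are

$$\mathrm{score} = 100\;\frac{\sum_r w_r c_r}{\sum_r w_r n_r},$$

over the seven regions, with per-residue weights FR = 1, CDR1 = CDR2 = 3,
CDR3 = 10 by default (only the ordering — CDR3 heaviest — is dictated by
the method; values are configurable). Unresolved regions carry zero
weight; sequences whose annotation failed entirely are scored with uniform
weights and flagged.

Clonotypes are CDR3 groups: exact mode keys on the I/L-collapsed CDR3
string; cluster mode single-linkage-merges groups with length difference
≤ 1 and identity ≥ 0.8, which pools single-substitution sequencing-error
variants with their parent clonotype. Groups rank by their top-scoring
member (ties by total read count); members rank by read count within the
group — high-count sequences are the ones most likely to be real
transcripts rather than PCR/sequencing errors. Groups whose key CDR3 is
unresolved are kept and flagged but rank after all resolved groups: a
clonotype that cannot state its CDR3 is not reviewable.

Each (peptide, group) pair gets a uniqueness score
$100 \cdot n_{\text{group}} / n_{\text{database}}$ over containing
sequences — the probability the peptide originated from that clonotype.
Selection requires at least one matched peptide with uniqueness strictly
above 80, no GLEW hallmark, and no cross-antigen hit (a CDR3-covering
high-uniqueness peptide also observed in an unrelated antigen's sample —
evidence of non-specific binding). `evidence_summary()` lists each
selected candidate's CDR3-spanning peptides for manual MS/MS fragmentation
review; the package deliberately stops short of automated spectral
validation.

## The simulator and what passing tests mean

`sim_config()` defines the study conditions: 500 clones on a shared VHH
scaffold with random CDRs (CDR3 length uniform on 5–22), log-normal clone
abundances (sdlog 1), equiprobable long/short hinge, amplicons carrying
the built-in primer sites verbatim, 20,000 2×300 read pairs at a 0.3%
per-base substitution rate, and an MS arm in which 5 binder clones —
drawn with probability proportional to abundance, since serum-dominant
clonotypes are the biological binders — are digested in silico and each
peptide of ≥ 6 residues is observed with probability 0.6 per search list
(trypsin, chymotrypsin high, chymotrypsin low), plus ~5% contaminant
observations and a decoy observation set from unrelated clones. All
randomness flows through the single seed.

What the simulator does *not* emulate: germline framework diversity and
somatic hypermutation (all clones share one scaffold), indel sequencing
errors, quality-score degradation along reads, peptide detectability
physics (length/charge/hydrophobicity), and spectral mis-identification.
The shared scaffold is the conservative choice for the matching problem —
it maximizes peptide sharing between clones, making uniqueness and
ranking *harder* than in real repertoires where frameworks differ.

Consequences observed in the recovery experiment
(`recovery_experiment()`: 20 seeded end-to-end runs at the above
conditions, asking whether all 5 binder clonotypes rank in the top 5):

* Because frameworks are identical, every observed framework peptide
  matches essentially every database sequence, so *all* ~500 clonotype
  groups receive a baseline coverage score (~45–60) that rises as CDR3
  length shrinks (a short CDR3 leaves less uncovered weight in the
  denominator).
* A binder whose long CDR3 is rich in cleavage sites yields few
  observable (≥ 6-residue) CDR3 peptides; at detection probability 0.6
  its CDR3 coverage occasionally drops below ~50%, and its group then
  falls below the short-CDR3 baseline groups.

Under these fixed conditions the all-binders-in-top-5 rate measures
roughly 40–70% across seeds (reported by `scripts/acceptance.R` as
`recovery_top5_pct`), while top-10 recovery is substantially higher. This
is a property of the study conditions — per-peptide detection 0.6 with a
maximally adversarial shared-framework repertoire — not of the
implementation; the noiseless limit (zero sequencing error, detection 1)
reconstructs and selects exactly the binder set with no false selections,
a tested invariant.

## Numerical and degenerate-input choices

* Mismatch budgets use `ceiling(frac × length)` — the only rounding
  consistent with "5 mismatches in 23 bp at 20%".
* Merging and primer search are substitution-only; no indels anywhere in
  the hot path, which keeps the brute-force oracles exact.
* Dedup ties (equal DNA-variant support) go to the lexicographically
  smallest DNA; survey merging is greedy in descending abundance with
  deterministic tie-breaks; all orderings are total, so every output is
  byte-stable for a given seed.
* Peptides shorter than 6 residues (configurable) are dropped at
  ingestion with a logged count, mirroring the MS identifiability floor.
* An empty FASTA yields an empty table; a peptide matching no database
  sequence is an error for `uniqueness_score()` but merely "unmatched"
  for `map_peptides()`.

## Problem sizes used in the shipped checks

The test suite exercises the oracle-equivalence suites at 1000 randomized
cases each, the conservation properties at several hundred instances, and
the recovery experiment at its full stated conditions (20 seeds × 20,000
read pairs). The acceptance script re-runs the recovery experiment and a
60-clone noiseless study from scratch at whatever seed it is given.

## Known limitations

* Anchor motifs are canonical defaults, not learned from data; unusual
  germlines may need a custom `anchor_config()` or an imported numbering.
* Cluster-mode grouping chains aggressively for very short CDR3s (a
  1-substitution neighbour of a 5-mer is 80% identical), which can merge
  distinct short clonotypes.
* The cross-antigen filter compares peptide evidence, not whole
  sequences; a whole-sequence variant would flag shared clones even
  without shared observed peptides.
* No FDR modelling of the upstream peptide identifications: search-engine
  scores are carried through for reporting only.
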