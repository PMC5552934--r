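---
title: "Methods: models, rules and design choices in copascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in copascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`copascan` is a pipeline for surveying copper-transporting P1B-ATPases
(CopA) and the chaperones CopZ, CupA and CusF in multipartite bacterial
genomes. This vignette documents the models it implements, the parameters
that matter, what the synthetic-data generators do and do not emulate, and
the design choices made where the procedure was genuinely open.

## 1. Profile HMM retrieval

Candidates are retrieved with a profile hidden Markov model built from a
seed alignment of characterized P1B-ATPases. The model uses the standard
7-transition topology (M→M/I/D, I→M/I, D→M/D). Columns whose residue
occupancy is at least `occupancy_threshold` (default **0.5**, the
conventional default) become match states. Match emissions mix observed
counts with `pseudocount_weight` (default **1**) times the background:
`P(a) = (n_a + w·bg_a) / (n + w)`; transitions get the analogous
pseudocount spread over each state's outgoing edges. Background residue
frequencies are estimated from the seed itself so the model is fully
self-contained.

Scoring is log-odds against the background, global in the model with
flanking insert states, so a domain embedded in unrelated flanks is still
found. Both Viterbi and forward recursions use a vectorized prefix scan
over the delete chain; both are verified against exhaustive path
enumeration for small models in the test suite.

**E-values.** The profile is calibrated by scoring residue-shuffled decoys
(default 200; at least 50 enforced). Because the null score depends
strongly on sequence length under a model-global alignment (every residue
short of the model length forces a deletion), decoy scores are first
regressed on length and a Gumbel distribution is fitted to the residuals
by the method of moments. The E-value of a query is the database size
times the Gumbel upper tail of its length-corrected score. This replaces
the retrieval tool's internal (unspecified) calibration; the operational
cutoff is E ≤ 1e-3 throughout.

## 2. Maximum-likelihood phylogenetics

Sequences are projected onto the profile's match states (deletions as
gaps, insertions dropped), giving a fixed-width alignment. The protein
model is LG with empirical "+F" frequencies available; the nucleotide
model is GTR with optional proportion of invariant sites. Rate
heterogeneity uses a discrete gamma with **K = 4** categories (the common
default; the procedure leaves K unstated) placed at category medians and
renormalized to mean 1. Rate matrices are scaled to one expected
substitution per unit branch length and exponentiated by eigen
decomposition of the reversibility-symmetrized generator.

Likelihoods use Felsenstein pruning with per-column rescaling. Pairwise
distances maximize the two-sequence likelihood by Brent search (capped at
10 substitutions/site with a warning for saturated pairs). Tree search is
hill climbing over nearest-neighbor interchanges with round-robin Brent
branch-length optimization, multi-started from a BioNJ tree plus random
topologies; each start's log-likelihood trajectory is monotone by
construction. Branch supports are nonparametric bootstrap proportions.

**Deviation.** The original procedure thresholds clades at
Shimodaira–Hasegawa-like aLRT support ρ ≥ 0.9. The aLRT statistic itself
is out of scope here; bootstrap proportions are used with the same ≥ 0.9
threshold semantics. Bootstrap supports are typically more conservative
than SH-like values, so clade extraction errs toward fewer, stronger
clades. Similarly, the original bootstrap-stopping criterion (extended
majority rule) is replaced by a fixed configurable replicate count
(default 50 at desk scale, 150 at `paper_scale`), and the 100-random-start
plus BioNJ search (101 searches) is available via
`run_config(paper_scale = TRUE)` while desk runs default to the BioNJ tree
without NNI refinement — pure-R tree search at full scale would dominate
the runtime budget without changing what the desk-scale tests establish.

Clade extraction returns maximal, disjoint, well-supported clades that
contain at least one characterized anchor; the clade inherits its anchors'
substrate. Incongruence between a marker tree (16S rRNA) and the gene tree
is reported as the Robinson–Foulds distance on shared leaves, a per-class
monophyly verdict (bipartition presence, the correct unrooted notion), and
the list of "scattered" taxa nested inside another class's smallest
containing clade in the gene tree only. Nesting queries require a root;
both trees are rooted on a leaf of the smallest class by default
(configurable), and host classes whose containing clade is the whole tree
are skipped as uninformative.

## 3. The subtype rule engine

Table-derived motif evidence is extracted at fixed anchor spans (match
states for the N-MBD, TM6, TM7 and TM8 regions) and fed to a deterministic
first-match rule chain:

1. TM6 `CPH` → **P1B-3**; 2. TM6 `CPD` → **P1B-3a**;
3. TM6 `CPC` + ≥ 2 TRASH (`CXCXC`) repeats + `CPKC`/`CPIC` + N-MBD ≥ 120
   residues → **P1B-1b**;
4. TM6 `CPC` + His-rich N-MBD + `CPIC` → **P1B-1a**;
5. TM6 `CPC` + CXXC set within {`CAGC`,`CAAC`,`CASC`} + TM8 in
   {`MSGSS`,`MSLSS`} + FixI gene-neighborhood context → **P1B-1c**;
6. TM6 `CPC` + any CXXC → **P1B-1**; otherwise non-copper/unclassified.

Operationalized definitions (the source material gives qualitative
descriptions only):

* **His-rich**: ≥ 5 histidines in any 20-residue window of the N-MBD, or
  ≥ 4 consecutive histidines (the described "short H-rich segment of six
  to 10 residues" satisfies both).
* **P1B-1b length gate 120**: the subtype's described N-MBD is ~160
  residues; 120 leaves slack for divergent members.
* **FixI context**: supplied from the annotation (a cbb3-type oxidase gene
  within 5 kb on the same replicon), because the P1B-1c motif set overlaps
  the plain P1B-1 motifs and the clade is defined by its FixI association.
* Pentads shaped `MXXSS` but outside the five observed variants are
  accepted for rule 6 with a warning recorded in the evidence — the rule
  set does not claim the observed pentads are exhaustive.

Every label carries the fired rule chain as evidence, so any assignment
can be re-derived by hand. Classification is order-stable and total.

## 4. Composition-based HGT screen

* **G+C**: percent G+C with ambiguity codes excluded from numerator and
  denominator (the original web calculator's behavior is unspecified;
  exclusion avoids bias).
* **G+C deviation**: a **paired** t-test of per-gene vs own-genome G+C
  (99% CI). Paired, because the described comparison is per gene against
  its own genomic context; an unpaired Welch variant would conflate
  between-genome variance with the signal. Per-gene deviance additionally
  uses a 2-point margin.
* **CAI**: geometric mean of relative adaptiveness `w`, excluding stops
  and the non-degenerate Met/Trp codons (standard practice; the source is
  silent), with unseen codons floored at `w = 0.01` so one missing codon
  cannot zero the geometric mean.
* **eCAI**: the (1 − p) quantile (p = 0.01) of CAI over `n = 500` random
  sequences with the query's exact amino-acid composition and uniform
  synonymous codon choice. The quantile form makes "CAI/eCAI < 1 at
  p < 0.01" well defined; whether the original server preserved amino-acid
  order in a Markov sense is unstated, and uniform synonymous sampling is
  adopted. Reproducible under a seed; the Monte-Carlo error at n = 500 is
  about ±0.02 (checked against an n = 50,000 oracle).
* **Closest homolog**: local BLOSUM62 alignment (gap open 10, extend 0.5)
  against a user-supplied database; identity and similarity (positive
  substitution scores) over alignment columns, coverage over the aligned
  query span; "foreign" requires 50/70/90 plus a subject taxon outside the
  query's class.
* **Verdict**: foreign homolog AND (G+C deviant OR CAI deviant); the
  metal/mobility cluster scan (≥ 2 keyword neighbors within 75 kb) is
  supporting evidence only, mirroring the narrative use of genomic-island
  and cluster context. Direction-of-transfer reasoning is reported
  descriptively, never as a hard verdict.

## 5. Chaperone detectors

All three detectors require a calibrated family profile match at E ≤ 1e-3
plus family-specific evidence. Length bounds are soft-widened versions of
the observed ranges, because observed ranges are not filters: CopZ
[50, 150] around the observed 67–114; CupA [90, 170] around 100–150; CusF
lengths are reported but unfiltered (observed 94–236). CupA's N-terminal
transmembrane helix is a Kyte–Doolittle window (mean > 1.6 over 19
residues, starting within the first 40). CusF's invariant H36/M47/M49 are
checked through a reference-position map carried by the profile — absolute
numbering breaks under indels, so positions map through match states of a
designated reference row. The five electropositive positions
(23/30/31/35/50) are reported as a polymorphism profile, not filtered, and
the missing Cys…Cys-X-Met-X-Met motif in CupA partners is an annotation,
not a filter.

## 6. What the synthetic world is, and is not

The generators define the package's stated world:

* Cu-ATPases are a fixed 320-residue family consensus with subtype motif
  layouts planted at fixed template coordinates (N-MBD 1–180, TM6 200–202,
  TM7 240–246, TM8 280–284) plus divergence noise outside motifs.
  Cysteine is excluded from background and (in the survey bundle) from the
  noise alphabet, because spurious CXXC/CXCXC motifs would silently
  corrupt ground truth; the classifier robustness criterion uses the full
  20-letter noise alphabet instead, and its ≥ 95% bar absorbs the rare
  spurious-motif failures. Histidine is likewise only ever planted in the
  N-MBD.
* The survey bundle draws per-genome copy numbers from the reported
  copy-number histogram (0–8, modal at 1–3), subtypes with the reported
  prevalence ranking, a 43% plasmid fraction, and genome G+C in 57–63%.
* HGT scenarios use alanine/glycine-rich proteins (typical of GC-rich
  genomes, and necessary for +4.8-point G+C targets to remain reachable by
  synonymous choice), a donor codon table with reversed synonymous
  preferences, and per-gene G+C jitter of σ = 0.5 points.
* `simulate_alignment` evolves substitutions only — no indels — with
  per-site gamma categories drawn at the root.

A green test therefore establishes that the implemented procedure recovers
planted truth under homologous-family statistics with site-independent
substitutions. It does not establish robustness to real-data features the
world omits: domain rearrangements, indel-rich alignments, compositional
heterogeneity across lineages, ameliorated (old) transfers, or annotation
errors.

## 7. Numerical choices and degenerate inputs

* Branch lengths are optimized in a local Brent bracket around the current
  value (1/30× to 30× + 0.2), accepting only improvements, so NNI
  trajectories cannot decrease; likelihood columns rescale when partials
  drop below 1e-150.
* Gamma shape is fitted on [0.05, 10] by golden-section, alternating with
  branch-length rounds.
* Saturated pairwise distances cap at 10 with a warning; identical
  sequences short-circuit to 0.
* Zero-variance G+C differences return a degenerate report with no
  p-value rather than NaN.
* All Monte-Carlo stages (decoy calibration, eCAI, bootstrap, simulation)
  take explicit seeds, save and restore the caller's RNG state, and are
  bit-reproducible; `run_all` manifests carry md5 digests over every
  artifact and reruns are digest-identical.

## 8. Known limitations

Pure-R tree search limits full-scale (hundreds of taxa) ML analyses;
`paper_scale` settings exist but are intended for long-running jobs, and
the desk defaults (BioNJ + 50 bootstrap replicates) are the tested path.
The profile HMM is single-domain and glocal only. E-value calibration is
decoy-based and approximate in the extreme tail. The SH-like aLRT
statistic is not implemented; supports are bootstrap proportions.
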