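---
title: "Methods: toxin-gene discovery in venom-gland transcriptomes"
author: "venomscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toxin-gene discovery in venom-gland transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(venomscreen)
```

## The problem

Caterpillars with urticating (stinging) hairs, like other venomous animals,
express a cocktail of secreted toxins in their venom-producing tissue. Given
a de novo assembled transcriptome of that tissue (a set of nucleotide
contigs, called Unigenes), a fragment-count table from read mapping, and
free-text functional annotations, the analysis asks four questions:

1. Which contigs encode **toxin homologs** — and are they genuinely toxins
   rather than housekeeping relatives of toxin families?
2. Which highly expressed contigs with **no database hit** encode novel
   secreted cysteine-rich peptides (inhibitor-cystine-knot, "knottin",
   candidates)?
3. Which toxin families show **lineage-specific expansion** relative to
   non-venomous comparison species?
4. What are the **evolutionary relationships** within each recovered family?

`venomscreen` implements this workflow as deterministic, testable R
functions, with a seeded synthetic-transcriptome generator that plants
ground truth so that the entire pipeline can be validated end to end.

## Homology search

BLAST-style search is replaced by an exact affine-gap Smith–Waterman
implementation (Rcpp): BLOSUM62, gap open 11, gap extend 1, where a gap of
length $g$ costs $11 + (g-1)$. Bit scores and E-values use the
Karlin–Altschul form

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2},
\qquad E = m\,n\,2^{-\mathrm{bit}},$$

with the ungapped constants $\lambda = 0.267$, $K = 0.041$ applied to gapped
scores, as BLAST does for this parameter set. Translated search
(`search_translated`) aligns every stop-free segment of at least 10 residues
from all six reading frames. The ambiguity residue `X` (from `N`-containing
codons) scores 0 against everything, so it neither rewards nor penalizes.

**Word prescreen.** Database-scale operations (`search_translated`,
`search_protein`, `cluster_families`) first require the query/subject pair
to share at least one exact 5-mer; pairs that do not are reported as no-hit
without running the DP. At the E-value cutoff used throughout
($10^{-5}$), a reportable alignment of two ~250-residue proteins needs a raw
score near 100, which in practice implies long stretches of conservation and
dozens of shared 5-mers, so the prescreen is effectively lossless for
reportable hits while removing the vast majority of unrelated pairs. It is
configuration (`prefilter_k`; `0` disables it), and the pairwise primitives
`local_align`/`global_align` are always exact.

## Candidate-toxin classification

`classify_transcriptome` composes seven steps:

1. **Keyword preselection** — case-insensitive substring match of nine
   toxin-related terms (serine protease, protease inhibitor, serpin, venom,
   toxin, allergen, CAP, phospholipase A2, lopap) against the annotation
   text.
2. **Toxin-database search** — the best translated hit fixes the reading
   frame; the open reading frame carrying the homologous region is chosen by
   re-alignment score among the frame's ORFs.
3. **Conserved-region gate** — the best toxin hit must span at least 40% of
   the subject (`min_subject_coverage`). This is an explicit, reproducible
   proxy for the visual "conserved region" check an annotator would perform
   on a family alignment.
4. **Animal-database search** of the candidate protein.
5. **Dual-database differential filter** — the candidate is discarded when
   its best general-animal hit scores *strictly higher* than its best
   toxin-database hit, unless the animal hit comes from a venomous or
   poisonous taxon. Scores are compared as bit scores by default
   (comparable across databases of different sizes; `score_type = "raw"`
   switches to raw scores). A tie keeps the candidate.
6. **Completeness tagging** — `Full`, `NTE`, `CTE` or `NC`: the N terminus
   is present when the ORF starts at a methionine *and* the alignment
   reaches within 20 residues (`margin`) of the subject N terminus;
   symmetrically for the C terminus with the stop codon.
7. **Fragment merging and reciprocal expansion** — same-family candidates
   sharing the same best-hit subject are merged into a `Join` gene model if
   their subject spans overlap by ≥ 15 residues at ≥ 90% identity between
   the two query sequences. Only complementary partial models merge (a
   C-incomplete fragment with an N-incomplete one); without that guard two
   near-identical full-length paralogs of the same subject would be fused.
   Finally, candidate proteins are searched back against the transcriptome;
   newly hit contigs pass through the full classification path with
   provenance `reciprocal`. The expansion iterates to a fixpoint with a cap
   of three rounds (a superset of the single pass an annotator would run;
   the cap guarantees termination).

All thresholds live in `classify_config()` with the defaults above. The
completeness margin (20 aa) and the merge thresholds are conservative
choices, not published values, and are deliberately configuration.

## The novel-peptide (knottin) screen

`screen_novel` formalizes a manual inspection as a deterministic cascade:

1. **No-hit, high expression** — contigs without any hit at $E \le 10^{-5}$
   in either database, with FPKM at or above the rank threshold of the top
   2.5% (`top_fraction`): the FPKM of the $\lceil 0.025\,n\rceil$-th highest
   contig, ties included. The quantile pool is the contigs with positive
   counts by default (`expressed_only`); a contig assembled from reads
   necessarily has at least one supporting fragment, so the two readings
   coincide on well-formed inputs.
2. **ORF** — Met-initiated ORFs of ≥ 40 residues (below the smallest
   published novel peptide of this kind, 46 aa, to avoid clipping true
   positives); the longest qualifying ORF yields at most one call per
   contig.
3. **Signal peptide** — a simplified von Heijne-style rule
   (`detect_signal_peptide`): the smallest cleavage index in [12, 35] with
   an 8-residue window of mean Kyte–Doolittle hydropathy ≥ 2.0 inside the
   signal, small residues (`A,G,S,C,T,V`) at the −3 and −1 positions, and a
   non-negatively charged n-region before the earliest hydrophobic window.
   This is a hydropathy heuristic, not an HMM; its thresholds are exposed.
4. **No transmembrane helix** in the mature peptide: no 19-residue window
   with mean hydropathy ≥ 1.8.
5. **Cysteine framework** — exactly six cysteines in a mature peptide of
   30–90 residues with inter-cysteine gaps C1–C2 ∈ [2,12], C2–C3 ∈ [3,16],
   C3–C4 ∈ [0,8] (adjacent `CC` allowed), C4–C5 ∈ [1,12], C5–C6 ∈ [3,20] —
   ranges derived from canonical ICK descriptions — reported with the
   knottin connectivity C1–C4, C2–C5, C3–C6.

Three-dimensional fold recognition is explicitly out of scope; the cysteine
framework plus the secretion gates is the deterministic stand-in, so a call
means "secreted six-cysteine peptide with ICK-compatible spacing", not a
verified knot.

## Expression

FPKM is computed from the count table as
$\mathrm{FPKM} = c \cdot 10^9 / (L \cdot N)$ with $c$ the fragment count,
$L$ the contig length in bp and $N$ the total mapped fragments. Read
mapping itself is upstream of this package: the count table is an input.
Rank percentiles use average ranks from the top. Family box-plot summaries
use linearly interpolated quartiles (`quantile` type 7 — the plotting
convention of the original figures is unknown, so the default R convention
is used and stated) and flag members beyond 1.5·IQR.

## Gene-family expansion

Orthologous-group counting is a single-linkage clustering: all-vs-all local
alignment (with the word prescreen), edges at $E \le 10^{-5}$ and ≥ 40%
identity, connected components as families. The identity floor curbs the
chaining that pure single linkage invites; an MCL-style inflation step is
deliberately not reimplemented. Pairs already connected are skipped, which
is exact for single linkage. Each family is labeled by the majority toxin
class of its members.

The expansion test treats the per-species gene counts of one family as a
goodness-of-fit problem against equal expected counts
(df = species − 1; with five species df = 4, matching the published
per-family statistics this package's tests reproduce). Families are tested
only when they have more than five genes in every species; raw p-values are
reported with a significance flag at α = 0.05 and no multiple-testing
correction, matching how such per-family tests are conventionally reported.

## Phylogenetics

A deliberately simple distance stack stands in for the ML pipeline of the
original analysis — the *machinery* (alignment, trimming, distances, trees,
bootstrap, rooting) is provided; published topology claims are not
reproduced, and maximum likelihood with model selection is a non-goal:

- `center_star_align`: the center sequence minimizes the summed pairwise
  global-alignment p-distance; others are merged onto it under "once a
  gap, always a gap". Deterministic (lexicographic tie-break).
- `drop_gappy_columns`: columns with gap fraction > 0.5 removed.
- Distances: p-distance with pairwise deletion, Poisson-corrected
  ($d = -\ln(1-p)$), with saturated pairs capped at 10.0 so matrices stay
  finite.
- `nj_tree`: Saitou–Nei neighbor joining; ties on the Q criterion break on
  the lexicographically smallest pair; negative branch lengths are clamped
  to zero with the deficit moved to the sister branch. NJ is exact on
  additive matrices, which the test suite exercises against path-length
  oracles.
- `bootstrap_support`: column resampling (default 1000 replicates),
  supports as the percentage of replicate trees containing each original
  bipartition; computed on the fixed original topology (no consensus).
- `midpoint_root`: root at the midpoint of the longest leaf-to-leaf path,
  lexicographic tie-break, node-exact rooting when the midpoint falls on a
  node.

## The synthetic transcriptome

`simulate_bundle` generates the full labeled universe from one seed:
toxin and animal protein databases, a focal-species transcriptome, counts,
annotations and truth labels. It emulates the statistical structure the
pipeline assumes:

- **Families** (see `default_families()`): 14 toxin families whose focal
  gene counts mirror the family-size spectrum reported for a caterpillar
  venom-gland transcriptome (168 homology candidates in total), with the
  chymotrypsin-family serine protease (peptidase S1) five-fold expanded
  (12 genes per comparison species, 60 focal) and truncated/split gene
  models hosted in that family. Ancestor proteins are random sequences of
  family-specific lengths (120–450 aa); gene lineages diverge from the
  family ancestor and species copies from each lineage at a per-branch
  substitution probability of 0.15 (no indels inside homologs, so
  completeness truth stays unambiguous).
- **Margins by construction.** Every planted positive clears each pipeline
  threshold with margin and every planted negative misses with margin, for
  *any* seed: animal-database relatives of toxin genes derive from a
  comparison-species copy plus extra divergence (strictly farther than the
  toxin database, so the dual filter keeps them); serine-protease-like
  housekeeping decoys carry protease keywords but a 95%-identical animal
  database source (the dual filter must discard them); CAP-family genes
  get a *closer* animal relative flagged as a venomous taxon (the
  exception must keep them); truncations remove 40–50 residues — more than
  twice the 20-residue margin — and carry a planted methionine within their
  first five residues so ORF start-trimming cannot erode the alignment;
  split pairs overlap by 24–28 identical residues and share a dedicated
  near-identical database "sister" entry, so both fragments agree on one
  best-hit subject; knottin counts are raised until every knottin's
  count-per-base exceeds 1.3× the best non-knottin (FPKM ratios are
  independent of the total, so this pins the top-2.5% set exactly).
- **Expression** is heavy-tailed: per-contig means are log-normal
  (log-scale μ = 3, σ = 1.5), counts negative-binomial (size 5), floored at
  one fragment (an assembled contig must have support), with knottin means
  at 50× the median. The transcriptome totals 289 contigs, large enough
  that the top-2.5% rank set can hold all eight planted knottins
  ($\lceil 0.025 n \rceil \ge 8$ requires $n \ge 281$); the generator
  validates this and rejects configurations that cannot satisfy it.
- **Noise** contigs are first-order Markov resamples of the pooled real
  contigs (dinucleotide composition preserved).

What the generator does *not* emulate — and what green tests therefore do
not show about real data: sequencing error, assembly chimerism and
fragmentation beyond the planted truncations, indels between homologs,
multi-mapping ambiguity in counts, biased amino-acid composition,
low-complexity regions, and annotation text that is wrong rather than
merely absent. Recovery rates of 100% on the planted universe validate the
pipeline's logic and thresholds, not its performance on noisy biological
input.

## Scales and seeds

All randomness descends from a single seed (the generator's, plus an
explicit seed for bootstrap resampling). The default end-to-end run
(`run_all`) on the 289-contig bundle classifies, screens, clusters the
~700 focal + comparison proteins, tests expansions, and builds per-family
NJ trees for families of 4–40 members at 100 bootstrap replicates —
sizes chosen so a complete run finishes in about two minutes on one core;
`bootstrap_support` itself defaults to 1000 replicates for standalone use.
Reruns on identical inputs are byte-identical.

## Known limitations

- The signal-peptide and transmembrane rules are hydropathy heuristics;
  they formalize, not reproduce, predictor output.
- The cysteine-spacing framework cannot distinguish a true knot from other
  six-cysteine topologies.
- Single-linkage families can over-merge at permissive thresholds; the
  identity floor mitigates but does not eliminate chaining.
- The center-star aligner is adequate for closely related families but
  inferior to progressive aligners for deep divergence; distances saturate
  at the configured ceiling.
- The word prescreen can in principle miss a borderline-significant hit
  between extremely diverged sequences; disable it (`prefilter_k = 0`)
  for exhaustive search at a quadratic cost.
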