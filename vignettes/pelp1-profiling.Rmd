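---
title: "Profiling PELP1-family proteins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling PELP1-family proteins: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

PELP1 (Proline-, Glutamic acid-, Leucine-rich Protein 1) is a nuclear
scaffolding protein that couples steroid-receptor signalling to ribosome
biogenesis. At the sequence level the family is recognisable by a fixed
domain architecture — an N-terminal RIX1 (Ribosome Export 1, Pfam PF08167)
domain followed by one or two NUC202 (nucleolar, Pfam PF08166) domains —
and by a set of short linear motifs inside the RIX1 region: eleven LxxLL
nuclear-receptor boxes (LM1–LM11, with LM5 a 9-residue tandem LxxLLxxLL)
and three PxxP motifs (PM1–PM3). The C-terminal half is a low-complexity
region rich in proline, glutamic acid and cysteine.

`pelpscope` implements the sequence-level profiling stages used to
characterise such a family across species: screening candidate proteins by
domain architecture, quantifying compositional enrichment against proteome
background frequencies, measuring per-position motif predominance by
reference-anchored alignment, and summarising cross-species divergence as a
percent-identity matrix with hierarchical clustering. A seeded synthetic
cohort generator with planted ground truth makes every stage testable
without database downloads.

## Screening model

Domain hits arrive as HMMER3 `--domtblout` tables or plain TSVs. Hits with
per-domain independent E-value above a configurable acceptance threshold
(default 0.01 — search tools differ in their defaults, so the threshold is
explicit) are dropped. Same-domain hits on one protein that overlap by more
than 50% of the shorter hit are reduced to the best hit (lowest E-value,
ties by higher score, then smaller start); the 50%-of-shorter rule and the
deterministic tie-break are this package's own convention, chosen so that
repeated runs give identical calls. Architecture labels are a pure function
of the surviving counts:

| n(RIX1) | n(NUC202) | label |
|---|---|---|
| ≥1 | 2 | `PELP1_2NUC` |
| ≥1 | 1 | `PELP1_1NUC` |
| ≥1 | ≥3 | `PELP1_multiNUC` |
| ≥1 | 0 | `RIX_only` |
| 0 | ≥1 | `NUC_only` |
| 0 | 0 | `other` |

`PELP1_multiNUC` is a robustness label: observed PELP1 proteins carry one
or two NUC202 copies, but the classifier should not fold a three-copy
protein silently into either class. Multiple non-overlapping RIX1 hits are
retained in the call (`n_rix`) but do not change the label.

Duplicate removal is conjunctive: two records are duplicates only when
they share both 100% sequence identity and the species of origin. The
first record in input order is kept — the choice of representative is
arbitrary in principle, so it is pinned to input order for determinism.
Near-duplicates below 100% identity are never collapsed.

## Composition and enrichment model

For a protein of length $N$ (unknown residues `X` excluded from both
numerator and denominator — an `X` is an unobserved residue, not an absent
one), the composition of residue $r$ is $p_r = n_r / N$. Enrichment is a
fold change against a background distribution $b_r$:

$$\mathrm{FC}_r = \frac{n_r / N}{b_r}, \qquad
  \text{enriched} \iff \mathrm{FC}_r \ge 1.5 .$$

The threshold is inclusive; because the division is done in floating
point, the comparison uses a $10^{-9}$ tolerance so a ratio that is
exactly 1.5 in real arithmetic is always called enriched.
$\log_2 \mathrm{FC}$ is reported as undefined (`NA`) when $n_r = 0$ — no
pseudocounts are added.

The packaged background table is the UniProtKB/Swiss-Prot release
composition statistics (20 fractions, renormalised on load); any
two-column TSV can be substituted. Absolute cohort-level enrichment counts
depend on the background release used, so they are reproducible within the
package but only approximate against counts computed with another table.

Contribution ranks are computed over all 20 residues (rank 1 = highest
percentage, ties get the mean of tied positions); cohort aggregation sums
ranks per residue over proteins and orders the tracked signature residues
(default L, E, P, D, C) by ascending rank sum.

### Detection probability of a planted multiplier

The generator plants compositional bias by multiply-and-renormalise:
multiplier $m$ on residue $r$ turns its frequency into
$f' = m f / Z$ with $Z = 1 + \sum_{\text{planted } j} (m_j - 1) f_j$. The
fold change recovered by the composition module is then $m / Z$ in
expectation, and a planted protein of length $L$ is flagged when its
binomial count reaches $\lceil 1.5\, b_r L \rceil$. For a single 2.0×
proline plant at $L = 500$ this exact detection probability is 0.94 — not
1 — so recovery tests compare the flagged fraction against the binomial
oracle with a 4-SD band rather than against an absolute fraction. At the
study-scale defaults (lengths around 1000, several residues co-planted)
per-protein detection ranges from roughly 0.99 (leucine) down to roughly
0.78 (cysteine, whose low background frequency gives the widest relative
binomial noise); recovered cohort counts sit correspondingly below the
planted prevalence.

## Motif model

Motif windows are located by global pairwise alignment of each protein to
an annotated reference (Needleman–Wunsch, BLOSUM62, affine gaps with open
10 and extension 0.5, all configurable). For each annotated motif the
query residues in the alignment columns spanning the reference motif —
including insertion columns strictly inside the span — form the instance
window; deletions shorten it. Windows whose length differs from the
canonical motif length (5 for LM, 9 for LM5, 4 for PM) are flagged
`length_deviant`, reported, and excluded from positional statistics, since
per-position percentages presuppose a fixed length.

Per-position predominance is computed over the counted instances with the
total set to 100%. The consensus pattern shows, at each position, the
residues contributing strictly more than 10% (the display rule is
strictly-greater-than; integer rounding happens after thresholding), as
`R(pct)` terms joined by `/`; a position at 100% is flagged fully
conserved. Position-frequency matrices are exported as TSV in percentage
and raw-count forms; re-importing a PFM regenerates the consensus string
exactly.

The reference's motif coordinates are not hard-coded: they are derived by
a greedy N-to-C scan for the canonical patterns (trying the 9-mer tandem
first, then LxxLL, then PxxP) and numbered in the canonical order
LM1, PM1, PM2, LM2, …, PM3, LM10, LM11. This auto-derivation is a
documented convention of the package, not a claim about any published
coordinate set; an explicit annotation TSV overrides it. The packaged
reference itself is fully synthetic (see below), so coordinate-faithful
analyses of a real family should supply the real reference sequence plus
its annotation.

The de novo scanner counts LxxLL / PxxP matches both with overlaps and
with a greedy left-to-right sweep in which consecutive matches may share
one boundary residue — so the tandem LxxLLxxLL counts as two boxes and
PxxPxxP as two PxxP.

## Identity and clustering model

Percent identity between two proteins is computed from their global
pairwise alignment as identical columns divided by columns containing at
least one residue (in a pairwise global alignment, every column), ×100.
Identities are pairwise, not extracted from a multiple alignment: this
avoids a progressive-MSA dependency and is documented as an approximation
— values from MSA-based tools will differ by a few points. Each unordered
pair is aligned once and mirrored, making the matrix symmetric by
construction.

Clustering follows the heatmap-viewer convention: Euclidean distances
between identity-matrix rows (each protein represented by its identity
vector), agglomerative clustering with average linkage by default
(complete and single are available), leaf order made deterministic by
label-sorted tie-breaking. The dendrogram exports to Newick with branch
lengths equal to merge-height differences, and the reordered matrix to a
labelled TSV for heatmap rendering (blue at 0%, red at 100% when an image
is requested).

## What the synthetic generator emulates — and what it does not

The generator draws cohorts whose defaults are the study conditions the
package targets: 646 proteins, lengths ~N(1000, 150) (clamped at 660 so
fabricated domain coordinates fit), domain architectures allocated exactly
as 589 double-NUC202 and 57 single-NUC202 by largest remainder,
compositional enrichment planted at the published per-residue prevalence
(P in 469/646 proteins, E 459, C 252, Q 119, S 95, L 64, G 20, multiplier
2.0), no duplicates unless requested. Motif-planned cohorts share the
synthetic reference backbone with a configurable fraction of substituted
sites (default 0.2) and splice emission-sampled windows at the annotated
offsets, with optional single-residue indels inside windows. Per-protein
RNG streams are derived from the cohort seed by counter offsets, so
protein *k* regenerates identically regardless of cohort size; the same
spec and seed give byte-identical output files.

What it deliberately does not emulate: real phylogenetic descent (the
family simulator applies independent per-lineage substitutions from a
single ancestor — sufficient for within- vs between-family identity
contrasts, not for tree-shape realism), indel evolution outside motif
windows, genuine low-complexity tail structure, database noise such as
fragments or mispredicted isoforms, and any real PELP1 sequence content.
Passing tests therefore demonstrate that the pipeline's statistics recover
known planted signals under controlled noise — they do not certify
numerical agreement with analyses of the real family, which additionally
depend on the search engine, background release and alignment tool used.

## Numerical choices and degenerate inputs

* Enrichment threshold comparison carries a $10^{-9}$ tolerance (see
  above); the >10% consensus display rule is exact (strictly greater).
* Alignment tie-breaking is delegated to the alignment engine; scores are
  checked against an exhaustive-enumeration oracle, alignments themselves
  are not asserted unique.
* A sequence consisting only of `X` has no composition denominator and is
  an error; an empty FASTA is an empty cohort, not an error.
* Motif instances containing `X` are excluded from positional counts
  (consistent with `X` never counting as a specific residue).
* `hclust` heights are doubled before Newick conversion because
  `ape::as.phylo` halves them; branch lengths in the exported tree are
  merge-height differences.
* Windows fully deleted by alignment transfer have length 0 and stay in
  the instance table as length-deviant.

## Problem sizes used by the tests and scripts

The shipped suites run at sizes chosen to give tight statistical bounds
at interactive runtimes: the study-scale cohort at its natural n = 646;
motif-consensus recovery at 1000 instances per motif (multinomial SE
< 1.6 percentage points); aligner-oracle equivalence exhaustively for all
pairs up to length 2 over a four-letter alphabet plus randomised pairs to
length 6 (enumeration grows as the Delannoy numbers, so exhaustive
coverage beyond tiny lengths buys no additional assurance); identity
clustering on 22 representatives in the analysis workflow, mirroring the
representative-subset design used for cross-species comparisons.

## Known limitations

* Alignment-transferred windows are ambiguous when an indel sits exactly
  at a motif boundary; at 20% backbone divergence with 2% indel rates,
  window recovery is ≥95% exact rather than perfect. This is a property
  of alignment transfer itself, not of the implementation.
* Pairwise identities underestimate MSA-derived identities for divergent
  sequences; the matrix is internally consistent but not comparable
  across conventions.
* Enrichment counts at cohort scale inherit binomial detection noise
  (see the detection-probability section); planted prevalence is
  recovered as a lower bound, most visibly for cysteine.
* No positional (windowed) enrichment along the sequence is computed;
  composition is whole-protein.
* The screening module consumes hit tables; it does not run HMM or BLAST
  searches.
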