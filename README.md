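# pelpscope

Cross-species profiling of PELP1-family proteins from sequence data.

PELP1 (Proline-, Glutamic acid-, Leucine-rich Protein 1) is a nuclear
scaffolding protein recognisable by one RIX1 (Ribosome Export 1, Pfam
PF08167) domain followed by one or two NUC202 (nucleolar, Pfam PF08166)
domains, eleven LxxLL nuclear-receptor boxes and three PxxP motifs in the
RIX1 region, and a proline/glutamic-acid/cysteine-rich low-complexity
C-terminus. `pelpscope` implements the sequence-level analyses used to
characterise such a family across species, for anyone screening candidate
homologs from domain-search output:

* **Screening** — parse HMMER3 `--domtblout` or TSV domain-hit tables,
  resolve overlapping hits, classify each protein's architecture
  (`PELP1_2NUC`, `PELP1_1NUC`, `RIX_only`, `NUC_only`, …) and summarise
  counts by taxonomy. Duplicate records (100% identity *and* same species)
  are removed, keeping the first.
* **Composition** — per-residue composition and fold-change enrichment
  FC_r = (n_r/N) / b_r against proteome background frequencies
  (packaged UniProtKB/Swiss-Prot table), with the inclusive call
  FC ≥ 1.5, log2 fold changes (undefined at zero counts), contribution
  ranks and cohort-level rank aggregation.
* **Motifs** — global Needleman–Wunsch alignment (BLOSUM62, affine gaps
  10/0.5) of each protein to an annotated reference, alignment transfer of
  the LM1–LM11/PM1–PM3 windows, per-position predominance with the
  strictly-greater-than-10% consensus display rule, PFM export, and a de
  novo LxxLL/PxxP scanner.
* **Identity** — all-vs-all percent identity (identical columns / columns
  with ≥1 residue), Euclidean-distance hierarchical clustering of the
  identity rows (average linkage by default), heatmap table and Newick
  tree export.
* **Synthetic cohorts** — a seeded generator planting compositional
  multipliers, emission-sampled motif windows, domain architectures,
  duplicates and taxonomy labels, with full ground truth, so every stage is
  verifiable offline.

## Worked example

Generate a study-scale synthetic cohort (646 proteins at the family's
published architecture and enrichment prevalence), classify and profile it:

```r
library(pelpscope)

g <- generate_cohort(cohort_spec(seed = 1))

calls <- classify_cohort(g$hits, g$cohort$id)
table(calls$label)
#> PELP1_1NUC PELP1_2NUC
#>         57        589

profiles <- compose_cohort(g$cohort)
enrichment_counts(profiles)[c("P", "E", "C", "L")]
#>   P   E   C   L
#> 434 433 197  57

aggregate_ranks(profiles)
#>  residue rank_sum overall_rank
#>        L   1491.0            1
#>        E   1765.5            2
#>        P   3327.5            3
#>        D   6444.5            4
#>        C  11796.5            5
```

The architecture counts recover the planted 589/57 split exactly. The
enrichment counts sit a little below the planted prevalence (469, 459,
252, 64) because a 2.0× planted multiplier is detected with probability
below one — about 0.78 for cysteine up to about 0.99 for leucine at these
lengths (see the methods vignette). Leucine is the top overall contributor
by rank even though it is rarely *enriched*: it is abundant everywhere, so
its background frequency is high.

Motif consensus from 1000 instances sampled from the LM3 emission table:

```r
cs <- position_frequencies(generate_motif_instances("LM3", 1000, seed = 2), 5)
cs$consensus_pattern
#> "L(95)-L(95)-S(85)-L(54)/M(22)/V(14)-L(91)"
```

The full workflow (simulate, screen, compose, motifs, identity) is scripted
as numbered drivers under `analysis/`; each writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen.R
# ...
Rscript analysis/05_identity.R
```

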