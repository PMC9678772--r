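# chromcoloc

Colocalization and regulatory-element enrichment analysis for chromatin
interval sets.

Given the peaks of a chromatin-bound protein (ChIP-seq), chromcoloc asks
which transcription-factor binding catalogs, open-chromatin regions, and
gene-linked regulatory elements those peaks associate with beyond chance,
and at which genomic scale. It is aimed at computational biologists who
have BED-family interval data (peaks, TF site catalogs, ATAC peaks), a
regulatory-element table with gene pairings, a differential-expression
gene list, and JASPAR-format motifs, and who want the entire inference
chain — permutation nulls, multiple-testing control, group comparisons,
and motif statistics — reproducible from one seed.

## The statistics at the core

**Shuffle-null colocalization.** For query set $Q$ and catalog $C$, the
observed count of overlap events (intersection ≥ a minimal fraction,
default 10%) is compared against $S$ shuffled replicates of $Q$ that
preserve interval lengths and chromosomes (default $S = 15$), optionally
inside a restricted universe. With
$z = (n_{obs} - \bar n_{null})/sd_{null}$, the two-tailed p comes from a
Student $t$ with $S-1$ df (the null sd is estimated, so a normal tail
would be anti-conservative at small $S$), q-values are
Benjamini–Yekutieli across catalogs, and the effect is
$\log_2((n_{obs}+1)/(\bar n_{null}+1))$. The screen runs at three
scales: peaks as-is, peaks with 100-kb flanks, and peaks against their
own merged 1-Mb neighborhood as the shuffling universe.

**Feature annotation.** Two-tailed Fisher exact tests on interval-count
contingency tables (the unobservable "neither" cell estimated by the
bedtools convention, `round(G / mean length)` minus the rest), peak
fractions per feature class versus genome fractions, promoter blocks
`[TSS − 5 kb, TSS + 1 kb)`, TSS-distance binning, and the fraction of
peaks within 10 kb of open chromatin.

**Enhancer–gene pairing and the dual background.** Regulatory elements
with score > 0.7 paired to differentially expressed genes are split into
peak-associated and peak-free groups (≤ 10 kb edge-to-edge); the groups
are compared on score, length, and TSS distance (Mann–Whitney), and each
TF catalog is tested between groups with a continuity-corrected
chi-square plus per-Mb site densities. Abundant TFs (> 75% of
peak-associated elements) feed a 0/1 presence matrix, PCA with iterative
SVD imputation, and average-linkage clustering (Euclidean for elements,
Canberra for TFs, with 0/0 terms contributing zero).

**Motif enrichment.** Log-odds PWM scanning of both strands (hit = score
≥ 80% of the consensus score), fold enrichment of per-kb hit rates in
query versus control sequences, and a two-sided binomial p at the control
hit rate. A dinucleotide-preserving shuffle is provided for building
controls.

**Synthetic data.** `generate_dataset()` emulates every input from a
seeded spec — genome, TF catalogs, peaks planted to colocalize with
chosen catalogs at probability 0.6 within 500 bp, open chromatin, scored
regulatory elements with gene links, DE lists, and motif-bearing
sequences — and records the planted truth in a manifest, so the full
chain is testable offline.

## Worked example

Simulate a dataset and run the first stages of the pipeline:

```r
library(chromcoloc)

out <- "demo_run"
cfg <- run_stage("simulate", validate_config(list(seed = 11)), out)
for (st in c("coloc", "annotate", "re-pair")) cfg <- run_stage(st, cfg, out)

co <- read_stage_tsv(file.path(out, "coloc.tsv"))
co <- co[co$scale == "flank0", ]
co[order(co$q_by), c("catalog", "n_obs", "mean_null", "z", "q_by",
                     "log2_effect", "selected")][1:4, ]
```

```
    catalog n_obs mean_null      z     q_by log2_effect selected
 SMAD3_like   171      11.5 55.972 1.57e-16       3.786     TRUE
  IRF1_like   164      10.7 41.262 5.49e-15       3.822     TRUE
  TF_null_1    14      11.1  0.974 1.00e+00       0.314    FALSE
  TF_null_2    10       9.2  0.322 1.00e+00       0.109    FALSE
```

The two factors the generator planted (60% of peaks anchored within
500 bp of their sites) are recovered with q ≈ 0 and ~3.8 log2-fold more
overlap events than the shuffle null; the six null factors sit at their
null means and are not selected (selection = q < 0.05 and catalog
size > 100).

```r
read_stage_tsv(file.path(out, "re_split.tsv"))
read_stage_tsv(file.path(out, "open_chromatin.tsv"))
```

```
          group   n
     with_peaks 204
  without_peaks 187
 selected_total 391

 max_dist fraction_near_open_chromatin
    10000                        0.824
```

Of the 391 regulatory elements that score > 0.7 and pair to a DE gene,
204 lie within 10 kb of a peak; 82.4% of peaks are within 10 kb of open
chromatin. (Both numbers fold in substantial chance proximity at this
simulated density — the generator's manifest records the planted rates,
0.12 and 0.25, and the tests verify recovery against that truth.)

A thin command-line wrapper over the same functions is installed at
`inst/scripts/chromcoloc`:

```sh
Rscript inst/scripts/chromcoloc all --seed 11 --out-dir demo_run
```

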