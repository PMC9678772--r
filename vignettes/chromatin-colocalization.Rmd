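---
title: "Colocalization analysis of chromatin interval sets: models and design"
author: "chromcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colocalization analysis of chromatin interval sets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcoloc)
```

## The problem

A ChIP-seq experiment for a chromatin-associated protein yields a set of
genomic intervals (peaks). The recurring question is whether those peaks
fall near the binding sites of known transcription factors, near open
chromatin, or inside regulatory elements more often than chance placement
would produce — and if so, which factors, at which genomic scale, and with
what consequence for the genes those elements regulate. chromcoloc
implements that analysis chain for interval sets in BED-family
coordinates: shuffle-null colocalization screening, genomic-feature
annotation, enhancer–gene pairing against a differential-expression list,
dual-background TF enrichment over regulatory-element groups,
presence-matrix PCA with clustering, and known-motif enrichment in peak
sequences. A seeded generator produces every input with planted structure
so the whole chain is testable without external downloads.

All coordinates are 0-based half-open (BED native) at every I/O boundary;
internally interval sets are `GRanges` bound to a `Seqinfo` genome so
out-of-range coordinates fail at construction. Strand is ignored
throughout: every analysis here is strand-agnostic, including promoter
construction (see below).

## The colocalization model

Let $Q$ be the query set ($n$ intervals) and $C$ a catalog of binding
sites. A query interval counts as an *overlap event* when some catalog
interval intersects it and the intersection reaches a minimal fraction
$f$ (default 0.1) of the interval lengths. The fraction can be required
of both intervals, of the query only, or of the catalog site only
(`mode` in `overlap_events()`); the default for a single-scale screen is
both-sided.

The null distribution of the event count comes from shuffling: each
query interval is re-placed uniformly at random among the feasible start
positions of a *universe* (whole chromosomes by default), preserving the
interval-length multiset and, with `by_chrom = TRUE` (the default), each
interval's chromosome. Shuffled intervals may overlap one another — the
null is independent uniform placement, not a packing. With $S$ shuffles
(default 15) the observed count $n_{obs}$ is standardized,

$$ z = \frac{n_{obs} - \bar{n}_{null}}{sd_{null}}, $$

and the two-tailed p-value is taken from a Student $t$ distribution with
$S - 1$ degrees of freedom. The $t$ tail, not the normal, is deliberate:
$sd_{null}$ is itself estimated from the $S$ shuffles, and at $S = 15$ a
normal tail is anti-conservative enough that null catalogs regularly
reach adjusted significance in a screen of several catalogs; at
$S = 100$ the two tails coincide for practical purposes. When
$sd_{null} = 0$ (tiny toys), the p-value is 1 if $n_{obs}$ equals the
null mean and otherwise a floor of 0.5 events is used for the sd, which
avoids infinite $z$ without manufacturing significance.

P-values are adjusted across catalogs with Benjamini–Yekutieli
(`by_adjust()`), which controls FDR under arbitrary dependence — catalogs
of cooperating TFs are strongly dependent — at the price of the harmonic
factor $c(m)$. The reported effect size is
$\log_2((n_{obs}+1)/(\bar{n}_{null}+1))$. The same shuffle replicates are
reused across catalogs within a run: this makes the table reproducible
from one seed and leaves catalogs exchangeable under the null.

### The three scales

`multiscale_enrichment()` runs the screen three ways: the query as-is
against genome-wide shuffling (`flank0`); the query extended by 100-kb
flanks (`flank100kb`), which detects factors that bind *near* rather than
*on* the peaks; and the query as-is with shuffling restricted to the
merged 1-Mb neighborhood of the peaks (`universe1Mb`), a local background
that asks whether a factor is enriched at the peaks *given* that it
frequents their broad neighborhood. A `selected` column applies the
screen filter q < 0.05 and catalog size > 100.

One design choice needs stating: at the multiscale level the overlap
fraction is measured on the catalog interval (`mode = "catalog"`). With
100-kb flanks a query interval is hundreds of times longer than a
typical binding site, so demanding 10% of the *query* length would make
overlap events impossible by construction and silently void the flanked
scale. Measuring the fraction on the catalog site is the only reading
under which "10% minimal overlap" means the same thing at every scale.
`overlap_events()` itself keeps the both-sided default and exposes the
mode switch.

## Feature annotation

`fisher_overlap()` tests two interval sets for association with a
two-tailed Fisher exact test on interval counts. The unobservable
"neither" cell is estimated by the bedtools-fisher convention,
$n_{22} = \max(0,\; \mathrm{round}(G/\bar{L}) - n_{11} - n_{12} - n_{21})$,
with $G$ the genome length and $\bar{L}$ the mean interval length of both
sets; the raw table is always returned so the estimate can be audited.
`feature_distribution()` reports, per feature class, the fraction of
peaks touching the class, the genome fraction the class covers, and
their ratio.

Promoters are built as $[t - 5\,\mathrm{kb},\, t + 1\,\mathrm{kb})$
around each TSS $t$, merged. The pads are configurable; the asymmetric
default treats lower coordinates as upstream, since the pipeline carries
no strand information. `open_chromatin_fraction()` reports the fraction
of peaks within 10 kb (edge-to-edge; overlap = 0; the cutoff is
inclusive) of an open-chromatin interval.

## Regulatory elements and the dual background

`select_connected_res()` keeps regulatory elements with score strictly
above 0.7 that are paired to at least one differentially expressed gene
(case-insensitive symbols, deduplicated by element id), and
`split_by_proximity()` partitions them into peak-associated
(within 10 kb of a peak) and peak-free groups. `compare_covariates()`
checks that the two groups are comparable populations — element score,
length, and TSS distance — with two-sided Mann–Whitney U tests; the
nonparametric choice assumes nothing about the score distribution.

`tf_dual_enrichment()` then asks which TF catalogs distinguish the two
groups: a 2×2 table of elements containing at least one site, tested
with a continuity-corrected chi-square (the `chisq.test` default for
2×2 tables) and Benjamini–Hochberg adjustment over TFs, alongside
per-megabase site densities. The density denominator is the merged base
coverage of each element group, the only denominator that is invariant
to how elements are split into rows. A degenerate margin (a TF present
in every element of both groups) is reported as no association, p = 1.
An optional second axis delegates to the shuffle screen on the
peak-associated elements, giving each TF a genome-background q-value as
well.

`select_abundant_tfs()` keeps TFs present in strictly more than 75% of
the peak-associated elements; `build_presence_matrix()` encodes those
TFs over elements as 0/1, dropping rows with no presence call. Cells are
masked (`NA`) only when a catalog carries no data at all for an
element's chromosome — the one situation where absence of an overlap is
not evidence of absence, and the reason the PCA supports imputation.

### PCA with SVD imputation and clustering

`pca_svd_impute()` centers columns, fills missing cells with the column
mean, and refines them by iterated rank-$k$ SVD reconstruction until the
largest absolute change in an imputed cell drops below $10^{-6}$ or 100
iterations pass. On a complete matrix the loop is a no-op and the result
equals plain centered-SVD PCA. Component signs are fixed by making each
component's largest-magnitude loading positive.

`hcluster()` performs average-linkage agglomeration with Euclidean
distance (for elements) or Canberra distance (for TFs). Canberra is
implemented in-package as $\sum_i |x_i - y_i|/(|x_i| + |y_i|)$ with 0/0
terms contributing zero: the base-R `dist()` implementation rescales the
sum when such terms are omitted, which changes distances between sparse
binary profiles — exactly the data this clustering sees. Average linkage
is the package's choice where no linkage is dictated; it is configurable.

## Motif enrichment

PWMs are parsed from JASPAR PFM text. Scanning scores every window of
motif width on both strands with
$s(w) = \sum_i \log_2 \frac{(c_{w_i,i} + \epsilon)/\sum_b (c_{b,i}+\epsilon)}{\pi_{w_i}}$
(pseudocount $\epsilon = 0.5$, background $\pi$ uniform by default), and
a window is a hit when $s \ge 0.8 \cdot s_{max}$ with $s_{max}$ the
consensus score. Windows containing N are skipped; hit positions are
0-based forward-strand starts. Hits are counted as windows, not as
sequences with at least one hit, because multiple sites per peak are
informative.

`motif_enrichment()` converts hit counts to rates per kb of scanned
windows in the query and control sets, reports
$\mathrm{fold} = \mathrm{rate}_q / \mathrm{rate}_c$ with 0.5 pseudo-hits
per set, and a two-sided binomial p-value for the query hit count at the
control hit probability. The control rate is plugged in as if known, so
the test is exact only when the control set is large relative to the
query; a control several times the query size (the function's
recommendation) keeps the size close to nominal, and the calibration
test runs with a 5× control for that reason. `dinuc_shuffle()` provides
a dinucleotide-preserving (Euler-path) shuffle of real sequence as one
way to build such a control.

## The synthetic generator

`generate_dataset()` emulates every input from one seeded specification:
a 3×10-Mb genome, eight TF catalogs of 600 sites × 200 bp, 1000 query
peaks of 400 bp of which each is anchored within 500 bp of an
`IRF1_like` or `SMAD3_like` site with probability 0.6 per factor (a peak
flagged for both picks one at random), 2000 open-chromatin sites with a
quarter of peaks given a planted neighbor within 10 kb, 1000 regulatory
elements (12% planted within 10 kb of a peak) scored log-normally and
paired to their three nearest genes with distance-decaying scores, a 25%
DE gene subset, and 200 query sequences of 500 bp with the `IRF1_like`
motif sampled from its PFM into 30% of them against 200 plain-random
controls. The planted truth — realized anchor counts, planted element
ids, insertion counts — is written to `manifest.json`, and all
randomness flows from the master seed through named substreams so
regenerating one artifact class cannot perturb another.

Two points about what these defaults mean. First, the planted rates are
nominal probabilities; the manifest records the realized draws, and
recovery tests count against the manifest rather than against raw
observed fractions, because at this density chance proximity is large (a
10-kb window around 1000 peaks covers a substantial share of a 30-Mb
genome, so the observed open-chromatin fraction sits far above the
planted 0.25). Second, the generator is deliberately minimal: bases are
i.i.d. uniform, sites are uniformly placed, and there is no chromatin-
state autocorrelation, GC or mappability structure, peak-width
variation, or motif clustering. Passing tests therefore demonstrate that
the statistics recover planted structure under their own null — not that
real genomes satisfy that null. On real data the local-universe scale
and a carefully chosen sequence background carry the burden the
generator sidesteps.

## Numerical choices, in one place

* Merging unions intervals sharing ≥ 1 bp; bookended intervals stay
  separate. Merge is idempotent and coverage-preserving.
* Flanks clip at chromosome ends and are not auto-merged.
* Nearest-distance ties resolve to the smaller coordinate; distances are
  intervening-base counts (overlap = 0), `Inf` when a chromosome has no
  reference point.
* Shuffle p-values: Student t with `n_shuffles − 1` df; sd floor 0.5
  events for degenerate nulls; BY across catalogs within one scale, not
  across scales (each scale is its own screen).
* PCA imputation: convergence `1e-6`, cap 100 iterations; sign fixed by
  largest-|loading|.
* Clustering ties break deterministically by (lexicographic) label order
  of the input matrix.
* Motif scanning: pseudocount 0.5, uniform background, threshold 0.8 of
  the consensus score — all configurable and recorded in outputs.
* The pipeline runner writes outputs atomically (temp file + rename),
  stamps every table with a config hash, and appends a JSONL manifest
  keyed by output basenames, so identical config + seed reproduces every
  file byte-for-byte.

## Problem sizes used by the test suite

The suite exercises oracle equivalence on hundreds of small random
instances (10-kb toy chromosomes); null calibration with 200 simulations
per screen (100 shuffles for the colocalization null); planted-signal
recovery on 20 generated datasets at the full default scale; and a
scale-separation design with peaks planted 50–200 kb from catalog sites
on a 30-Mb genome. These sizes were chosen so every property is measured
with useful power while the whole suite stays comfortably runnable on a
laptop.

## Known limitations

* The event-count statistic treats a query interval as one event however
  many catalog sites it touches; a base-pair-overlap statistic would
  weight long interactions differently.
* The Fisher `n22` cell is an estimate by construction; conclusions that
  hinge on it should use the emitted raw table.
* The dual-background chi-square treats elements as independent, which
  adjacent elements on real chromatin are not.
* The binomial motif p treats windows as independent trials;
  overlapping windows violate this mildly, and palindromic motifs count
  both strands of the same site.
* No strand awareness anywhere; promoter asymmetry refers to coordinate
  order, not transcription direction.
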