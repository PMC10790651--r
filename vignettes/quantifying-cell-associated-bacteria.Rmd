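---
title: "Quantifying cell-associated bacteria in droplet scRNA-seq"
author: "bacsc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-associated bacteria in droplet scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacsc)
```

## The measurement model

In a droplet experiment each gel-bead emulsion partition (GEM) carries one
host cell and one barcoded bead. Every cDNA molecule captured in that
partition — host mRNA, but also bacterial 16S rRNA-derived cDNA from
bacteria adherent to or inside the cell — receives the same cell barcode
(CB) and a molecule-specific UMI. Two sequencing libraries are made from
the same amplified cDNA: the standard 5' gene-expression (GEX) library,
and a 16S-enrichment library produced by nested amplification of
bacterial 16S cDNA, which retains CBs and UMIs.

`bacsc` estimates, per host cell $c$ and bacterial genus $g$, the number
of captured bacterial molecules as the distinct-UMI count

$$ n(c,g) \;=\; \bigl|\{\, u : \text{some read with } CB=c \text{ was
classified to } g \text{ and carries } UMI=u \,\}\bigr|. $$

Distinct-UMI counting makes the estimate invariant to PCR/sequencing
duplication: duplicating every read changes nothing (a tested
invariant). Genus is the quantification rank because 16S variable
regions are conserved within genera; finer ranks are not reliably
distinguishable from short reads.

### Candidate reads

From the GEX library a read is a candidate when it is **host-unmapped**,
carries a **whitelisted** cell barcode (the droplet caller's filtered
barcode list from the GEX library — the 16S library's own calls are not
used, since only the GEX library defines which droplets are cells),
carries a **UMI**, and is a **primary** alignment
(secondary/supplementary records would double-count one read). From the
16S-enrichment library the host-mapped filter is dropped: the library is
16S-targeted, so host mapping there is incidental. Filtered reads are
tallied per drop reason (`secondary`, `host_mapped`, `barcode`, `umi`)
because troubleshooting a low-yield run starts with where reads were
lost.

Barcodes are compared verbatim, including the trailing `-1` suffix;
whitelist and tags come from the same upstream run, so stripping
suffixes could only introduce collisions. Only corrected tags (`CB`/`UB`
by default, configurable) are used, never the raw uncorrected ones.

### Read-1 trimming (16S path)

The 16S Read 1 is quality-trimmed before classification with the
conventional single-end operator set: adapter clip, LEADING:3,
TRAILING:3, SLIDINGWINDOW:4:15 (cut at the first 4-base window with mean
Phred below 15, then trim trailing sub-threshold bases), MINLEN:36,
HEADCROP:15 (the bases holding CB/UMI, already captured in tags). Two
deliberate simplifications, tested only against this package's own
declared definitions:

* **Adapter clip** truncates at the leftmost exact occurrence of an
  adapter, or of an adapter prefix of ≥10 bases at the read 3' end. The
  cited trimming tool's seed-and-extend/palindrome matching is not
  reproduced.
* **Operator order**: headcrop is applied before the quality operators so
  that MINLEN is the final gate on the surviving read. In a single
  trimming command all operators apply to each read; applying the fixed
  head-crop first and length-filtering last is the order in which the
  operators compose meaningfully (a read whose post-headcrop length is
  below MINLEN is discarded).

Trimming gates only what reaches the classifier in end-to-end runs; the
quantifier itself accepts any post-classification hits.

### Genus assignment

The classifier reports per read the set of best-scoring taxa. The rule:
map every taxon to its genus by walking the lineage (species and strain
collapse upward; kingdom-to-family-only lineages yield nothing); if all
mapped genera agree, assign that genus, otherwise the read is
`unassigned` and contributes to no genus. This conservative
concordance rule was chosen over fractional counting (which would break
integer UMI semantics) and over above-genus LCA buckets (the output
matrix is genus-keyed). How the original analysis resolved multi-hit
reads is not documented; the rule here is declared, not inferred.
Unassigned reads still appear in the read-level annotation for auditing.

### Merge and deduplication

Both libraries sample the same emulsion, so an identical
(cell, genus, UMI) observation in both is one molecule. The merge
unions per-(cell, genus) UMI sets and counts each triplet once,
recording per-triplet provenance (which libraries saw it). This is the
sharpest interpretation gap in the upstream protocol — "removing UMI
duplicates" could also mean read-name deduplication — and is surfaced as
a hard contract: merging requires the UMI-set sidecars, and bare count
CSVs are refused because counts alone cannot be deduplicated. Merging
is commutative, associative and idempotent (tested on random triples);
cross-sample deduplication never occurs because cell ids are prefixed
`sample_barcode` (underscore separator, matching the naming produced
when samples are combined into one expression object).

### Contaminant denylist

Low-biomass samples are sensitive to reagent/environmental taxa. A
denylist removes whole genus columns (cells are retained at total 0).
The default is empty; `contaminant_denylist()` ships the documented
example preset (*Patulibacter*, *Pseudomonas*, *Sphingomonas*) but is
never applied silently, because contaminant status is cohort-specific.

## Cell classification and host analysis

Each expression-matrix cell gets per-genus counts and total $T(c)$; cells
absent from the merged matrix get zeros (never missing). Classification
for a taxon $g$ at threshold $k$:

* **Positive** if $n(c,g) \ge k$,
* **Negative** if $T(c) = 0$,
* **NA** otherwise (low, sub-threshold loads — excluded from testing).

The threshold default is $k=4$ and the comparison is `>=`: the upstream
protocol's prose says "more than four" but its executable predicate is
`>= 4`, and the code is treated as ground truth. Raising $k$ shrinks the
Positive set monotonically (tested property). `taxon = "Total"` gives
kingdom-level (any-bacteria) grouping.

Differential expression uses the two-sided Wilcoxon rank-sum test on
log-normalised expression ($\log(1 + 10^4 x_{gc} / \sum_g x_{gc})$,
scale factor $10^4$), testing genes detected in ≥`min_pct` (default 0.1)
of either group, with Benjamini–Hochberg adjustment. Figure-style
reports in the upstream work attribute effects to a linear mixed model;
the protocol's executable steps use the rank-sum default, and that is
what is implemented. The volcano cutoffs (|log2FC| ≥ 0.58,
−log10 p ≥ 1.301) are reporting parameters only. The fold change is
$\log_2\frac{\mathrm{mean}(\mathrm{expm1}(x^+))+1}{\mathrm{mean}(\mathrm{expm1}(x^-))+1}$ —
back-transformed normalised means with pseudocount 1; the exact upstream
formula era is unstated, so this definition is declared.

Preranked GSEA ranks genes by decreasing log2FC and computes the
weighted Kolmogorov–Smirnov running sum (hit increments proportional to
|log2FC|, weight exponent 1; miss decrement $1/(n - n_{hit})$). ES is
the signed maximum deviation. Numerical choice: when the positive and
negative extremes tie in magnitude (to a $10^{-9}$ relative tolerance),
the sign is taken from the net running-sum area — this keeps ES exactly
antisymmetric under ranking reversal, which the default first-extremum
tie-break would violate. The null shuffles gene labels (default 1,000
permutations, explicit seed); NES divides ES by the mean |null ES| of
matching sign (whether the original analysis used signed or absolute
mean is unstated; sign-matched absolute mean is declared here), and the
permutation p-value is computed within the sign-matched null with a +1
continuity correction, so $p \in (0,1]$. Sets disjoint from the ranking
are reported untestable (`NA`), not errors.

## The synthetic world

The generator emulates the validation designs used for this kind of
method — dose-dependent infection, nonadherent negative controls,
contaminants — with known truth. Defaults (the stated world, chosen
once):

| parameter | default | why |
|---|---|---|
| cells | 200 | desk-scale; acceptance checks use ≤200–500 |
| barcode / UMI length | 16 / 12 bases | standard droplet chemistry |
| infected fraction | 0.20 | mid-range adherent-infection design |
| UMI load | NB(mean 5, size 0.3) | heavy-tailed: some cells carry >100 bacterial transcripts, most one or none |
| duplication | geometric, rate 0.5 | ~1 extra read per molecule |
| ambient rate | 0 (per-taxon option) | nonadherent taxa emit only barcode-less reads |
| host genes | 100, lognormal(log 5, 0.8) means | moderate depth so rank tests are calibrated |
| signal genes | 10 at log2FC 1.0 | recoverable two-fold induction |

Classifier emulation writes per-read hits directly — no sequence-based
classification happens — and a misassignment probability (default 0)
injects genus-discordant hits to exercise the `unassigned` path. Same
seed gives byte-identical outputs.

What a green test does **not** establish: the simulation has no sequence
errors, no barcode errors, no chimeras, no index hopping, and its
classifier is perfect by construction. Green tests establish that the
bookkeeping — filtering, joining, deduplicating, thresholding, testing —
is exact, not that classification of real reads is.

Design-stage calibration (run once, then frozen): under the null
expression model the Wilcoxon raw-p<0.05 fraction came out ≈0.04
(slightly conservative, from count ties), and the estimated log2FC of
two-fold signal genes ≈0.9 — attenuated below 1.0 by the pseudocount in
the fold-change formula and by the signal genes' own contribution to
library size. Both are inside the acceptance bands; neither the
generator nor the bands were adjusted afterwards.

## Degenerate inputs and numeric edges

* Empty whitelist, duplicate barcodes, <3-field GMT lines, unknown taxon
  ids, negative/non-integer matrix cells: hard errors naming the datum.
* Unknown alignment tag keys yield absent fields, not errors.
* Zero candidate reads produce a valid empty matrix; an empty merged
  matrix annotates every cell as all-zero (Negative at any threshold).
* A count CSV is cross-checked against its UMI-set sidecar on read; a
  mismatch (the "incompatible sidecar" case) is an error.
* Genes flat across all cells get p = 1, log2FC = 0 without invoking the
  rank test.
* Library-size zero cells are normalised with divisor 1 rather than NaN.

## Limitations

* No UMI error correction (no 1-mismatch network collapsing): exact
  sequence identity is reproducible and conservative; counts can be
  slightly inflated by sequencing errors in real data.
* The simplified adapter clip is not the seed-and-extend algorithm of
  the cited trimming tool; reads with errored adapters are not clipped.
* The Wilcoxon/BH analysis treats cells as exchangeable; patient- or
  sample-level pseudoreplication is out of scope (a mixed model would be
  the next step).
* Clustering, integration and cell typing are consumed, not computed:
  the pipeline attaches bacterial status to whatever cell universe the
  expression matrix provides.
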