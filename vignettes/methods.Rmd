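---
title: "Models and methods behind toppreserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind toppreserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toppreserve)
```

This vignette explains the statistical models the package implements, the
choices made where the procedures left room for interpretation, and what
the synthetic-data generators do and do not establish about real data.

## Coordinates and isoform arithmetic

All amino-acid coordinates are 1-based and inclusive, so a region
`(start, end)` covers `end − start + 1` residues: the exon spanning aa
775–1468 is 694 residues long, and a 2229-aa protein losing it leaves a
1535-aa short isoform. CDS lengths follow the stop-codon-excluded
convention (`length_nt / 3 = length_aa`), which is the only convention
under which a 6687-nt CDS encodes 2229 aa and a 4605-nt CDS encodes
1535 aa. Where a published nucleotide span disagrees with the amino-acid
span by one codon, the amino-acid coordinates are treated as authoritative;
nucleotide spans are annotation only.

## Dipeptide compositional bias

A protein of length $L$ has $D = L - 1$ dipeptide positions. For an
ordered pair X–Y with residue counts $n_X$, $n_Y$, the expected count
under compositional independence is

$$E = \frac{n_X\, n_Y}{D}.$$

Two nulls are offered for the observed count $O$:

* **Exact binomial** (default): $O \sim \mathrm{Binomial}(D, n_X n_Y /
  D^2)$, which has exactly the mean $E$ above. It treats positions as
  independent, which they are not quite (the composition is fixed and
  adjacent positions share a residue).
* **Permutation**: residues are shuffled uniformly and the count
  recomputed; one-sided p-values use the add-one estimator
  $(1 + \#\{\text{counts} \ge O\})/(1 + n)$ so zero is never reported.
  This is the assumption-free reference distribution.

On short sequences dense in the pair of interest the two nulls genuinely
differ — measured right-tail discrepancies reach about 0.04 at 10% R /
10% G and about 0.1 at 30%/30% — so the package reports which method was
used, and the test suite holds the binomial to the permutation reference
only within that modelling tolerance. For proteins of realistic length and
composition (the motivating protein is 2229 aa with 7% Arg, 9% Gly) the
two agree closely.

## Regional Fisher's exact test

`region_fet(a, b, pos_in, pos_out)` asks whether dipeptides of interest
concentrate inside a region. The 2×2 table is

$$\begin{pmatrix} a & b \\ \text{pos}_{in} & \text{pos}_{out} \end{pmatrix},$$

i.e. the listed dipeptide-position totals form the second row directly,
and the right tail is evaluated by Fisher's exact test. This construction
was frozen after brute-force comparison of both candidate readings
(subtracting the pair counts from the totals, or not) against the two
published p-values this analysis style reports: both readings round to
0.001 for an 11/4 split over 694/1533 positions, and only the
non-subtracting reading — fed the coordinate-true totals of a 64-aa domain
(63 internal dipeptide positions, 2164 outside) — reproduces 1.13e-07 for
a 7/8 split. The published statement of "50 dipeptides in the domain" is
internally inconsistent with its own published p-value; the package
therefore takes cell counts as explicit inputs and documents this reading.
The reported odds ratio is the sample cross-product $a\,\text{pos}_{out} /
(b\,\text{pos}_{in})$, with zero cells mapped to infinity.

## RG/RGG motif scanning

`scan_rg_motifs()` walks the sequence left to right, consuming RGG units
greedily (an RGG occurrence consumes its RG prefix, so a tripeptide is
never double-counted), then clusters consecutive units whose inter-unit
gap is at most `max_spacer` residues. The default spacer of 4 residues
follows conventional short-spacer RGG-box definitions; it is a parameter
because no single published value exists. Clusters are classified by unit
count (≥3 `Tri-`, 2 `Di-`, 1 `singleton`) and typed RGG when any unit is a
tripeptide.

## Conservation scoring and the region test

The per-column conservation score is the fraction of non-reference rows
matching the reference residue, with gaps counting as mismatches and
reference-gapped columns skipped. This is the simplest testable
definition; entropy- or substitution-matrix-based scores change the
numbers but not the test machinery.

The region test is a one-sided Mann–Whitney comparison with the fixed
alternative "columns outside the region are less conserved than those
inside". The U statistic counts wins with ties as half-wins. The p-value
path depends on problem size:

* full enumeration of all $\binom{n}{n_{in}}$ group assignments when that
  count is at most $2 \times 10^5$ — exact even under ties;
* the exact tie-free Mann–Whitney null (`pwilcox`) when there are no ties
  and $n_{in} n_{out} \le 10^4$;
* otherwise the normal approximation with mid-rank tie correction.

Literal enumeration at every size the exact label might suggest is not
computable ($\binom{660}{60}$ assignments), which is why the enumeration
cap is stated in assignments rather than in $n_{in} n_{out}$.

Weight-corrected testing (e.g. down-weighting columns inside RG dipeptides
by their background frequency in a proteome) is implemented as weighted
column resampling: columns are resampled with probability proportional to
their weights, the exact test runs per replicate, and the mean replicate
p-value is reported. This is one documented interpretation of
weight-correction; because the interpretation is not uniquely determined,
the unweighted exact test is the default.

## IP-MS differential enrichment

The pipeline mirrors standard label-free practice:

1. **Filtering** — decoys and contaminants out; a protein is kept when
   detected in ≥2 replicates of ≥1 group.
2. **Imputation** — missing log2 intensities are drawn per sample from
   $\mathcal{N}(m_s - 1.8\, s_s,\ (0.3\, s_s)^2)$, the downshifted-normal
   convention for missing-not-at-random non-detections ($m_s$, $s_s$ are
   the sample's observed mean and SD). Per-sample rather than global
   statistics, because detection limits are per-run. Both parameters are
   arguments; imputation is seeded and reproducible.
3. **Testing** — per-protein two-sample Student's t (equal variance) on
   log2 intensities, Welch as an option; `log2FC` is the difference of
   group means of log2 intensities, i.e. the log2 ratio of geometric
   means. FDR by Benjamini–Hochberg.
4. **Calling** — interactors require, strictly, ≥2 unique peptides,
   fold > 2 and FDR q < 0.05; boundary equality fails. Contrasting two
   bait IPs directly uses the looser raw-p criterion (fold > 2,
   p < 0.05), as such comparisons are typically reported.

A consequence of MNAR imputation worth knowing: a protein censored in the
control group but observed in the bait group receives downshifted control
values, so its estimated enrichment is intentionally large. The
`imputed_frac_*` columns flag this; the recovery tests quantify estimation
accuracy on proteins quantified without imputation.

## DE classification and TOP maintenance

`classify_degs()` applies `baseMean > 10`, `|log2FC| > 0.263`
(fold > 1.2) and `p < 0.05`, all strict, on the raw p-value as such
criteria are printed. Gene-set overlap uses the hypergeometric right tail
and the representation factor $x N / (n m)$. The universe for overlap
tests is the set of genes passing the expression filter — the natural
background for a detected-gene contingency analysis; it is configurable
because published analyses rarely state theirs. Percentages round to the
nearest integer, halves away from zero (the only rule consistent with
81% = 90/111 and 28% = 31/111 side by side).

## Spike-in quantification

With a constant amount of exogenous transcript added per cell, the ΔΔCt
fold change $2^{-\Delta\Delta Ct}$ against the spike-in reports per-cell
abundance even when equal RNA mass is processed per sample — the same
masking problem the equal-mass RNA-seq artifact creates. Amplification
efficiency is fixed at 2 (no efficiency correction was specified for this
analysis style); replicate Cts are averaged before the ΔΔCt. RIP
enrichments divide out the relative amount of bait protein recovered in
the IP, supplied from densitometry, and are tested one-sided against 0 on
the log2 scale because sub-baseline enrichment relative to a control IP is
not meaningful. Densitometry ratios normalize to a loading control and map
the reference sample to 1 by construction.

## Synthetic data: what it emulates, what it does not

Each generator is deterministic given its seed and ships its ground truth.

* `synth_protein()` — 2000-aa uniform-composition background with 10
  non-overlapping RG dipeptides planted in a 100-aa region: an effect size
  at which the regional FET detects enrichment in ≥95% of seeds while the
  global bias test stays null.
* `synth_msa()` — 10 rows × 660 columns, match probability 0.9 inside a
  60-column region vs 0.5 outside, roughly the contrast a deeply conserved
  domain shows across vertebrate orthologs.
* `synth_ipms()` — 200 proteins, 20 planted 4-fold interactors, log-normal
  baselines (log2 mean 25, SD 2), 5% CV noise, per-sample censoring below
  the 20th intensity percentile. The censoring is what makes downshifted
  imputation the right tool.
* `synth_de()` — 10 000 genes, 1% TOP, per-cell scale 0.4 for non-TOP
  genes under starvation vs 1.0 for TOP, negative-binomial counts
  (dispersion 0.05), and exact per-condition rescaling to equal totals.
  The rescaling reproduces the equal-mass artifact: maintained TOP genes
  appear shifted by about $\log_2(1/0.4) \approx 1.32$ while the dropping
  majority appears unchanged. The observed table's test statistics are a
  plain Welch t on log2 counts — adequate for a generator whose consumers
  only need a `gene/baseMean/log2FC/pvalue` table, but not a substitute
  for a count-model DE analysis.
* `synth_qpcr()` — Ct = baseline − log2(abundance) + noise, spike-in
  constant per sample.

Sizes used in the shipped tests are scaled to desk scale (hundreds to a
few thousand genes, tens of seeds); the power statements in the test suite
are statements about these generators at these effect sizes. Passing them
shows the machinery is correct and calibrated on data with the assumed
structure; it does not show that real IP-MS noise is log-normal, that real
conservation is iid across columns, or that real libraries are rescaled
exactly — batch effects, peptide-level variation and alignment errors are
out of scope by design.

## Numerical conventions

Exact hypergeometric/Fisher tails come from `fisher.test`/`phyper`; BH
adjustment from `p.adjust` (the hand step-up formula is kept as a test
oracle); t tails from `pt`. Permutation p-values use add-one estimators.
Degenerate inputs have defined behaviour rather than NA: all-tied
conservation scores give p = 0.5 with a warning, zero variance in both
t-test groups gives p = 1 with a flag, zero cells in odds ratios give
infinity, and empty sequences count zero with a warning.

## Known limitations

* The conservation score ignores phylogeny; closely related rows inflate
  apparent conservation.
* The weighted conservation test is one interpretation of
  weight-correction, reported as such in the result object.
* The binomial bias null is approximate on short pair-dense sequences
  (quantified above); use the permutation method when it matters.
* Interactor calling inherits whatever bias imputation introduces for
  heavily censored proteins; inspect `imputed_frac_*` before interpreting
  extreme fold changes.
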