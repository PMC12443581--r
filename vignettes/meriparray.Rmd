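---
title: "Quantifying m6A methylation from two-channel MeRIP arrays"
author: "meriparray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m6A methylation from two-channel MeRIP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meriparray)
```

## The assay and its two statistics

An epitranscriptomic two-channel microarray splits each RNA sample by
anti-m6A immunoprecipitation: the IP fraction (m6A-bearing transcripts) is
labelled with Cy5, the supernatant (unmodified transcripts) with Cy3, and
both are hybridized to the same slide. Each probe therefore reports a
paired measurement — how much of a transcript is methylated, and how much
is not.

Normalization is anchored on exogenous spike-in controls of fixed
quantity. For sample $s$ and channel $c$, the anchor is the arithmetic
mean of the log2 spike-in intensities (the log2 geometric mean of their
raw values), and every probe is normalized as

$$\tilde{x}_{ps c} = \log_2(\text{raw}_{psc}) -
  \overline{\log_2(\text{spike-in raw}_{sc})}.$$

Two per-transcript statistics follow:

* **m6A quantity** — the normalized IP (Cy5) intensity, the relative
  abundance of the methylated form of the transcript;
* **gene expression level** — the sum of the normalized IP and
  supernatant intensities, a total-abundance measure that uses both
  fractions.

Both are in log2 units, so between-group differences are log2 fold
changes. Under the package's generative model (below) a transcript with
abundance $2^E$ and methylated fraction $m$ has noise-free group
difference $\Delta E + \log_2(m_2/m_1)$ in m6A quantity and
$2\Delta E + \log_2\!\frac{m_2(1-m_2)}{m_1(1-m_1)}$ in expression level.
Note the second formula: the expression statistic is *not* exactly
invariant to methylation changes — a transcript whose methylated fraction
moves towards 0.5 gains a little apparent "expression". This is a
property of the sum-of-channels definition itself, not of the
implementation, and the test suite checks the closed form rather than
assuming invariance.

## The analysis chain

1. **QC filtering** (`filter_by_flags`): probes flagged present (`P`) or
   marginal (`M`) in at least three samples (counted across all arrays)
   are retained. Spike-in probes are exempt — dropping them would destroy
   the normalization anchor. Non-positive raw intensities become missing
   rather than being floored: flooring would fabricate signal before the
   log2 transform.
2. **Normalization** (`normalize_profile`): spike-in anchoring per sample
   and channel, then collapse of multiple probes per transcript by the
   median of normalized values (an even number of probes yields the mean
   of the central pair). By default every spike-in with usable signal in a
   channel enters that channel's anchor (`policy = "all"`); the
   `"matched"` policy restricts Cy5 to positive and Cy3 to negative
   controls for designs where the controls are channel-specific.
3. **Differential calling** (`diff_test`): per-transcript two-sided
   unpaired t-test on the log2 values, BH adjustment, and classification
   as `up`/`down` when the linear fold change *strictly* exceeds 1.5 (or
   falls below 1/1.5) **and** p < 0.05. The raw p-value gates the default
   call, with adjusted values always reported; `use_adjusted = TRUE`
   switches the gate.
4. **Clustering** (`hier_cluster`): average-linkage agglomeration of
   samples with distance $1 - r$ (Pearson), typically on the significant
   transcripts, with a $k = 2$ cut to compare against the known phases.
5. **Integration** (`join_and_classify`, `global_association`):
   transcripts significant in *both* measures are assigned a quadrant —
   `hyper`/`hypo` for the m6A direction crossed with `up`/`down` for
   expression — and the global association between the two fold-change
   axes is summarized by Pearson and Spearman correlations over all
   joined transcripts (Spearman is reported alongside because array fold
   changes are heavy-tailed).
6. **Enrichment** (`fisher_ora`): one-sided Fisher exact (hypergeometric
   tail) over-representation of a differential gene list against
   user-supplied GMT gene sets, BH-corrected, with the
   $(n_{up}-n_{down})/\sqrt{k}$ bubble z-score for directional summaries.
7. **qPCR calculators** (`percent_input`, `ddct`): the MeRIP enrichment
   measure $\%input = 2^{-Ct_{MeRIP}}/(2^{-Ct_{MeRIP}} +
   2^{-Ct_{Sup}}) \times 100$ and the comparative-Ct relative expression
   $2^{-\Delta\Delta Ct}$, with duplicate wells averaged on the Ct scale
   and an assumed amplification efficiency of 2.

## Choice of the two-group test

The package defaults to the pooled-variance (Student) t-test rather than
the Welch test. With three replicates per group the Welch–Satterthwaite
degrees-of-freedom approximation is noticeably conservative — in
simulation its null rejection rate at the 0.05 level is about 0.035 —
while the pooled test is exactly calibrated when the two groups share a
noise variance, which is how log-scale array noise is usually modelled
(and how the generator below is built). Welch remains one argument away
(`var_equal = FALSE`) for data where the equal-variance assumption is
doubtful. No moderated (empirical-Bayes) variance model is provided; at
n = 3 a moderated test would be more powerful, but the plain t-test is
what the calling rule here is defined around.

Degenerate inputs are resolved conservatively: fewer than two usable
values in a group gives a missing p-value (and an `ns` call); zero
variance in both groups gives p = 1 for equal means, and the smallest
representable positive p for unequal means so that an obviously forced
difference is flagged without fabricating an exact zero.

## What the synthetic-data generator emulates

`simulate_dataset()` generates the study design the package is aimed at:
two groups (proliferative vs involuting) of three replicate arrays,
roughly $10^4$ transcripts spread over six RNA classes in the proportions
of a human mRNA & lncRNA epitranscriptomic array (default census 7,525
mRNA, 1,914 lncRNA, 261 pri-miRNA, 172 pre-miRNA, 125 snoRNA, 3 snRNA),
positive and negative spike-ins, and a small rate (1%) of absent QC
flags.

The measurement model partitions each transcript's signal between the
channels: expected IP intensity $A \cdot 2^{E} \cdot m$ and supernatant
intensity $A \cdot 2^{E} \cdot (1-m)$, each multiplied by independent
lognormal noise $2^{N(0,\sigma^2)}$ with $\sigma = 0.25$ by default. The
scale $A = 2000$ together with baseline abundances $E \sim N(3, 1.2^2)$
puts raw intensities in the $10^2$–$10^5$ range of a 16-bit scanner.

Specific modelling choices, and why:

* **Methylated fraction**: baseline $m \sim$ Beta(2, 6) truncated to
  (0.05, 0.5) — IP capture fractions centred near 0.25, strictly inside
  (0, 1). Planted methylation changes shift $m$ on the log-odds scale by
  ±1.5, which on this baseline range guarantees a true methylation ratio
  of at least 1.5 in the planted direction (worst case, $m_1 = 0.5
  \rightarrow m_2 = 0.82$, ratio 1.63) — i.e. every planted effect is at
  or beyond the calling threshold, so sensitivity estimates are not
  diluted by sub-threshold "effects".
* **Spike-ins** are emitted at a fixed nominal intensity (split 90/10
  between channels for positive controls; negative controls are entirely
  unmethylated, so their IP signal is absent). Real spike-ins carry
  technical noise; modelling them as fixed keeps the per-sample anchor
  deterministic and transcripts independent, which is what the
  calibration analyses below rely on. The arrays' actual spike-in
  identities and quantities are proprietary, so this design is a
  synthetic stand-in.
* **Planted expression changes** shift $E$ by ±1 log2 unit; with
  `couple_dm_de = TRUE` they are placed on the same transcripts as the
  methylation changes with matching sign, emulating a positive
  methylation–expression coupling.
* A single seeded RNG stream is drawn in a fixed order (transcript
  parameters first, then per-array noise), so a configuration reproduces
  its dataset exactly.

What the generator does **not** emulate: probe-sequence or hybridization
effects, correlated (batch) noise across transcripts, intensity-dependent
variance, multiple probes per transcript (the collapse logic is tested on
hand-built fixtures instead), and unbalanced or >2-group designs.
Passing the recovery analyses therefore shows the chain is correct and
calibrated under a clean partition-of-signal model — not that real
arrays, with their dye biases and correlated noise, will achieve the same
sensitivity.

## Calibration results the test suite recomputes

Problem sizes were chosen so each analysis is informative at desk scale:
10,000 transcripts, 3 arrays per group, $\sigma = 0.25$.

* Under the null (no planted effects) the per-transcript t-test rejects
  at the nominal 0.05 rate (binomial 3-sigma band), and fewer than 1% of
  transcripts pass the joint fold-change + p calling rule for the m6A
  statistic. The *expression* statistic sums two noisy channels and so
  has twice the noise variance; its joint null call rate under these
  conditions is around 2% — a consequence of the sum-of-channels
  definition worth remembering when interpreting expression calls at
  n = 3.
* With 500 hyper- and 500 hypo-methylated transcripts planted,
  sensitivity of the m6A calls is ≈ 0.98 at an empirical FDR ≈ 0.02–0.03,
  and clustering the significant transcripts separates the two phases
  perfectly (adjusted Rand index 1).
* One more structural fact: even under the null, the m6A and expression
  *fold changes* correlate at about $1/\sqrt{2}$, because the expression
  statistic contains the IP channel. A positive global association
  between the two axes is therefore only meaningful against this
  baseline; the coupled-effect simulation pushes Pearson r above 0.97.

## Enrichment conventions

The ORA universe should be the genes the experiment could have called —
by default the annotated transcripts retained after QC filtering, not the
whole genome; using an over-wide universe inflates enrichment. The test
is one-sided (enrichment only), the standard ORA convention when the
question is over-representation. Both choices are arguments, not
constants. The package ships no GO/KEGG content: gene sets are user
input in GMT format, so results depend on the annotation the user
supplies.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(frac_dm_up = 0.05, frac_dm_down = 0.05, seed = 2)
sim <- simulate_dataset(cfg)
prof <- normalize_profile(filter_by_flags(sim$raw))
dm   <- diff_test(prof, "m6a")
de   <- diff_test(prof, "expression")
summary(dm)
joint <- join_and_classify(dm, de)
global_association(joint)
hier_cluster(prof, measure = "m6a",
             transcripts = dm$transcript_id[dm$class != "ns"])
```

## Known limitations

* No between-array normalization beyond the spike-in anchor (no
  quantile/loess step): the method is defined by the spike-in formula.
* Calling thresholds (fold change > 1.5, p < 0.05 unadjusted) reproduce
  the screening convention of the assay, which does not control FDR;
  the BH-adjusted p-values are reported for stricter use.
* The t-test at n = 3 has limited power for effects near the fold-change
  boundary; the recovery figures above are for planted ratios ≥ 1.5.
* %input and $2^{-\Delta\Delta Ct}$ assume amplification efficiency 2;
  no standard-curve efficiency correction is applied.
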