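---
title: "satmut: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satmut: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the model

A saturation-mutagenesis MPRA couples error-prone PCR over a single
promoter or enhancer element (about 100-600 bp) to a reporter construct
carrying a random 15- or 20-bp tag in its 3' UTR. Sequencing of the
plasmid pool links each tag to the set of variants on its insert (the
haplotype); RNA and DNA tag sequencing with 10-bp UMIs then reads out
per-construct expression across transfection replicates.

The central estimator is an ordinary least squares fit over all usable
(replicate, tag) observations:

$$
\log_2(\mathrm{RNA}_{i,j}) \sim \sum_{r=1}^{3}
\mathbb{1}[i = r]\,\log_2(\mathrm{DNA}_{r,j}) + N\beta + \mu
$$

where $N$ is the binary tag-by-variant indicator matrix, $\mu$ a single
global intercept, and the DNA predictors are kept in separate
per-replicate columns (zero off-replicate, hence orthogonal across
replicates by construction). The coefficient $\beta_v$ of each variant
column is its log2 expression effect relative to the wild-type sequence,
whose expectation is defined by the intercept and DNA slope. Tags
associated with insertions or multi-bp deletions are excluded from the
design entirely.

Assumptions worth keeping in mind:

* **Additivity.** Tags carrying several variants contribute the sum of
  their effects; no epistasis terms are fit.
* **Independence.** Tags are treated as independent observations. They
  are not (constructs sharing a variant are correlated), so the
  coefficient t-test p-values are anti-conservative. They are used, as in
  the original analyses, as a ranking proxy with a stringent threshold
  (default $\alpha = 10^{-5}$) rather than as calibrated error rates.
* **No refit after filtering.** The minimum-tag filter (default 10
  supporting observations) removes variants from *reporting*; the fit is
  not re-run, so retained coefficients are always adjusted for all
  co-occurring variants.

`n_tags` is counted, by default, as (tag, replicate) rows of the combined
design — the model's effective sample size. The alternative reading,
distinct tags across replicates, is available via
`tag_count_mode = "distinct_tags"`; the two differ for tags absent from
some replicate.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_coverage` | 3 | reads/position | a tag's variants are only trusted when every element position is covered by at least three subassembly reads |
| `min_tags` | 10 | (tag, replicate) rows | replicate correlation of effects improves sharply up to ~10 supporting observations and slowly beyond |
| `alpha` | 1e-5 | – | significance threshold on the coefficient p-value |
| `fold_threshold` | none / 2 | fold change | optional two-fold gate, \|log2 effect\| >= 1 |
| `n_shuffles` | 1000 | permutations | clustering-test null resolution; the permutation p floor is ~1/(B+1) |
| `mutation_rate` | 0.008 | per base | error-prone PCR at under 1 change per 100 bp |
| `tag_length` / `umi_length` | 15 / 10 | bp | designed read structure; the length filters are exact |

# The synthetic generator: what it emulates, what it does not

`sim_config()` + `simulate_experiment()` generate a complete experiment:

* a random element of configured length and GC (within ±5%);
* TFBS-like effect architecture: a few non-overlapping footprints
  (default 3 × 12 bp) carry all nonzero effects, gamma-distributed
  magnitudes with a 37/63 activating/repressing split and larger
  magnitudes for 1-bp deletions — mirroring the observed predominance of
  small repressive effects and positional clustering;
* a transition-biased mutation spectrum with A↔T the most common
  transversion, 1-bp deletions at comparable rates, and rare insertions
  (generated only to exercise the disqualification filter; they never
  carry planted effects);
* log-normal per-tag DNA abundance (heavy-tailed library representation),
  resampled per replicate around a shared tag mean so the three DNA
  columns are exercised with distinct values;
* RNA counts as the generative inverse of the model:
  $\log_2 \mathrm{RNA} = \log_2 \mathrm{DNA} + \sum\beta + \varepsilon$,
  $\varepsilon \sim \mathcal{N}(0, \sigma)$ with $\sigma = 0.3$ by
  default;
* optionally, read-level records with distinct UMIs per molecule,
  duplicate multiplicity, and a configured fraction of corrupted records
  (N bases, wrong lengths) for filter testing.

It does **not** emulate: PCR jackpotting beyond UMI duplicates,
sequencing errors inside tags, UMI collisions or sequencing saturation,
epistasis, or cell-type-specific trans context. A green recovery test
therefore establishes that the estimator inverts its own generative
model at realistic noise levels — not that it is robust to artefacts the
generator omits.

Defaults were fixed once from the stated experimental regime (50k tags is
the low end of reported library complexity; absolute per-tag depth is
unreported anywhere, so the log-normal meanlog log(20) was chosen to give
order-of-magnitude realistic tags-per-variant) and are not tuned against
test outcomes.

## Integer counts and the noiseless limit

UMI counts are integers, so even with zero RNA noise the fitted effects
differ from the planted ones by rounding (relative error ~1/count). The
generator's `count_rounding = "none"` diagnostic mode emits real-valued
molecule counts, under which the noiseless pipeline identity is exact to
numerical precision; the default mode rounds. Tests use the diagnostic
mode only for the exact-identity check.

# Numerical and procedural choices

**Alignment.** Subassembly reads are aligned by an exact semi-global
affine-gap dynamic program (free gaps at the reference ends), not a
banded heuristic: at amplicon scale the full matrix is cheap and
exactness matters more than throughput. Ties prefer a mismatch over a
gap; indels are left-normalised to their leftmost equivalent placement
after traceback. Reads below 80% matching columns are rejected. An SNV
directly adjacent to a deletion admits two score-equivalent alignments;
the caller picks one deterministically, and both imply the same molecule
sequence.

**Variant calling.** A difference is called when supported by a strict
majority (> 0.5) of reads covering its position. The ambiguity rule is a
declared substitute for an unstated consensus procedure: any uncalled
difference supported by at least 30% of covering reads flags the tag
`ambiguous` and disqualifies it.

**Rank deficiency.** Variants observed only on tags that always co-occur
produce identical design columns. The fitter detects rank deficiency on
the cross-product matrix and drops a minimal set of later columns
(greedy incremental Cholesky in column order), recording them in the
diagnostics. Such variants almost always fail the min-tag filter anyway.

**Clustering test.** Each significant variant is assigned the length of
the maximal run of consecutive same-label variants containing it
(nonsignificant variants break runs); the null pools the same statistic
over uniform label permutations. Two p-values are reported: the analytic
Wilcoxon rank-sum p of observed versus pooled null run lengths
(`p_rank_sum`, the form used in the original analyses, whose printed
values go far below the permutation floor) and, as the default decision
value, a shuffle-calibrated one-sided mid-p permutation p-value on the
mean run length. The analytic form is anti-conservative under the null
because run lengths within a track are dependent; the permutation form is
approximately uniform under label exchange, which is what a
calibration-checking test suite needs. When all run lengths are identical
(e.g. a single significant variant) there is no clustering evidence and
both p-values are 1. Shuffles are drawn from a canonical sorted copy of
the labels, making the test exactly invariant to track reversal at fixed
seed.

**deltaSVM sign.** The score is mean(reference k-mer weights) −
mean(alternative k-mer weights), with absent k-mers contributing zero, and
`sign = "alt-minus-ref"` available to match the original deltaSVM
convention. Lookups try the literal k-mer, then its reverse complement
(weight files are typically strand-canonical); set `canonicalize = FALSE`
for literal-only tables.

**Percentiles.** Motif-score percentile thresholds use the
linear-interpolation estimator (R quantile type 7); the printed reference
thresholds cannot disambiguate the estimator, so it is documented and
configurable rather than asserted.

**PWM construction.** JASPAR count matrices become log2-odds with a +0.8
pseudocount per cell against a uniform background. The 80th-percentile
gate for variant PWM deltas compares the best overlapping-window score
(either allele, both strands) against 0.8 × the PWM's best possible
score.

**Classification benchmark.** Positives are the top-N significant
variants by |effect| (boundary ties included, then trimmed by smallest
p-value); negatives are resampled without replacement from the
|effect| < 0.05 pool with per-element counts matched to the positives,
downsampling positives where an element's negative pool is scarcer.
AUROC uses midranks (the Mann-Whitney identity); AUPRC uses tie-aware
step integration. Both the mean and median across resamples are
reported (the averaging convention is unstated in the reference
analyses; the mean is the headline number).

**Configuration files.** The CLI accepts JSON configuration (the
environment provides no YAML/TOML parser); all randomness flows from the
explicit `--seed`.

**Coordinates.** 0-based half-open internally and in BED; 1-based in the
effects TSV and the VCF-like export. Each writer states its convention.

# Known limitations

* OLS standard errors ignore tag-sharing correlation; no robust or
  clustered variance option is provided.
* No error-tolerant UMI clustering: UMIs match exactly, so sequencing
  errors in UMIs inflate counts slightly on real data.
* The per-tag consensus rule (majority + 30% ambiguity zone) is a
  declared substitute for the unstated original procedure, not a
  reconstruction.
* The leave-one-out reproducibility meta-regression over element
  features, genome-scale track retrieval, and lift-over are out of
  scope.
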