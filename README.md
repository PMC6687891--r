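# satmut

Analysis of **saturation-mutagenesis massively parallel reporter assays
(MPRAs)** — experiments that introduce (nearly) every possible single-base
change into one promoter or enhancer element by error-prone PCR, link each
construct to a random 3'-UTR tag, and read out per-construct expression by
RNA/DNA tag sequencing with UMIs across transfection replicates.

The package is for regulatory-genomics analysts who need the full path from
reads to interpretation in one tested toolchain:

1. **Subassembly** (`align_to_reference`, `call_tag_variants`): learn the
   tag → variant assignment by exact semi-global alignment and per-position
   majority vote, requiring ≥ 3 reads of coverage along the whole target;
   tags with insertions, multi-bp deletions or ambiguous evidence are
   disqualified.
2. **Counting** (`parse_tag_umi_reads`, `dedup_and_match`, `join_rna_dna`):
   UMI-deduplicated RNA and DNA tag counts, excluding reads with N bases or
   off-design lengths, tags absent from the assignment, and tags not seen in
   both RNA and DNA of the same replicate.
3. **Effect model** (`build_design`, `fit_effects`): the combined multiple
   linear regression

   log2(RNA_ij) ~ log2(DNA_1j)·1[i=1] + log2(DNA_2j)·1[i=2] +
   log2(DNA_3j)·1[i=3] + N·β + offset

   over all (replicate, tag) rows, where N is the binary tag×variant
   indicator matrix; the coefficient β_v of each variant is its log2
   expression effect versus wild type, with OLS SEs, t-test p-values and
   95% CIs. Variants need ≥ 10 supporting observations
   (`filter_min_tags`) before downstream reporting.
4. **Region statistics** (`significance_report`, `clustering_test`,
   `class_comparisons`, `compare_conditions`): activating/repressing
   classification (p < 1e-5, optional two-fold gate), run-length positional
   clustering against 1000 label shuffles, rank-sum/binomial class
   contrasts, and knockdown-vs-control comparison by non-overlapping CIs.
5. **Annotation scoring** (`delta_svm_score`, `scan_pwm`, `pwm_delta`,
   `top_factors`): deltaSVM from k-mer weight tables (absent k-mers count
   zero), PWM scanning with length-normalised scores, percentile
   thresholds, and the 80th-percentile best-match gate for variant motif
   deltas.
6. **Benchmarking** (`correlate_scores`, `classification_eval`):
   Pearson/Spearman of scores against |effect|, and the matched top-N
   classification with per-element-balanced resampled negatives
   (AUROC/AUPRC over 100 resamples).
7. **Synthetic data** (`sim_config`, `simulate_experiment`): a seeded
   generator emulating the whole assay — mutation rate < 1/100 bp,
   transition-biased spectrum, 15/20-bp tags, 10-bp UMIs, three
   replicates, log-normal DNA abundance, TFBS-like effect footprints — so
   every stage runs and is tested without any download.

See `vignettes/satmut-methods.Rmd` for the model, its assumptions, and the
numerical choices.

## Worked example

```r
library(satmut)

cfg  <- sim_config(element_length = 200L, n_tags = 10000L, seed = 42L)
sim  <- simulate_experiment(cfg)                      # element, truth, tags, counts
fit  <- fit_effects(build_design(sim$counts, sim$assignment))
kept <- filter_min_tags(fit$estimates, 10L)
rep_ <- significance_report(kept, alpha = 1e-5)
rep_$summary
#>             class     n median_abs_effect
#> 1: nonsignificant   627         0.0337517
#> 2:     repressing    55         0.5649208
#> 3:     activating    38         0.3378615

head(kept[order(p_value)][, .(position, ref, alt,
  log2_effect = round(log2_effect, 3), se = round(se, 3),
  p_value = signif(p_value, 2), n_tags)], 5)
#>    position    ref    alt log2_effect    se  p_value n_tags
#> 1:       70      G      A       1.281 0.033  0.0e+00     99
#> 2:      105      T      C      -1.194 0.028  0.0e+00    126
#> 3:      189      C      T      -1.115 0.028  0.0e+00    129
#> 4:      107      G      A      -0.944 0.027 5.2e-261    143
#> 5:      184      T      C      -0.911 0.026 8.2e-254    147

fit$diagnostics$dna_slopes          # per-replicate DNA slopes, ~1 as modelled
#> replicate_1 replicate_2 replicate_3
#>       0.996       0.997       0.996

m <- merge(kept, sim$truth$effects, by = c("position", "ref", "alt"))
cor(m$effect, m$log2_effect)        # recovery of planted effects
#> [1] 0.974

clus <- clustering_test(ordered_track(rep_$estimates),
                        n_shuffles = 1000L, seed = 42L)
c(clus$p_value, clus$p_rank_sum)    # calibrated permutation p, analytic p
#> [1] 5.0e-04 2.75e-47
```

Reading the numbers: 93 of 720 well-supported variants change expression
significantly, repressing outnumbering activating roughly 63:37 with
median effects of −0.56 and +0.34 log2 units — the planted footprint
architecture — and significant variants cluster positionally (permutation
p at its 1000-shuffle floor). The DNA slopes near 1 say expression scales
proportionally with construct abundance, as the model assumes.

## Command line

```sh
Rscript -e 'satmut::satmut_cli()' simulate --config cfg.json --seed 7 --out outdir
Rscript -e 'satmut::satmut_cli()' run      --config cfg.json
```

Configuration is JSON (`pipeline_config()` documents the fields); every
artifact is stamped with the seed and a config hash.

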