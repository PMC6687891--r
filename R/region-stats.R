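#' Replicate reproducibility of fitted effects
#'
#' Pearson correlation over shared variants of the standardized effects
#' (effect divided by its standard error), plus the plain-effect
#' correlation.
#'
#' @param estimates_a,estimates_b estimates tables (already filtered to the
#'   desired minimum tag support).
#' @return list with `r_standardized`, `r_effect`, `n_shared`.
#' @export
replicate_reproducibility <- function(estimates_a, estimates_b) {
  m <- merge(as.data.table(estimates_a), as.data.table(estimates_b),
             by = "token", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stop("need at least 3 shared variants, got ", nrow(m))
  list(
    r_standardized = cor(m$log2_effect_a / m$se_a, m$log2_effect_b / m$se_b),
    r_effect = cor(m$log2_effect_a, m$log2_effect_b),
    n_shared = nrow(m))
}

#' Order variants into a positional effect track
#'
#' Stable total order by (position, alt allele A < C < G < T < deletion).
#'
#' @param estimates estimates table with a `class` column (from
#'   [significance_report()]).
#' @return ordered `data.table`.
#' @export
ordered_track <- function(estimates) {
  est <- as.data.table(estimates)
  est[order(position, alt_order(alt))]
}

# each significant variant contributes the length of the maximal
# same-label run containing it, so the statistic has one entry per
# significant variant and long runs carry proportional weight
run_lengths <- function(labels) {
  r <- rle(labels)
  len <- r$lengths[r$values != "nonsignificant"]
  rep(len, len)
}

#' Positional clustering test for significant effects
#'
#' Tests whether significant variants (split by direction) cluster along
#' the element. Each significant variant is assigned the length of the
#' maximal run of consecutive variants sharing its label (activating or
#' repressing; nonsignificant variants terminate runs and contribute
#' nothing); the null pools the same per-variant run lengths from
#' `n_shuffles` uniform permutations of the labels; the p-value is a
#' two-sided Wilcoxon rank-sum test with continuity correction of observed
#' versus pooled null run lengths.
#'
#' Two p-values are reported. `p_rank_sum` is the analytic rank-sum p of
#' observed versus pooled null run lengths, as used in the original
#' analyses; it is anti-conservative under the null because the run lengths
#' within a track are dependent. `p_value` (the default decision value)
#' wraps the same statistic in a shuffle-calibrated one-sided mid-p
#' permutation p-value on the mean per-variant run length (clustering
#' implies longer runs), which is approximately uniform under label
#' exchange; when observed and null run lengths are all identical the test
#' carries no clustering evidence and both p-values are 1.
#'
#' @param track ordered estimates with a `class` column (see
#'   [ordered_track()]).
#' @param n_shuffles number of label permutations (default 1000).
#' @param seed optional seed for the shuffles.
#' @return list with `p_value` (shuffle-calibrated), `p_rank_sum`
#'   (analytic), `observed_runs`, `null_runs` (pooled), and
#'   `n_significant`. With zero significant variants the test is not
#'   applicable and both p-values are `NA`.
#' @export
clustering_test <- function(track, n_shuffles = 1000L, seed = NULL) {
  labels <- track$class
  n_sig <- sum(labels != "nonsignificant")
  if (n_sig == 0L)
    return(list(p_value = NA_real_, p_rank_sum = NA_real_,
                observed_runs = integer(), null_runs = integer(),
                n_significant = 0L))
  if (!is.null(seed)) set.seed(seed)
  obs <- run_lengths(labels)
  # shuffle a canonical (sorted) copy: the null depends only on label
  # counts, and this makes the test exactly invariant to track reversal
  pool <- sort(labels)
  null_list <- lapply(seq_len(n_shuffles), function(i)
    run_lengths(sample(pool)))
  null_runs <- unlist(null_list)
  degenerate <- length(unique(c(obs, null_runs))) == 1L
  p_rank_sum <- if (degenerate) 1 else
    wilcox.test(obs, null_runs, correct = TRUE, exact = FALSE)$p.value
  t_obs <- mean(obs)
  t_null <- vapply(null_list, mean, numeric(1))
  # one-sided (clustering => longer runs) mid-p permutation p-value:
  # approximately uniform under label exchange despite the discreteness of
  # the run-length statistic
  p_perm <- if (degenerate) 1 else
    (0.5 + sum(t_null > t_obs) + 0.5 * sum(t_null == t_obs)) /
      (n_shuffles + 1)
  list(p_value = p_perm, p_rank_sum = p_rank_sum, observed_runs = obs,
       null_runs = null_runs, n_significant = n_sig)
}

#' Effect-size contrast between two variant classes
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction plus the
#' Hodges-Lehmann location-shift estimate.
#'
#' @param x,y numeric effect (or |effect|) samples.
#' @return list with `p_value`, `location_shift`, `conf_int`, `n`.
#' @export
effect_size_contrast <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("empty class in effect-size contrast")
  w <- wilcox.test(x, y, correct = TRUE, exact = FALSE, conf.int = TRUE)
  list(p_value = w$p.value, location_shift = unname(w$estimate),
       conf_int = unname(w$conf.int), n = c(length(x), length(y)))
}

#' Exact binomial proportion contrast
#'
#' @param k successes, @param n trials, @param p0 null proportion.
#' @return list with `p_value`, `estimate`, `conf_int`.
#' @export
proportion_contrast <- function(k, n, p0 = 0.5) {
  b <- binom.test(k, n, p = p0)
  list(p_value = b$p.value, estimate = unname(b$estimate),
       conf_int = unname(b$conf.int))
}

#' Standard class-level comparisons over fitted effects
#'
#' Runs the usual contrasts: |effect| of transversions versus transitions
#' (rank-sum with continuity correction, Hodges-Lehmann shift), |effect| of
#' 1-bp deletions versus SNVs, and the activating-versus-repressing
#' proportion among significant variants (exact binomial against 0.5).
#' Contrasts with an empty class are skipped with a warning.
#'
#' @param estimates estimates table with `class` and `vclass` columns.
#' @return named list of contrast results plus class counts.
#' @export
class_comparisons <- function(estimates) {
  est <- as.data.table(estimates)
  out <- list(counts = est[, .N, by = .(vclass, class)])
  snv <- est[vclass %in% c("transition", "transversion")]
  if (nrow(snv[vclass == "transition"]) && nrow(snv[vclass == "transversion"])) {
    out$transversion_vs_transition <- effect_size_contrast(
      abs(snv[vclass == "transversion", log2_effect]),
      abs(snv[vclass == "transition", log2_effect]))
  } else warning("empty transition or transversion class; contrast skipped")
  del <- est[vclass == "deletion_1bp"]
  if (nrow(del) && nrow(snv)) {
    out$deletion_vs_snv <- effect_size_contrast(
      abs(del$log2_effect), abs(snv$log2_effect))
  }
  sig <- est[class %in% c("activating", "repressing")]
  if (nrow(sig)) {
    out$activating_vs_repressing <- proportion_contrast(
      sum(sig$class == "activating"), nrow(sig), 0.5)
  } else warning("no significant variants; proportion contrast skipped")
  out
}
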