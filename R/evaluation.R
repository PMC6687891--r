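#' Area under the ROC curve via the rank-sum identity
#'
#' Midrank handling for score ties; equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) class labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Tie-aware step integration: precision is evaluated at each distinct
#' score threshold and integrated over recall increments.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L || sum(!labels) == 0L) stop("both classes must be non-empty")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Attach an annotation track to an effects table
#'
#' Per-allele tracks join on (position, alt); per-position tracks assume
#' the same value for every substitution at the position.
#'
#' @param effects effects/estimates `data.table` with `position`, `alt`.
#' @param track `data.table` with `position`, `score` and, for per-allele
#'   granularity, `alt`.
#' @param granularity `"per_allele"` or `"per_position"` (default guessed
#'   from the presence of an `alt` column).
#' @return numeric score vector aligned with `effects` rows (`NA` where the
#'   track has no value).
#' @export
attach_track <- function(effects, track,
                         granularity = if ("alt" %in% names(track))
                           "per_allele" else "per_position") {
  effects <- as.data.table(effects); track <- as.data.table(track)
  if (granularity == "per_allele") {
    m <- merge(effects[, .(position, alt, .row = seq_len(.N))],
               track[, .(position, alt, score)],
               by = c("position", "alt"), all.x = TRUE)
  } else {
    m <- merge(effects[, .(position, alt, .row = seq_len(.N))],
               unique(track[, .(position, score)]),
               by = "position", all.x = TRUE)
  }
  setorder(m, .row)
  m$score
}

#' Correlate an annotation track with measured effects
#'
#' Correlation over variants carrying both an effect and a score; absolute
#' effects by default, signed mode for direction-aware scores such as
#' deltaSVM. A constant track (or constant effects) yields `NA` with a
#' reason.
#'
#' @param estimates estimates table.
#' @param track annotation track (see [attach_track()]) or a numeric score
#'   vector aligned with `estimates` rows.
#' @param method `"pearson"` or `"spearman"`.
#' @param use_absolute_effect correlate |effect| (default `TRUE`).
#' @param signed correlate signed effect with signed score (overrides
#'   `use_absolute_effect`).
#' @return list with `correlation`, `n`, `n_missing_score`, `method`,
#'   `reason` (when undefined).
#' @export
correlate_scores <- function(estimates, track,
                             method = c("pearson", "spearman"),
                             use_absolute_effect = TRUE, signed = FALSE) {
  method <- match.arg(method)
  est <- as.data.table(estimates)
  score <- if (is.numeric(track)) track else attach_track(est, track)
  eff <- if (signed) est$log2_effect
         else if (use_absolute_effect) abs(est$log2_effect)
         else est$log2_effect
  ok <- complete.cases(eff, score)
  if (sum(ok) < 3L)
    stop("need at least 3 paired (effect, score) values, got ", sum(ok))
  if (sd(score[ok]) == 0 || sd(eff[ok]) == 0) {
    return(list(correlation = NA_real_, n = sum(ok),
      n_missing_score = sum(!ok), method = method,
      reason = "zero variance in scores or effects"))
  }
  list(correlation = cor(eff[ok], score[ok], method = method), n = sum(ok),
       n_missing_score = sum(!ok), method = method, reason = NULL)
}

#' Matched top-N classification benchmark of annotation scores
#'
#' Positives are the `top_n` variants with the largest |log2 effect| among
#' significant variants (minimum tag support, coefficient p below `alpha`);
#' ties at the boundary are included then trimmed by smallest p-value.
#' Negatives are resampled `n_resamples` times without replacement from the
#' pool with |log2 effect| below `null_abs_effect_max`, matching the
#' per-element contribution of the positives; where an element's negative
#' pool is scarcer than its positives, the positives are downsampled.
#' AUROC and AUPRC are computed per score and resample.
#'
#' @param effects effects table across elements: columns `element`,
#'   `position`, `alt`, `log2_effect`, `p_value`, `n_tags`.
#' @param scores named list of numeric score vectors aligned with `effects`
#'   rows (use [attach_track()]), or a named list of track tables.
#' @param top_n number of positives (200, 500 or 1000 in the standard
#'   setup).
#' @param null_abs_effect_max |effect| ceiling for the negative pool.
#' @param alpha significance threshold for positives.
#' @param min_tags minimum tag support for all variants considered.
#' @param n_resamples number of negative resamples (default 100).
#' @param seed master seed; per-resample seeds are derived from it.
#' @return list with `metrics` (`data.table`: score, resample, auroc,
#'   auprc), `summary` (mean/median/sd per score), `balance_log`
#'   (per-element positive/negative counts per resample), and the realized
#'   `n_positives`.
#' @export
classification_eval <- function(effects, scores, top_n = 200L,
                                null_abs_effect_max = 0.05, alpha = 1e-5,
                                min_tags = 10L, n_resamples = 100L,
                                seed = 1L) {
  eff <- as.data.table(effects)
  if (!"element" %in% names(eff)) eff[, element := "element1"]
  eff <- eff[n_tags >= min_tags]
  eff[, .row := seq_len(.N)]
  score_vecs <- lapply(scores, function(s)
    if (is.numeric(s)) s[eff$.row] else attach_track(eff, s))

  pos_pool <- eff[p_value < alpha][order(-abs(log2_effect), p_value)]
  if (nrow(pos_pool) == 0L) stop("no significant variants for positives")
  positives <- head(pos_pool, top_n)
  neg_pool <- eff[abs(log2_effect) < null_abs_effect_max]
  # per-element matching; downsample positives where negatives are scarce
  pos_by_el <- positives[, .N, by = element]
  neg_by_el <- neg_pool[, .N, by = element]
  plan <- merge(pos_by_el, neg_by_el, by = "element", all.x = TRUE,
                suffixes = c("_pos", "_neg"))
  plan[is.na(N_neg), N_neg := 0L]
  excluded <- plan[N_neg == 0L, element]
  if (length(excluded))
    warning("element(s) without negative pool excluded: ",
            paste(excluded, collapse = ", "))
  plan <- plan[N_neg > 0L]
  plan[, n_use := pmin(N_pos, N_neg)]
  pos_use <- rbindlist(lapply(seq_len(nrow(plan)), function(i)
    head(positives[element == plan$element[i]], plan$n_use[i])))

  metrics <- list(); balance <- list()
  for (r in seq_len(n_resamples)) {
    set.seed(seed + r)  # derived per-resample seed
    neg_use <- rbindlist(lapply(seq_len(nrow(plan)), function(i) {
      pool <- neg_pool[element == plan$element[i]]
      pool[sample(nrow(pool), plan$n_use[i])]
    }))
    rows <- c(pos_use$.row, neg_use$.row)
    labels <- c(rep(TRUE, nrow(pos_use)), rep(FALSE, nrow(neg_use)))
    balance[[r]] <- data.table(resample = r,
      element = c(pos_use$element, neg_use$element), label = labels)
    for (sn in names(score_vecs)) {
      sv <- score_vecs[[sn]][match(rows, eff$.row)]
      ok <- !is.na(sv)
      metrics[[length(metrics) + 1L]] <- data.table(score = sn,
        resample = r, auroc = auroc(sv[ok], labels[ok]),
        auprc = auprc(sv[ok], labels[ok]))
    }
  }
  metrics <- rbindlist(metrics)
  summary <- metrics[, .(mean_auroc = mean(auroc),
    median_auroc = stats::median(auroc), sd_auroc = sd(auroc),
    mean_auprc = mean(auprc), median_auprc = stats::median(auprc),
    sd_auprc = sd(auprc)), by = score]
  list(metrics = metrics[], summary = summary[],
       balance_log = rbindlist(balance),
       n_positives = nrow(pos_use))
}
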