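#' Build the combined-replicate regression design
#'
#' Rows are (replicate, tag) observations with both RNA and DNA counts.
#' The response is `log2(rna_count)`; predictors are one `log2(dna_count)`
#' column per replicate (zero off-replicate, so the DNA columns are
#' orthogonal across replicates by construction), a single intercept (the
#' model offset), and one binary indicator column per variant observed on at
#' least one included row. Tags flagged disqualified (insertions, multi-bp
#' deletions, ambiguous calls) contribute no rows.
#'
#' @param counts CountTable (`data.table`: replicate, tag, dna_count,
#'   rna_count).
#' @param assignment assignment `data.table` mapping tags to variant tokens.
#' @param mode `"combined"` (per-replicate DNA columns) or
#'   `"single_replicate"` (one DNA column; counts must then hold a single
#'   replicate).
#' @return list with sparse `X` (`dgCMatrix`), `y`, `col_info`
#'   (`data.table`: type, replicate, token, position, ref, alt) and
#'   `row_info` (replicate, tag).
#' @export
build_design <- function(counts, assignment, mode = c("combined",
                                                      "single_replicate")) {
  mode <- match.arg(mode)
  counts <- as.data.table(counts)
  keep_tags <- assignment[disqualified %in% c(FALSE, NA), tag]
  rows <- counts[tag %in% keep_tags]
  if (nrow(rows) == 0L) stop("empty design: no usable (replicate, tag) rows")
  if (mode == "single_replicate" && length(unique(rows$replicate)) > 1L)
    stop("single_replicate mode requires counts from one replicate")
  setorder(rows, replicate, tag)
  y <- log2(rows$rna_count)
  reps <- sort(unique(rows$replicate))
  n <- nrow(rows)

  # variant indicator block
  hap <- assignment[tag %in% rows$tag, .(tag, variants)]
  vars <- parse_variant_tokens(hap$variants)
  vars[, tag := hap$tag[idx]]
  # columns for variants observed on >= 1 included row
  vtab <- unique(vars[, .(position, ref, alt)])
  setorder(vtab, position)
  vtab <- vtab[order(position, alt_order(alt))]
  vtab[, token := format_variant_tokens(position, ref, alt)]
  vars[, token := format_variant_tokens(position, ref, alt)]

  n_dna <- if (mode == "combined") length(reps) else 1L
  p <- 1L + n_dna + nrow(vtab)
  # triplets: intercept
  ti <- seq_len(n); tj <- rep(1L, n); tx <- rep(1, n)
  # DNA columns
  rep_col <- if (mode == "combined") match(rows$replicate, reps) else rep(1L, n)
  ti <- c(ti, seq_len(n)); tj <- c(tj, 1L + rep_col)
  tx <- c(tx, log2(rows$dna_count))
  # variant block: one entry per (row, variant on that row's tag)
  if (nrow(vtab)) {
    row_idx <- data.table(tag = rows$tag, row = seq_len(n))
    vrows <- merge(row_idx, vars[, .(tag, token)], by = "tag",
                   allow.cartesian = TRUE)
    vj <- 1L + n_dna + match(vrows$token, vtab$token)
    ti <- c(ti, vrows$row); tj <- c(tj, vj); tx <- c(tx, rep(1, nrow(vrows)))
  }
  X <- sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, p))
  col_info <- rbindlist(list(
    data.table(type = "intercept", replicate = NA_integer_,
      token = NA_character_, position = NA_integer_, ref = NA_character_,
      alt = NA_character_),
    data.table(type = "dna", replicate = if (mode == "combined") reps else
      rows$replicate[1L], token = NA_character_, position = NA_integer_,
      ref = NA_character_, alt = NA_character_),
    if (nrow(vtab)) data.table(type = "variant", replicate = NA_integer_,
      token = vtab$token, position = vtab$position, ref = vtab$ref,
      alt = vtab$alt)))
  list(X = X, y = y, col_info = col_info,
       row_info = rows[, .(replicate, tag)])
}

#' Fit per-variant log2 expression effects by ordinary least squares
#'
#' Solves the multiple linear regression of log2 RNA on per-replicate log2
#' DNA, variant indicators, and an intercept; the coefficient of each
#' variant column is its log2 expression effect relative to wild type.
#' Standard errors, two-sided t-test p-values and 95% confidence intervals
#' come from the OLS covariance (acknowledged anti-conservative: tags are
#' treated as independent). Linearly dependent variant columns are dropped
#' with a diagnostic, preferring to keep earlier columns.
#'
#' @param design output of [build_design()].
#' @param conf_level confidence level for the reported intervals.
#' @return list with `estimates` (`data.table`: token, position, ref, alt,
#'   vclass, log2_effect, se, p_value, ci_low, ci_high, n_tags,
#'   n_distinct_tags) and `diagnostics` (intercept, dna_slopes, sigma, df,
#'   aliased tokens).
#' @export
fit_effects <- function(design, conf_level = 0.95) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L)
    stop("under-determined design: ", n, " rows for ", p, " columns")
  keep <- seq_len(p)
  XtX <- as.matrix(crossprod(X))
  qrx <- qr(XtX)
  aliased <- integer(0)
  if (qrx$rank < p) {
    # identify a maximal independent set preferring earlier columns:
    # greedy Cholesky updates on the (small, p x p) cross-product matrix
    keep <- greedy_independent(XtX)
    aliased <- setdiff(seq_len(p), keep)
    X <- X[, keep, drop = FALSE]
    XtX <- as.matrix(crossprod(X))
  }
  Xty <- as.numeric(crossprod(X, y))
  ch <- chol(XtX)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  fitted <- as.numeric(X %*% beta)
  rss <- sum((y - fitted)^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(ch)
  se_hat <- sqrt(pmax(0, sigma2 * diag(XtX_inv)))
  tstat <- ifelse(se_hat > 0, beta / se_hat, NA_real_)
  pval <- 2 * pt(-abs(tstat), df)
  zq <- qt(1 - (1 - conf_level) / 2, df)
  lo_hat <- beta - zq * se_hat
  hi_hat <- beta + zq * se_hat

  ci <- design$col_info
  full <- data.table(col = seq_len(p))
  full[, `:=`(coef = NA_real_, se = NA_real_, p_value = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_)]
  full[keep, `:=`(coef = beta, se = se_hat, p_value = pval,
                  ci_low = lo_hat, ci_high = hi_hat)]
  vcols <- which(ci$type == "variant")
  est <- data.table(token = ci$token[vcols], position = ci$position[vcols],
    ref = ci$ref[vcols], alt = ci$alt[vcols],
    log2_effect = full$coef[vcols], se = full$se[vcols],
    p_value = full$p_value[vcols], ci_low = full$ci_low[vcols],
    ci_high = full$ci_high[vcols])
  est[, vclass := variant_class(ref, alt)]
  # tag support: rows carrying the variant, and distinct tags carrying it
  if (nrow(est)) {
    Xv <- design$X[, vcols, drop = FALSE]
    est[, n_tags := as.integer(Matrix::colSums(Xv))]
    tag_of_row <- design$row_info$tag
    nd <- vapply(seq_along(vcols), function(k) {
      length(unique(tag_of_row[which(Xv[, k] != 0)]))
    }, integer(1))
    est[, n_distinct_tags := nd]
  } else {
    est[, `:=`(n_tags = integer(), n_distinct_tags = integer())]
  }
  est <- est[!(token %in% ci$token[aliased])]
  dcols <- which(ci$type == "dna")
  diagnostics <- list(
    intercept = full$coef[which(ci$type == "intercept")],
    dna_slopes = setNames(full$coef[dcols],
                          paste0("replicate_", ci$replicate[dcols])),
    sigma = sqrt(sigma2), df = df, n_rows = n,
    aliased = ci$token[aliased])
  list(estimates = est[], diagnostics = diagnostics)
}

# greedy maximal independent column set in position order, from the Gram
# matrix: incremental Cholesky -- accept column k if its squared residual
# norm after projection on the accepted set exceeds a relative tolerance
greedy_independent <- function(G, tol = 1e-7) {
  p <- ncol(G)
  keep <- integer(0)
  R <- matrix(0, 0, 0)  # upper-triangular factor for the accepted set
  for (k in seq_len(p)) {
    gk <- G[keep, k]
    r <- if (length(keep)) backsolve(R, gk, transpose = TRUE) else numeric(0)
    d2 <- G[k, k] - sum(r^2)
    if (d2 > tol * max(G[k, k], 1)) {
      m <- length(keep) + 1L
      Rnew <- matrix(0, m, m)
      if (m > 1L) {
        Rnew[-m, -m] <- R
        Rnew[-m, m] <- r
      }
      Rnew[m, m] <- sqrt(d2)
      R <- Rnew
      keep <- c(keep, k)
    }
  }
  keep
}

#' Filter fitted effects on minimum tag support
#'
#' Variants supported by fewer than `min_tags` observations are removed
#' from downstream reporting; the fit itself is not re-run. Support is
#' counted either as (tag, replicate) rows in the combined design (the
#' model's effective sample size) or as distinct tags.
#'
#' @param estimates estimates table from [fit_effects()].
#' @param min_tags minimum support (default 10).
#' @param tag_count_mode `"rows"` or `"distinct_tags"`.
#' @return filtered estimates `data.table`.
#' @export
filter_min_tags <- function(estimates, min_tags = 10L,
                            tag_count_mode = c("rows", "distinct_tags")) {
  tag_count_mode <- match.arg(tag_count_mode)
  col <- if (tag_count_mode == "rows") "n_tags" else "n_distinct_tags"
  estimates[estimates[[col]] >= min_tags]
}

#' Classify variant effects as activating / repressing / nonsignificant
#'
#' A variant is significant when its coefficient p-value is below `alpha`
#' (default 1e-5) and, if `fold_threshold` is given, |log2 effect| reaches
#' `log2(fold_threshold)`.
#'
#' @param estimates (filtered) estimates table.
#' @param alpha significance threshold on the coefficient p-value.
#' @param fold_threshold optional minimum fold change (e.g. 2 for the
#'   two-fold classification), or `NULL`.
#' @return list with `estimates` (input plus a `class` column) and
#'   `summary` (counts and median |effect| by class).
#' @export
significance_report <- function(estimates, alpha = 1e-5,
                                fold_threshold = NULL) {
  est <- copy(as.data.table(estimates))
  sig <- est$p_value < alpha & !is.na(est$p_value)
  if (!is.null(fold_threshold))
    sig <- sig & abs(est$log2_effect) >= log2(fold_threshold)
  est[, class := "nonsignificant"]
  est[sig & log2_effect > 0, class := "activating"]
  est[sig & log2_effect < 0, class := "repressing"]
  summ <- est[, .(n = .N, median_abs_effect = stats::median(abs(log2_effect))),
              by = class]
  list(estimates = est[], summary = summ[])
}

#' Compare two experiments by confidence-interval overlap
#'
#' A shared variant is significantly different between two experiments
#' (e.g. a knockdown versus scramble control) iff its confidence intervals
#' do not intersect.
#'
#' @param estimates_a,estimates_b estimates tables sharing variant tokens.
#' @return `data.table` of shared variants with both intervals, a
#'   `different` flag and the `direction` ("a_higher"/"b_higher") where
#'   different.
#' @export
compare_conditions <- function(estimates_a, estimates_b) {
  m <- merge(as.data.table(estimates_a), as.data.table(estimates_b),
             by = c("token", "position", "ref", "alt"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    warning("no shared variants between the two estimate sets")
    return(m)
  }
  m[, different := ci_high_a < ci_low_b | ci_high_b < ci_low_a]
  m[, direction := NA_character_]
  m[different & ci_high_a < ci_low_b, direction := "b_higher"]
  m[different & ci_high_b < ci_low_a, direction := "a_higher"]
  setorder(m, position, alt)
  m[]
}
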