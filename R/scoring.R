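#' Construct a k-mer weight table
#'
#' @param weights named numeric vector (names are k-mers over A/C/G/T, all
#'   the same length) or a two-column data.frame (kmer, weight).
#' @param canonicalize if `TRUE` (default) a k-mer lookup tries the literal
#'   k-mer, then its reverse complement, before defaulting to zero (weight
#'   files are typically strand-canonical).
#' @return `satmut_kmer_table` list with `k`, `weights`, `canonicalize`.
#' @export
kmer_weight_table <- function(weights, canonicalize = TRUE) {
  if (is.data.frame(weights))
    weights <- setNames(as.numeric(weights[[2L]]), as.character(weights[[1L]]))
  ks <- unique(nchar(names(weights)))
  if (length(ks) != 1L || ks < 2L)
    stop("k-mer keys must share one length k >= 2")
  if (!all(grepl("^[ACGT]+$", names(weights))))
    stop("k-mer keys must be over {A,C,G,T}")
  structure(list(k = as.integer(ks), weights = weights,
                 canonicalize = canonicalize),
            class = "satmut_kmer_table")
}

lookup_kmers <- function(kmers, table) {
  w <- table$weights[kmers]
  if (table$canonicalize) {
    miss <- is.na(w)
    if (any(miss)) w[miss] <- table$weights[revcomp(kmers[miss])]
  }
  w[is.na(w)] <- 0  # absent k-mers are treated as zero
  unname(w)
}

#' deltaSVM score of an SNV from a k-mer weight table
#'
#' The score is the mean weight of all k-mers of the reference sequence
#' overlapping the variant base minus the mean weight of the corresponding
#' alternative-allele k-mers (fewer windows near element edges); k-mers
#' absent from the table contribute zero. The default sign follows the
#' reference-minus-alternative reading; `sign = "alt-minus-ref"` negates it
#' to match the original deltaSVM convention.
#'
#' @param position 0-based SNV position.
#' @param ref,alt single-base alleles.
#' @param element element (or plain sequence string).
#' @param table a [kmer_weight_table()].
#' @param sign `"ref-minus-alt"` (default) or `"alt-minus-ref"`.
#' @return numeric score.
#' @export
delta_svm_score <- function(position, ref, alt, element, table,
                            sign = c("ref-minus-alt", "alt-minus-ref")) {
  sign <- match.arg(sign)
  seq <- if (is.list(element)) element$sequence else element
  L <- nchar(seq)
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == "-" || alt == "-")
    stop("delta_svm_score supports SNVs only")
  if (substr(seq, position + 1L, position + 1L) != ref)
    stop("ref allele does not match element sequence at position ", position)
  k <- table$k
  starts <- max(0L, position - k + 1L):min(L - k, position)
  if (length(starts) == 0L || starts[1L] > position)
    stop("position allows no overlapping k-mer")
  ref_kmers <- substring(seq, starts + 1L, starts + k)
  altseq <- paste0(substr(seq, 1L, position), alt,
                   substr(seq, position + 2L, L))
  alt_kmers <- substring(altseq, starts + 1L, starts + k)
  s <- mean(lookup_kmers(ref_kmers, table)) -
       mean(lookup_kmers(alt_kmers, table))
  if (sign == "alt-minus-ref") -s else s
}

#' deltaSVM scores for a table of SNVs
#'
#' @param variants `data.table` with columns `position`, `ref`, `alt`
#'   (SNVs; other classes get `NA`).
#' @inheritParams delta_svm_score
#' @return numeric vector aligned with `variants` rows.
#' @export
delta_svm_scores <- function(variants, element, table,
                             sign = c("ref-minus-alt", "alt-minus-ref")) {
  sign <- match.arg(sign)
  vapply(seq_len(nrow(variants)), function(i) {
    if (variants$alt[i] == "-" || variants$ref[i] == "-") return(NA_real_)
    delta_svm_score(variants$position[i], variants$ref[i], variants$alt[i],
                    element, table, sign)
  }, numeric(1))
}

#' Build a position weight matrix from a position frequency matrix
#'
#' Converts base counts to log2-odds weights with a pseudocount per cell
#' and a uniform background.
#'
#' @param counts 4 x L numeric matrix, rows A, C, G, T.
#' @param motif_id motif identifier.
#' @param factor transcription-factor name (defaults to `motif_id`).
#' @param pseudocount added to every cell (default 0.8).
#' @param background base background probabilities (default uniform).
#' @return `satmut_pwm` list with `motif_id`, `factor`, `mat` (log2-odds),
#'   `length`, `best_possible_score`.
#' @export
pfm_to_pwm <- function(counts, motif_id = "motif", factor = motif_id,
                       pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop("motif length must be >= 4")
  prob <- sweep(counts + pseudocount, 2L,
                colSums(counts + pseudocount), "/")
  mat <- log2(prob / background)
  rownames(mat) <- BASES
  structure(list(motif_id = motif_id, factor = factor, mat = mat,
                 length = ncol(mat),
                 best_possible_score = sum(apply(mat, 2L, max))),
            class = "satmut_pwm")
}

encode_seq <- function(seq) match(strsplit(seq, NULL)[[1]], BASES)

score_windows <- function(code, mat) {
  w <- ncol(mat)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(s)
    sum(mat[cbind(code[s:(s + w - 1L)], seq_len(w))]), numeric(1))
}

#' Scan an element with a PWM on both strands
#'
#' Scores every window on the forward and reverse-complement strand and
#' reports raw and length-normalized (raw / motif length) scores, in
#' deterministic (start, strand) order.
#'
#' @param element element (or plain sequence string).
#' @param pwm a [pfm_to_pwm()] object.
#' @param threshold optional minimum length-normalized score.
#' @return `data.table`: motif_id, factor, start, end (0-based half-open),
#'   strand, raw_score, norm_score. Empty when the PWM is wider than the
#'   element.
#' @export
scan_pwm <- function(element, pwm, threshold = NULL) {
  seq <- if (is.list(element)) element$sequence else element
  L <- nchar(seq)
  w <- pwm$length
  empty <- data.table(motif_id = character(), factor = character(),
    start = integer(), end = integer(), strand = character(),
    raw_score = numeric(), norm_score = numeric())
  if (w > L) return(empty)
  code <- encode_seq(seq)
  fwd <- score_windows(code, pwm$mat)
  # reverse strand: score the reverse complement of each window, reported
  # at the same element coordinates
  rc_mat <- pwm$mat[4:1, w:1, drop = FALSE]
  rownames(rc_mat) <- BASES
  rev <- score_windows(code, rc_mat)
  out <- data.table(motif_id = pwm$motif_id, factor = pwm$factor,
    start = rep(0:(L - w), 2L), strand = rep(c("+", "-"), each = L - w + 1L),
    raw_score = c(fwd, rev))
  out[, end := start + w]
  out[, norm_score := raw_score / w]
  if (!is.null(threshold)) out <- out[norm_score >= threshold]
  setorder(out, start, strand)
  out[, .(motif_id, factor, start, end, strand, raw_score, norm_score)]
}

#' Percentile thresholds of pooled motif scores
#'
#' Linear-interpolation percentiles (quantile type 7) of the pooled
#' length-normalized match scores, usable as filters downstream.
#'
#' @param scores numeric vector of length-normalized match scores (pooled
#'   across elements).
#' @param percentiles requested percentiles in \[0, 1\].
#' @return named numeric vector of thresholds.
#' @export
motif_percentile_thresholds <- function(scores,
                                        percentiles = c(0.9, 0.75, 0.5,
                                                        0.25, 0.1)) {
  if (length(scores) == 0L) stop("empty score pool")
  quantile(scores, probs = percentiles, type = 7, names = TRUE)
}

#' Count distinct motifs overlapping a position
#'
#' Overlapping matches of the same motif are combined and matches on both
#' strands considered only once; the count is the number of distinct motif
#' identities whose merged intervals overlap the position.
#'
#' @param position 0-based element position.
#' @param matches match table from [scan_pwm()] (possibly thresholded,
#'   possibly several motifs concatenated).
#' @param merge_same_motif merge overlapping same-motif matches (default
#'   `TRUE`; with `FALSE` every match counts).
#' @return integer count.
#' @export
count_overlapping_motifs <- function(position, matches,
                                     merge_same_motif = TRUE) {
  m <- as.data.table(matches)
  hit <- m[start <= position & position < end]
  if (!merge_same_motif) return(nrow(hit))
  length(unique(hit$motif_id))
}

#' PWM score change of an SNV with the 80th-percentile gate
#'
#' Best window score for the reference and the alternative sequence over
#' all windows (both strands) overlapping the variant;
#' `delta = alt_best - ref_best`. The variant passes the gate when either
#' best score exceeds `gate_percentile` of the PWM's best possible score.
#'
#' @param position,ref,alt 0-based SNV.
#' @param element element (or plain sequence string).
#' @param pwm a [pfm_to_pwm()] object.
#' @param gate_percentile gate fraction of `best_possible_score`
#'   (default 0.8).
#' @return list with `delta`, `ref_best`, `alt_best`, `gated`.
#' @export
pwm_delta <- function(position, ref, alt, element, pwm,
                      gate_percentile = 0.8) {
  seq <- if (is.list(element)) element$sequence else element
  L <- nchar(seq)
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == "-" || alt == "-")
    stop("pwm_delta supports SNVs only")
  w <- pwm$length
  lo <- max(0L, position - w + 1L)
  hi <- min(L - w, position)
  if (hi < lo)
    return(list(delta = NA_real_, ref_best = -Inf, alt_best = -Inf,
                gated = FALSE))
  altseq <- paste0(substr(seq, 1L, position), alt,
                   substr(seq, position + 2L, L))
  best_over <- function(s) {
    sc <- scan_pwm(s, pwm)
    sc <- sc[start >= lo & start <= hi]
    if (nrow(sc) == 0L) -Inf else max(sc$raw_score)
  }
  ref_best <- best_over(seq)
  alt_best <- best_over(altseq)
  list(delta = alt_best - ref_best, ref_best = ref_best,
       alt_best = alt_best,
       gated = max(ref_best, alt_best) >
         gate_percentile * pwm$best_possible_score)
}

#' Most frequent factors in a match set, with ties included
#'
#' Returns the `top_n` factors with the most motif matches plus any factor
#' tied with the n-th count.
#'
#' @param matches match table with a `factor` column.
#' @param top_n number of top factors before tie expansion (default 5).
#' @return character vector of factor names (most frequent first).
#' @export
top_factors <- function(matches, top_n = 5L) {
  counts <- sort(table(matches$factor), decreasing = TRUE)
  if (length(counts) <= top_n) return(names(counts))
  cutoff <- counts[top_n]
  names(counts)[counts >= cutoff]
}
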