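#' Align a read to the target element
#'
#' Exact semi-global alignment (free gaps at the reference ends, affine gap
#' penalties) of an amplicon read against the element. Ties are broken by
#' preferring a mismatch over a gap, and indels are left-normalised so the
#' leftmost equivalent placement is reported. Reads whose fraction of
#' matching columns falls below `min_identity` are rejected.
#'
#' @param read DNA string.
#' @param element element (list with `sequence`) or a plain DNA string.
#' @param band maximum admissible excess of read length over element length.
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   positive).
#' @param min_identity identity floor; below it the read is unalignable.
#' @return list with `aligned` (logical), `ref_start`/`ref_end` (0-based
#'   half-open covered interval), `coverage` (logical mask over the
#'   element), `differences` (`data.table`: position, ref, alt, kind),
#'   `score`, `identity`.
#' @export
align_to_reference <- function(read, element, band = 25L, match = 1,
                               mismatch = -1, gap_open = 3, gap_extend = 1,
                               min_identity = 0.8) {
  ref <- if (is.list(element)) element$sequence else element
  L <- nchar(ref)
  if (nchar(read) > L + band)
    stop("read longer than element + band (", nchar(read), " > ", L + band, ")")
  al <- align_semi_global_cpp(read, ref, match, mismatch, gap_open, gap_extend)
  identity <- al$n_match / max(1L, al$n_cols)
  cov <- rep(FALSE, L)
  if (al$ref_end > al$ref_start) cov[(al$ref_start + 1L):al$ref_end] <- TRUE
  if (identity < min_identity) {
    return(list(aligned = FALSE, ref_start = al$ref_start,
      ref_end = al$ref_end, coverage = rep(FALSE, L),
      differences = empty_differences(), score = al$score,
      identity = identity))
  }
  diffs <- extract_differences(al$ops, read, ref, al$ref_start)
  diffs <- left_normalize_indels(diffs, ref)
  list(aligned = TRUE, ref_start = al$ref_start, ref_end = al$ref_end,
    coverage = cov, differences = diffs, score = al$score,
    identity = identity)
}

empty_differences <- function() {
  data.table(position = integer(), ref = character(), alt = character(),
             kind = character())
}

# walk the op string (=, X, D, I) and collect mismatches / indels; adjacent
# D ops merge into one multi-bp deletion, adjacent I ops into one insertion
extract_differences <- function(ops, read, ref, ref_start) {
  o <- strsplit(ops, NULL)[[1]]
  i <- 0L                 # read position consumed (0-based count)
  j <- ref_start          # reference position (0-based)
  pos <- integer(); rr <- character(); aa <- character(); kk <- character()
  k <- 1L
  n_ops <- length(o)
  while (k <= n_ops) {
    op <- o[k]
    if (op == "=" ) { i <- i + 1L; j <- j + 1L; k <- k + 1L
    } else if (op == "X") {
      pos <- c(pos, j)
      rr <- c(rr, substr(ref, j + 1L, j + 1L))
      aa <- c(aa, substr(read, i + 1L, i + 1L))
      kk <- c(kk, "snv")
      i <- i + 1L; j <- j + 1L; k <- k + 1L
    } else if (op == "D") {
      len <- 0L
      while (k <= n_ops && o[k] == "D") { len <- len + 1L; k <- k + 1L }
      pos <- c(pos, j)
      rr <- c(rr, substr(ref, j + 1L, j + len))
      aa <- c(aa, "-")
      kk <- c(kk, if (len == 1L) "deletion_1bp" else "deletion_multi")
      j <- j + len
    } else {  # I
      len <- 0L
      start_i <- i
      while (k <= n_ops && o[k] == "I") { len <- len + 1L; i <- i + 1L; k <- k + 1L }
      pos <- c(pos, j)
      rr <- c(rr, "-")
      aa <- c(aa, substr(read, start_i + 1L, start_i + len))
      kk <- c(kk, "insertion")
    }
  }
  data.table(position = pos, ref = rr, alt = aa, kind = kk)
}

# shift indels left through repeat runs (VCF-style left alignment) so that
# equivalent placements report the leftmost coordinate
left_normalize_indels <- function(diffs, ref) {
  if (nrow(diffs) == 0L) return(diffs)
  for (r in which(diffs$kind %in% c("deletion_1bp", "deletion_multi"))) {
    p <- diffs$position[r]
    len <- nchar(diffs$ref[r])
    while (p > 0L &&
           substr(ref, p, p) == substr(ref, p + len, p + len)) {
      p <- p - 1L
    }
    diffs$position[r] <- p
    diffs$ref[r] <- substr(ref, p + 1L, p + len)
  }
  for (r in which(diffs$kind == "insertion")) {
    p <- diffs$position[r]
    ins <- diffs$alt[r]
    len <- nchar(ins)
    # inserting `ins` before position p: can shift left while the base
    # before equals the last inserted base (rotate)
    while (p > 0L && substr(ref, p, p) == substr(ins, len, len)) {
      ins <- paste0(substr(ref, p, p), substr(ins, 1L, len - 1L))
      p <- p - 1L
    }
    diffs$position[r] <- p
    diffs$alt[r] <- ins
  }
  setorder(diffs, position)
  diffs[]
}

#' Call per-tag variants from grouped subassembly reads
#'
#' Implements the assignment rule: a tag is included only when every element
#' position is covered by at least `min_coverage` aligned reads; a
#' difference becomes a called variant when supported by more than
#' `majority` of the reads covering its position. Tags with a called
#' insertion or multi-bp deletion are disqualified; tags with uncalled
#' differences at near-50% support are flagged ambiguous.
#'
#' @param reads named list: tag -> character vector of reads, or a
#'   `data.table` with columns `tag`, `read`.
#' @param element target element (or plain sequence string).
#' @param min_coverage minimum per-position read coverage (default 3).
#' @param majority strict majority fraction for a call (default 0.5).
#' @param ambiguous_min uncalled differences supported by at least this
#'   fraction of covering reads flag the tag ambiguous (default 0.3).
#' @param ... passed to [align_to_reference()].
#' @return assignment `data.table` (tag, variants, n_supporting_reads,
#'   disqualified, reason).
#' @export
call_tag_variants <- function(reads, element, min_coverage = 3L,
                              majority = 0.5, ambiguous_min = 0.3, ...) {
  if (is.data.frame(reads)) {
    reads <- split(reads$read, reads$tag)
  }
  ref <- if (is.list(element)) element$sequence else element
  L <- nchar(ref)
  rows <- lapply(names(reads), function(tg) {
    rds <- reads[[tg]]
    if (length(rds) == 0L)
      return(data.table(tag = tg, variants = "", n_supporting_reads = 0L,
        disqualified = TRUE, reason = "low_coverage"))
    als <- lapply(rds, align_to_reference, element = ref, ...)
    als <- Filter(function(a) a$aligned, als)
    n_reads <- length(als)
    cov <- if (n_reads) Reduce(`+`, lapply(als, `[[`, "coverage"))
           else rep(0L, L)
    if (n_reads < min_coverage || any(cov < min_coverage))
      return(data.table(tag = tg, variants = "", n_supporting_reads = n_reads,
        disqualified = TRUE, reason = "low_coverage"))
    diffs <- rbindlist(lapply(als, `[[`, "differences"))
    if (nrow(diffs) == 0L)
      return(data.table(tag = tg, variants = "", n_supporting_reads = n_reads,
        disqualified = FALSE, reason = NA_character_))
    tab <- diffs[, .(support = .N), by = .(position, ref, alt, kind)]
    tab[, covering := cov[position + 1L]]
    tab[, frac := support / covering]
    called <- tab[frac > majority]
    ambiguous <- nrow(tab[frac <= majority & frac >= ambiguous_min]) > 0L
    dq <- FALSE; reason <- NA_character_
    if (nrow(called) && any(called$kind == "insertion")) {
      dq <- TRUE; reason <- "insertion"
    } else if (nrow(called) && any(called$kind == "deletion_multi")) {
      dq <- TRUE; reason <- "multi_bp_deletion"
    } else if (ambiguous && nrow(called) == 0L) {
      dq <- TRUE; reason <- "ambiguous"
    } else if (ambiguous) {
      dq <- TRUE; reason <- "ambiguous"
    }
    setorder(called, position)
    data.table(tag = tg,
      variants = paste(format_variant_tokens(called$position, called$ref,
                                             called$alt), collapse = ","),
      n_supporting_reads = n_reads, disqualified = dq, reason = reason)
  })
  rbindlist(rows)
}

#' Summarise a tag assignment against its element
#'
#' Reports the fraction of the `3L` possible SNVs and `L` 1-bp deletions
#' represented by at least one (non-disqualified) tag, the tags-per-variant
#' distribution, the wild-type tag fraction, and mean variants per tag.
#'
#' @param assignment assignment `data.table`.
#' @param element target element (or sequence string).
#' @return list of summary statistics.
#' @export
assignment_stats <- function(assignment, element) {
  if (nrow(assignment) == 0L) stop("empty assignment")
  ref <- if (is.list(element)) element$sequence else element
  L <- nchar(ref)
  ok <- assignment[!disqualified | is.na(disqualified)]
  vars <- parse_variant_tokens(ok$variants)
  snv <- vars[vclass %in% c("transition", "transversion")]
  del <- vars[vclass == "deletion_1bp"]
  tags_per_variant <- vars[, .(n_tags = .N), by = .(position, ref, alt)]
  list(
    snv_coverage = length(unique(paste(snv$position, snv$alt))) / (3L * L),
    deletion_coverage = length(unique(del$position)) / L,
    tags_per_variant = tags_per_variant[],
    wildtype_fraction = mean(!nzchar(ok$variants)),
    mean_variants_per_tag = nrow(vars) / nrow(ok),
    n_tags = nrow(assignment),
    n_disqualified = sum(assignment$disqualified, na.rm = TRUE))
}
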