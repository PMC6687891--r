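#' Parse tag/UMI sequencing reads with the standard exclusion filters
#'
#' Tag or UMI reads containing unresolved bases (N) or not matching the
#' designed length are excluded. When a reverse tag read is supplied, the
#' pair is consensus-merged: the reverse read must be the exact reverse
#' complement of the forward tag, otherwise the pair is dropped. Filters are
#' applied in a fixed order (tag length, tag N, pair agreement, UMI length,
#' UMI N) and each dropped record is tallied under the first filter it
#' fails, so tallies plus passed records conserve the input count.
#'
#' @param tag_fwd character vector of forward tag reads, or a FASTQ path.
#' @param umi character vector of UMI reads, or a FASTQ path.
#' @param tag_rev optional reverse tag reads (or FASTQ path), expected to be
#'   the reverse complement of the forward tag.
#' @param tag_length,umi_length designed lengths (tags 15 or 20, UMIs 10).
#' @return list with `records` (`data.table`: tag, umi) and `report`
#'   (named tallies).
#' @export
parse_tag_umi_reads <- function(tag_fwd, umi, tag_rev = NULL,
                                tag_length = 15L, umi_length = 10L) {
  tag_fwd <- as_sequences(tag_fwd)
  umi <- as_sequences(umi)
  if (!is.null(tag_rev)) tag_rev <- as_sequences(tag_rev)
  n <- length(tag_fwd)
  if (length(umi) != n || (!is.null(tag_rev) && length(tag_rev) != n))
    stop("tag, UMI (and reverse tag) inputs must have equal record counts")
  state <- rep("pass", n)
  mark <- function(state, bad, label) {
    ifelse(state == "pass" & bad, label, state)
  }
  state <- mark(state, nchar(tag_fwd) != tag_length, "tag_length")
  state <- mark(state, grepl("N", tag_fwd, fixed = TRUE), "tag_N")
  if (!is.null(tag_rev)) {
    rc_ok <- revcomp(tag_rev) == tag_fwd
    state <- mark(state, !rc_ok, "pair_mismatch")
  }
  state <- mark(state, nchar(umi) != umi_length, "umi_length")
  state <- mark(state, grepl("N", umi, fixed = TRUE), "umi_N")
  keep <- state == "pass"
  report <- list(n_input = n, n_pass = sum(keep),
    tag_length = sum(state == "tag_length"),
    tag_N = sum(state == "tag_N"),
    pair_mismatch = sum(state == "pair_mismatch"),
    umi_length = sum(state == "umi_length"),
    umi_N = sum(state == "umi_N"))
  list(records = data.table(tag = tag_fwd[keep], umi = umi[keep]),
       report = report)
}

as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fastq_sequences(x))
  }
  as.character(x)
}

#' UMI-deduplicate records and keep only assigned tags
#'
#' Each tag x UMI pair is counted only once; the per-tag count is the number
#' of distinct UMIs. Tags absent from the assignment are dropped and
#' tallied.
#'
#' @param records `data.table` with columns `tag`, `umi`.
#' @param assignment assignment `data.table` (column `tag`), or `NULL` to
#'   skip assignment matching.
#' @return list with `counts` (`data.table`: tag, count) and
#'   `n_unassigned_records`.
#' @export
dedup_and_match <- function(records, assignment = NULL) {
  records <- as.data.table(records)
  n_unassigned <- 0L
  if (!is.null(assignment)) {
    keep <- records$tag %in% assignment$tag
    n_unassigned <- sum(!keep)
    records <- records[keep]
  }
  dedup <- unique(records, by = c("tag", "umi"))
  counts <- dedup[, .(count = .N), by = tag]
  setorder(counts, tag)
  list(counts = counts[], n_unassigned_records = n_unassigned)
}

#' Join RNA and DNA tag counts within replicates
#'
#' A row is emitted iff the tag was observed in both the RNA and the DNA of
#' the same experimental replicate; one-sided tags are tallied.
#'
#' @param rna,dna `data.table`s with columns `replicate`, `tag`, `count`.
#' @return list with `counts` (`data.table`: replicate, tag, dna_count,
#'   rna_count) and a `report` of RNA-only / DNA-only tag counts.
#' @export
join_rna_dna <- function(rna, dna) {
  rna <- as.data.table(rna); dna <- as.data.table(dna)
  for (x in list(rna, dna))
    if (!all(c("replicate", "tag", "count") %in% names(x)))
      stop("inputs need columns replicate, tag, count")
  if (nrow(rna) && nrow(dna) &&
      !any(unique(rna$replicate) %in% unique(dna$replicate)))
    warning("no shared replicate labels between RNA and DNA inputs")
  m <- merge(dna, rna, by = c("replicate", "tag"),
             suffixes = c("_dna", "_rna"))
  counts <- m[, .(replicate, tag, dna_count = count_dna,
                  rna_count = count_rna)]
  setorder(counts, replicate, tag)
  list(counts = counts[],
    report = list(n_rna_only = nrow(rna) - nrow(counts),
                  n_dna_only = nrow(dna) - nrow(counts)))
}

#' Count a stream of replicate/source-labelled records into a CountTable
#'
#' Convenience wrapper chaining [dedup_and_match()] per (source, replicate)
#' and [join_rna_dna()].
#'
#' @param records `data.table` with columns `source` ("RNA"/"DNA"),
#'   `replicate`, `tag`, `umi`.
#' @param assignment assignment `data.table`, or `NULL`.
#' @param tag_length,umi_length designed lengths for the record filters.
#' @return list with `counts` and `report` (filter plus join tallies).
#' @export
tally_counts <- function(records, assignment = NULL, tag_length = 15L,
                         umi_length = 10L) {
  records <- as.data.table(records)
  per <- records[, {
    parsed <- parse_tag_umi_reads(tag, umi, tag_length = tag_length,
                                  umi_length = umi_length)
    dm <- dedup_and_match(parsed$records, assignment)
    cbind(dm$counts,
          n_unassigned = dm$n_unassigned_records,
          n_filtered = parsed$report$n_input - parsed$report$n_pass)
  }, by = .(source, replicate)]
  rna <- per[source == "RNA", .(replicate, tag, count)]
  dna <- per[source == "DNA", .(replicate, tag, count)]
  j <- join_rna_dna(rna, dna)
  j$report$n_unassigned_records <- sum(unique(
    per[, .(source, replicate, n_unassigned)])$n_unassigned)
  j$report$n_filtered_records <- sum(unique(
    per[, .(source, replicate, n_filtered)])$n_filtered)
  j
}
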