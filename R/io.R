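# File dialects. Coordinates: 0-based half-open internally and in BED;
# 1-based in the effects TSV and the VCF-like export (each header says so).
# All text inputs may be gzip-compressed.

#' @noRd
read_fastq_sequences <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write sequences as FASTA or FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output path (`.gz` for compression).
#' @param format `"fasta"` or `"fastq"` (constant quality "I").
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  if (format == "fastq") {
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta",
                                compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Read an element FASTA
#' @param path FASTA path; the first record is used.
#' @return `satmut_element` list.
#' @export
read_element <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(element_id = names(x)[1L],
    sequence = as.character(x[[1L]]), element_type = "promoter",
    coordinate_origin = 0L), class = "satmut_element")
}

#' Write / read a tag assignment TSV
#'
#' Columns: tag, variants (comma-separated `pos:ref>alt` tokens, 0-based,
#' empty for wild type), n_supporting_reads, disqualified, reason.
#'
#' @param assignment assignment `data.table`.
#' @param path TSV path.
#' @return the path (write) or the assignment `data.table` (read).
#' @export
write_assignment <- function(assignment, path) {
  fwrite(assignment, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  a <- fread(path, sep = "\t", colClasses = list(
    character = c("tag", "variants", "reason")))
  a[is.na(variants), variants := ""]
  need <- c("tag", "variants", "n_supporting_reads", "disqualified", "reason")
  if (!all(need %in% names(a)))
    stop("assignment file ", path, " lacks columns: ",
         paste(setdiff(need, names(a)), collapse = ", "))
  # enforce the non-overlap invariant with a line number on failure
  for (i in which(nzchar(a$variants))) {
    v <- parse_variant_tokens(a$variants[i])
    pos <- v[vclass != "insertion", position]
    if (anyDuplicated(pos))
      stop("assignment file ", path, ", line ", i + 1L,
           ": overlapping variant tokens in field 'variants'")
  }
  a[]
}

#' Write / read a CountTable TSV
#'
#' Columns: replicate, tag, dna_count, rna_count.
#' @param counts CountTable.
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  fwrite(counts, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- fread(path, sep = "\t")
  need <- c("replicate", "tag", "dna_count", "rna_count")
  if (!all(need %in% names(x)))
    stop("count file ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x[]
}

#' Write / read a fitted-effects TSV (positions 1-based on disk)
#'
#' Columns: element, position (1-based), ref, alt, log2_effect, se,
#' p_value, ci_low, ci_high, n_tags.
#'
#' @param estimates estimates table (0-based `position` internally).
#' @param path TSV path.
#' @param element_id element identifier stamped into the file.
#' @export
write_effects <- function(estimates, path, element_id = "element1") {
  out <- as.data.table(estimates)[, .(element = element_id,
    position = position + 1L, ref, alt, log2_effect, se, p_value,
    ci_low, ci_high, n_tags)]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  x <- fread(path, sep = "\t")
  x[, position := position - 1L]
  x[, token := format_variant_tokens(position, ref, alt)]
  x[, vclass := variant_class(ref, alt)]
  x[]
}

#' Export fitted effects as a VCF-like file (1-based positions)
#'
#' Minimal VCF-style text: CHROM = element id, POS 1-based, REF/ALT
#' alleles (`-` for the empty allele), INFO holds EFFECT, SE, P and NTAGS.
#' @inheritParams write_effects
#' @export
write_effects_vcf <- function(estimates, path, element_id = "element1") {
  est <- as.data.table(estimates)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2-like",
    "##coordinates=1-based",
    paste0("##INFO=<ID=EFFECT,Type=Float,Description=",
           "\"log2 expression effect\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(est)) {
    writeLines(paste(element_id, est$position + 1L, ".", est$ref, est$alt,
      ".", "PASS",
      sprintf("EFFECT=%.6g;SE=%.6g;P=%.6g;NTAGS=%d", est$log2_effect,
              est$se, est$p_value, est$n_tags), sep = "\t"), con)
  }
  invisible(path)
}

#' Write motif matches as BED (0-based half-open)
#'
#' Score column holds the length-normalized match score.
#' @param matches match table from [scan_pwm()].
#' @param path BED path.
#' @param element_id chromosome/element name.
#' @export
write_bed <- function(matches, path, element_id = "element1") {
  m <- as.data.table(matches)
  bed <- m[, .(chrom = element_id, start, end,
               name = motif_id, score = norm_score, strand)]
  fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a k-mer weight TSV (kmer <TAB> weight, no header)
#' @param path TSV path.
#' @param canonicalize see [kmer_weight_table()].
#' @export
read_kmer_weights <- function(path, canonicalize = TRUE) {
  x <- fread(path, sep = "\t", header = FALSE,
             col.names = c("kmer", "weight"))
  kmer_weight_table(x, canonicalize = canonicalize)
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts the standard JASPAR text dialect:
#' ```
#' >MA0001.1 FACTOR
#' A [ 1 2 3 ]
#' C [ 0 1 0 ]
#' ...
#' ```
#' @param path PFM text path.
#' @param ... passed to [pfm_to_pwm()].
#' @return named list of `satmut_pwm` objects.
#' @export
read_jaspar_pfm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR records in ", path)
  out <- list()
  for (s in seq_along(starts)) {
    i <- starts[s]
    hdr <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]]
    motif_id <- hdr[1L]
    factor <- if (length(hdr) > 1L) hdr[2L] else motif_id
    rows <- lines[(i + 1L):(i + 4L)]
    mat <- t(vapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("[0-9.]+", r))[[1]]
      as.numeric(nums)
    }, numeric(length(
      regmatches(rows[1L], gregexpr("[0-9.]+", rows[1L]))[[1]]))))
    base_order <- toupper(substr(trimws(rows), 1L, 1L))
    if (!setequal(base_order, BASES))
      stop("JASPAR record ", motif_id, " in ", path,
           " lacks A/C/G/T count rows")
    mat <- mat[match(BASES, base_order), , drop = FALSE]
    out[[motif_id]] <- pfm_to_pwm(mat, motif_id = motif_id,
                                  factor = factor, ...)
  }
  out
}

#' Write the synthetic truth table (per-variant true effects)
#' @param truth truth object from [simulate_element()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  fwrite(truth$effects, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Emits the element FASTA, assignment TSV, truth TSV, CountTable TSV and
#' (when read records were generated) per-replicate paired tag FASTQ
#' (read1 = forward tag, read2 = reverse complement) plus UMI FASTQ for RNA
#' and DNA.
#'
#' @param sim output of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    element = file.path(dir, "element.fa"),
    assignment = file.path(dir, "assignment.tsv"),
    truth = file.path(dir, "truth.tsv"),
    counts = file.path(dir, "counts.tsv"))
  write_sequences(setNames(sim$element$sequence, sim$element$element_id),
                  paths$element)
  write_assignment(sim$assignment, paths$assignment)
  write_truth(sim$truth, paths$truth)
  write_counts(sim$counts, paths$counts)
  if (!is.null(sim$records)) {
    recs <- as.data.table(sim$records)
    for (src in unique(recs$source)) for (r in unique(recs$replicate)) {
      sub <- recs[source == src & replicate == r]
      stem <- file.path(dir, paste0(tolower(src), "_rep", r))
      ids <- sprintf("%s_rep%d_%06d", tolower(src), r, seq_len(nrow(sub)))
      write_sequences(setNames(sub$tag, ids),
                      paste0(stem, "_tag1.fastq"), "fastq")
      write_sequences(setNames(revcomp(sub$tag), ids),
                      paste0(stem, "_tag2.fastq"), "fastq")
      write_sequences(setNames(sub$umi, ids),
                      paste0(stem, "_umi.fastq"), "fastq")
      paths[[paste0(tolower(src), "_rep", r)]] <- stem
    }
  }
  paths
}
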