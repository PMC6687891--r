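test_that("align_to_reference: identity, mismatch and deletion placement", {
  ref <- "ACGTACGT"
  id <- align_to_reference(ref, ref)
  expect_true(id$aligned)
  expect_equal(nrow(id$differences), 0L)
  expect_true(all(id$coverage))

  # single substitution, checked against exhaustive expectations on this toy
  mm <- align_to_reference("ACGAACGT", ref)
  expect_equal(mm$differences,
    data.table(position = 3L, ref = "T", alt = "A", kind = "snv"))

  # deletion in a repeat run reports the leftmost equivalent placement:
  # removing either C at positions 10/11 gives the same read; leftmost is 10
  ref_d <- "ACGTAGTCTTCCGGATCAGTTGCA"
  read_d <- paste0(substr(ref_d, 1, 10), substr(ref_d, 12, 24))
  del <- align_to_reference(read_d, ref_d)
  expect_equal(del$differences$kind, "deletion_1bp")
  expect_equal(del$differences$position, 10L)
  expect_equal(del$differences$ref, "C")

  # verify leftmost rule by enumerating all equivalent single-deletion
  # placements: every position whose removal reproduces the read
  ref2 <- "ACGTTGGGGTCAGATTGACA"
  read2 <- "ACGTTGGGTCAGATTGACA"
  equiv <- which(vapply(seq_len(nchar(ref2)), function(i)
    paste0(substr(ref2, 1, i - 1), substr(ref2, i + 1, nchar(ref2))) == read2,
    logical(1))) - 1L
  out <- align_to_reference(read2, ref2)
  expect_equal(out$differences$position, min(equiv))
})

test_that("align_to_reference rejects low-identity reads and over-long reads", {
  ref <- strrep("ACGT", 10)
  junk <- strrep("T", 40)
  out <- align_to_reference(junk, ref)
  expect_false(out$aligned)
  expect_error(align_to_reference(strrep("A", 100), ref, band = 10),
               "band")
})

test_that("partial reads report their covered interval", {
  ref <- "ACGTAGTCTTCCGGATCAGTTGCATTGCCAGTCAATCGAT"
  read <- substr(ref, 11, 25)  # unique placement in this reference
  out <- align_to_reference(read, ref)
  expect_true(out$aligned)
  expect_equal(out$ref_start, 10L)
  expect_equal(out$ref_end, 25L)
  expect_equal(sum(out$coverage), 15L)
})

test_that("call_tag_variants applies the coverage and majority rules", {
  ref <- "ACGTACGTACGTACGTACGT"
  mut <- paste0(substr(ref, 1, 10), "T", substr(ref, 12, 20))  # pos 10 G>T

  # 3 identical wild-type reads -> wild-type tag
  wt <- call_tag_variants(list(tagA = rep(ref, 3)), ref)
  expect_equal(wt$variants, "")
  expect_false(wt$disqualified)

  # 2 reads only -> disqualified low_coverage
  low <- call_tag_variants(list(tagB = rep(ref, 2)), ref)
  expect_true(low$disqualified)
  expect_equal(low$reason, "low_coverage")

  # 4 of 5 reads supporting pos 10 G>T -> called (majority oracle: 0.8 > 0.5)
  maj <- call_tag_variants(list(tagC = c(rep(mut, 4), ref)), ref)
  expect_equal(maj$variants, "10:G>T")
  expect_false(maj$disqualified)

  # 2 of 5 supporting -> no call, ambiguous flag (0.4 in the ambiguity zone)
  amb <- call_tag_variants(list(tagD = c(rep(mut, 2), rep(ref, 3))), ref)
  expect_equal(amb$variants, "")
  expect_true(amb$disqualified)
  expect_equal(amb$reason, "ambiguous")
})

test_that("calling is invariant to read order within a tag group", {
  ref <- "ACGTACGTACGTACGTACGT"
  mut <- paste0(substr(ref, 1, 5), "A", substr(ref, 7, 20))
  reads <- c(rep(mut, 4), ref)
  a <- call_tag_variants(list(t1 = reads), ref)
  b <- call_tag_variants(list(t1 = rev(reads)), ref)
  expect_identical(a, b)
})

test_that("multi-bp deletions and insertions disqualify the tag", {
  ref <- strrep("ACGTG", 8)
  del2 <- paste0(substr(ref, 1, 10), substr(ref, 13, 40))
  out <- call_tag_variants(list(t1 = rep(del2, 3)), ref)
  expect_true(out$disqualified)
  expect_equal(out$reason, "multi_bp_deletion")
  ins <- paste0(substr(ref, 1, 12), "T", substr(ref, 13, 40))
  out2 <- call_tag_variants(list(t2 = rep(ins, 3)), ref)
  expect_true(out2$disqualified)
  expect_equal(out2$reason, "insertion")
})

test_that("zero-error subassembly recovers generator haplotypes exactly", {
  cfg <- sim_config(element_length = 100L, n_tags = 60L, mutation_rate = 0.02,
                    wildtype_tag_fraction = 0,
                    spectrum = c(transition = 0.6, transversion_at = 0.1,
                                 transversion_other = 0.2, deletion_1bp = 0.1,
                                 insertion = 0),
                    seed = 31L)
  el <- simulate_element(cfg)$element
  asg <- mutagenize_library(el, cfg)
  reads <- lapply(asg$variants, function(v)
    rep(apply_haplotype(el$sequence, v), 3))
  names(reads) <- asg$tag
  called <- call_tag_variants(reads, el$sequence)
  called <- called[match(asg$tag, called$tag)]
  expect_false(any(called$disqualified))
  # an SNV adjacent to a deletion admits two score-equivalent alignments
  # (the read cannot distinguish them); require exact token recovery for
  # unambiguous haplotypes and identical implied sequences for all
  ambiguous_rep <- vapply(asg$variants, function(v) {
    if (!nzchar(v)) return(FALSE)
    p <- parse_variant_tokens(v)
    any(p$vclass == "deletion_1bp") && nrow(p) > 1L &&
      min(diff(sort(p$position))) <= 2L
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(called$variants[!ambiguous_rep],
               asg$variants[!ambiguous_rep])
  implied <- function(v) vapply(v, function(x)
    apply_haplotype(el$sequence, x), "", USE.NAMES = FALSE)
  expect_equal(implied(called$variants), implied(asg$variants))
})

test_that("assignment_stats enumerates SNV and deletion coverage", {
  el <- "ACGT"
  # tags covering only A>G at 0 and C>T at 1 -> SNV coverage 2/12
  asg <- data.table(tag = c("T1", "T2"), variants = c("0:A>G", "1:C>T"),
    n_supporting_reads = 3L, disqualified = FALSE, reason = NA_character_)
  st <- assignment_stats(asg, el)
  expect_equal(st$snv_coverage, 2 / 12)
  expect_equal(st$deletion_coverage, 0)
  expect_equal(st$wildtype_fraction, 0)

  # full single-coverage assignment -> SNV coverage 1
  all_snv <- parse_variant_tokens("")  # build every SNV token
  toks <- unlist(lapply(0:3, function(p) {
    b <- substr(el, p + 1, p + 1)
    paste0(p, ":", b, ">", setdiff(c("A", "C", "G", "T"), b))
  }))
  asg2 <- data.table(tag = sprintf("T%02d", seq_along(toks)),
    variants = toks, n_supporting_reads = 3L, disqualified = FALSE,
    reason = NA_character_)
  expect_equal(assignment_stats(asg2, el)$snv_coverage, 1)

  # all-wild-type assignment -> coverage 0, wild-type fraction 1
  asg3 <- data.table(tag = "T1", variants = "", n_supporting_reads = 3L,
                     disqualified = FALSE, reason = NA_character_)
  st3 <- assignment_stats(asg3, el)
  expect_equal(st3$snv_coverage, 0)
  expect_equal(st3$wildtype_fraction, 1)
})
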