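test_that("simulate_element plants effects exactly inside footprints", {
  cfg <- sim_config(element_length = 200L, n_footprints = 3L,
                    footprint_width = 12L, seed = 42L, n_tags = 100L)
  sim <- simulate_element(cfg)
  expect_equal(nchar(sim$element$sequence), 200L)
  expect_true(abs(gc_fraction(sim$element$sequence) - 0.5) <= 0.05)
  eff <- sim$truth$effects
  # all 3L SNVs + L deletions enumerated
  expect_equal(nrow(eff), 4L * 200L)
  expect_equal(sum(eff$vclass == "deletion_1bp"), 200L)
  # brute-force interval check: nonzero effect mass exactly at footprint
  # positions
  fp <- sim$truth$footprints
  fp_pos <- unlist(Map(function(s, e) s:(e - 1), fp$start, fp$end))
  expect_equal(nrow(fp), 3L)
  expect_equal(length(fp_pos), 36L)
  mass <- tapply(abs(eff$effect), eff$position, sum)
  expect_setequal(as.integer(names(mass)[mass > 0]), fp_pos)
  # repressing outnumber activating at the configured 37/63 split
  nz <- eff[effect != 0]
  expect_gt(sum(nz$effect < 0), sum(nz$effect > 0))
})

test_that("simulate_element: zero footprints give an inert element; seeded runs reproduce", {
  cfg <- sim_config(element_length = 150L, n_footprints = 0L, seed = 9L,
                    n_tags = 100L)
  sim <- simulate_element(cfg)
  expect_true(all(sim$truth$effects$effect == 0))
  cfg2 <- sim_config(element_length = 200L, gc_target = 0.5, seed = 123L,
                     n_tags = 100L)
  a <- simulate_element(cfg2)
  b <- simulate_element(cfg2)
  expect_identical(a$element$sequence, b$element$sequence)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("mutagenize_library matches its binomial and spectrum oracles", {
  cfg <- sim_config(element_length = 250L, n_tags = 100000L,
                    mutation_rate = 0.008, wildtype_tag_fraction = 0,
                    seed = 7L)
  el <- simulate_element(cfg)$element
  asg <- mutagenize_library(el, cfg)
  expect_equal(nrow(asg), 100000L)
  expect_false(anyDuplicated(asg$tag) > 0)
  v <- parse_variant_tokens(asg$variants)
  # empirical per-base mutation frequency within 3 binomial SDs of 0.008
  n_bases <- 100000 * 250
  p_hat <- nrow(v) / n_bases
  tol <- 3 * sqrt(0.008 * 0.992 / n_bases)
  expect_lt(abs(p_hat - 0.008), tol)
  # insertion-carrying tags disqualified, others not
  ins_idx <- unique(v[vclass == "insertion", idx])
  expect_true(all(asg$disqualified[ins_idx]))
  expect_true(all(asg$reason[ins_idx] == "insertion"))
  expect_false(any(asg$disqualified[setdiff(seq_len(nrow(asg)), ins_idx)]))
})

test_that("mutagenize_library: rate zero gives an all-wild-type library", {
  cfg <- sim_config(element_length = 120L, n_tags = 500L, mutation_rate = 0,
                    seed = 3L)
  el <- simulate_element(cfg)$element
  asg <- mutagenize_library(el, cfg)
  expect_true(all(asg$variants == ""))
  expect_false(any(asg$disqualified))
})

test_that("transition:transversion ratio follows 2:1 spectrum weights", {
  cfg <- sim_config(element_length = 250L, n_tags = 50000L,
                    mutation_rate = 0.01, wildtype_tag_fraction = 0,
                    spectrum = c(transition = 2, transversion_at = 0,
                                 transversion_other = 1, deletion_1bp = 0,
                                 insertion = 0),
                    seed = 21L)
  el <- simulate_element(cfg)$element
  asg <- mutagenize_library(el, cfg)
  v <- parse_variant_tokens(asg$variants)
  n_ts <- sum(v$vclass == "transition")
  n_tv <- sum(v$vclass == "transversion")
  n <- n_ts + n_tv
  # tally oracle: P(transition) = 2/3 per mutation
  expect_lt(abs(n_ts / n - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / n))
})

test_that("aggregate mutation spectrum matches configured weights (chi-square)", {
  spectrum <- c(transition = 0.55, transversion_at = 0.12,
                transversion_other = 0.18, deletion_1bp = 0.12,
                insertion = 0.03)
  cfg <- sim_config(element_length = 250L, n_tags = 50000L,
                    mutation_rate = 0.008, wildtype_tag_fraction = 0,
                    spectrum = spectrum, seed = 17L)
  el <- simulate_element(cfg)$element
  asg <- mutagenize_library(el, cfg)
  v <- parse_variant_tokens(asg$variants)
  # realized class of every mutation
  cls <- v$vclass
  at <- cls == "transversion" & v$ref %in% c("A", "T") &
    v$alt %in% c("A", "T")
  cls[at] <- "transversion_at"
  cls[cls == "transversion"] <- "transversion_other"
  observed <- table(factor(cls, levels = names(spectrum)))
  # oracle: expected class probabilities given each mutated base
  # (transversion_at unavailable at C/G, weights renormalised)
  base <- v$ref
  base[v$vclass == "insertion"] <-
    substr(el$sequence, v$position[v$vclass == "insertion"] + 1L,
           v$position[v$vclass == "insertion"] + 1L)
  is_at <- base %in% c("A", "T")
  w_at <- spectrum / sum(spectrum)
  w_cg <- spectrum; w_cg["transversion_at"] <- 0
  w_cg <- w_cg / sum(w_cg)
  expected <- sum(is_at) * w_at + sum(!is_at) * w_cg
  chisq <- sum((as.numeric(observed) - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = length(spectrum) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("simulate_counts: noiseless zero-effect library has RNA == DNA", {
  cfg <- sim_config(element_length = 120L, n_tags = 400L, rna_noise_sd = 0,
                    n_footprints = 0L, seed = 5L)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$counts$rna_count == sim$counts$dna_count))
})

test_that("simulate_counts: planted +1 effect doubles the RNA/DNA ratio", {
  # closed-form ratio check on a hand-built truth
  seq <- strrep("ACGT", 30)
  truth <- list(effects = data.table(position = 5L, ref = "C", alt = "T",
                                     vclass = "transition", effect = 1.0))
  assignment <- data.table(tag = c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"),
    variants = c("", "5:C>T"), n_supporting_reads = 3L,
    disqualified = FALSE, reason = NA_character_)
  cfg <- sim_config(element_length = 120L, n_tags = 2L, rna_noise_sd = 0,
                    count_rounding = "none", n_replicates = 1L, seed = 2L)
  cnt <- simulate_counts(assignment, truth, cfg)$counts
  wt_ratio <- cnt[tag == "AAAAAAAAAAAAAAA", rna_count / dna_count]
  mut_ratio <- cnt[tag == "CCCCCCCCCCCCCCC", rna_count / dna_count]
  expect_equal(mut_ratio / wt_ratio, 2, tolerance = 1e-12)
})

test_that("corrupted-record fraction matches its binomial oracle", {
  cfg <- sim_config(element_length = 120L, n_tags = 400L,
                    corrupt_fraction = 0.05, dna_meanlog = log(8),
                    seed = 13L)
  sim <- simulate_experiment(cfg, level = "reads")
  recs <- sim$records
  parsed <- parse_tag_umi_reads(recs$tag, recs$umi, tag_length = 15L,
                                umi_length = 10L)
  frac_fail <- 1 - parsed$report$n_pass / parsed$report$n_input
  n <- nrow(recs)
  expect_lt(abs(frac_fail - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # every corrupted record fails a filter; no clean record does
  expect_equal(parsed$report$n_input - parsed$report$n_pass,
               sum(recs$corrupted))
})

test_that("seeded simulation is bit-reproducible end to end", {
  cfg <- sim_config(element_length = 150L, n_tags = 800L, seed = 77L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$counts, b$counts)
})
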