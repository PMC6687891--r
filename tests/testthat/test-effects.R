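test_that("build_design lays out DNA, intercept and variant columns", {
  fx <- toy_count_fixture()
  d <- build_design(fx$counts, fx$assignment)
  ci <- d$col_info
  expect_equal(sum(ci$type == "intercept"), 1L)
  expect_equal(sum(ci$type == "dna"), 2L)  # two replicates present
  expect_equal(sum(ci$type == "variant"), 1L)
  # constructed fixture: variant on tags 4-6 -> indicator (0,0,0,1,1,1) per
  # replicate block
  vcol <- as.numeric(d$X[, which(ci$type == "variant")])
  expect_equal(vcol, rep(c(0, 0, 0, 1, 1, 1), 2))
  # DNA columns orthogonal across replicates by construction
  dna <- as.matrix(d$X[, which(ci$type == "dna")])
  expect_equal(sum(dna[, 1] * dna[, 2]), 0)
  # all-wild-type library -> zero variant columns
  wt <- copy(fx$assignment)[, variants := ""]
  d0 <- build_design(fx$counts, wt)
  expect_equal(sum(d0$col_info$type == "variant"), 0L)
})

test_that("disqualified tags contribute no rows to the design", {
  fx <- toy_count_fixture()
  fx$assignment[tag == "TAG04", `:=`(disqualified = TRUE,
                                     reason = "insertion")]
  d <- build_design(fx$counts, fx$assignment)
  expect_false("TAG04" %in% d$row_info$tag)
  expect_equal(nrow(d$row_info), 10L)
})

test_that("fit_effects matches the independent least-squares oracle", {
  fx <- toy_count_fixture()
  d <- build_design(fx$counts, fx$assignment)
  f <- fit_effects(d)
  beta_oracle <- ols_oracle(d$X, d$y)
  vcol <- which(d$col_info$type == "variant")
  expect_equal(f$estimates$log2_effect, unname(beta_oracle[vcol]),
               tolerance = 1e-10)
  # the toy doubles RNA for variant tags: fitted effect exactly 1
  expect_equal(f$estimates$log2_effect, 1, tolerance = 1e-10)
  expect_equal(unname(f$diagnostics$dna_slopes), c(1, 1), tolerance = 1e-10)
  # support counted as rows and as distinct tags
  expect_equal(f$estimates$n_tags, 6L)
  expect_equal(f$estimates$n_distinct_tags, 3L)
})

test_that("coefficients, SEs, p-values and CIs match the lm() oracle", {
  cfg <- sim_config(element_length = 100L, n_tags = 400L, seed = 26L)
  sim <- simulate_experiment(cfg)
  d <- build_design(sim$counts, sim$assignment)
  f <- fit_effects(d)
  # drop any columns the fitter flagged aliased so lm() sees the same system
  keep_cols <- which(!(d$col_info$token %in% f$diagnostics$aliased))
  Xd <- as.matrix(d$X[, keep_cols])
  lmfit <- stats::lm(d$y ~ Xd - 1)
  sm <- summary(lmfit)$coefficients
  vcol <- which(d$col_info$type[keep_cols] == "variant")
  expect_equal(f$estimates$log2_effect, unname(sm[vcol, 1]),
               tolerance = 1e-8)
  expect_equal(f$estimates$se, unname(sm[vcol, 2]), tolerance = 1e-8)
  expect_equal(f$estimates$p_value, unname(sm[vcol, 4]), tolerance = 1e-8)
  ci <- stats::confint(lmfit, level = 0.95)
  expect_equal(f$estimates$ci_low, unname(ci[vcol, 1]), tolerance = 1e-6)
  expect_equal(f$estimates$ci_high, unname(ci[vcol, 2]), tolerance = 1e-6)
})

test_that("fit_effects drops aliased columns and keeps earlier ones", {
  fx <- toy_count_fixture()
  # variant present on every tag duplicates the intercept
  fx$assignment[, variants := "5:A>G"]
  d <- build_design(fx$counts, fx$assignment)
  f <- fit_effects(d)
  expect_equal(f$diagnostics$aliased, "5:A>G")
  expect_equal(nrow(f$estimates), 0L)
  expect_false(is.na(f$diagnostics$intercept))
})

test_that("estimates are invariant to row order", {
  cfg <- sim_config(element_length = 100L, n_tags = 600L, seed = 4L)
  sim <- simulate_experiment(cfg)
  d <- build_design(sim$counts, sim$assignment)
  f1 <- fit_effects(d)
  set.seed(1)
  perm <- sample(nrow(d$X))
  d2 <- list(X = d$X[perm, ], y = d$y[perm], col_info = d$col_info,
             row_info = d$row_info[perm])
  f2 <- fit_effects(d2)
  expect_equal(f1$estimates$log2_effect, f2$estimates$log2_effect,
               tolerance = 1e-12)
  expect_equal(f1$estimates$se, f2$estimates$se, tolerance = 1e-12)
})

test_that("combined model on a single replicate equals the single-replicate model", {
  cfg <- sim_config(element_length = 100L, n_tags = 500L,
                    n_replicates = 1L, seed = 8L)
  sim <- simulate_experiment(cfg)
  fc <- fit_effects(build_design(sim$counts, sim$assignment,
                                 mode = "combined"))
  fs <- fit_effects(build_design(sim$counts, sim$assignment,
                                 mode = "single_replicate"))
  expect_equal(fc$estimates$log2_effect, fs$estimates$log2_effect,
               tolerance = 1e-12)
  expect_equal(fc$estimates$p_value, fs$estimates$p_value,
               tolerance = 1e-12)
})

test_that("filter_min_tags removes low-support variants without refitting", {
  est <- data.table(token = c("a", "b", "c"), position = 1:3,
    ref = "A", alt = "G", log2_effect = 0.1, se = 0.01, p_value = 0.5,
    ci_low = 0, ci_high = 0.2, vclass = "transition",
    n_tags = c(9L, 10L, 30L), n_distinct_tags = c(3L, 4L, 10L))
  expect_equal(filter_min_tags(est, 10L)$token, c("b", "c"))
  expect_equal(nrow(filter_min_tags(est, 1L)), 3L)
  expect_equal(filter_min_tags(est, 10L, "distinct_tags")$token, "c")
  # counting oracle on a simulated support distribution
  cfg <- sim_config(element_length = 100L, n_tags = 800L, seed = 14L)
  sim <- simulate_experiment(cfg)
  f <- fit_effects(build_design(sim$counts, sim$assignment))
  kept <- filter_min_tags(f$estimates, 10L)
  expect_equal(nrow(kept), sum(f$estimates$n_tags >= 10L))
})

test_that("significance_report classifies with alpha and fold gates", {
  est <- data.table(
    token = c("t1", "t2", "t3", "t4"), position = 1:4, ref = "A",
    alt = "G", vclass = "transition",
    log2_effect = c(0.5, -1.2, 0.3, 2.0),
    se = 0.05, ci_low = 0, ci_high = 0,
    p_value = c(1e-7, 1e-9, 0.5, 1e-12),
    n_tags = 20L, n_distinct_tags = 10L)
  plain <- significance_report(est, alpha = 1e-5)
  expect_equal(plain$estimates$class,
               c("activating", "repressing", "nonsignificant", "activating"))
  gated <- significance_report(est, alpha = 1e-5, fold_threshold = 2)
  # 0.5 < log2(2): t1 drops to nonsignificant under the two-fold gate
  expect_equal(gated$estimates$class,
               c("nonsignificant", "repressing", "nonsignificant",
                 "activating"))
  # tally oracle on constructed (effect, p) pairs
  set.seed(2)
  big <- data.table(token = as.character(1:500), position = 1:500,
    ref = "A", alt = "G", vclass = "transition",
    log2_effect = rnorm(500), se = 0.1, ci_low = 0, ci_high = 0,
    p_value = 10^-runif(500, 0, 10), n_tags = 20L, n_distinct_tags = 10L)
  rep_ <- significance_report(big, alpha = 1e-5)
  expect_equal(sum(rep_$estimates$class == "activating"),
               sum(big$p_value < 1e-5 & big$log2_effect > 0))
  expect_equal(sum(rep_$estimates$class == "repressing"),
               sum(big$p_value < 1e-5 & big$log2_effect < 0))
})

test_that("compare_conditions flags exactly the non-overlapping intervals", {
  mk <- function(tok, lo, hi) data.table(token = tok,
    position = seq_along(tok), ref = "A", alt = "G",
    log2_effect = (lo + hi) / 2, se = 0.1, p_value = 0.01,
    ci_low = lo, ci_high = hi, vclass = "transition", n_tags = 20L,
    n_distinct_tags = 10L)
  a <- mk(c("v1", "v2"), c(0.2, 0.2), c(0.6, 0.8))
  b <- mk(c("v1", "v2"), c(0.7, 0.7), c(1.1, 1.1))
  out <- compare_conditions(a, b)
  expect_equal(out[token == "v1", different], TRUE)
  expect_equal(out[token == "v1", direction], "b_higher")
  expect_equal(out[token == "v2", different], FALSE)
  # brute-force interval oracle on random CI pairs
  set.seed(3)
  n <- 200
  lo_a <- runif(n); hi_a <- lo_a + runif(n)
  lo_b <- runif(n); hi_b <- lo_b + runif(n)
  toks <- sprintf("t%03d", 1:n)
  out2 <- compare_conditions(mk(toks, lo_a, hi_a), mk(toks, lo_b, hi_b))
  setorder(out2, position)
  oracle <- vapply(1:n, function(i)
    !(lo_a[i] <= hi_b[i] && lo_b[i] <= hi_a[i]), logical(1))
  expect_equal(out2$different, oracle)
})
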