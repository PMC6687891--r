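#' Configuration for a synthetic saturation-mutagenesis MPRA experiment
#'
#' Defaults describe the experimental regime the analysis is designed for:
#' error-prone PCR at a frequency below 1 change per 100 bp with a
#' transition-biased spectrum and rare insertions, libraries of 50k or more
#' distinct 15-bp tags, 10-bp UMIs, and three transfection replicates.
#' Planted effects cluster into TFBS-like footprints, with repressive
#' variants outnumbering activating ones 63:37.
#'
#' @param element_length element length in bp (targets span roughly 187-601).
#' @param gc_target target GC fraction of the element.
#' @param mutation_rate per-base mutation probability (default 0.008, i.e.
#'   under 1 change per 100 bp).
#' @param spectrum named nonnegative weights for mutation classes
#'   `transition`, `transversion_at` (A<->T exchanges, the common
#'   error-prone-PCR transversion), `transversion_other`, `deletion_1bp`,
#'   `insertion`. Classes not available at a base (e.g. `transversion_at` at
#'   C/G) are renormalised away.
#' @param n_tags number of distinct tags to generate.
#' @param tag_length tag length, 15 or 20.
#' @param umi_length UMI length (default 10).
#' @param n_replicates number of transfection replicates (default 3).
#' @param wildtype_tag_fraction fraction of tags forced wild-type on top of
#'   the Binomial zero-mutation class.
#' @param dna_meanlog,dna_dispersion log-normal DNA abundance model per tag
#'   (meanlog / sdlog); heavy-tailed tag representation of cloned libraries.
#' @param replicate_dispersion sdlog of per-replicate resampling around the
#'   shared tag abundance.
#' @param rna_noise_sd multiplicative RNA noise, sd on the log2 scale.
#' @param n_footprints,footprint_width TFBS-like effect footprints: number
#'   and width (bp) of intervals carrying nonzero effects.
#' @param activating_fraction probability a footprint variant activates
#'   rather than represses (default 0.37).
#' @param effect_shape,effect_scale_activating,effect_scale_repressing gamma
#'   parameters for |log2 effect| magnitudes inside footprints.
#' @param inert_fraction fraction of footprint positions whose variants all
#'   have zero effect.
#' @param deletion_effect_multiplier multiplier on 1-bp deletion magnitudes
#'   (deletions tend to have larger absolute effects than SNVs).
#' @param corrupt_fraction fraction of emitted read records corrupted (N
#'   bases / wrong lengths) to exercise the counting filters.
#' @param reads_per_molecule duplicate read multiplicity per UMI molecule.
#' @param count_rounding `"round"` (integer molecule counts, the default) or
#'   `"none"` (real-valued counts; diagnostic mode in which the noiseless
#'   pipeline identity is exact).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated `satmut_config` list.
#' @export
sim_config <- function(element_length = 250L,
                       gc_target = 0.5,
                       mutation_rate = 0.008,
                       spectrum = c(transition = 0.55, transversion_at = 0.12,
                                    transversion_other = 0.18,
                                    deletion_1bp = 0.12, insertion = 0.03),
                       n_tags = 50000L,
                       tag_length = 15L,
                       umi_length = 10L,
                       n_replicates = 3L,
                       wildtype_tag_fraction = 0.05,
                       dna_meanlog = log(20),
                       dna_dispersion = 1.0,
                       replicate_dispersion = 0.25,
                       rna_noise_sd = 0.3,
                       n_footprints = 3L,
                       footprint_width = 12L,
                       activating_fraction = 0.37,
                       effect_shape = 2,
                       effect_scale_activating = 0.16,
                       effect_scale_repressing = 0.24,
                       inert_fraction = 0,
                       deletion_effect_multiplier = 1.5,
                       corrupt_fraction = 0,
                       reads_per_molecule = 2L,
                       count_rounding = c("round", "none"),
                       seed = 1L) {
  count_rounding <- match.arg(count_rounding)
  cfg <- list(element_length = as.integer(element_length),
    gc_target = gc_target, mutation_rate = mutation_rate,
    spectrum = spectrum, n_tags = as.integer(n_tags),
    tag_length = as.integer(tag_length), umi_length = as.integer(umi_length),
    n_replicates = as.integer(n_replicates),
    wildtype_tag_fraction = wildtype_tag_fraction,
    dna_meanlog = dna_meanlog, dna_dispersion = dna_dispersion,
    replicate_dispersion = replicate_dispersion, rna_noise_sd = rna_noise_sd,
    n_footprints = as.integer(n_footprints),
    footprint_width = as.integer(footprint_width),
    activating_fraction = activating_fraction, effect_shape = effect_shape,
    effect_scale_activating = effect_scale_activating,
    effect_scale_repressing = effect_scale_repressing,
    inert_fraction = inert_fraction,
    deletion_effect_multiplier = deletion_effect_multiplier,
    corrupt_fraction = corrupt_fraction,
    reads_per_molecule = as.integer(reads_per_molecule),
    count_rounding = count_rounding, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "satmut_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$element_length < 100L || cfg$element_length > 601L)
    stop("element_length must be in [100, 601]")
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1)
    stop("gc_target must be in (0, 1)")
  rates <- c(cfg$mutation_rate, cfg$wildtype_tag_fraction,
             cfg$inert_fraction, cfg$corrupt_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  need <- c("transition", "transversion_at", "transversion_other",
            "deletion_1bp", "insertion")
  if (!all(need %in% names(cfg$spectrum)) || any(cfg$spectrum < 0))
    stop("spectrum must be nonnegative weights named ",
         paste(need, collapse = ", "))
  if (!cfg$tag_length %in% c(15L, 20L))
    stop("tag_length must be 15 or 20")
  if (cfg$n_footprints > 0 &&
      cfg$n_footprints * cfg$footprint_width > cfg$element_length)
    stop("footprints do not fit in the element")
  invisible(cfg)
}

#' Simulate a target element and its planted effect architecture
#'
#' Draws a random element of the configured length and GC content, places
#' `n_footprints` non-overlapping footprints, and assigns a true log2 effect
#' to each of the `3L` possible SNVs and `L` 1-bp deletions: zero outside
#' footprints; inside, a gamma-distributed magnitude with repressive sign in
#' proportion `1 - activating_fraction`.
#'
#' @param config a [sim_config()].
#' @param element_id element identifier.
#' @return list with `element` (fields `element_id`, `sequence`,
#'   `element_type`, `coordinate_origin`) and `truth` (fields `effects` --
#'   a `data.table` of all possible variants with their true effects --
#'   `footprints`, and `config`).
#' @export
simulate_element <- function(config, element_id = "element1") {
  validate_config(config)
  set.seed(config$seed)
  L <- config$element_length
  seq <- random_dna(1L, L, config$gc_target)
  if (abs(gc_fraction(seq) - config$gc_target) > 0.05) {
    # resample a bounded number of times to respect the +-5% GC tolerance
    for (i in 1:50) {
      seq <- random_dna(1L, L, config$gc_target)
      if (abs(gc_fraction(seq) - config$gc_target) <= 0.05) break
    }
  }
  fp <- place_footprints(L, config$n_footprints, config$footprint_width)
  bases <- strsplit(seq, NULL)[[1]]
  # enumerate all 3L SNVs + L deletions
  snv <- data.table(position = rep(0:(L - 1L), each = 3L),
    ref = rep(bases, each = 3L))
  snv[, alt := unlist(lapply(bases, function(b) setdiff(BASES, b)))]
  del <- data.table(position = 0:(L - 1L), ref = bases, alt = "-")
  eff <- rbindlist(list(snv, del))
  eff[, vclass := variant_class(ref, alt)]
  setorder(eff, position)
  eff[, in_footprint := position %in% fp$positions]
  inert_pos <- integer(0)
  if (config$inert_fraction > 0 && length(fp$positions)) {
    n_inert <- floor(config$inert_fraction * length(fp$positions))
    inert_pos <- sample(fp$positions, n_inert)
  }
  eff[, effect := 0]
  live <- eff$in_footprint & !(eff$position %in% inert_pos)
  n_live <- sum(live)
  if (n_live > 0) {
    act <- runif(n_live) < config$activating_fraction
    mag <- ifelse(act,
      rgamma(n_live, shape = config$effect_shape,
             scale = config$effect_scale_activating),
      rgamma(n_live, shape = config$effect_shape,
             scale = config$effect_scale_repressing))
    e <- ifelse(act, mag, -mag)
    isdel <- eff$vclass[live] == "deletion_1bp"
    e[isdel] <- e[isdel] * config$deletion_effect_multiplier
    eff[live, effect := e]
  }
  eff[, in_footprint := NULL]
  element <- list(element_id = element_id, sequence = seq,
    element_type = "promoter", coordinate_origin = 0L)
  class(element) <- "satmut_element"
  truth <- list(effects = eff[], footprints = fp$intervals, config = config)
  list(element = element, truth = truth)
}

place_footprints <- function(L, n, width) {
  if (n == 0L) {
    return(list(intervals = data.table(start = integer(), end = integer()),
                positions = integer(0)))
  }
  for (attempt in 1:200) {
    starts <- sort(sample(0:(L - width), n))
    if (n == 1L || all(diff(starts) >= width)) {
      iv <- data.table(start = starts, end = starts + width)
      pos <- unlist(Map(function(s, e) s:(e - 1L), iv$start, iv$end))
      return(list(intervals = iv, positions = as.integer(pos)))
    }
  }
  stop("could not place non-overlapping footprints; reduce n or width")
}

#' Mutagenize a tagged library
#'
#' Emulates error-prone PCR over the element: each tag receives a
#' Binomial(L, rate) number of mutations at distinct positions, with classes
#' drawn from the configured spectrum (transitions preferred; A<->T the
#' common transversion; 1-bp deletions at similar rates; insertions rare).
#' Tags carrying an insertion are flagged disqualified, as are any multi-bp
#' deletions (not generated here, but honoured by the flagging rule).
#'
#' @param element element from [simulate_element()].
#' @param config a [sim_config()].
#' @return a tag assignment `data.table` with columns `tag`, `variants`
#'   (comma-separated `pos:ref>alt` tokens, `""` for wild-type),
#'   `n_supporting_reads` (NA for simulated truth), `disqualified`, `reason`.
#' @export
mutagenize_library <- function(element, config) {
  validate_config(config)
  set.seed(config$seed + 1L)
  L <- nchar(element$sequence)
  bases <- strsplit(element$sequence, NULL)[[1]]
  n <- config$n_tags
  tags <- generate_distinct_tags(n, config$tag_length)
  forced_wt <- rep(FALSE, n)
  n_wt <- round(config$wildtype_tag_fraction * n)
  if (n_wt > 0) forced_wt[sample(n, n_wt)] <- TRUE
  n_mut <- ifelse(forced_wt, 0L, rbinom(n, L, config$mutation_rate))
  total <- sum(n_mut)
  tokens <- character(n)
  dq <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  if (total > 0) {
    idx <- which(n_mut > 0)
    pos_list <- lapply(idx, function(i) sort(sample.int(L, n_mut[i]) - 1L))
    tag_of <- rep(idx, n_mut[idx])
    pos <- unlist(pos_list)
    b <- bases[pos + 1L]
    cls <- draw_mutation_class(b, config$spectrum)
    alt <- draw_alt_allele(b, cls)
    ref <- ifelse(cls == "insertion", "-", b)
    # canonicalise 1-bp deletions to their leftmost equivalent placement
    # (matching the caller's left-normalisation), unless the shift would
    # collide with another mutation on the same tag
    isdel <- which(cls == "deletion_1bp")
    for (d in isdel) {
      p <- pos[d]
      while (p > 0L && bases[p] == bases[p + 1L]) p <- p - 1L
      same_tag <- which(tag_of == tag_of[d])
      if (p != pos[d] && !(p %in% pos[same_tag])) {
        pos[d] <- p
        ref[d] <- bases[p + 1L]
      }
    }
    tok <- format_variant_tokens(pos, ref, alt)
    tokens_by_tag <- split(tok, tag_of)
    cls_by_tag <- split(cls, tag_of)
    pos_by_tag <- split(pos, tag_of)
    for (k in seq_along(tokens_by_tag)) {
      i <- idx[k]
      tokens[i] <- paste(tokens_by_tag[[k]][order(pos_by_tag[[k]])],
                         collapse = ",")
      if (any(cls_by_tag[[k]] == "insertion")) {
        dq[i] <- TRUE
        reason[i] <- "insertion"
      }
    }
  }
  data.table(tag = tags, variants = tokens,
    n_supporting_reads = NA_integer_, disqualified = dq, reason = reason)
}

generate_distinct_tags <- function(n, len, max_retries = 10L) {
  tags <- random_dna(n, len)
  for (r in seq_len(max_retries)) {
    d <- duplicated(tags)
    if (!any(d)) return(tags)
    tags[d] <- random_dna(sum(d), len)
  }
  stop("tag collision persisted after ", max_retries, " retries; ",
       "increase tag_length or reduce n_tags")
}

# class availability depends on the reference base: transversion_at (A<->T)
# exists only at A/T bases; weights for unavailable classes renormalise away
draw_mutation_class <- function(base, spectrum) {
  cls_names <- c("transition", "transversion_at", "transversion_other",
                 "deletion_1bp", "insertion")
  w <- matrix(rep(spectrum[cls_names], each = length(base)),
              nrow = length(base))
  w[!(base %in% c("A", "T")), 2L] <- 0
  w <- w / rowSums(w)
  cw <- t(apply(w, 1, cumsum))
  u <- runif(length(base))
  cls_names[max.col(cw >= u, ties.method = "first")]
}

draw_alt_allele <- function(base, cls) {
  alt <- character(length(base))
  ts <- cls == "transition"
  alt[ts] <- TRANSITION_OF[base[ts]]
  at <- cls == "transversion_at"
  alt[at] <- ifelse(base[at] == "A", "T", "A")
  ot <- cls == "transversion_other"
  if (any(ot)) {
    alt[ot] <- vapply(base[ot], function(b) {
      opts <- setdiff(BASES, c(b, TRANSITION_OF[b]))
      if (b %in% c("A", "T")) opts <- setdiff(opts, c("A", "T"))
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1))
  }
  alt[cls == "deletion_1bp"] <- "-"
  ins <- cls == "insertion"
  if (any(ins)) alt[ins] <- sample(BASES, sum(ins), replace = TRUE)
  alt
}

#' Simulate RNA/DNA counts (and optionally raw tag/UMI read records)
#'
#' Per-tag DNA abundance is log-normal (shared tag mean, per-replicate
#' resampling), rounded to an integer minimum 1. RNA counts follow the
#' generative inverse of the effect model:
#' `log2(RNA) = log2(DNA) + sum(effects) + Normal(0, rna_noise_sd)`.
#' With `level = "reads"` each molecule is expanded into
#' `reads_per_molecule` duplicate records carrying a distinct UMI, and a
#' configured fraction of records is corrupted (N bases, wrong lengths) to
#' exercise the counting filters.
#'
#' @param assignment tag assignment from [mutagenize_library()].
#' @param truth truth object from [simulate_element()].
#' @param config a [sim_config()].
#' @param level `"counts"` for the per-tag molecule-count table, `"reads"`
#'   to additionally emit raw tag/UMI records.
#' @return list with `counts` (`data.table`: replicate, tag, dna_count,
#'   rna_count), `tag_effects` (per-tag summed true effect), and, for
#'   `level = "reads"`, `records` (`data.table`: source, replicate, tag,
#'   umi, tag_true, corrupted).
#' @export
simulate_counts <- function(assignment, truth, config,
                            level = c("counts", "reads")) {
  level <- match.arg(level)
  validate_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(assignment)
  eff <- truth$effects
  key <- format_variant_tokens(eff$position, eff$ref, eff$alt)
  emap <- setNames(eff$effect, key)
  tag_effect <- vapply(assignment$variants, function(v) {
    if (!nzchar(v)) return(0)
    toks <- strsplit(v, ",", fixed = TRUE)[[1]]
    sum(emap[toks], na.rm = TRUE)  # insertions carry no planted effect
  }, numeric(1), USE.NAMES = FALSE)
  tag_mean <- rlnorm(n, config$dna_meanlog, config$dna_dispersion)
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    dna_lat <- rlnorm(n, log(tag_mean), config$replicate_dispersion)
    dna <- if (config$count_rounding == "round") pmax(1, round(dna_lat))
           else pmax(1, dna_lat)
    noise <- if (config$rna_noise_sd > 0)
      rnorm(n, 0, config$rna_noise_sd) else 0
    rna_lat <- dna * 2^(tag_effect + noise)
    rna <- if (config$count_rounding == "round") round(rna_lat) else rna_lat
    out[[r]] <- data.table(replicate = r, tag = assignment$tag,
      dna_count = dna, rna_count = rna)
  }
  counts <- rbindlist(out)
  counts <- counts[rna_count >= 1 & dna_count >= 1]
  res <- list(counts = counts[],
    tag_effects = data.table(tag = assignment$tag, true_effect = tag_effect))
  if (level == "reads") {
    if (config$count_rounding != "round")
      stop("read-level emission requires integer counts")
    res$records <- expand_read_records(counts, config)
  }
  res
}

expand_read_records <- function(counts, config) {
  long <- rbindlist(list(
    counts[, .(source = "DNA", replicate, tag, n = as.integer(dna_count))],
    counts[, .(source = "RNA", replicate, tag, n = as.integer(rna_count))]))
  total_mol <- sum(long$n)
  umis <- random_dna(total_mol, config$umi_length)
  mol <- long[rep(seq_len(.N), n)]
  mol[, umi := umis]
  # distinct UMIs within each (source, replicate, tag) group so that
  # UMI-deduplicated counts recover molecule counts exactly
  for (pass in 1:10) {
    dup <- duplicated(mol, by = c("source", "replicate", "tag", "umi"))
    if (!any(dup)) break
    mol[dup, umi := random_dna(sum(dup), config$umi_length)]
  }
  recs <- mol[rep(seq_len(.N), each = config$reads_per_molecule),
              .(source, replicate, tag_true = tag, umi)]
  recs[, tag := tag_true]
  recs[, corrupted := FALSE]
  if (config$corrupt_fraction > 0) {
    n_bad <- rbinom(1L, nrow(recs), config$corrupt_fraction)
    bad <- sample(nrow(recs), n_bad)
    mode <- sample(3L, n_bad, replace = TRUE)
    tagN <- bad[mode == 1L]
    recs[tagN, tag := paste0("N", substr(tag, 2L, nchar(tag)))]
    short <- bad[mode == 2L]
    recs[short, tag := substr(tag, 1L, nchar(tag) - 1L)]
    umiN <- bad[mode == 3L]
    recs[umiN, umi := paste0("N", substr(umi, 2L, nchar(umi)))]
    recs[bad, corrupted := TRUE]
  }
  recs[, .(source, replicate, tag, umi, tag_true, corrupted)]
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: element + effect architecture, mutagenized tagged
#' library, and per-replicate counts in one call.
#'
#' @inheritParams simulate_element
#' @param level passed to [simulate_counts()].
#' @return list with `element`, `truth`, `assignment`, `counts`,
#'   `tag_effects`, and optionally `records`.
#' @export
simulate_experiment <- function(config, element_id = "element1",
                                level = c("counts", "reads")) {
  level <- match.arg(level)
  sim <- simulate_element(config, element_id)
  assignment <- mutagenize_library(sim$element, config)
  cnt <- simulate_counts(assignment, sim$truth, config, level = level)
  c(list(element = sim$element, truth = sim$truth, assignment = assignment),
    cnt)
}
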