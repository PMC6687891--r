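#' Default pipeline configuration
#'
#' Stage parameters with their standard values: minimum per-position read
#' coverage 3 for assignment, minimum 10 tags per variant, significance
#' threshold 1e-5 on the coefficient p-value, 1000 shuffles for the
#' clustering test.
#'
#' @param ... overrides.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    outdir = "satmut_out",
    seed = 1L,
    sim = list(),            # sim_config() overrides
    min_coverage = 3L,
    tag_length = 15L,
    umi_length = 10L,
    min_tags = 10L,
    tag_count_mode = "rows",
    alpha = 1e-5,
    fold_threshold = NULL,
    n_shuffles = 1000L,
    mode = "combined")
  modifyList(cfg, list(...))
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the pipeline end to end on synthetic data
#'
#' simulate -> count -> fit -> stats, writing every artifact under
#' `config$outdir`, stamped with the configuration hash and seed. The
#' assignment stage can be bypassed with a supplied assignment table
#' (`skip_assignment`), which must give results identical to the full run
#' on the same data.
#'
#' @param config from [pipeline_config()].
#' @param assignment optional pre-computed assignment `data.table`
#'   (skip-assignment mode).
#' @return named list of artifacts (`sim`, `counts`, `fit`, `report`,
#'   `clustering`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config(), assignment = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scfg <- stage("simulate",
    do.call(sim_config, modifyList(list(seed = config$seed), config$sim)))
  sim <- stage("simulate", simulate_experiment(scfg))
  if (is.null(assignment)) assignment <- sim$assignment
  paths <- stage("write", write_simulation(sim, config$outdir))
  design <- stage("fit", build_design(sim$counts, assignment,
                                      mode = config$mode))
  fit <- stage("fit", fit_effects(design))
  kept <- stage("fit", filter_min_tags(fit$estimates, config$min_tags,
                                       config$tag_count_mode))
  rep_ <- stage("stats", significance_report(kept, alpha = config$alpha,
    fold_threshold = config$fold_threshold))
  clus <- stage("stats", clustering_test(ordered_track(rep_$estimates),
    n_shuffles = config$n_shuffles, seed = config$seed))
  paths$effects <- file.path(config$outdir, "effects.tsv")
  write_effects(rep_$estimates, paths$effects,
                element_id = sim$element$element_id)
  paths$report <- file.path(config$outdir, "report.json")
  stamp <- list(seed = config$seed,
    config_hash = config_hash(config),
    n_variants_fit = nrow(fit$estimates),
    n_variants_min_tags = nrow(kept),
    class_summary = rep_$summary,
    clustering_p = clus$p_value,
    diagnostics = fit$diagnostics[c("intercept", "dna_slopes", "sigma",
                                    "df", "n_rows")])
  jsonlite::write_json(stamp, paths$report, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(sim = sim, counts = sim$counts, fit = fit, report = rep_,
       clustering = clus, paths = paths)
}

config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251)) %% .Machine$integer.max
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `assign`, `count`, `fit`, `run`. Invoke from a
#' shell as
#' `Rscript -e 'satmut::satmut_cli()' <subcommand> --config cfg.json`.
#' Configuration files are JSON; `--seed` overrides the configured seed.
#'
#' @param args character vector of arguments (defaults to the command
#'   line).
#' @return exit status, invisibly.
#' @export
satmut_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: satmut <simulate|assign|count|fit|run> [--config cfg.json]",
            " [--seed N] [--out dir]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- parse_cli_flags(args[-1L])
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
         else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$outdir <- opt$out
  switch(cmd,
    simulate = {
      scfg <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
      sim <- simulate_experiment(scfg, level = "reads")
      write_simulation(sim, cfg$outdir)
    },
    assign = {
      element <- read_element(opt$reference)
      reads <- data.table(read = read_fastq_sequences(opt$reads),
                          tag = sub("_.*$", "", names(
                            Biostrings::readDNAStringSet(opt$reads,
                                                         format = "fastq"))))
      a <- call_tag_variants(reads, element,
                             min_coverage = cfg$min_coverage)
      write_assignment(a, file.path(cfg$outdir, "assignment.tsv"))
    },
    count = {
      a <- read_assignment(opt$assignment)
      parsed <- parse_tag_umi_reads(opt$rna, opt$umi,
        tag_length = cfg$tag_length, umi_length = cfg$umi_length)
      dm <- dedup_and_match(parsed$records, a)
      fwrite(dm$counts, file.path(cfg$outdir, "counts_raw.tsv"), sep = "\t")
    },
    fit = {
      counts <- read_counts(opt$counts)
      a <- read_assignment(opt$assignment)
      design <- build_design(counts, a, mode = cfg$mode)
      fit <- fit_effects(design)
      kept <- filter_min_tags(fit$estimates, cfg$min_tags,
                              cfg$tag_count_mode)
      write_effects(kept, file.path(cfg$outdir, "effects.tsv"))
    },
    run = run_pipeline(cfg),
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      out[[key]] <- if (i < length(args) && !grepl("^--", args[i + 1L])) {
        i <- i + 1L; args[i]
      } else TRUE
    }
    i <- i + 1L
  }
  out
}
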