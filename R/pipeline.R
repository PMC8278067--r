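#' Default pipeline run configuration
#'
#' A nested list driving [run_pipeline()]. Every randomized step derives
#' its stream from the single top-level `seed`; the configuration
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Top-level integer seed.
#' @param n_participants,reps_per_clip Generator design.
#' @param mode Generator mode (see [generate_dataset()]).
#' @param fast Use reduced sampler settings throughout (desk scale).
#' @param rl_models Model names for the comparison stage.
#' @param out Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_participants = 12L, reps_per_clip = 12L,
                       mode = "ddm_joint", fast = TRUE,
                       rl_models = c("copy_bias", "baseline_no_bias"),
                       out = "mimicrl-run") {
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 reps_per_clip = as.integer(reps_per_clip),
                 mode = mode, fast = isTRUE(fast),
                 rl_models = rl_models, out = out),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

PIPELINE_STAGES <- c("simulate", "preprocess", "fit-rl", "fit-ddm",
                     "compare", "contrasts", "report")

stage_requires <- list(
  "preprocess" = "records.csv", "fit-rl" = "filtered.csv",
  "fit-ddm" = "filtered.csv", "compare" = "filtered.csv",
  "contrasts" = "ddm_summary.csv",
  "report" = "behaviour_cells.csv")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing versioned plain-text
#' artifacts (CSV/JSON) plus a manifest with the configuration hash, seed,
#' stage durations and md5 checksums of all inputs and outputs. Rerunning
#' with an identical configuration reproduces identical outputs (MCMC
#' stages included, since all sampler seeds derive from the top-level
#' seed). A stage whose upstream artifact is missing fails with an error
#' naming the missing file and the stage that produces it.
#'
#' @param config A [run_config()].
#' @param stages Subset of `simulate`, `preprocess`, `fit-rl`, `fit-ddm`,
#'   `compare`, `contrasts`, `report` (order is enforced internally).
#' @param out_dir Output directory (default `config$out`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = PIPELINE_STAGES,
                         out_dir = config$out) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(out_dir, f)
  need <- function(stage) {
    f <- stage_requires[[stage]]
    if (!is.null(f) && !file.exists(art(f)))
      stop(sprintf("stage '%s' requires missing artifact '%s' (run the stage that produces it first)",
                   stage, f))
  }
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   seed = config$seed, stages = list())
  t_all <- Sys.time()
  for (stage in stages) {
    need(stage)
    t0 <- Sys.time()
    outputs <- switch(stage,
      "simulate" = {
        ds <- generate_dataset(generator_config(
          n_participants = config$n_participants,
          reps_per_clip = config$reps_per_clip, seed = config$seed),
          mode = config$mode)
        write_records_csv(ds$records, art("records.csv"))
        truth_report(ds, art("truth.json"))
        c("records.csv", "truth.json")
      },
      "preprocess" = {
        rec <- read_records_csv(art("records.csv"))
        flt <- filter_trials(rec)
        write_records_csv(flt$records, art("filtered.csv"))
        write_filter_report(flt$report, art("filter_report.json"))
        summ <- summarize_behaviour(flt$records)
        utils::write.csv(summ$cells, art("behaviour_cells.csv"), row.names = FALSE)
        utils::write.csv(summ$curves, art("behaviour_curves.csv"), row.names = FALSE)
        utils::write.csv(reversal_early_late(rec), art("reversal.csv"),
                         row.names = FALSE)
        c("filtered.csv", "filter_report.json", "behaviour_cells.csv",
          "behaviour_curves.csv", "reversal.csv")
      },
      "fit-rl" = {
        rec <- read_records_csv(art("filtered.csv"))
        cfg <- if (config$fast) rl_sampler_config(chains = 2L, iter = 1200L,
                                                  warmup = 400L,
                                                  seed = config$seed)
               else rl_sampler_config(seed = config$seed)
        fit <- fit_rl_hierarchical(rec, rl_model_spec("copy_bias"), cfg)
        utils::write.csv(fit$summary, art("rl_summary.csv"), row.names = FALSE)
        pp <- posterior_predict(fit, n_sims_per_draw = 50L, n_draws = 100L,
                                seed = config$seed)
        utils::write.csv(pp, art("rl_posterior_predict.csv"), row.names = FALSE)
        jsonlite::write_json(list(converged = fit$converged),
                             art("rl_diagnostics.json"), auto_unbox = TRUE)
        c("rl_summary.csv", "rl_posterior_predict.csv", "rl_diagnostics.json")
      },
      "fit-ddm" = {
        rec <- read_records_csv(art("filtered.csv"))
        cfg <- ddm_sampler_config(seed = config$seed, fast = config$fast)
        fit <- fit_ddm_hierarchical(rec, cfg)
        utils::write.csv(fit$summary, art("ddm_summary.csv"), row.names = FALSE)
        pd <- ddm_population_draws(fit)
        utils::write.csv(as.data.frame(pd), art("ddm_population_draws.csv"),
                         row.names = FALSE)
        c("ddm_summary.csv", "ddm_population_draws.csv")
      },
      "compare" = {
        rec <- read_records_csv(art("filtered.csv"))
        cfg <- if (config$fast) rl_sampler_config(chains = 2L, iter = 1000L,
                                                  warmup = 400L,
                                                  seed = config$seed)
               else rl_sampler_config(seed = config$seed)
        cmp <- compare_models(rec, as.list(config$rl_models), cfg)
        utils::write.csv(cmp$table, art("model_comparison.csv"),
                         row.names = FALSE)
        "model_comparison.csv"
      },
      "contrasts" = {
        pd <- as.matrix(utils::read.csv(art("ddm_population_draws.csv")))
        dc <- contrast_drift_congruency(pd)
        out <- list(
          drift_congruency_sum = unclass(dc$sum),
          drift_congruency_mean = unclass(dc$mean),
          drift_expression = unclass(contrast_expression(pd, "v_abs")),
          boundary_congruency = unclass(contrast_boundary_congruency(pd)),
          boundary_expression = unclass(contrast_expression(pd, "a")),
          bias_expression = unclass(contrast_expression(pd, "z")))
        jsonlite::write_json(out, art("contrasts.json"), auto_unbox = TRUE,
                             digits = NA)
        "contrasts.json"
      },
      "report" = {
        report <- list(seed = config$seed,
                       config_hash = manifest$config_hash)
        for (f in c("filter_report.json", "contrasts.json"))
          if (file.exists(art(f)))
            report[[sub("\\.json$", "", f)]] <- jsonlite::read_json(art(f))
        for (f in c("behaviour_cells.csv", "reversal.csv",
                    "model_comparison.csv"))
          if (file.exists(art(f)))
            report[[sub("\\.csv$", "", f)]] <- utils::read.csv(art(f))
        jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                             digits = NA)
        "report.json"
      })
    manifest$stages[[stage]] <- list(
      duration_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = as.list(unname(tools::md5sum(vapply(outputs, art, "")))))
  }
  manifest$total_duration_s <- as.numeric(difftime(Sys.time(), t_all,
                                                   units = "secs"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand interface over [run_pipeline()]:
#' `mimicrl <stage|all> --config PATH --seed INT --out DIR --stages LIST
#' --fast`. An executable wrapper is installed at
#' `system.file("cli", "mimicrl.R", package = "mimicrl")`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the pipeline manifest.
#' @export
mimicrl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: mimicrl <simulate|preprocess|fit-rl|fit-ddm|compare|contrasts|report|all>",
        "[--config PATH] [--seed INT] [--out DIR] [--stages LIST] [--fast]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--stages", type = "character", default = NULL),
    optparse::make_option("--fast", action = "store_true", default = FALSE)))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
  if (!is.null(opt$seed)) config$seed <- opt$seed
  if (!is.null(opt$out)) config$out <- opt$out
  if (opt$fast) config$fast <- TRUE
  stages <- if (cmd == "all") {
    if (!is.null(opt$stages)) strsplit(opt$stages, ",")[[1]] else PIPELINE_STAGES
  } else cmd
  invisible(run_pipeline(config, stages = stages))
}
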