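# Run configuration handling and the end-to-end pipeline
# (simulate -> select -> evaluate -> compare), with provenance.

run_config_schema <- list(
  top = c("responses", "covariates", "method", "k", "seed", "output_dir",
          "verbose", "simulate", "aco", "ga"),
  simulate = c("preset", "n_persons", "seed", "loading_difficulty_corr"),
  aco = c("n_ants", "evaporation_rate", "deposit_scale", "deposit_rule",
          "max_iterations", "stall_limit", "n_replications", "clamp_sens"),
  ga = c("item_cost_I", "population_size", "crossover_rate", "mutation_rate",
         "max_generations", "stall_limit", "elitism_count")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate a pipeline run configuration
#'
#' Run configurations are YAML with a fixed vocabulary: `responses` and
#' optional `covariates` paths (or a `simulate` block with
#' `preset: ppvt_like`), exactly one `method` (`scofa`, `aco`, or `ga`),
#' the short-form length `k`, a master `seed`, an `output_dir`, and
#' optional per-method blocks (`aco`, `ga`). Unknown keys are errors.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return The validated configuration list, classed `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  check_keys(cfg, run_config_schema$top, "configuration")
  for (blk in c("simulate", "aco", "ga")) {
    if (!is.null(cfg[[blk]])) {
      check_keys(cfg[[blk]], run_config_schema[[blk]],
                 sprintf("`%s` block", blk))
    }
  }
  if (is.null(cfg$method) || length(cfg$method) != 1L ||
      !cfg$method %in% c("scofa", "aco", "ga")) {
    stop("`method` must be exactly one of scofa, aco, ga", call. = FALSE)
  }
  if (is.null(cfg$k)) stop("`k` is required", call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$responses) && is.null(cfg$simulate)) {
    stop("either `responses` or a `simulate` block is required", call. = FALSE)
  }
  for (f in c("responses", "covariates")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("`%s` file not found: %s", f, cfg[[f]]), call. = FALSE)
    }
  }
  if (!is.null(cfg$simulate) &&
      !identical(cfg$simulate$preset %||% "ppvt_like", "ppvt_like")) {
    stop("only `preset: ppvt_like` is supported in the simulate block",
         call. = FALSE)
  }
  cfg$verbose <- isTRUE(cfg$verbose)
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full selection pipeline from a configuration
#'
#' Executes (optionally) simulate, then select with the configured method,
#' then evaluate the selected short form against the long form, writing all
#' artifacts (data copies when simulated, selection result JSON, evaluation
#' JSON, comparison CSV) plus a provenance record (config echo and hash,
#' master seed, package version, wall time) into `output_dir`. Any stage
#' error aborts with the stage name; artifacts written before the failure
#' are left in place.
#'
#' @param config a [read_run_config()] result, a config list, or a YAML
#'   path.
#' @return Invisibly, a list with `selection` (`selection_result`),
#'   `evaluation` (`short_form_eval`), `comparison`, and `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- pipeline_stage("simulate", {
      pool <- make_ppvt_like_pool(
        seed = as.integer(config$simulate$seed %||% seed),
        n_persons = config$simulate$n_persons %||% 3000,
        loading_difficulty_corr =
          config$simulate$loading_difficulty_corr %||% 0.7
      )
      s <- simulate_responses(pool)
      write_response_matrix(s$responses, file.path(out_dir, "responses.csv"))
      if (!is.null(s$covariates)) {
        write_covariates(s$covariates, file.path(out_dir, "covariates.csv"))
      }
      write_truth_record(s$truth, file.path(out_dir, "truth.json"))
      s
    })
  }
  responses <- if (!is.null(sim)) sim$responses else {
    pipeline_stage("read", read_response_matrix(config$responses))
  }
  covariates <- if (!is.null(sim)) sim$covariates else if (!is.null(config$covariates)) {
    pipeline_stage("read", read_covariates(config$covariates))
  }
  k <- as.integer(config$k)
  if (k < 3 || k >= ncol(responses)) {
    stop(sprintf("`k` = %d must satisfy 3 <= k < %d (pool size)", k,
                 ncol(responses)), call. = FALSE)
  }

  selection <- pipeline_stage("select", {
    corr <- tetrachoric_matrix(responses)
    switch(config$method,
      scofa = scofa_select(responses, k = k, corr = corr),
      aco = {
        args <- c(list(k = k, seed = seed), config$aco)
        aco_select(responses, covariates, do.call(aco_config, args),
                   corr = corr)
      },
      ga = {
        args <- c(list(fixed_k = k, seed = seed), config$ga)
        ga_select(responses, do.call(ga_config, args))
      }
    )
  })
  write_selection_result(selection, file.path(out_dir, "selection.json"))

  evaluation <- pipeline_stage("evaluate", {
    evaluate_short_form(responses, covariates, subset = selection$best_subset,
                        label = selection$method)
  })
  comparison <- pipeline_stage("compare", {
    compare_methods(list(evaluation), responses, covariates)
  })
  utils::write.csv(as.data.frame(comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)

  provenance <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    master_seed = seed,
    package_version = as.character(utils::packageVersion("scaleshort")),
    r_version = R.version.string,
    wall_time_seconds = proc.time()[["elapsed"]] - t0
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (config$verbose) {
    message(sprintf("%s selected %d items in %.1fs; artifacts in %s",
                    selection$method, selection$k,
                    provenance$wall_time_seconds, out_dir))
  }
  invisible(list(selection = selection, evaluation = evaluation,
                 comparison = comparison, output_dir = out_dir))
}

# Small stable hash of the configuration (djb2 over its serialized form);
# enough to tie artifacts to the config that produced them.
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
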