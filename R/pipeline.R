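#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the input source (a fixture
#' directory, or the synthetic generator when none is given), the stage
#' toggles, and the per-stage parameters. Every stochastic stage derives
#' its seed from the single `seed` so a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param out_dir run directory for stage outputs and the manifest.
#' @param input_dir optional fixture directory readable by
#'   [read_cohort()]; when `NULL` a synthetic cohort is generated.
#' @param generator [generator_config()] used when `input_dir` is `NULL`.
#' @param stages character vector of stages to run, in fixed order.
#' @param min_active_weeks activity filter threshold.
#' @param n_subsamples subsamples per effect-size comparison.
#' @param n_perm permutations per homophily test (`NULL` = 2E).
#' @param homophily_channels channels to run the permutation test on.
#' @param homophily_weeks aggregation window (week indices) for the
#'   homophily graphs; `NULL` = all weeks.
#' @param k imputation neighbourhood size.
#' @param n_folds cross-validation folds.
#' @param grid classifier grid; desk-scale [small_model_grid()] by
#'   default.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL,
                            generator = generator_config(),
                            stages = c("effects", "mobility", "network",
                                       "homophily", "impute", "predict"),
                            min_active_weeks = 4L, n_subsamples = 1000L,
                            n_perm = 500L,
                            homophily_channels = c("facebook_friend",
                                                   "call"),
                            homophily_weeks = 0:3, k = 7L, n_folds = 10L,
                            grid = small_model_grid(), seed = 1L) {
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 generator = generator, stages = stages,
                 min_active_weeks = min_active_weeks,
                 n_subsamples = n_subsamples, n_perm = n_perm,
                 homophily_channels = homophily_channels,
                 homophily_weeks = homophily_weeks, k = k,
                 n_folds = n_folds, grid = grid, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(log_path, stage, status, detail = NULL) {
  line <- jsonlite::toJSON(list(stage = stage, status = status,
                                detail = detail), auto_unbox = TRUE)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  message(sprintf("[gendernet] %s: %s", stage, status))
}

#' Run the full analysis pipeline
#'
#' Executes generate/load, activity filtering, indicator computation,
#' effect sizes, homophily permutation tests, imputation and gender
#' prediction in fixed order, writing each stage's outputs and a manifest
#' (configuration hash, seed, per-file checksums) into the run directory.
#' A failing stage aborts with the stage named; outputs of completed
#' stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  written <- character(0)
  stage_names <- character(0)

  run_stage <- function(stage, fun) {
    log_stage(log_path, stage, "start")
    out <- tryCatch(fun(), error = function(e) {
      log_stage(log_path, stage, "error", conditionMessage(e))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(log_path, stage, "done")
    stage_names <<- c(stage_names, stage)
    out
  }

  model <- run_stage("load", function() {
    if (!is.null(config$input_dir)) return(read_cohort(config$input_dir))
    m <- generate(config$generator)
    fix_dir <- file.path(config$out_dir, "data")
    written <<- c(written, write_fixture(m, fix_dir))
    m
  })

  coh <- run_stage("filter", function()
    filter_active(model$cohort, config$min_active_weeks))
  labels <- gender_labels(coh)

  mobility <- run_stage("mobility", function() {
    tab <- mobility_indicator_table(coh, model$locations)
    p <- file.path(config$out_dir, "mobility_indicators.csv")
    utils::write.csv(cbind(id = rownames(tab), tab), p,
                     row.names = FALSE, na = "")
    written <<- c(written, p)
    tab
  })

  network <- run_stage("network", function() {
    tab <- network_indicator_table(coh, model$networks)
    p <- file.path(config$out_dir, "network_indicators.csv")
    utils::write.csv(cbind(id = rownames(tab), tab), p,
                     row.names = FALSE, na = "")
    written <<- c(written, p)
    tab
  })

  assembled <- assemble_features(coh, model$traits, mobility, network)

  if ("effects" %in% config$stages) run_stage("effects", function() {
    eff <- effect_size_table(assembled$features, labels,
                             n_subsamples = config$n_subsamples,
                             seed = config$seed)
    p <- file.path(config$out_dir, "effect_sizes.csv")
    utils::write.csv(eff, p, row.names = FALSE)
    written <<- c(written, p)
    eff
  })

  if ("homophily" %in% config$stages) run_stage("homophily", function() {
    res <- lapply(config$homophily_channels, function(ch) {
      g <- aggregate_graph(model$networks[[ch]], coh,
                           weeks = config$homophily_weeks)
      ht <- homophily_test(g, n_perm = config$n_perm,
                           seed = config$seed + match(ch, CHANNELS))
      list(channel = ch, n_edges = ht$n_edges, n_perm = ht$n_perm,
           observed = as.list(ht$observed), z = as.list(ht$z),
           p_greater = as.list(ht$p_greater),
           p_less = as.list(ht$p_less))
    })
    p <- file.path(config$out_dir, "homophily.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, p)
    res
  })

  complete <- NULL
  if ("impute" %in% config$stages) complete <- run_stage(
    "impute", function() {
      filtered <- category_filter(assembled$features)
      imp <- knn_impute(filtered, k = config$k)
      p <- file.path(config$out_dir, "features_complete.csv")
      utils::write.csv(cbind(id = rownames(imp), imp), p,
                       row.names = FALSE)
      pl <- file.path(config$out_dir, "imputation_log.csv")
      utils::write.csv(attr(imp, "imputation_log"), pl,
                       row.names = FALSE)
      written <<- c(written, p, pl)
      imp
    })

  if ("predict" %in% config$stages) {
    if (is.null(complete))
      stop("stage 'predict' requires stage 'impute'")
    run_stage("predict", function() {
      lab <- factor(labels[rownames(complete)], levels = c("M", "F"))
      rep_ <- tune_and_evaluate(complete, lab, grid = config$grid,
                                n_folds = config$n_folds,
                                seed = config$seed)
      p <- file.path(config$out_dir, "prediction_report.json")
      jsonlite::write_json(
        list(models = rep_$models, baselines = rep_$baselines,
             importance = rep_$importance, n_folds = rep_$n_folds),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <<- c(written, p)
      rep_
    })
  }

  # hash the analytic configuration only: the output path is not part of it
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config),
                                              c("grid", "out_dir"))],
                               auto_unbox = TRUE, force = TRUE)
  cfg_file <- tempfile(); writeLines(cfg_json, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gendernet")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stage_names,
    outputs = as.list(setNames(unname(tools::md5sum(written)),
                               basename(written))))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(log_path, "manifest", "done")
  invisible(manifest)
}
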