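#' Pipeline configuration
#'
#' One object driving the end-to-end run: ingest or generate events, select
#' model inputs per gender, fit the quasi-Poisson models, bootstrap, enumerate
#' and rank the mesh, sweep the mixing policies, and compare against the
#' benchmark. All defaults mirror the study settings: 10 CV folds, 80/20
#' split, B = 1,000 bootstrap replicates, list sizes {100, 50, 10}, X from 0
#' to 100% in 10% steps, benchmark 122 total / 23 female per event.
#'
#' @param input `"synthetic"` or `"csv"`.
#' @param csv_path events CSV when `input = "csv"`.
#' @param generator a [generator_config()] when `input = "synthetic"`.
#' @param spec a [design_spec()].
#' @param run_selection run grouped input selection; when `FALSE` the
#'   [default_terms()] are used.
#' @param methods shrinkage approaches to compare.
#' @param nfolds,split_fraction selection settings.
#' @param B bootstrap replicates.
#' @param N_menu,X_grid policy grid.
#' @param benchmark named numeric `total`/`female` per-event averages.
#' @param month_level fixed mesh month.
#' @param seed master seed, fanned out to stage seeds.
#' @param out_dir where artifacts are written (created if needed).
#' @param nlambda penalized-path grid size.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = c("synthetic", "csv"), csv_path = NULL,
                            generator = generator_config(),
                            spec = design_spec(),
                            run_selection = TRUE,
                            methods = c("group_mcp", "group_scad", "group_lasso"),
                            nfolds = 10L, split_fraction = 0.8,
                            B = 1000L,
                            N_menu = c(100, 50, 10),
                            X_grid = seq(0, 100, by = 10),
                            benchmark = c(total = 122, female = 23),
                            month_level = "jan2019",
                            seed = 1L, out_dir = tempfile("agritrain_run_"),
                            nlambda = 100) {
  input <- match.arg(input)
  if (input == "csv" && is.null(csv_path)) stop("csv input requires csv_path")
  structure(list(input = input, csv_path = csv_path, generator = generator,
                 spec = spec, run_selection = run_selection, methods = methods,
                 nfolds = nfolds, split_fraction = split_fraction, B = B,
                 N_menu = N_menu, X_grid = X_grid, benchmark = benchmark,
                 month_level = month_level, seed = as.integer(seed),
                 out_dir = out_dir, nlambda = nlambda),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; the generator
#' section accepts `n_events`, `female_zero_excess` and `seed`.
#'
#' @param path YAML (or JSON) file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  gen <- if (is.null(gen_args)) generator_config()
         else do.call(generator_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  args$generator <- gen
  if (!is.null(args$benchmark)) args$benchmark <- unlist(args$benchmark)
  if (!is.null(args$N_menu)) args$N_menu <- as.numeric(args$N_menu)
  if (!is.null(args$X_grid)) args$X_grid <- as.numeric(args$X_grid)
  do.call(pipeline_config, args)
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in order: ingest/generate -> exclusion audit -> per-gender input
#' selection -> quasi-Poisson fits -> bootstrap -> mesh summary -> ranked top
#' lists -> policy sweep -> benchmark flags. Any stage failure aborts with a
#' stage-tagged error. Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to stderr.
#' @return a `run_report` list: audit, selection results, models, paths of all
#'   written artifacts, benchmark flags, seeds.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[agritrain] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  say("ingest")
  events <- stage("ingest", {
    if (config$input == "csv") read_events(config$csv_path)
    else generate_events(config$generator)
  })
  paths$events <- file.path(config$out_dir, "events.csv")
  write_events(events, paths$events)

  say("audit")
  audit <- stage("audit", audit_exclusions(events))

  say("selection")
  selection <- stage("selection", {
    if (config$run_selection) {
      lapply(stats::setNames(c("males", "females"), c("males", "females")),
             function(o) select_inputs(events, config$spec, o,
                                       methods = config$methods,
                                       seed = config$seed,
                                       fraction = config$split_fraction,
                                       nfolds = config$nfolds,
                                       nlambda = config$nlambda))
    } else NULL
  })
  male_terms <- if (is.null(selection)) default_terms("males") else selection$males$terms
  female_terms <- if (is.null(selection)) default_terms("females") else selection$females$terms
  # interactions with empty cells are not estimable by the unpenalized GLM
  male_terms <- estimable_terms(events, male_terms)
  female_terms <- estimable_terms(events, female_terms)
  for (tm in c(attr(male_terms, "dropped"), attr(female_terms, "dropped")))
    say("dropped inestimable interaction: ", tm)
  if (!is.null(selection)) {
    paths$selection_males <- file.path(config$out_dir, "selection_males.json")
    paths$selection_females <- file.path(config$out_dir, "selection_females.json")
    selection_to_json(selection$males, paths$selection_males)
    selection_to_json(selection$females, paths$selection_females)
  }

  say("fit + bootstrap (B = ", config$B, ")")
  ensemble <- stage("bootstrap",
    bootstrap_models(events, male_terms, female_terms,
                     B = config$B, seed = config$seed))
  paths$male_model <- file.path(config$out_dir, "model_males.json")
  paths$female_model <- file.path(config$out_dir, "model_females.json")
  model_to_json(ensemble$male_model, paths$male_model)
  model_to_json(ensemble$female_model, paths$female_model)

  say("mesh")
  mesh <- stage("mesh", build_mesh(male_terms, female_terms,
                                   month_level = config$month_level))
  msum <- stage("mesh_summary", summarize_mesh(ensemble, mesh))
  paths$mesh <- file.path(config$out_dir, "mesh_summary.csv")
  utils::write.csv(as.data.frame(msum), paths$mesh, row.names = FALSE)

  say("ranking + policy sweep")
  total_list <- rank_mesh(msum, "total")
  female_list <- rank_mesh(msum, "female")
  paths$top_total <- file.path(config$out_dir, "top_total.csv")
  paths$top_female <- file.path(config$out_dir, "top_female.csv")
  utils::write.csv(as.data.frame(utils::head(total_list, max(config$N_menu))),
                   paths$top_total, row.names = FALSE)
  utils::write.csv(as.data.frame(utils::head(female_list, max(config$N_menu))),
                   paths$top_female, row.names = FALSE)

  tradeoff <- stage("sweep",
    sweep_policies(total_list, female_list, ensemble,
                   N_menu = config$N_menu, X_grid = config$X_grid))
  paths$tradeoff <- file.path(config$out_dir, "tradeoff.csv")
  utils::write.csv(tradeoff, paths$tradeoff, row.names = FALSE)

  flags <- lapply(seq_len(nrow(tradeoff)), function(i)
    benchmark_compare(tradeoff[i, ], config$benchmark))

  report <- structure(list(
    audit = audit, selection = selection,
    male_terms = male_terms, female_terms = female_terms,
    male_model = ensemble$male_model, female_model = ensemble$female_model,
    mesh_size = nrow(mesh), tradeoff = tradeoff, benchmark_flags = flags,
    benchmark = config$benchmark, paths = paths, seed = config$seed,
    B = config$B, n_redraws = ensemble$n_redraws,
    version = as.character(utils::packageVersion("agritrain"))
  ), class = "run_report")
  paths$report <- file.path(config$out_dir, "report.json")
  report_to_json(report, paths$report)
  report$paths <- paths
  say("done")
  report
}

report_to_json <- function(report, path) {
  payload <- list(
    version = report$version, seed = report$seed, B = report$B,
    mesh_size = report$mesh_size,
    male_terms = report$male_terms, female_terms = report$female_terms,
    audit = list(n_included = report$audit$n_included,
                 n_excluded = report$audit$n_excluded,
                 exclusion_percent = report$audit$exclusion_percent),
    benchmark = as.list(report$benchmark),
    n_bootstrap_redraws = report$n_redraws,
    files = lapply(report$paths, identity)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
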