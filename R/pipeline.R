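#' Full run configuration for the five-stage analysis
#'
#' Exactly one of `input` (a long-format data file) or `sim` (a
#' [sim_config()]) must be supplied. One master seed deterministically
#' spawns the per-stage seeds (simulation, split, network training,
#' bootstrap), so a run is reproducible from config + seed alone.
#'
#' @param input path to a long-format trial file, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param schema column map for `input`, see [trial_schema()].
#' @param threshold a [threshold_spec()].
#' @param split_fraction placebo training fraction.
#' @param grid topology candidates (list of hidden-size vectors).
#' @param train a [train_config()] (its seed is overridden by the spawned
#'   stage seed).
#' @param p_min,p_max probability clipping bounds before inversion.
#' @param n_boot bootstrap replicates for the validation AUC.
#' @param mmrm an [mmrm_spec()].
#' @param low_cut,high_cut sensitivity propensity cuts.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, sim = NULL, schema = trial_schema(),
                       threshold = threshold_spec("HAMD17"),
                       split_fraction = 0.75,
                       grid = NULL, train = train_config(),
                       p_min = 0.05, p_max = 1, n_boot = 1000L,
                       mmrm = mmrm_spec(), low_cut = 0.2, high_cut = 0.8,
                       seed = 1L) {
  if (is.null(input) == is.null(sim))
    stopf("exactly one of `input` and `sim` must be given",
          class = "pwmmrm_config_error")
  structure(list(input = input, sim = sim, schema = schema,
                 threshold = threshold, split_fraction = split_fraction,
                 grid = grid, train = train, p_min = p_min, p_max = p_max,
                 n_boot = as.integer(n_boot), mmrm = mmrm,
                 low_cut = low_cut, high_cut = high_cut,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the five-stage propensity-weighted analysis
#'
#' Stage 1 labels end-of-study placebo response; stage 2 trains the
#' network on 75% of the labeled placebo arm with a topology grid search;
#' stage 3 validates it on the held-out 25% by bootstrap ROC; stage 4
#' predicts the propensity of every randomized subject and derives
#' inverse-probability weights; stage 5 fits the weighted and unweighted
#' MMRM and the propensity sensitivity grid.
#'
#' @param cfg a [run_config()].
#' @param verbose log stage progress to stderr.
#' @return A `pw_report` with all stage outputs.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "load"
  res <- list(config = cfg, seed = cfg$seed)
  tryCatch({
    if (!is.null(cfg$sim)) {
      gen <- generate_trial(cfg$sim, seed = spawn_seed(cfg$seed, "simulate"))
      ds <- gen$dataset
      res$truth <- gen$truth
    } else {
      ds <- read_trial_long(cfg$input, cfg$schema)
    }
    res$census <- table(ds$subjects$arm)
    say("loaded %d subjects (%s)", nrow(ds$subjects),
        paste(names(res$census), res$census, sep = "=", collapse = ", "))

    stage <- "label"
    labels <- label_response(ds, cfg$threshold)
    res$labels <- labels
    res$threshold <- cfg$threshold

    stage <- "split"
    sp <- split_placebo(ds, labels, cfg$split_fraction,
                        seed = spawn_seed(cfg$seed, "split"))
    res$split <- sp
    say("placebo split: %d train / %d validation",
        length(sp$train), length(sp$validation))

    stage <- "grid_search"
    lab_of <- stats::setNames(labels$label, labels$subject_id)
    Xall <- item_changes(ds)
    tr_cfg <- cfg$train
    tr_cfg$seed <- spawn_seed(cfg$seed, "train")
    grid <- cfg$grid %||% default_topology_grid(ncol(Xall))
    gs <- grid_search_topology(Xall[sp$train, , drop = FALSE],
                               lab_of[sp$train],
                               Xall[sp$validation, , drop = FALSE],
                               lab_of[sp$validation],
                               grid = grid, cfg = tr_cfg)
    res$grid_table <- gs$table
    res$topology <- gs$best
    res$model <- gs$model
    say("selected topology: %s", paste(gs$best, collapse = "-"))

    stage <- "validate"
    res$validation <- bootstrap_auc_ci(
      predict(gs$model, Xall[sp$validation, , drop = FALSE]),
      lab_of[sp$validation], n_boot = cfg$n_boot,
      seed = spawn_seed(cfg$seed, "bootstrap"))
    say("validation AUC %.3f (CI %.3f-%.3f)", res$validation$auc,
        res$validation$ci_low, res$validation$ci_high)

    stage <- "predict_propensity"
    res$propensity <- predict_propensity(gs$model, ds, cfg$p_min, cfg$p_max)
    res$propensity_bins <- bin_propensity(res$propensity)

    stage <- "mmrm"
    design <- build_design(ds, cfg$mmrm)
    fit_u <- mmrm_fit(design, weights = NULL, spec = cfg$mmrm)
    fit_w <- mmrm_fit(design, weights = res$propensity, spec = cfg$mmrm)
    av <- design$visits[length(design$visits)]
    res$unweighted <- list(
      fit = fit_u,
      effects = lapply(design$active_arms, function(a)
        treatment_effect(fit_u, a, visit = av)))
    res$weighted <- list(
      fit = fit_w,
      effects = lapply(design$active_arms, function(a)
        treatment_effect(fit_w, a, visit = av)))

    stage <- "sensitivity"
    res$sensitivity <- run_sensitivity_grid(ds, res$propensity,
                                            cfg$low_cut, cfg$high_cut,
                                            cfg$mmrm, visit = av)
    res$dataset <- ds
    class(res) <- "pw_report"
    res
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e),
          class = "pwmmrm_pipeline_error")
  })
}

#' @export
print.pw_report <- function(x, ...) {
  cat("Propensity-weighted trial analysis\n")
  cat("  census: ", paste(names(x$census), x$census, sep = "=",
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  response threshold: %.0f%% reduction (%s)\n",
              100 * x$threshold$percent_reduction, x$threshold$scale))
  cat(sprintf("  selected topology: %s\n", paste(x$topology, collapse = "-")))
  print(x$validation)
  cat("\nTreatment effects at the analysis visit:\n")
  for (nm in c("unweighted", "weighted")) {
    cat(sprintf("  [%s]\n", nm))
    for (te in x[[nm]]$effects) { cat("    "); print(te) }
  }
  cat(sprintf("\nSensitivity bias B: weighted %.3f, unweighted %.3f\n",
              x$sensitivity$bias[["weighted"]],
              x$sensitivity$bias[["unweighted"]]))
  invisible(x)
}

te_rows <- function(effects, analysis) {
  do.call(rbind, lapply(effects, function(te) {
    d <- as.data.frame(te); d$analysis <- analysis
    d[c("analysis", setdiff(names(d), "analysis"))]
  }))
}

#' Write the report artifacts of a pipeline run
#'
#' Emits `report.json` (census, threshold, topology, grid table,
#' validation AUC, propensity bins, contrasts, sensitivity grid, bias,
#' seed), `table2_style.csv` (the sensitivity grid in flat form),
#' `propensity.csv` and `model.json` into `dir`.
#'
#' @param report a `pw_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- report$sensitivity$grid
  utils::write.csv(grid[c("analysis", "subset", "comparison", "te", "p",
                          "effect_size")],
                   file.path(dir, "table2_style.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$propensity),
                   file.path(dir, "propensity.csv"), row.names = FALSE)
  mlp_to_json(report$model, file.path(dir, "model.json"))
  doc <- list(
    seed = report$seed,
    census = as.list(stats::setNames(as.integer(report$census),
                                     names(report$census))),
    threshold = list(scale = report$threshold$scale,
                     percent_reduction = report$threshold$percent_reduction),
    topology = report$topology,
    grid_table = report$grid_table,
    validation = list(auc = report$validation$auc,
                      ci = c(report$validation$ci_low,
                             report$validation$ci_high),
                      n_bootstrap = report$validation$n_bootstrap),
    propensity_bins = report$propensity_bins,
    effects = rbind(te_rows(report$unweighted$effects, "unweighted"),
                    te_rows(report$weighted$effects, "weighted")),
    sensitivity = grid,
    bias = as.list(report$sensitivity$bias)
  )
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a run configuration from a YAML or JSON file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; nested
#' `sim`, `train`, `mmrm` and `threshold` blocks are passed to their
#' constructors.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path,
                                class = "pwmmrm_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (k in c("input", "split_fraction", "p_min", "p_max", "n_boot",
              "low_cut", "high_cut", "seed"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$sim))
    args$sim <- do.call(sim_config, lapply(raw$sim, unlist))
  if (!is.null(raw$threshold))
    args$threshold <- do.call(threshold_spec, raw$threshold)
  if (!is.null(raw$train)) args$train <- do.call(train_config, raw$train)
  if (!is.null(raw$mmrm)) args$mmrm <- do.call(mmrm_spec, raw$mmrm)
  if (!is.null(raw$grid)) args$grid <- lapply(raw$grid, as.integer)
  do.call(run_config, args)
}
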