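#' Build a run configuration
#'
#' Collects paths, analysis selections and the simulation block into a
#' validated list, either programmatically or from a YAML file.
#'
#' @param cohort_path optional cohort CSV (ignored when `simulate` is
#'   `TRUE`).
#' @param instruments_path optional instrument TSV for two-sample MR.
#' @param out_dir output directory.
#' @param simulate generate the cohort from `sim` instead of reading one.
#' @param sim a [sim_config()] (or argument list for it).
#' @param outcomes outcomes analysed by each stage.
#' @param K quantile group count for the dose-response stage.
#' @param models adjustment models to run (subset of 1:4).
#' @param strata sex strata to run.
#' @param ipw also run IPW-weighted sensitivity analyses.
#' @param mr_designs MR designs to run.
#' @param stages which stages to execute.
#' @param seed global seed; stage substreams are derived from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, instruments_path = NULL,
                       out_dir = NULL, simulate = TRUE,
                       sim = sim_config(),
                       outcomes = c("dep_score", "anx_score",
                                    "dep_dx", "gad_dx"),
                       K = 5, models = c(1, 4), strata = "all",
                       ipw = FALSE,
                       mr_designs = "one_sample",
                       stages = c("simulate", "observational",
                                  "specificity", "mr"),
                       seed = 1L) {
  if (is.list(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  cfg <- list(cohort_path = cohort_path,
              instruments_path = instruments_path,
              out_dir = out_dir, simulate = simulate, sim = sim,
              outcomes = outcomes, K = as.integer(K),
              models = as.integer(models), strata = strata, ipw = ipw,
              mr_designs = mr_designs, stages = stages,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with fields matching the arguments of
#'   `run_config()` (the `sim` block holds [sim_config()] arguments).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- if (is.null(sim_args)) sim_config() else
    do.call(sim_config, sim_args)
  do.call(run_config, y)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- unclass(config)
  stripped$out_dir <- NULL
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Execute the full analysis pipeline
#'
#' Runs simulate (optional) -> observational -> specificity -> MR in
#' order, deterministically for a given seed, and returns a results
#' bundle with a provenance manifest (config hash, seed, package
#' version, skipped stages). When `out_dir` is set, the cohort, truth
#' record and JSON results are written there.
#'
#' @param config a [run_config()].
#' @return object of class `results_bundle`: list with `manifest`,
#'   `cohort`/`truth` (when simulated), `observational`, `specificity`,
#'   `mr` components (present only for executed stages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  bundle <- list()
  manifest <- list(config_hash = .config_hash(config),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("inflamr")),
                   stages_run = stages,
                   stages_skipped = setdiff(
                     c("simulate", "observational", "specificity", "mr"),
                     stages))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- NULL; truth <- NULL
  if ("simulate" %in% stages && config$simulate) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- run_stage("simulate", generate_cohort(sim_cfg))
    cohort <- sim$cohort
    truth <- sim$truth
    bundle$truth <- truth
  } else if (!is.null(config$cohort_path)) {
    cohort <- run_stage("read_cohort", read_cohort(config$cohort_path))
  }
  bundle$cohort <- cohort

  needs_cohort <- intersect(stages, c("observational", "specificity", "mr"))
  if (length(needs_cohort) && is.null(cohort))
    stop("no cohort available: enable the simulate stage or give cohort_path")

  weights <- NULL
  if (config$ipw && !is.null(cohort) && "selected" %in% names(cohort))
    weights <- fit_selection_model(cohort)

  if ("observational" %in% stages) {
    obs <- list()
    for (out in config$outcomes) for (m in config$models)
      for (st in config$strata) {
        key <- paste(out, paste0("model", m), st, sep = ".")
        obs[[key]] <- run_stage("observational",
          fit_doseresponse(cohort, out, K = config$K, model = m,
                           sex_stratum = st))
        if (config$ipw && !is.null(weights))
          obs[[paste0(key, ".ipw")]] <- run_stage("observational",
            fit_doseresponse(cohort[cohort$selected == 1, ], out,
                             K = config$K, model = m, sex_stratum = st,
                             weights =
                               weights$weights[cohort$selected == 1]))
      }
    bundle$observational <- obs
  }
  if ("specificity" %in% stages) {
    m <- max(config$models)
    bundle$specificity <- run_stage("specificity", list(
      categorical = specificity_test(cohort, "categorical", model = m),
      continuous = specificity_test(cohort, "continuous", model = m),
      mutual_adjustment = mutual_adjustment(cohort, model = m)))
  }
  if ("mr" %in% stages) {
    instruments <- if (!is.null(config$instruments_path))
      read_instruments(config$instruments_path) else NULL
    mr <- list()
    for (des in config$mr_designs) for (expo in c("crp", "il6"))
      for (out in config$outcomes) {
        if (des == "two_sample" && is.null(instruments)) next
        key <- paste(des, expo, out, sep = ".")
        mr[[key]] <- run_stage("mr",
          run_mr(des, expo, out, cohort = cohort,
                 instruments = instruments))
      }
    bundle$mr <- mr
  }
  bundle$manifest <- manifest
  class(bundle) <- "results_bundle"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cohort))
      write_cohort(cohort, file.path(config$out_dir, "cohort.csv"),
                   seed = config$seed)
    if (!is.null(truth))
      write_truth(truth, file.path(config$out_dir, "truth.json"))
    jsonlite::write_json(results_json(bundle),
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Flatten a results bundle for JSON serialisation
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @return plain list of numeric summaries, deterministic for a given
#'   config and seed.
#' @export
results_json <- function(bundle) {
  out <- list(manifest = bundle$manifest)
  if (!is.null(bundle$observational))
    out$observational <- lapply(bundle$observational, function(x) list(
      outcome = x$outcome, K = x$K, model = x$model,
      stratum = x$sex_stratum, n = x$n,
      groups = x$groups, trend = as.list(x$trend),
      quadratic_p = x$quadratic_p,
      sex_interaction_p = x$sex_interaction_p))
  if (!is.null(bundle$specificity)) {
    sp <- bundle$specificity
    out$specificity <- list(
      categorical = list(LR = sp$categorical$LR, p = sp$categorical$p,
                         coef = as.list(sp$categorical$coef),
                         or = sp$categorical$or,
                         rho = sp$categorical$rho),
      continuous = list(LR = sp$continuous$LR, p = sp$continuous$p,
                        coef = as.list(sp$continuous$coef),
                        rho = sp$continuous$rho),
      mutual_adjustment = sp$mutual_adjustment)
  }
  if (!is.null(bundle$mr))
    out$mr <- lapply(bundle$mr, function(x) list(
      design = x$design, exposure = x$exposure, outcome = x$outcome,
      stratum = x$stratum, or = x$or, lo = x$lo, hi = x$hi, p = x$p,
      beta = x$beta, se = x$se, Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p,
      J = x$J))
  if (!is.null(bundle$truth))
    out$truth <- bundle$truth
  out
}
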