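#' Pipeline run configuration
#'
#' Collects every tunable of the modelling pipeline with defaults that
#' follow the standard design for this workflow: 10,000 background points
#' from the entire study area (a 10-km road bias-correction zone can be
#' switched on), 100 subsample replicates with a 50/50 split,
#' the 11-point decile threshold grid, default regularisation (beta 1),
#' correlation cutoff 0.75 and contribution cutoff 0.5%. Unknown keys are
#' rejected so variable-name typos fail before any compute starts.
#'
#' @param overrides named list of overrides.
#' @param verbose log every default substituted for a missing key.
#' @return configuration list of class `run_config`.
#' @export
run_config <- function(overrides = list(), verbose = FALSE) {
  defaults <- list(
    background_n = 10000,
    bias_radius = 10,          # map units (km on the synthetic grid)
    bias_correction = FALSE,   # TRUE restricts background to the road zone
    n_reps = 100,
    split_fraction = 0.5,
    thresholds = seq(0, 1, by = 0.1),
    beta = 1.0,
    n_knots = 50,
    classes = NULL,            # NULL: auto rule at the training size
    r_cut = 0.75,
    contrib_cut = 0.5,
    pseudo_absence_n = NULL,
    select = TRUE,
    tol = 1e-6,
    max_iter = 5000L,
    seed = 1L)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown run_config keys: ",
                            paste(unknown, collapse = ", "))
  if (verbose) {
    for (k in setdiff(names(defaults), names(overrides)))
      message("run_config: using default ", k, " = ",
              paste(format(defaults[[k]]), collapse = " "))
  }
  structure(utils::modifyList(defaults, overrides), class = "run_config")
}

# Internal: subset of run_config understood by the evaluation functions.
as_eval_config <- function(cfg) {
  list(beta = cfg$beta, n_knots = cfg$n_knots, classes = cfg$classes,
       thresholds = cfg$thresholds, pseudo_absence_n = cfg$pseudo_absence_n,
       split_fraction = cfg$split_fraction, tol = cfg$tol,
       max_iter = cfg$max_iter)
}

#' Assemble the occurrence set for a study
#'
#' Samples the background (inside the road bias-correction buffer when
#' enabled, capped at the number of eligible cells only if the caller says
#' so via `background_n`) and extracts feature tables for presences and
#' background.
#'
#' @param study a `synthetic_study` (or any list with `stack`, `roads`,
#'   `presence_xy`).
#' @param config a [run_config()].
#' @return an [occurrence_set()].
#' @export
build_occurrences <- function(study, config = run_config()) {
  mask <- NULL
  if (isTRUE(config$bias_correction) && !is.null(study$roads))
    mask <- buffer_mask(study$roads, study$stack$spec, config$bias_radius)
  bg <- sample_background(study$stack, config$background_n, bias_mask = mask,
                          seed = derive_seed(config$seed, "background"))
  occurrence_set(study$stack, study$presence_xy, bg)
}

#' Run the full fit-and-evaluate stage
#'
#' Variable selection (jackknife gains, correlation pruning, contribution
#' floor) followed by replicate fitting, threshold optimisation and map
#' products — the complete modelling procedure applied to one scenario.
#'
#' @param study a `synthetic_study`.
#' @param config a [run_config()].
#' @param occ optional prebuilt [occurrence_set()] (shared across
#'   scenarios).
#' @param variables optional explicit variable subset (skips selection).
#' @param plans optional shared split plans.
#' @return list of class `pipeline_result`: `report` (an `eval_report`),
#'   `jackknife`, `selection`, `variables`, `map`, `binary`, `threshold`,
#'   `area`, `occ`, `config`.
#' @export
fit_evaluate <- function(study, config = run_config(), occ = NULL,
                         variables = NULL, plans = NULL) {
  ecfg <- as_eval_config(config)
  if (is.null(occ)) occ <- build_occurrences(study, config)
  jk <- jackknife(occ, study$kinds, config = ecfg, variables = variables)
  sel <- NULL
  if (is.null(variables)) {
    if (isTRUE(config$select)) {
      sel <- select_variables(occ, study$kinds, jk, r_cut = config$r_cut,
                              contrib_cut = config$contrib_cut,
                              config = ecfg,
                              seed = derive_seed(config$seed, "contrib"))
      variables <- sel$retained
    } else variables <- names(occ$features_presence)
  }
  report <- run_replicates(occ, study$kinds, stack = study$stack,
                           config = ecfg, n_reps = config$n_reps,
                           seed = config$seed, plans = plans,
                           variables = variables)
  map <- report$mean_map
  thr <- report$opt_threshold
  bin <- binarize(map, thr)
  area <- suitable_area(bin)
  structure(list(report = report, jackknife = jk, selection = sel,
                 variables = variables, map = map, binary = bin,
                 threshold = thr, area = area, occ = occ, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n  variables: ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  print(x$report)
  cat(sprintf("  suitable area %.4g (%.1f%% of valid land)\n",
              x$area$area, 100 * x$area$fraction))
  invisible(x)
}

#' Paired with/without-variables scenario comparison
#'
#' Runs the pipeline twice on shared background and split plans — once with
#' all (or the selected) variables, once with `drop_variables` removed —
#' and compares the scenarios (thresholds, areas, increase area, paired
#' Wilcoxon tests on the per-replicate metrics).
#'
#' @param study a `synthetic_study`.
#' @param drop_variables variables removed in the reduced scenario (e.g.
#'   `c("dis_to_road", "dis_to_resident")`).
#' @param config a [run_config()].
#' @param variables variables for the full scenario (default: all layers;
#'   set `config$select = TRUE` upstream if selection is wanted first).
#' @return list with `full`, `reduced` (both `pipeline_result`) and
#'   `comparison` (a `scenario_comparison`).
#' @export
compare_scenarios_run <- function(study, drop_variables,
                                  config = run_config(), variables = NULL) {
  if (is.null(variables)) variables <- names(study$stack$layers)
  unknown <- setdiff(drop_variables, variables)
  if (length(unknown)) stop("drop_variables not in the variable set: ",
                            paste(unknown, collapse = ", "))
  occ <- build_occurrences(study, config)
  plans <- make_split_plans(nrow(occ$features_presence), config$n_reps,
                            config$split_fraction, config$seed)
  full <- fit_evaluate(study, config, occ = occ, variables = variables,
                       plans = plans)
  reduced <- fit_evaluate(study, config, occ = occ,
                          variables = setdiff(variables, drop_variables),
                          plans = plans)
  structure(list(full = full, reduced = reduced,
                 comparison = compare_scenarios(full$report,
                                                reduced$report)),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-replicate metrics as CSV, the replicate-mean threshold curve as CSV
#' (`threshold,sensitivity,specificity,tss`), and a JSON summary with the
#' aggregate means/SDs and the optimal threshold.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return written paths, invisibly.
#' @export
write_eval_report <- function(report, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_replicates.csv"))
  utils::write.csv(report$replicates, p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_tss_curve.csv"))
  utils::write.csv(report$mean_tss_curve, p2, row.names = FALSE)
  p3 <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(
    list(summary = report$summary, opt_threshold = report$opt_threshold,
         opt_tss = report$opt_tss, n_reps = nrow(report$replicates),
         variables = report$variables, classes = report$classes),
    p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}

#' Write a jackknife report as CSV
#'
#' @param jk a `jackknife_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_jackknife <- function(jk, path) {
  tab <- jk$table
  tab$gain_all <- jk$gain_all
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
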