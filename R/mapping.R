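#' Predict a suitability map
#'
#' Per-valid-cell logistic prediction over a layer stack. Given a fitted
#' `maxent_model` the map is its direct logistic output; given an
#' `eval_report` the map is the mean logistic map across replicates (the
#' report must have been produced with the same grid).
#'
#' @param x a `maxent_model` or `eval_report`.
#' @param stack `layer_stack` holding every model variable.
#' @return a `px_layer` of probabilities in `[0, 1]`, nodata propagated.
#' @export
predict_map <- function(x, stack) {
  if (inherits(x, "eval_report")) {
    if (is.null(x$mean_map))
      stop("eval_report carries no map; re-run run_replicates with a stack")
    if (!spec_aligned(x$spec, stack$spec))
      stop("eval_report grid does not match the stack")
    return(x$mean_map)
  }
  stopifnot(inherits(x, "maxent_model"))
  missing <- setdiff(unique(x$expansion$features$var[x$feature_idx]),
                     names(stack$layers))
  if (length(missing))
    stop("stack is missing model variable(s): ",
         paste(missing, collapse = ", "))
  vm <- valid_mask(stack)
  idx <- which(vm)
  cells <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]))
  names(cells) <- names(stack$layers)
  v <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  v[idx] <- predict_logistic(x, cells)
  px_layer("logistic", v, stack$spec)
}

#' Binarise a probability map
#'
#' Cell value 1 iff probability `>= threshold`, else 0; nodata preserved.
#'
#' @param map probability `px_layer` in `[0, 1]`.
#' @param threshold cutoff in `[0, 1]` (typically the max-TSS threshold).
#' @return a 0/1 `px_layer`.
#' @export
binarize <- function(map, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  px_layer(paste0(map$name, "_binary"), (map$values >= threshold) * 1,
           map$spec)
}

#' Suitable area and fraction of valid land
#'
#' @param binary a 0/1 `px_layer` (e.g. from [binarize()]).
#' @return list with `area` (`count(cells == 1) * cell_size^2`, squared map
#'   units — km^2 when the cell size is in km) and `fraction` (relative to
#'   valid, non-nodata cells, so masked water bodies are excluded from the
#'   denominator).
#' @export
suitable_area <- function(binary) {
  n_suit <- sum(binary$values == 1, na.rm = TRUE)
  n_valid <- sum(!is.na(binary$values))
  list(area = n_suit * binary$spec$cell_size^2,
       fraction = if (n_valid > 0) n_suit / n_valid else NA_real_)
}

#' Paired comparison of two model scenarios
#'
#' Compares a full model against a reduced one (e.g. with vs without the
#' anthropogenic covariates) fitted on shared split plans. Each scenario is
#' binarised at its own max-TSS threshold; the "increase area" counts valid
#' cells where the full model's mean probability exceeds the reduced one's
#' by more than `delta` (by default restricted to cells suitable under the
#' full model); per-replicate training AUC, test AUC and max TSS are
#' compared with the paired Wilcoxon signed-rank test.
#'
#' @param full_report,reduced_report `eval_report`s sharing grid and plans.
#' @param delta minimum probability increase to count a cell (default 0).
#' @param restrict_to_full_suitable if `TRUE` (default) only cells suitable
#'   under the full model are counted in the increase area.
#' @return object of class `scenario_comparison`.
#' @export
compare_scenarios <- function(full_report, reduced_report, delta = 0,
                              restrict_to_full_suitable = TRUE) {
  if (is.null(full_report$mean_map) || is.null(reduced_report$mean_map))
    stop("both reports need mean maps (run_replicates with a stack)")
  if (!spec_aligned(full_report$spec, reduced_report$spec))
    stop("scenario grids do not match")
  ps <- vapply(full_report$plans, `[[`, 0L, "seed")
  qs <- vapply(reduced_report$plans, `[[`, 0L, "seed")
  if (length(ps) != length(qs) || any(ps != qs))
    stop("scenario replicates are not paired (split plans differ)")
  thr_full <- full_report$opt_threshold
  thr_red <- reduced_report$opt_threshold
  bin_full <- binarize(full_report$mean_map, thr_full)
  bin_red <- binarize(reduced_report$mean_map, thr_red)
  area_full <- suitable_area(bin_full)
  area_red <- suitable_area(bin_red)
  inc <- full_report$mean_map$values - reduced_report$mean_map$values > delta
  if (restrict_to_full_suitable) inc <- inc & bin_full$values == 1
  s <- full_report$spec$cell_size
  increase_area <- sum(inc, na.rm = TRUE) * s^2
  extension_percent <- if (area_red$area > 0)
    100 * (area_full$area - area_red$area) / area_red$area else NA_real_
  wtests <- lapply(c(train_auc = "train_auc", test_auc = "test_auc",
                     max_tss = "max_tss"), function(mt)
    wilcoxon_signed_rank(full_report$replicates[[mt]],
                         reduced_report$replicates[[mt]]))
  structure(list(map_full = full_report$mean_map,
                 map_reduced = reduced_report$mean_map,
                 threshold_full = thr_full, threshold_reduced = thr_red,
                 binary_full = bin_full, binary_reduced = bin_red,
                 suitable_area_full = area_full$area,
                 suitable_area_reduced = area_red$area,
                 fraction_full = area_full$fraction,
                 fraction_reduced = area_red$fraction,
                 increase_area = increase_area,
                 extension_percent = extension_percent,
                 delta = delta,
                 restrict_to_full_suitable = restrict_to_full_suitable,
                 wilcoxon = wtests,
                 summary_full = full_report$summary,
                 summary_reduced = reduced_report$summary),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("scenario_comparison (full vs reduced)\n")
  cat(sprintf("  thresholds: %.4g / %.4g\n", x$threshold_full,
              x$threshold_reduced))
  cat(sprintf("  suitable area: %.4g / %.4g (extension %+.1f%%)\n",
              x$suitable_area_full, x$suitable_area_reduced,
              x$extension_percent))
  cat(sprintf("  increase area: %.4g\n", x$increase_area))
  for (mt in names(x$wilcoxon)) {
    w <- x$wilcoxon[[mt]]
    cat(sprintf("  Wilcoxon %-9s W = %-8.4g p = %-10.3g (%s)\n",
                mt, w$statistic, w$p_value, w$direction))
  }
  invisible(x)
}

#' Serialise a scenario comparison to JSON
#'
#' Writes thresholds, areas, the increase-area rule metadata and the
#' per-metric Wilcoxon results (not the maps).
#'
#' @param comparison a `scenario_comparison`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  keep <- c("threshold_full", "threshold_reduced", "suitable_area_full",
            "suitable_area_reduced", "fraction_full", "fraction_reduced",
            "increase_area", "extension_percent", "delta",
            "restrict_to_full_suitable")
  out <- comparison[keep]
  out$wilcoxon <- lapply(comparison$wilcoxon, function(w)
    w[c("statistic", "p_value", "direction", "n", "method")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
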