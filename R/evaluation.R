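#' Rank-based AUC
#'
#' Mann-Whitney form of the area under the ROC curve:
#' `P(score_presence > score_background) + 0.5 P(tie)`, computed from
#' midranks so ties are handled exactly.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Sensitivity, specificity and TSS over a threshold grid
#'
#' At threshold `t` a record is predicted present iff its score is `>= t`.
#' TSS = sensitivity + specificity - 1. The default grid is the 11-point
#' decile grid `{0, 0.1, ..., 1}`.
#'
#' @param presence_scores scores of observed presences (class 1).
#' @param pseudoabsence_scores scores of pseudo-absences (class 0).
#' @param thresholds non-empty increasing numeric vector.
#' @return data frame `threshold, sensitivity, specificity, tss`.
#' @export
tss_curve <- function(presence_scores, pseudoabsence_scores,
                      thresholds = seq(0, 1, by = 0.1)) {
  stopifnot(length(thresholds) > 0)
  thresholds <- sort(thresholds)
  m <- length(presence_scores); n <- length(pseudoabsence_scores)
  sens <- vapply(thresholds, function(t) sum(presence_scores >= t) / m, 0)
  spec <- vapply(thresholds, function(t)
    sum(pseudoabsence_scores < t) / n, 0)
  data.frame(threshold = thresholds, sensitivity = sens,
             specificity = spec, tss = sens + spec - 1)
}

#' Threshold maximising TSS
#'
#' Ties are broken toward the smaller threshold (favouring sensitivity).
#'
#' @param curve data frame from [tss_curve()].
#' @return list with `threshold` and `tss` (the maximum).
#' @export
optimal_threshold <- function(curve) {
  curve <- curve[order(curve$threshold), ]
  i <- which.max(curve$tss)
  list(threshold = curve$threshold[i], tss = curve$tss[i])
}

#' Grade an AUC or TSS value
#'
#' Standard qualitative scales with left-open, right-closed intervals.
#' AUC: worse than random (<= 0.5), failed (0.5, 0.6], poor (0.6, 0.7],
#' fair (0.7, 0.8], good (0.8, 0.9], excellent (0.9, 1].
#' TSS: worse than random (<= 0), bad (0, 0.2], poor (0.2, 0.4],
#' fair (0.4, 0.6], good (0.6, 0.8], excellent (0.8, 1].
#'
#' @param value the statistic.
#' @param scale `"auc"` (domain `[0, 1]`) or `"tss"` (domain `[-1, 1]`).
#' @return category label, character.
#' @export
grade <- function(value, scale = c("auc", "tss")) {
  scale <- match.arg(scale)
  if (scale == "auc") {
    if (value < 0 || value > 1) stop("AUC must lie in [0, 1]")
    if (value <= 0.5) return("worse than random")
    labs <- c("failed", "poor", "fair", "good", "excellent")
    cuts <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1)
  } else {
    if (value < -1 || value > 1) stop("TSS must lie in [-1, 1]")
    if (value <= 0) return("worse than random")
    labs <- c("bad", "poor", "fair", "good", "excellent")
    cuts <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  }
  labs[findInterval(value, cuts, left.open = TRUE, rightmost.closed = TRUE)]
}

#' Deterministic subsample split plans
#'
#' Generates `n_reps` random presence splits (default 50/50; with 77
#' presences that is 38 training / 39 test records). Plans are a pure
#' function of `(n_presence, n_reps, fraction, seed)` so two scenario runs
#' given the same arguments share identical splits — the basis of the
#' paired design.
#'
#' @param n_presence number of presence records.
#' @param n_reps number of replicates.
#' @param fraction training fraction (default 0.5).
#' @param seed master seed.
#' @return list of plans, each `list(replicate_id, train, test, seed)`.
#' @export
make_split_plans <- function(n_presence, n_reps, fraction = 0.5, seed = 1L) {
  n_train <- floor(n_presence * fraction)
  stopifnot(n_train >= 2, n_presence - n_train >= 1)
  lapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, "split", r)
    train <- with_seed(s, sort(sample.int(n_presence, n_train)))
    list(replicate_id = r, train = train,
         test = setdiff(seq_len(n_presence), train), seed = s)
  })
}

# Internal: default evaluation configuration.
eval_config <- function(config = list()) {
  defaults <- list(beta = 1.0, n_knots = 50, classes = NULL,
                   thresholds = seq(0, 1, by = 0.1),
                   pseudo_absence_n = NULL, split_fraction = 0.5,
                   tol = 1e-6, max_iter = 5000L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Replicate-based model evaluation
#'
#' Repeated-subsample validation: for each replicate the presences are split
#' per its plan, the model is fitted on the training half against the full
#' background, and scored. Training AUC uses training presences vs
#' background; test AUC uses test presences vs background; TSS uses test
#' presences vs the pseudo-absence set (the full background by default, or
#' a per-replicate subsample of `pseudo_absence_n` cells) on the 11-point
#' decile threshold grid. A mean logistic map over replicates is produced
#' when `stack` is supplied.
#'
#' @param occ an [occurrence_set()].
#' @param kinds named character vector of variable kinds.
#' @param stack optional `layer_stack` for the mean probability map.
#' @param config list of overrides: `beta`, `n_knots`, `classes`
#'   (default: auto rule at the training sample size), `thresholds`,
#'   `pseudo_absence_n`, `split_fraction`, `tol`, `max_iter`.
#' @param n_reps number of replicates (default 100).
#' @param seed master seed (ignored when `plans` given).
#' @param plans optional shared split plans from [make_split_plans()].
#' @param variables optional subset of variables to model (default all).
#' @return object of class `eval_report`: per-replicate metrics, aggregate
#'   mean/SD, the replicate-mean TSS curve and its optimal threshold, split
#'   plans, and the mean map (or `NULL`).
#' @export
run_replicates <- function(occ, kinds, stack = NULL, config = list(),
                           n_reps = 100, seed = 1L, plans = NULL,
                           variables = NULL) {
  cfg <- eval_config(config)
  pres <- occ$features_presence
  bg <- occ$features_background
  if (!is.null(variables)) {
    pres <- pres[, variables, drop = FALSE]
    bg <- bg[, variables, drop = FALSE]
  }
  if (is.null(plans))
    plans <- make_split_plans(nrow(pres), n_reps, cfg$split_fraction, seed)
  n_train <- length(plans[[1]]$train)
  classes <- if (is.null(cfg$classes)) feature_classes_auto(n_train)
  else cfg$classes
  expansion <- build_expansion(bg, kinds, classes = classes,
                               n_knots = cfg$n_knots)
  Xp <- expand_features(expansion, pres, warn_unseen = FALSE)
  Xb <- expand_features(expansion, bg, warn_unseen = FALSE)
  Xmap <- NULL; map_idx <- NULL
  if (!is.null(stack)) {
    vm <- valid_mask(stack)
    map_idx <- which(vm)
    cells <- as.data.frame(lapply(stack$layers, function(l)
      l$values[map_idx]))
    names(cells) <- names(stack$layers)
    Xmap <- expand_features(expansion, cells, warn_unseen = FALSE)
  }
  reps <- vector("list", length(plans))
  map_sum <- if (!is.null(Xmap)) numeric(length(map_idx)) else NULL
  tss_sum <- NULL
  for (k in seq_along(plans)) {
    pl <- plans[[k]]
    # each replicate is fitted cold so that any replicate re-run in
    # isolation reproduces its metrics bit-identically
    fit <- maxent_fit_mat(Xp[pl$train, , drop = FALSE], Xb, expansion,
                          beta = cfg$beta, tol = cfg$tol,
                          max_iter = cfg$max_iter)
    sc_bg <- predict_logistic(fit, Xb)
    sc_train <- predict_logistic(fit, Xp[pl$train, , drop = FALSE])
    sc_test <- predict_logistic(fit, Xp[pl$test, , drop = FALSE])
    pa <- if (is.null(cfg$pseudo_absence_n)) sc_bg else
      sc_bg[with_seed(derive_seed(pl$seed, "pseudoabs"),
                      sample.int(length(sc_bg), cfg$pseudo_absence_n))]
    curve <- tss_curve(sc_test, pa, cfg$thresholds)
    opt <- optimal_threshold(curve)
    tss_sum <- if (is.null(tss_sum)) curve[, -1] else tss_sum + curve[, -1]
    if (!is.null(Xmap)) map_sum <- map_sum + predict_logistic(fit, Xmap)
    reps[[k]] <- data.frame(replicate = pl$replicate_id,
                            train_auc = auc(sc_train, sc_bg),
                            test_auc = auc(sc_test, sc_bg),
                            max_tss = opt$tss,
                            opt_threshold = opt$threshold)
  }
  reps <- do.call(rbind, reps)
  summ <- data.frame(
    metric = c("train_auc", "test_auc", "max_tss"),
    mean = c(mean(reps$train_auc), mean(reps$test_auc), mean(reps$max_tss)),
    sd = c(stats::sd(reps$train_auc), stats::sd(reps$test_auc),
           stats::sd(reps$max_tss)))
  mean_curve <- cbind(threshold = cfg$thresholds,
                      tss_sum / length(plans))
  mean_curve <- as.data.frame(mean_curve)
  opt_mean <- optimal_threshold(mean_curve)
  mean_map <- NULL
  if (!is.null(Xmap)) {
    v <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
    v[map_idx] <- map_sum / length(plans)
    mean_map <- px_layer("mean_logistic", v, stack$spec)
  }
  structure(list(replicates = reps, summary = summ,
                 mean_tss_curve = mean_curve,
                 opt_threshold = opt_mean$threshold,
                 opt_tss = opt_mean$tss,
                 plans = plans, config = cfg, classes = classes,
                 variables = names(pres), mean_map = mean_map,
                 spec = if (is.null(stack)) NULL else stack$spec),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d replicates over %d variables\n",
              nrow(x$replicates), length(x$variables)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("max-TSS threshold (replicate-mean curve): %.4g (TSS %.4g)\n",
              x$opt_threshold, x$opt_tss))
  invisible(x)
}

#' Jackknife variable importance
#'
#' For every variable: refit with only that variable and with all variables
#' but that one, recording regularised training gains, plus the
#' all-variables gain. Fits use all presences. The variable with the
#' highest with-only gain carries the most predictive ability on its own;
#' the one whose omission drops the gain most carries the most information
#' absent from the others.
#'
#' @inheritParams run_replicates
#' @param variables variables to assess (>= 2; default all).
#' @param compute_without also fit the leave-one-out models (default TRUE;
#'   switch off when only the with-only ranking is needed).
#' @return object of class `jackknife_report` with a per-variable data
#'   frame (`gain_with_only`, `gain_without`) and `gain_all`.
#' @export
jackknife <- function(occ, kinds, config = list(), variables = NULL,
                      compute_without = TRUE) {
  cfg <- eval_config(config)
  pres <- occ$features_presence
  bg <- occ$features_background
  if (is.null(variables)) variables <- names(pres)
  if (length(variables) < 2) stop("jackknife needs at least 2 variables")
  pres <- pres[, variables, drop = FALSE]
  bg <- bg[, variables, drop = FALSE]
  classes <- if (is.null(cfg$classes)) feature_classes_auto(nrow(pres))
  else cfg$classes
  expansion <- build_expansion(bg, kinds, classes = classes,
                               n_knots = cfg$n_knots)
  Xp <- expand_features(expansion, pres, warn_unseen = FALSE)
  Xb <- expand_features(expansion, bg, warn_unseen = FALSE)
  fvar <- expansion$features$var
  fvar2 <- expansion$features$var2
  uses <- function(v) fvar == v | (!is.na(fvar2) & fvar2 == v)
  fit_gain <- function(idx, lambda0 = NULL) {
    fit <- maxent_fit_mat(Xp, Xb, expansion, beta = cfg$beta,
                          feature_idx = idx, tol = cfg$tol,
                          max_iter = cfg$max_iter, lambda0 = lambda0)
    training_gain(fit, Xp)  # model_eta subsets to the fit's features
  }
  all_idx <- seq_len(nrow(expansion$features))
  fit_all <- maxent_fit_mat(Xp, Xb, expansion, beta = cfg$beta,
                            tol = cfg$tol, max_iter = cfg$max_iter)
  gain_all <- training_gain(fit_all, Xp)
  rows <- lapply(variables, function(v) {
    only <- tryCatch(fit_gain(which(uses(v))),
                     error = function(e) stop("jackknife fit failed for ",
                                              "variable '", v, "': ",
                                              conditionMessage(e)))
    # leave-one-out fits warm-start from the all-variables solution
    without <- if (!compute_without) NA_real_ else
      tryCatch(fit_gain(which(!uses(v)),
                        lambda0 = fit_all$lambdas[!uses(v)]),
               error = function(e) stop("jackknife fit failed ",
                                        "without variable '", v,
                                        "': ", conditionMessage(e)))
    data.frame(variable = v, gain_with_only = only, gain_without = without)
  })
  structure(list(table = do.call(rbind, rows), gain_all = gain_all,
                 variables = variables),
            class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat(sprintf("jackknife_report: all-variables gain %.4f\n", x$gain_all))
  print(x$table[order(-x$table$gain_with_only), ], row.names = FALSE)
  invisible(x)
}

#' Permutation variable contribution
#'
#' Percent contribution of each variable to a fitted model, measured as the
#' drop in regularised training gain when that variable's values are
#' permuted jointly across presence and background records (mean over
#' `n_perm` permutations). Negative drops are floored at zero and the
#' result is normalised to sum to 100.
#'
#' @param model a fitted `maxent_model`.
#' @param presence,background the covariate tables the model was fitted on.
#' @param seed integer seed for the permutations.
#' @param n_perm permutations per variable (default 10).
#' @return named numeric vector of percentages summing to 100.
#' @export
contribution <- function(model, presence, background, seed = 1L,
                         n_perm = 10L) {
  expansion <- model$expansion
  vars <- unique(expansion$features$var[model$feature_idx])
  tab <- rbind(presence[, expansion$vars, drop = FALSE],
               background[, expansion$vars, drop = FALSE])
  m <- nrow(presence)
  Xall <- expand_features(expansion, tab, warn_unseen = FALSE)
  gain_of <- function(X) {
    eta <- drop(X[, model$feature_idx, drop = FALSE] %*% model$lambdas)
    lnZ <- lse(eta[-seq_len(m)])
    mean(eta[seq_len(m)]) - lnZ + log(model$n_background) -
      sum(model$beta_j * abs(model$lambdas))
  }
  g0 <- gain_of(Xall)
  fvar <- expansion$features$var
  fvar2 <- expansion$features$var2
  drops <- vapply(vars, function(v) {
    idx <- which(fvar == v | (!is.na(fvar2) & fvar2 == v))
    mean(vapply(seq_len(n_perm), function(r) {
      perm <- with_seed(derive_seed(seed, paste0("perm_", v), r),
                        sample.int(nrow(tab)))
      tab2 <- tab
      tab2[[v]] <- tab[[v]][perm]
      Xv <- expand_features_idx(expansion, tab2, idx)
      X2 <- Xall
      X2[, idx] <- Xv
      g0 - gain_of(X2)
    }, 0))
  }, 0)
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) drops[] <- 1  # degenerate: spread evenly
  100 * drops / sum(drops)
}

# Internal: expand only a subset of features (by row index into
# expansion$features); returns an n x length(idx) matrix.
expand_features_idx <- function(expansion, tab, idx) {
  sub <- expansion
  sub$features <- expansion$features[idx, , drop = FALSE]
  expand_features(sub, tab, warn_unseen = FALSE)
}

#' Correlation- and contribution-based variable selection
#'
#' Greedy pruning of collinear variables followed by a contribution floor:
#' while any pair of continuous variables has `|r| > r_cut` (Pearson, over
#' background cells), the member with the lower jackknife with-only gain is
#' removed; categorical variables are exempt from the correlation screen
#' (r is undefined for codes). Variables whose permutation contribution to
#' a model refitted on the retained set falls below `contrib_cut` percent
#' are then dropped.
#'
#' @param occ an [occurrence_set()].
#' @param kinds named character vector of variable kinds.
#' @param jk a `jackknife_report` covering the variables.
#' @param r_cut Pearson correlation cutoff (default 0.75).
#' @param contrib_cut percent-contribution floor (default 0.5).
#' @param config evaluation config overrides (see [run_replicates()]).
#' @param seed seed for the permutation contributions.
#' @return list with `retained`, `removed_correlation`,
#'   `removed_contribution` and the `contributions` vector.
#' @export
select_variables <- function(occ, kinds, jk, r_cut = 0.75,
                             contrib_cut = 0.5, config = list(), seed = 1L) {
  cfg <- eval_config(config)
  bg <- occ$features_background
  gains <- stats::setNames(jk$table$gain_with_only, jk$table$variable)
  retained <- jk$table$variable
  removed_cor <- character()
  repeat {
    cont <- retained[kinds[retained] == "continuous"]
    if (length(cont) < 2) break
    cm <- stats::cor(bg[, cont, drop = FALSE])
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (abs(cm[worst[1], worst[2]]) <= r_cut) break
    pair <- cont[worst]
    drop_var <- pair[which.min(gains[pair])]
    removed_cor <- c(removed_cor, drop_var)
    retained <- setdiff(retained, drop_var)
  }
  classes <- if (is.null(cfg$classes))
    feature_classes_auto(nrow(occ$features_presence)) else cfg$classes
  expansion <- build_expansion(bg[, retained, drop = FALSE], kinds,
                               classes = classes, n_knots = cfg$n_knots)
  model <- maxent_fit(occ$features_presence[, retained, drop = FALSE],
                      bg[, retained, drop = FALSE], expansion,
                      beta = cfg$beta, tol = cfg$tol,
                      max_iter = cfg$max_iter)
  contrib <- contribution(model, occ$features_presence[, retained,
                                                       drop = FALSE],
                          bg[, retained, drop = FALSE], seed = seed)
  removed_contrib <- names(contrib)[contrib < contrib_cut]
  list(retained = setdiff(retained, removed_contrib),
       removed_correlation = removed_cor,
       removed_contribution = removed_contrib,
       contributions = contrib)
}

#' Exact / approximate Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped before ranking; ties
#' among the absolute differences get midranks. For `n <= 25` (after
#' dropping zeros) the null distribution of the positive-rank sum `W` is
#' enumerated exactly via the rank generating polynomial (so midranks are
#' handled exactly); larger samples use the normal approximation with tie
#' and continuity correction.
#'
#' @param paired_a,paired_b equal-length numeric vectors; at least 5
#'   non-zero differences are required.
#' @param exact_limit switch point to the normal approximation.
#' @return list with `statistic` (W, the positive-rank sum), `p_value`
#'   (two-sided), `direction` (`"greater"`, `"less"` or `"none"`: the sign
#'   of the a-vs-b shift), `n` (pairs used) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_limit = 25L) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p_value = 1, direction = "none", n = 0,
                method = "degenerate"))
  }
  if (n < 5) stop("need at least 5 non-zero differences, have ", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- sum(r)
  if (n <= exact_limit) {
    # generating polynomial over doubled ranks (midranks -> integers)
    r2 <- as.integer(round(2 * r))
    coef <- rep(0, sum(r2) + 1)
    coef[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), coef[seq_len(length(coef) - rr)])
      coef <- coef + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(coef[seq_len(w2 + 1)]) / tot
    p_ge <- sum(coef[(w2 + 1):length(coef)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- S / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  direction <- if (W > S / 2) "greater" else if (W < S / 2) "less" else
    "none"
  list(statistic = W, p_value = p, direction = direction, n = n,
       method = method)
}
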