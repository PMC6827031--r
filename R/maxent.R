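#' Default feature-class rule by presence sample size
#'
#' Mirrors the auto-feature behaviour of the reference Maxent tool: with
#' `m` presences, `m < 10` uses linear features only; `10 <= m < 15` adds
#' quadratic; `15 <= m < 80` adds hinge; `m >= 80` activates all classes
#' (adding product and threshold).
#'
#' @param m number of presence records.
#' @return character vector of active feature classes.
#' @export
feature_classes_auto <- function(m) {
  if (m < 10) "linear"
  else if (m < 15) c("linear", "quadratic")
  else if (m < 80) c("linear", "quadratic", "hinge")
  else c("linear", "quadratic", "product", "threshold", "hinge")
}

#' Build a deterministic feature expansion
#'
#' Maps raw covariates to the maxent feature space. Continuous variables are
#' min-max scaled to `[0, 1]` using *background* bounds (values outside the
#' background range are clamped at prediction time); hinge and threshold
#' knots sit at background quantiles. Each categorical code observed in the
#' background yields exactly one indicator. The expansion is a pure function
#' of (background sample, variable kinds, class configuration).
#'
#' @param background data frame of background covariate values, one column
#'   per variable.
#' @param kinds named character vector, `"continuous"` or `"categorical"`
#'   per variable.
#' @param classes active feature classes, subset of
#'   `c("linear","quadratic","product","threshold","hinge")`; see
#'   [feature_classes_auto()].
#' @param n_knots number of hinge/threshold knots per variable (default 50).
#' @return object of class `feature_expansion`.
#' @export
build_expansion <- function(background, kinds,
                            classes = c("linear", "quadratic", "hinge"),
                            n_knots = 50) {
  stopifnot(nrow(background) > 0)
  vars <- names(background)
  if (!all(vars %in% names(kinds)))
    stop("kinds missing for: ",
         paste(setdiff(vars, names(kinds)), collapse = ", "))
  classes <- match.arg(classes, several.ok = TRUE)
  bounds <- list(); codes <- list()
  feats <- list()
  add <- function(name, var, type, knot = NA_real_, code = NA_real_,
                  var2 = NA_character_) {
    feats[[length(feats) + 1]] <<- data.frame(
      name = name, var = var, var2 = var2, type = type,
      knot = knot, code = code, stringsAsFactors = FALSE)
  }
  cont <- vars[kinds[vars] == "continuous"]
  for (v in vars) {
    if (kinds[[v]] == "categorical") {
      cds <- sort(unique(background[[v]][!is.na(background[[v]])]))
      codes[[v]] <- cds
      for (cd in cds) add(sprintf("cat:%s=%g", v, cd), v, "categorical",
                          code = cd)
      next
    }
    x <- background[[v]]
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (lo == hi) {
      warning("variable '", v, "' is constant over the background; ",
              "no features generated")
      next
    }
    bounds[[v]] <- c(lo, hi)
    if ("linear" %in% classes) add(paste0("linear:", v), v, "linear")
    if ("quadratic" %in% classes) add(paste0("quadratic:", v), v, "quadratic")
    if ("hinge" %in% classes || "threshold" %in% classes) {
      qs <- unique(stats::quantile(x, probs = seq_len(n_knots) /
                                     (n_knots + 1), na.rm = TRUE,
                                   names = FALSE, type = 7))
      if ("threshold" %in% classes) {
        for (k in qs[qs > lo & qs < hi])
          add(sprintf("threshold:%s@%.17g", v, k), v, "threshold", knot = k)
      }
      if ("hinge" %in% classes) {
        for (k in qs[qs < hi])
          add(sprintf("hinge:%s@%.17g", v, k), v, "hinge", knot = k)
        for (k in qs[qs > lo])
          add(sprintf("rhinge:%s@%.17g", v, k), v, "rhinge", knot = k)
      }
    }
  }
  if ("product" %in% classes && length(cont) >= 2) {
    prs <- utils::combn(cont, 2)
    for (i in seq_len(ncol(prs))) {
      v1 <- prs[1, i]; v2 <- prs[2, i]
      if (!is.null(bounds[[v1]]) && !is.null(bounds[[v2]]))
        add(sprintf("product:%s*%s", v1, v2), v1, "product", var2 = v2)
    }
  }
  feats <- do.call(rbind, feats)
  structure(list(vars = vars, kinds = kinds[vars], classes = classes,
                 bounds = bounds, codes = codes, features = feats,
                 n_knots = n_knots),
            class = "feature_expansion")
}

#' Apply a feature expansion to a covariate table
#'
#' @param expansion a `feature_expansion`.
#' @param tab data frame with (at least) the expansion's variables.
#' @param warn_unseen warn when a categorical code absent from the
#'   background appears (its indicators are all zero).
#' @return numeric matrix, one column per feature, named.
#' @export
expand_features <- function(expansion, tab, warn_unseen = TRUE) {
  n <- nrow(tab)
  fs <- expansion$features
  scaled <- list()
  for (v in names(expansion$bounds)) {
    b <- expansion$bounds[[v]]
    z <- (tab[[v]] - b[1]) / (b[2] - b[1])
    scaled[[v]] <- pmin(pmax(z, 0), 1)
  }
  if (warn_unseen) {
    for (v in names(expansion$codes)) {
      seen <- unique(tab[[v]][!is.na(tab[[v]])])
      extra <- setdiff(seen, expansion$codes[[v]])
      if (length(extra))
        warning("unseen categorical code(s) in '", v, "': ",
                paste(extra, collapse = ", "),
                "; their indicators are all zero")
    }
  }
  X <- matrix(0, n, nrow(fs), dimnames = list(NULL, fs$name))
  for (j in seq_len(nrow(fs))) {
    v <- fs$var[j]
    X[, j] <- switch(fs$type[j],
      linear = scaled[[v]],
      quadratic = scaled[[v]]^2,
      product = scaled[[v]] * scaled[[fs$var2[j]]],
      threshold = as.double(tab[[v]] >= fs$knot[j]),
      hinge = {
        b <- expansion$bounds[[v]]
        pmin(pmax((tab[[v]] - fs$knot[j]) / (b[2] - fs$knot[j]), 0), 1)
      },
      rhinge = {
        b <- expansion$bounds[[v]]
        pmin(pmax((fs$knot[j] - tab[[v]]) / (fs$knot[j] - b[1]), 0), 1)
      },
      categorical = as.double(tab[[v]] == fs$code[j]))
  }
  X[is.na(X)] <- 0
  X
}

# Internal: log-sum-exp.
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Internal: FISTA with backtracking + gradient restart for
#   min_l  lnZ(l) - fbar . l + sum(beta_j |l_j|)
# where lnZ is the log-partition over background rows of Xb.
# Deterministic; lambda0 allows warm starts.
fit_l1_maxent <- function(Xp, Xb, beta_j, tol = 1e-6, max_iter = 5000L,
                          lambda0 = NULL) {
  p <- ncol(Xb)
  fbar <- colMeans(Xp)
  g_of <- function(sb, l) lse(sb) - sum(fbar * l)
  x <- if (is.null(lambda0)) rep(0, p) else lambda0
  sb_x <- drop(Xb %*% x)
  gx <- g_of(sb_x, x)
  Fx <- gx + sum(beta_j * abs(x))
  y <- x; sb_y <- sb_x
  tk <- 1
  L <- 1
  converged <- FALSE
  grad <- NULL
  for (it in seq_len(max_iter)) {
    lnZ_y <- lse(sb_y)
    q <- exp(sb_y - lnZ_y)
    gy <- lnZ_y - sum(fbar * y)
    grad <- drop(crossprod(Xb, q)) - fbar
    L <- max(L / 1.5, 1e-4)
    repeat {
      x_new <- soft_threshold(y - grad / L, beta_j / L)
      d <- x_new - y
      sb_new <- drop(Xb %*% x_new)
      g_new <- g_of(sb_new, x_new)
      if (g_new <= gy + sum(grad * d) + (L / 2) * sum(d * d) + 1e-12) break
      L <- L * 2
      if (L > 1e12) break
    }
    F_new <- g_new + sum(beta_j * abs(x_new))
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / t_new
    # gradient-based adaptive restart
    if (sum((y - x_new) * (x_new - x)) > 0) { t_new <- 1; mom <- 0 }
    y <- x_new + mom * (x_new - x)
    # the momentum point is a linear combination of known iterates, so its
    # score vector needs no extra matrix-vector product
    sb_y <- sb_new + mom * (sb_new - sb_x)
    x <- x_new; sb_x <- sb_new
    tk <- t_new
    if (it > 1 && abs(Fx - F_new) < tol) {
      Fx <- F_new
      converged <- TRUE
      break
    }
    Fx <- F_new
  }
  if (!converged) {
    gnorm <- sqrt(sum(grad^2))
    stop("maxent fit did not converge in ", max_iter,
         " iterations (final gradient norm ", format(gnorm), ")")
  }
  lnZ <- lse(sb_x)
  q <- exp(sb_x - lnZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  list(lambdas = x, log_partition = lnZ, entropy = H, objective = -Fx,
       iterations = it, q = q)
}

#' Fit an L1-regularised maximum-entropy model
#'
#' Maximises the penalised log-likelihood of the presence sample relative to
#' the background (Gibbs) distribution:
#' `(1/m) sum_presence lambda . f(x) - ln sum_background e^{lambda . f(x)}
#'  - sum_j beta_j |lambda_j|`.
#' The problem is convex; the solver is a deterministic proximal-gradient
#' (FISTA) scheme with backtracking, run to an objective-change tolerance of
#' `1e-6` (`seed` is accepted for interface symmetry but no randomness is
#' used). Per-feature penalties are `beta * beta_class * s_j / sqrt(m)` with
#' `s_j` the background standard deviation of feature j.
#'
#' @param presence,background covariate data frames (rows = records).
#' @param expansion a `feature_expansion` built from the background.
#' @param beta global regularisation multiplier (default 1; 0 disables).
#' @param beta_class optional named per-class multipliers (default all 1).
#' @param seed unused placeholder for API stability.
#' @param tol objective-change convergence tolerance.
#' @param max_iter iteration cap; exceeded caps raise an error carrying the
#'   final gradient norm.
#' @param add_samples mirror the reference tool's default of adding any
#'   presence record whose feature combination is absent from the
#'   background to the fitting background (keeps the presence feature means
#'   inside the background feature hull, so the penalised objective stays
#'   bounded). Set `FALSE` for the strict given-background formulation.
#' @return object of class `maxent_model`.
#' @export
maxent_fit <- function(presence, background, expansion, beta = 1.0,
                       beta_class = NULL, seed = 1L, tol = 1e-6,
                       max_iter = 5000L, add_samples = TRUE) {
  if (nrow(presence) < 2) stop("need at least 2 presence records")
  if (nrow(background) < nrow(presence))
    stop("background must have at least as many rows as presence")
  Xp <- expand_features(expansion, presence, warn_unseen = FALSE)
  Xb <- expand_features(expansion, background, warn_unseen = FALSE)
  maxent_fit_mat(Xp, Xb, expansion, beta = beta, beta_class = beta_class,
                 tol = tol, max_iter = max_iter, add_samples = add_samples)
}

# Internal fast path: fit from prebuilt feature matrices (used by the
# replicate and jackknife loops, which expand once and subset columns).
# feature_idx restricts the model to a subset of the expansion's features.
maxent_fit_mat <- function(Xp, Xb, expansion, beta = 1.0, beta_class = NULL,
                           feature_idx = NULL, tol = 1e-6, max_iter = 5000L,
                           lambda0 = NULL, add_samples = TRUE) {
  if (is.null(feature_idx)) feature_idx <- seq_len(ncol(Xb))
  Xp <- Xp[, feature_idx, drop = FALSE]
  Xb <- Xb[, feature_idx, drop = FALSE]
  if (add_samples) {
    novel <- !duplicated(rbind(Xb, Xp))[nrow(Xb) + seq_len(nrow(Xp))]
    if (any(novel)) Xb <- rbind(Xb, Xp[novel, , drop = FALSE])
  }
  m <- nrow(Xp)
  s_j <- sqrt(pmax(colMeans(Xb^2) - colMeans(Xb)^2, 0))
  cls <- feature_class_of(expansion$features$type[feature_idx])
  mult <- rep(1, length(feature_idx))
  if (!is.null(beta_class)) {
    known <- intersect(names(beta_class), unique(cls))
    for (k in known) mult[cls == k] <- beta_class[[k]]
  }
  beta_j <- beta * mult * s_j / sqrt(m)
  # features constant over the background carry no information and can make
  # the objective unbounded; freeze them at zero
  active <- s_j > 0
  fit <- fit_l1_maxent(Xp[, active, drop = FALSE],
                       Xb[, active, drop = FALSE],
                       beta_j[active], tol = tol, max_iter = max_iter,
                       lambda0 = if (is.null(lambda0)) NULL else
                         lambda0[active])
  lambdas <- rep(0, length(feature_idx))
  lambdas[active] <- fit$lambdas
  names(lambdas) <- expansion$features$name[feature_idx]
  structure(list(expansion = expansion, feature_idx = feature_idx,
                 lambdas = lambdas, log_partition = fit$log_partition,
                 entropy = fit$entropy, beta = beta, beta_j = beta_j,
                 n_background = nrow(Xb), n_presence = m,
                 iterations = fit$iterations, objective = fit$objective),
            class = "maxent_model")
}

# Internal: feature type -> regularization class.
feature_class_of <- function(type) {
  ifelse(type %in% c("hinge", "rhinge"), "hinge",
         ifelse(type == "categorical", "categorical", type))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("maxent_model: %d features (%d nonzero), ",
                     "m = %d presences, N = %d background\n"),
              length(x$lambdas), sum(x$lambdas != 0), x$n_presence,
              x$n_background))
  cat(sprintf("  ln Z = %.6f, entropy H = %.6f, %d iterations\n",
              x$log_partition, x$entropy, x$iterations))
  invisible(x)
}

# Internal: linear predictor eta = lambda . f(x) for a covariate table or a
# prebuilt full-expansion matrix.
model_eta <- function(model, newdata) {
  X <- if (is.matrix(newdata)) newdata[, model$feature_idx, drop = FALSE]
  else expand_features(model$expansion, newdata)[, model$feature_idx,
                                                 drop = FALSE]
  drop(X %*% model$lambdas)
}

#' Raw (Gibbs) maxent prediction
#'
#' `raw(x) = e^{lambda . f(x) - ln Z}` with `ln Z` the log-partition over
#' the training background, so raw values over that background sum to 1.
#'
#' @param model a `maxent_model`.
#' @param newdata covariate data frame (or prebuilt expansion matrix).
#' @return numeric vector of raw probability mass per record.
#' @export
predict_raw <- function(model, newdata) {
  exp(model_eta(model, newdata) - model$log_partition)
}

#' Logistic maxent prediction
#'
#' The entropy-calibrated 0-1 suitability index:
#' `L(x) = e^H raw(x) / (1 + e^H raw(x))` with `H` the entropy of the fitted
#' raw distribution over the background (equivalent to assuming a default
#' prevalence of 0.5).
#'
#' @inheritParams predict_raw
#' @return numeric vector in `[0, 1]`.
#' @export
predict_logistic <- function(model, newdata) {
  v <- exp(model$entropy + model_eta(model, newdata) - model$log_partition)
  v / (1 + v)
}

#' Regularised training gain
#'
#' Average presence log-likelihood improvement over the uniform background
#' distribution, minus the L1 penalty:
#' `gain = (1/m) sum ln raw(x_i) + ln N_background - sum_j beta_j
#' |lambda_j|`. The uniform (all-zero) model has gain 0.
#'
#' @param model a `maxent_model`.
#' @param presence presence covariate table (or expansion matrix).
#' @return scalar gain in nats.
#' @export
training_gain <- function(model, presence) {
  mean(model_eta(model, presence)) - model$log_partition +
    log(model$n_background) - sum(model$beta_j * abs(model$lambdas))
}

#' Serialise a fitted model to a plain-text lambdas file
#'
#' Format: header lines `lnZ <value>`, `H <value>`, `N <background size>`,
#' then one CSV line per feature: `descriptor, lambda, scale_min,
#' scale_max`. Scale bounds are the background min/max used for feature
#' scaling (NA for categorical indicators and threshold features).
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lambdas <- function(model, path) {
  fs <- model$expansion$features[model$feature_idx, ]
  b <- model$expansion$bounds
  lo <- vapply(fs$var, function(v) if (is.null(b[[v]])) NA_real_ else
    b[[v]][1], 0)
  hi <- vapply(fs$var, function(v) if (is.null(b[[v]])) NA_real_ else
    b[[v]][2], 0)
  lines <- c(sprintf("lnZ %.17g", model$log_partition),
             sprintf("H %.17g", model$entropy),
             sprintf("N %d", model$n_background),
             sprintf("%s, %.17g, %.17g, %.17g", fs$name, model$lambdas,
                     lo, hi))
  writeLines(lines, path)
  invisible(path)
}

#' Read a lambdas file back into a predictor
#'
#' Reconstructs enough of a model (feature descriptors, weights, scaling
#' bounds, normaliser, entropy) to reproduce [predict_raw()] and
#' [predict_logistic()] output from an exchanged file.
#'
#' @param path lambdas file written by [write_lambdas()].
#' @return a `maxent_model`-compatible object.
#' @export
read_lambdas <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:3], " ")
  stopifnot(hdr[[1]][1] == "lnZ", hdr[[2]][1] == "H", hdr[[3]][1] == "N")
  rows <- strsplit(lines[-(1:3)], ",\\s*")
  name <- vapply(rows, `[`, "", 1)
  lambda <- as.numeric(vapply(rows, `[`, "", 2))
  # scale bounds are written as "NA" for indicator/threshold features
  lo <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3)))
  hi <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 4)))
  parsed <- parse_feature_names(name)
  bounds <- list()
  for (i in seq_along(name)) {
    v <- parsed$var[i]
    if (!is.na(lo[i]) && is.null(bounds[[v]])) bounds[[v]] <- c(lo[i], hi[i])
  }
  codes <- list()
  for (i in which(parsed$type == "categorical")) {
    v <- parsed$var[i]
    codes[[v]] <- sort(unique(c(codes[[v]], parsed$code[i])))
  }
  expansion <- structure(list(vars = unique(parsed$var),
                              kinds = NULL, classes = NULL, bounds = bounds,
                              codes = codes,
                              features = data.frame(
                                name = name, var = parsed$var,
                                var2 = parsed$var2, type = parsed$type,
                                knot = parsed$knot, code = parsed$code,
                                stringsAsFactors = FALSE)),
                         class = "feature_expansion")
  structure(list(expansion = expansion,
                 feature_idx = seq_along(name),
                 lambdas = stats::setNames(lambda, name),
                 log_partition = as.numeric(hdr[[1]][2]),
                 entropy = as.numeric(hdr[[2]][2]),
                 beta = NA_real_, beta_j = rep(0, length(name)),
                 n_background = as.integer(hdr[[3]][2]),
                 n_presence = NA_integer_, iterations = NA_integer_,
                 objective = NA_real_),
            class = "maxent_model")
}

# Internal: invert the feature descriptor naming scheme.
parse_feature_names <- function(name) {
  type <- sub(":.*$", "", name)
  type[type == "cat"] <- "categorical"
  rest <- sub("^[a-z]+:", "", name)
  var <- rest; var2 <- rep(NA_character_, length(name))
  knot <- rep(NA_real_, length(name)); code <- rep(NA_real_, length(name))
  at <- grepl("@", rest)
  var[at] <- sub("@.*$", "", rest[at])
  knot[at] <- as.numeric(sub("^.*@", "", rest[at]))
  eq <- type == "categorical"
  var[eq] <- sub("=.*$", "", rest[eq])
  code[eq] <- as.numeric(sub("^.*=", "", rest[eq]))
  pr <- type == "product"
  var[pr] <- sub("\\*.*$", "", rest[pr])
  var2[pr] <- sub("^.*\\*", "", rest[pr])
  list(var = var, var2 = var2, type = type, knot = knot, code = code)
}
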