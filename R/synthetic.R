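#' Gaussian random field layer
#'
#' Zero-mean, unit-variance stationary field with isotropic
#' squared-exponential correlation, generated by circular (FFT) Gaussian
#' kernel smoothing of seeded white noise and re-standardising. Used as a
#' stand-in for smooth environmental covariates (climate, vegetation
#' indices, altitude).
#'
#' @param spec target `grid_spec`.
#' @param correlation_length correlation length in map units (> 0); at or
#'   below one cell the field is effectively white noise.
#' @param seed integer seed; fields are bit-identical under the same seed.
#' @param name layer name.
#' @return a continuous `px_layer`.
#' @export
gaussian_random_field <- function(spec, correlation_length, seed = 1L,
                                  name = "grf") {
  stopifnot(correlation_length > 0)
  nr <- spec$n_rows; nc <- spec$n_cols
  noise <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  sigma <- correlation_length / spec$cell_size / sqrt(2)
  if (sigma > 1e-6) {
    dx <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    dy <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    kern <- exp(-outer(dy^2, dx^2, `+`) / (2 * sigma^2))
    sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                        inverse = TRUE)) / (nr * nc)
  } else sm <- noise
  sm <- (sm - mean(sm)) / stats::sd(c(sm))
  px_layer(name, sm, spec)
}

#' Quantile-bin a continuous field into spatially coherent classes
#'
#' @param field continuous `px_layer`.
#' @param n_codes number of classes (>= 2); codes are contiguous integers
#'   `1..n_codes` with approximately equal cell shares.
#' @param name output layer name.
#' @return a categorical `px_layer`.
#' @export
make_categorical <- function(field, n_codes, name = NULL) {
  stopifnot(n_codes >= 2)
  if (is.null(name)) name <- paste0(field$name, "_class")
  v <- field$values
  qs <- stats::quantile(v, probs = seq_len(n_codes - 1) / n_codes,
                        na.rm = TRUE, names = FALSE)
  codes <- findInterval(v, qs) + 1
  codes[is.na(v)] <- NA
  px_layer(name, matrix(codes, nrow(v), ncol(v)), field$spec,
           kind = "categorical")
}

#' Generate synthetic road / river / resident features
#'
#' Roads and rivers are random-walk polylines crossing the grid west to
#' east (heading jitter around due east); resident sites are points, either
#' uniform or clustered near a supplied road network (mimicking settlement
#' along roads).
#'
#' @param spec `grid_spec`.
#' @param kind `"road"`, `"river"` or `"resident"`.
#' @param n number of features (>= 1).
#' @param seed integer seed.
#' @param cluster_near optional `vector_features` (roads) to cluster
#'   resident points around.
#' @param cluster_sd Gaussian jitter (map units) for clustered residents.
#' @return a `vector_features` object.
#' @export
make_features <- function(spec, kind = c("road", "river", "resident"),
                          n = 1, seed = 1L, cluster_near = NULL,
                          cluster_sd = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  s <- spec$cell_size
  xmin <- spec$x_origin; xmax <- spec$x_origin + spec$n_cols * s
  ymin <- spec$y_origin - spec$n_rows * s; ymax <- spec$y_origin
  with_seed(seed, {
    if (kind %in% c("road", "river")) {
      lines <- lapply(seq_len(n), function(i) {
        y <- stats::runif(1, ymin + 0.1 * (ymax - ymin),
                          ymax - 0.1 * (ymax - ymin))
        x <- xmin
        step <- 2 * s
        pts <- matrix(c(x, y), 1)
        heading <- 0  # radians, 0 = due east
        while (x < xmax) {
          heading <- 0.7 * heading + stats::rnorm(1, 0, 0.35)
          x <- x + step * cos(heading)
          y <- min(max(y + step * sin(heading), ymin), ymax)
          pts <- rbind(pts, c(min(x, xmax), y))
        }
        pts
      })
      vector_features("polylines", lines, label = kind)
    } else {
      if (is.null(cluster_sd)) cluster_sd <- 5 * s
      if (is.null(cluster_near)) {
        pts <- cbind(stats::runif(n, xmin, xmax), stats::runif(n, ymin, ymax))
      } else {
        verts <- do.call(rbind, cluster_near$coordinates)
        pick <- sample.int(nrow(verts), n, replace = TRUE)
        pts <- verts[pick, , drop = FALSE] +
          matrix(stats::rnorm(2 * n, 0, cluster_sd), n, 2)
        pts[, 1] <- pmin(pmax(pts[, 1], xmin), xmax)
        pts[, 2] <- pmin(pmax(pts[, 2], ymin), ymax)
      }
      vector_features("points", list(pts), label = kind)
    }
  })
}

#' True suitability surface from a coefficient specification
#'
#' `suitability = logistic(intercept + sum linear_v z_v + sum quadratic_v
#' z_v^2 + categorical effects)` where `z_v` is the min-max scaling of
#' variable `v` over valid cells. This is the known generative truth the
#' recovery tests compare against.
#'
#' @param stack `layer_stack` holding every named variable.
#' @param truth list with `intercept` (scalar), `linear` / `quadratic`
#'   (named coefficient vectors on scaled variables) and `categorical`
#'   (named list: variable -> named vector of per-code effects).
#' @return a `px_layer` named `suitability` with values in `(0, 1)`.
#' @export
true_suitability <- function(stack, truth) {
  need <- c(names(truth$linear), names(truth$quadratic),
            names(truth$categorical))
  missing <- setdiff(need, names(stack$layers))
  if (length(missing)) stop("truth names unknown variable(s): ",
                            paste(missing, collapse = ", "))
  eta <- matrix(truth$intercept %||% 0, stack$spec$n_rows,
                stack$spec$n_cols)
  scale01 <- function(v) {
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    if (hi == lo) v * 0 else (v - lo) / (hi - lo)
  }
  for (v in names(truth$linear))
    eta <- eta + truth$linear[[v]] * scale01(stack$layers[[v]]$values)
  for (v in names(truth$quadratic))
    eta <- eta + truth$quadratic[[v]] * scale01(stack$layers[[v]]$values)^2
  for (v in names(truth$categorical)) {
    eff <- truth$categorical[[v]]
    vals <- stack$layers[[v]]$values
    add <- matrix(0, nrow(vals), ncol(vals))
    for (code in names(eff)) add[vals == as.numeric(code)] <- eff[[code]]
    add[is.na(vals)] <- NA
    eta <- eta + add
  }
  px_layer("suitability", stats::plogis(eta), stack$spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample presence points from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' `suitability x exp(-d_road / decay)` (the bias term emulating
#' road-accessible survey effort; omit `bias` for unbiased sampling), then
#' greedily thinned: a drawn point closer than `thin_distance` to an
#' earlier-accepted point is discarded (earlier point wins). Points sit at
#' cell centers. Draws continue until `n` points survive or the landscape
#' is exhausted.
#'
#' @param suitability `px_layer` in `[0, 1]`; nodata cells are excluded.
#' @param n requested number of presences (>= 1).
#' @param bias optional list `list(decay_length =, dist_road =)` with
#'   `dist_road` a distance-to-road `px_layer`.
#' @param thin_distance minimum pairwise distance (map units); 0 disables.
#' @param seed integer seed.
#' @return data frame of presence coordinates `x`, `y` (one row per cell).
#' @export
sample_presences <- function(suitability, n, bias = NULL, thin_distance = 0,
                             seed = 1L) {
  stopifnot(n >= 1)
  spec <- suitability$spec
  w <- suitability$values
  if (!is.null(bias)) {
    stopifnot(!is.null(bias$decay_length), bias$decay_length > 0)
    w <- w * exp(-bias$dist_road$values / bias$decay_length)
  }
  pool <- which(!is.na(w) & w > 0)
  if (length(pool) == 0) stop("no cell has positive sampling weight")
  ord <- pool[with_seed(seed, sample.int(length(pool), length(pool),
                                         prob = w[pool]))]
  ctr <- cell_center_xy(spec)
  rc <- arrayInd(ord, dim(w))
  xs <- ctr$x[rc[, 2]]; ys <- ctr$y[rc[, 1]]
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_along(ord)) {
    if (thin_distance > 0 && length(keep_x)) {
      d2 <- (keep_x - xs[i])^2 + (keep_y - ys[i])^2
      if (any(d2 < thin_distance^2)) next
    }
    keep_x <- c(keep_x, xs[i]); keep_y <- c(keep_y, ys[i])
    if (length(keep_x) == n) break
  }
  if (length(keep_x) == 0) stop("thinning eliminated all sampled points")
  if (length(keep_x) < n)
    warning("only ", length(keep_x), " of ", n,
            " requested presences survive thinning")
  data.frame(x = keep_x, y = keep_y)
}

#' Default synthetic-study configuration
#'
#' The stated world the recovery tests run in: a 100 x 100 grid of 1-km
#' cells with an elliptical lake nodata mask, five smooth continuous
#' covariates (climate / vegetation / altitude stand-ins), one categorical
#' soil layer, road / river / resident features with their distance maps
#' (9 layers in all), and 77 road-biased, 2-km-thinned presences from a
#' known logistic truth in which distance to road (strong negative), soil
#' type and one climate stand-in are informative.
#'
#' @param overrides named list of overrides; unknown keys are errors.
#' @return full configuration list.
#' @export
study_config <- function(overrides = list()) {
  defaults <- list(
    n_rows = 100, n_cols = 100, cell_size = 1,  # 1-km cells, units = km
    x_origin = 0, y_origin = 100,
    lake = list(cx = 65, cy = 40, rx = 18, ry = 12),
    grf_layers = list(bio8 = 25, bio4 = 25, evi_std = 8,
                      lst_day_mean = 15, altitude = 20),
    soil = list(correlation_length = 12, n_codes = 4),
    n_roads = 2, n_rivers = 1, n_residents = 15,
    n_presence = 77,
    # road effect calibrated to the reported response shape (~ -1 logit/km:
    # the half-probability contour sits near 1 km from roads when the other
    # factors are favourable); road proximity is necessary but not
    # sufficient: climate, altitude, settlement distance and soil carve the
    # road zone further, so suitable habitat is a minority of the landscape
    truth = list(intercept = 0.5,
                 linear = c(dis_to_road = -45, bio8 = 3, altitude = -3,
                            dis_to_resident = -4),
                 quadratic = NULL,
                 categorical = list(soil_type = c("1" = 1.5, "2" = 0.5,
                                                  "3" = -0.5, "4" = -1.5))),
    bias_decay = 10, thin_distance = 2)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown study config keys: ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

#' Generate a complete synthetic study
#'
#' One call producing the full reproducible bundle: covariate stack,
#' anthropogenic features, known truth, suitability surface and the biased,
#' thinned presence sample. Everything is a pure function of
#' `(config, seed)`.
#'
#' @param config from [study_config()] (or a list of overrides).
#' @param seed master seed; every internal draw derives from it.
#' @return object of class `synthetic_study` with elements `stack`,
#'   `roads`, `rivers`, `residents`, `truth`, `suitability`,
#'   `presence_xy`, `kinds`, `config`, `seed`.
#' @export
generate_study <- function(config = list(), seed = 1L) {
  if (is.null(config$n_rows)) config <- study_config(config)
  spec <- grid_spec(config$x_origin, config$y_origin, config$cell_size,
                    config$n_rows, config$n_cols)
  # elliptical lake nodata mask
  ctr <- cell_center_xy(spec)
  X <- matrix(rep(ctr$x, each = spec$n_rows), spec$n_rows)
  Y <- matrix(rep(ctr$y, times = spec$n_cols), spec$n_rows)
  lk <- config$lake
  in_lake <- ((X - lk$cx) / lk$rx)^2 + ((Y - lk$cy) / lk$ry)^2 <= 1
  mask_na <- function(l) {
    v <- l$values; v[in_lake] <- NA
    px_layer(l$name, v, l$spec, kind = l$kind)
  }
  layers <- list()
  i <- 0
  for (nm in names(config$grf_layers)) {
    i <- i + 1
    layers[[nm]] <- mask_na(gaussian_random_field(
      spec, config$grf_layers[[nm]], seed = derive_seed(seed, "grf", i),
      name = nm))
  }
  soil_field <- gaussian_random_field(spec, config$soil$correlation_length,
                                      seed = derive_seed(seed, "soil"),
                                      name = "soil")
  layers$soil_type <- mask_na(make_categorical(soil_field,
                                               config$soil$n_codes,
                                               name = "soil_type"))
  roads <- make_features(spec, "road", config$n_roads,
                         seed = derive_seed(seed, "roads"))
  rivers <- make_features(spec, "river", config$n_rivers,
                          seed = derive_seed(seed, "rivers"))
  residents <- make_features(spec, "resident", config$n_residents,
                             seed = derive_seed(seed, "residents"),
                             cluster_near = roads)
  layers$dis_to_road <- mask_na(euclidean_distance(roads, spec))
  layers$dis_to_river <- mask_na(euclidean_distance(rivers, spec))
  layers$dis_to_resident <- mask_na(euclidean_distance(residents, spec))
  stack <- layer_stack(unname(layers))
  kinds <- vapply(stack$layers, function(l) l$kind, "")
  suit <- true_suitability(stack, config$truth)
  presence_xy <- sample_presences(
    suit, config$n_presence,
    bias = if (is.null(config$bias_decay)) NULL else
      list(decay_length = config$bias_decay,
           dist_road = stack$layers$dis_to_road),
    thin_distance = config$thin_distance,
    seed = derive_seed(seed, "presences"))
  structure(list(stack = stack, roads = roads, rivers = rivers,
                 residents = residents, truth = config$truth,
                 suitability = suit, presence_xy = presence_xy,
                 kinds = kinds, config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d x %d grid, %d layers, %d presences, seed %d\n",
              x$stack$spec$n_rows, x$stack$spec$n_cols,
              length(x$stack$layers), nrow(x$presence_xy), x$seed))
  invisible(x)
}

#' Write a synthetic study bundle to a directory
#'
#' Rasters as ESRI ASCII grids, features as GeoJSON, presences as CSV,
#' truth and configuration as JSON, plus a manifest listing every file —
#' the same formats the modelling pipeline reads, so synthetic and real
#' runs share one code path.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return the manifest (character vector of files), invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (l in study$stack$layers) {
    f <- file.path(dir, paste0(l$name, ".asc"))
    write_ascii_grid(l, f)
    files <- c(files, f)
  }
  for (nm in c("roads", "rivers", "residents")) {
    f <- file.path(dir, paste0(nm, ".geojson"))
    write_features(study[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "presences.csv")
  utils::write.csv(study$presence_xy, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  truth_out <- study$truth
  for (nm in c("linear", "quadratic"))
    if (!is.null(truth_out[[nm]])) truth_out[[nm]] <- as.list(truth_out[[nm]])
  if (!is.null(truth_out$categorical))
    truth_out$categorical <- lapply(truth_out$categorical, as.list)
  jsonlite::write_json(truth_out, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  f <- file.path(dir, "config.json")
  cfg <- study$config
  cfg$kinds <- as.list(study$kinds)
  cfg$seed <- study$seed
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  manifest <- file.path(dir, "MANIFEST.txt")
  writeLines(c(paste("seed", study$seed),
               paste("pikasdm", as.character(utils::packageVersion("pikasdm"))),
               basename(files)), manifest)
  invisible(c(files, manifest))
}
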