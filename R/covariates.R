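#' Construct a vector feature set
#'
#' Simple container for the road / river / resident-site geometries the
#' anthropogenic covariates are derived from: either a set of points or a
#' set of polylines, in map units.
#'
#' @param kind `"points"` or `"polylines"`.
#' @param coordinates list of numeric matrices with columns x, y; one matrix
#'   per feature. Polylines need at least 2 vertices.
#' @param label feature label, e.g. `"road"`, `"river"`, `"resident"`.
#' @return object of class `vector_features`.
#' @export
vector_features <- function(kind = c("points", "polylines"), coordinates,
                            label = "") {
  kind <- match.arg(kind)
  coordinates <- lapply(coordinates, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("feature coordinates must be two-column (x, y)")
    if (!all(is.finite(m))) stop("feature coordinates must be finite")
    if (kind == "polylines" && nrow(m) < 2)
      stop("polylines need at least 2 vertices")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  })
  structure(list(kind = kind, coordinates = coordinates, label = label),
            class = "vector_features")
}

#' Read vector features from GeoJSON or CSV
#'
#' GeoJSON `Point`, `MultiPoint`, `LineString` and `MultiLineString`
#' geometries are supported (FeatureCollection, Feature, or bare geometry).
#' The CSV dialect has a header `feature_id,vertex_index,x,y`; rows are
#' grouped by `feature_id` and ordered by `vertex_index`.
#'
#' @param path file path (`.json`/`.geojson` or `.csv`).
#' @param label label to attach.
#' @return a `vector_features` object.
#' @export
read_features <- function(path, label = "") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("feature_id", "vertex_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("feature CSV needs columns ", paste(need, collapse = ", "))
    coords <- lapply(split(df, df$feature_id), function(g) {
      g <- g[order(g$vertex_index), ]
      as.matrix(g[, c("x", "y")])
    })
    kind <- if (all(vapply(coords, nrow, 1L) == 1)) "points" else "polylines"
    if (kind == "points")
      return(vector_features("points", list(do.call(rbind, coords)), label))
    return(vector_features("polylines", coords, label))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- list()
  push_geom <- function(g) geoms[[length(geoms) + 1]] <<- g
  walk <- function(node) {
    if (is.null(node$type)) return(invisible())
    switch(node$type,
           FeatureCollection = lapply(node$features, walk),
           Feature = walk(node$geometry),
           push_geom(node))
    invisible()
  }
  walk(gj)
  pts <- list(); lines <- list()
  to_mat <- function(cc) do.call(rbind, lapply(cc, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  for (g in geoms) {
    switch(g$type,
           Point = { pts[[length(pts) + 1]] <- matrix(
             c(as.numeric(g$coordinates[[1]]),
               as.numeric(g$coordinates[[2]])), 1) },
           MultiPoint = { pts[[length(pts) + 1]] <- to_mat(g$coordinates) },
           LineString = { lines[[length(lines) + 1]] <- to_mat(g$coordinates) },
           MultiLineString = { for (part in g$coordinates)
             lines[[length(lines) + 1]] <- to_mat(part) },
           stop("unsupported GeoJSON geometry: ", g$type))
  }
  if (length(lines))
    vector_features("polylines", lines, label)
  else if (length(pts))
    vector_features("points", list(do.call(rbind, pts)), label)
  else stop("no usable geometry in ", path)
}

#' Write vector features as GeoJSON
#'
#' @param features a `vector_features` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  geom <- function(m) {
    if (features$kind == "points" && nrow(m) == 1)
      list(type = "Point", coordinates = c(m[1, 1], m[1, 2]))
    else if (features$kind == "points")
      list(type = "MultiPoint",
           coordinates = lapply(seq_len(nrow(m)), function(i) m[i, ]))
    else
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(i) m[i, ]))
  }
  fc <- list(type = "FeatureCollection",
             features = lapply(features$coordinates, function(m)
               list(type = "Feature",
                    properties = list(label = features$label),
                    geometry = geom(m))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Internal: pad a matrix by replicating its edge rows/columns.
pad_replicate <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Computes the 3x3 Horn finite-difference gradient on each cell. Grid edges
#' use edge-replication padding. Slope is returned in degrees in `[0, 90]`;
#' aspect in degrees clockwise from north in `[0, 360)`, with flat cells set
#' to the sentinel `-1`. Cells with any nodata neighbour are nodata.
#'
#' @param dem continuous `px_layer`, at least 3x3.
#' @return list with `slope` and `aspect` layers.
#' @export
slope_aspect <- function(dem) {
  if (dem$kind != "continuous") stop("DEM must be a continuous layer")
  nr <- dem$spec$n_rows; nc <- dem$spec$n_cols
  if (nr < 3 || nc < 3) stop("DEM must be at least 3 x 3")
  s <- dem$spec$cell_size
  z <- pad_replicate(dem$values)
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  nw <- z[i - 1, j - 1]; n_ <- z[i - 1, j]; ne <- z[i - 1, j + 1]
  w_ <- z[i, j - 1];                         e_ <- z[i, j + 1]
  sw <- z[i + 1, j - 1]; s_ <- z[i + 1, j]; se <- z[i + 1, j + 1]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * s)  # d z / d east
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * s)  # d z / d north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # downslope direction (-gx, -gy), angle clockwise from north
  aspect <- atan2(-gx, -gy) * 180 / pi
  aspect <- (aspect + 360) %% 360
  flat <- !is.na(gx) & gx == 0 & gy == 0
  aspect[flat] <- -1
  slope[is.na(dem$values)] <- NA
  aspect[is.na(dem$values)] <- NA
  list(slope = px_layer(paste0(dem$name, "_slope"), slope, dem$spec),
       aspect = px_layer(paste0(dem$name, "_aspect"), aspect, dem$spec))
}

# Internal: D8 flow accumulation (count of upstream cells draining through
# each cell). Steepest-descent receiver; ties broken by the first direction
# in clockwise order from north (N, NE, E, SE, S, SW, W, NW).
d8_accumulation <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # clockwise from north: (drow, dcol)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dist <- ifelse(dr != 0 & dc != 0, sqrt(2), 1) * dem$spec$cell_size
  recv <- matrix(NA_integer_, nr, nc)  # linear index of receiver
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    best <- 0; besti <- NA_integer_
    for (k in 1:8) {
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(z[r2, c2])) next
      drop <- (z[r, c] - z[r2, c2]) / dist[k]
      if (drop > best) { best <- drop; besti <- (c2 - 1) * nr + r2 }
    }
    recv[r, c] <- besti  # NA: pit or flat, drains nowhere
  }
  acc <- matrix(0, nr, nc)
  ord <- order(z, decreasing = TRUE, na.last = NA)
  for (cell in ord) {
    to <- recv[cell]
    if (!is.na(to)) acc[to] <- acc[to] + acc[cell] + 1
  }
  acc[is.na(z)] <- NA
  acc
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(beta))` with `a = (flow accumulation count + 1) *
#' cell_size` (upslope contributing area per unit contour width) from
#' single-direction D8 routing, and `beta` the Horn slope. `tan(beta)` is
#' floored at `eps` so flat cells stay finite.
#'
#' @param dem continuous `px_layer`.
#' @param eps floor for `tan(beta)`; default 0.001.
#' @return a `px_layer` named `<dem>_twi`.
#' @export
twi <- function(dem, eps = 0.001) {
  acc <- d8_accumulation(dem)
  sl <- slope_aspect(dem)$slope$values
  tanb <- pmax(tan(sl * pi / 180), eps)
  a <- (acc + 1) * dem$spec$cell_size
  px_layer(paste0(dem$name, "_twi"), log(a / tanb), dem$spec)
}

# Internal: squared distance from points (px, py) to segment (x1,y1)-(x2,y2).
dist2_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Euclidean distance map to vector features
#'
#' Each cell holds the minimum Euclidean distance (map units) from the cell
#' center to any feature point or polyline segment — measured against the
#' true vector geometry, not a rasterised copy.
#'
#' @param features non-empty `vector_features`.
#' @param spec target `grid_spec`.
#' @param name output layer name; default `dis_to_<label>`.
#' @return a continuous `px_layer`.
#' @export
euclidean_distance <- function(features, spec, name = NULL) {
  if (length(features$coordinates) == 0) stop("empty feature set")
  if (is.null(name))
    name <- paste0("dis_to_", if (nzchar(features$label))
      features$label else "feature")
  ctr <- cell_center_xy(spec)
  px <- rep(ctr$x, each = spec$n_rows)
  py <- rep(ctr$y, times = spec$n_cols)
  best <- rep(Inf, length(px))
  for (m in features$coordinates) {
    if (features$kind == "points" || nrow(m) == 1) {
      for (i in seq_len(nrow(m)))
        best <- pmin(best, (px - m[i, 1])^2 + (py - m[i, 2])^2)
    } else {
      for (i in seq_len(nrow(m) - 1))
        best <- pmin(best, dist2_to_segment(px, py, m[i, 1], m[i, 2],
                                            m[i + 1, 1], m[i + 1, 2]))
    }
  }
  px_layer(name, matrix(sqrt(best), spec$n_rows, spec$n_cols), spec)
}

#' Buffer mask around vector features
#'
#' 0/1 layer: 1 iff the cell center lies within `radius` of the features.
#' Composable with [sample_background()] as a bias-correction mask (e.g. the
#' 10-km road zone used to offset roadside survey bias).
#'
#' @param features `vector_features`.
#' @param spec target `grid_spec`.
#' @param radius buffer radius, map units; must be > 0.
#' @return a `px_layer` of 0/1 values.
#' @export
buffer_mask <- function(features, spec, radius) {
  stopifnot(radius > 0)
  d <- euclidean_distance(features, spec)
  px_layer(paste0("buffer_", if (nzchar(features$label))
    features$label else "feature"),
    (d$values <= radius) * 1, spec)
}

#' Construct a raster time-series cube
#'
#' @param spec `grid_spec`.
#' @param timestamps strictly increasing numeric vector, length T.
#' @param values numeric array `T x n_rows x n_cols`.
#' @return object of class `ts_cube`.
#' @export
ts_cube <- function(spec, timestamps, values) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(timestamps),
            dim(values)[2] == spec$n_rows, dim(values)[3] == spec$n_cols,
            all(diff(timestamps) > 0))
  structure(list(spec = spec, timestamps = as.double(timestamps),
                 values = values), class = "ts_cube")
}

# Internal: Savitzky-Golay weight matrix (T x T). Row t gives the weights of
# the local polynomial fit evaluated at step t; edge rows use the truncated
# window. Coefficients come from local least squares, so any (window, order)
# pair works.
sg_weights <- function(T, window, order) {
  h <- (window - 1) %/% 2
  W <- matrix(0, T, T)
  for (t in seq_len(T)) {
    lo <- max(1, t - h); hi <- min(T, t + h)
    idx <- lo:hi
    X <- outer(idx - t, 0:order, `^`)
    # row of the hat matrix at the evaluation point (offset 0)
    XtX <- crossprod(X)
    w <- solve(XtX, t(X))[1, ]
    W[t, idx] <- w
  }
  W
}

#' Savitzky-Golay smoothing of a time-series cube
#'
#' Per-cell local least-squares polynomial smoothing, the standard noise
#' filter for satellite vegetation-index series. Edges are handled by
#' fitting the polynomial on the truncated window. A series that *is* a
#' polynomial of degree <= `order` is reproduced exactly.
#'
#' @param cube a `ts_cube`.
#' @param window odd window length.
#' @param order polynomial order, `< window`.
#' @return a smoothed `ts_cube` on the same grid and timestamps.
#' @export
savitzky_golay <- function(cube, window = 5, order = 2) {
  if (window %% 2 == 0) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  T <- dim(cube$values)[1]
  if (T < window) stop("series shorter than the smoothing window")
  W <- sg_weights(T, window, order)
  V <- matrix(cube$values, nrow = T)  # T x (nr*nc)
  out <- W %*% V
  out[is.na(V)] <- NA  # nodata steps stay nodata
  ts_cube(cube$spec, cube$timestamps,
          array(out, dim = dim(cube$values)))
}

#' Per-cell summary statistics of a time-series cube
#'
#' Mean, maximum, minimum and standard deviation over time for every cell.
#' The standard deviation uses the population divisor `n` (the statistics
#' summarise a fixed observation year, not a sample). Cells that are nodata
#' at every time step are nodata in all four outputs.
#'
#' @param cube a `ts_cube` with at least 2 time steps.
#' @param name base layer name; outputs are suffixed `_mean`, `_max`,
#'   `_min`, `_std`.
#' @return list of four `px_layer`s.
#' @export
series_stats <- function(cube, name = "series") {
  T <- dim(cube$values)[1]
  if (T < 2) stop("need at least 2 time steps")
  V <- matrix(cube$values, nrow = T)
  n_ok <- colSums(!is.na(V))
  mu <- colMeans(V, na.rm = TRUE)
  mx <- suppressWarnings(apply(V, 2, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(V, 2, min, na.rm = TRUE))
  sd_pop <- sqrt(pmax(colMeans(V^2, na.rm = TRUE) - mu^2, 0))
  bad <- n_ok == 0
  mu[bad] <- NA; mx[bad] <- NA; mn[bad] <- NA; sd_pop[bad] <- NA
  shape <- function(v) matrix(v, cube$spec$n_rows, cube$spec$n_cols)
  list(mean = px_layer(paste0(name, "_mean"), shape(mu), cube$spec),
       max = px_layer(paste0(name, "_max"), shape(mx), cube$spec),
       min = px_layer(paste0(name, "_min"), shape(mn), cube$spec),
       std = px_layer(paste0(name, "_std"), shape(sd_pop), cube$spec))
}

#' Terrain covariates with configurable processing order
#'
#' Derives slope, aspect and TWI from a DEM, optionally on a coarser target
#' grid. The aggregation order is genuinely ambiguous in common GIS
#' practice, so both are exposed: `"derive_first"` computes the terrain
#' variables at the DEM's native resolution and bilinearly resamples them;
#' `"resample_first"` resamples the DEM and derives terrain variables on
#' the target grid. No claim is made that either is canonical.
#'
#' @param dem continuous `px_layer`.
#' @param to optional target `grid_spec` (default: the DEM's own grid).
#' @param order `"derive_first"` or `"resample_first"`.
#' @param eps TWI slope floor, passed to [twi()].
#' @return list of `px_layer`s: `slope`, `aspect`, `twi` (and `dem`, the
#'   resampled DEM when a target grid was given).
#' @export
terrain_covariates <- function(dem, to = NULL,
                               order = c("derive_first", "resample_first"),
                               eps = 0.001) {
  order <- match.arg(order)
  if (is.null(to) || spec_aligned(dem$spec, to)) {
    sa <- slope_aspect(dem)
    return(list(slope = sa$slope, aspect = sa$aspect, twi = twi(dem, eps),
                dem = dem))
  }
  if (order == "resample_first") {
    dem2 <- resample_layer(dem, to, "bilinear")
    sa <- slope_aspect(dem2)
    list(slope = sa$slope, aspect = sa$aspect, twi = twi(dem2, eps),
         dem = dem2)
  } else {
    sa <- slope_aspect(dem)
    list(slope = resample_layer(sa$slope, to, "bilinear"),
         # aspect is circular; nearest avoids averaging across 0/360
         aspect = resample_layer(sa$aspect, to, "nearest"),
         twi = resample_layer(twi(dem, eps), to, "bilinear"),
         dem = resample_layer(dem, to, "bilinear"))
  }
}
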