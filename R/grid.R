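# Internal: evaluate expr under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the pipeline flows through a hierarchical seed scheme:
#' each stage (and each replicate within a stage) derives its own seed from
#' the master seed, a stage label, and an integer id, so stages can be re-run
#' in isolation and scenario runs can share split plans. The result is always
#' a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"replicate"`, `"background"`).
#' @param id integer id within the stage (default 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage, id = 0L) {
  h <- as.double(utf8ToInt(paste0(stage, ":")))
  acc <- (as.double(master) %% 2147483647) + 1
  for (v in c(h, as.double(id) + 1)) {
    acc <- (acc * 48271 + v) %% 2147483647
  }
  as.integer(acc %% 2147483562 + 1)
}

#' Define a raster grid
#'
#' A `grid_spec` describes a north-up raster of square cells. `y_origin` is
#' the *north* edge: cell `(r, c)` (1-based) covers the half-open square
#' `[x_origin + (c-1) s, x_origin + c s)` by
#' `(y_origin - r s, y_origin - (r-1) s]`, so row 1 is the northernmost row.
#' Two specs are aligned iff all fields except `crs_tag` are equal.
#'
#' @param x_origin,y_origin west and north edge of the grid, map units.
#' @param cell_size side of the square cells, map units; must be > 0.
#' @param n_rows,n_cols grid dimensions, both >= 1.
#' @param nodata sentinel value used on disk for missing cells.
#' @param crs_tag opaque CRS string carried through unchanged.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(x_origin, y_origin, cell_size, n_rows, n_cols,
                      nodata = -9999, crs_tag = "") {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(list(x_origin = as.double(x_origin),
                 y_origin = as.double(y_origin),
                 cell_size = as.double(cell_size),
                 n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 nodata = as.double(nodata),
                 crs_tag = as.character(crs_tag)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %.6g, origin (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  invisible(x)
}

#' Test whether two grid specs are aligned
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` iff all fields except `crs_tag` agree.
#' @export
spec_aligned <- function(a, b) {
  isTRUE(all.equal(a$x_origin, b$x_origin)) &&
    isTRUE(all.equal(a$y_origin, b$y_origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$nodata, b$nodata))
}

#' Construct a raster layer
#'
#' Layers hold an `n_rows x n_cols` value matrix (row 1 = north) with `NA`
#' marking nodata cells; the disk sentinel lives in the `grid_spec`.
#' Categorical layers must contain only integer codes (or `NA`).
#'
#' @param name layer name, unique within a stack (e.g. `"dis_to_road"`).
#' @param values numeric matrix, `NA` for nodata.
#' @param spec the `grid_spec` the layer sits on.
#' @param kind `"continuous"` or `"categorical"`.
#' @return an object of class `px_layer`.
#' @export
px_layer <- function(name, values, spec, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values must be ", spec$n_rows, " x ", spec$n_cols)
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layer '", name, "' contains non-integer codes")
  }
  structure(list(name = name, kind = kind, values = values, spec = spec),
            class = "px_layer")
}

#' @export
print.px_layer <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("px_layer '%s' (%s): %d x %d, range [%.4g, %.4g], %d nodata\n",
              x$name, x$kind, nrow(x$values), ncol(x$values),
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Bundle aligned layers into a stack
#'
#' @param layers list of `px_layer` objects on identical specs, unique names.
#' @return an object of class `layer_stack` with elements `spec` and `layers`
#'   (a named list).
#' @export
layer_stack <- function(layers) {
  stopifnot(length(layers) >= 1)
  spec <- layers[[1]]$spec
  nms <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  for (l in layers) {
    if (!spec_aligned(spec, l$spec))
      stop("layer '", l$name, "' is not aligned with the stack grid")
  }
  names(layers) <- nms
  structure(list(spec = spec, layers = layers), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack: %d layers on %d x %d grid\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols))
  for (l in x$layers) cat(sprintf("  %-18s %s\n", l$name, l$kind))
  invisible(x)
}

#' Logical mask of valid (modelable) cells
#'
#' A cell is valid iff *no* layer holds nodata there: nodata propagates.
#'
#' @param stack a `layer_stack`.
#' @return logical matrix, `TRUE` where every layer has data.
#' @export
valid_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) m <- m & !is.na(l$values)
  m
}

# Internal: cell-center coordinates for every cell, in matrix layout.
cell_center_xy <- function(spec) {
  s <- spec$cell_size
  xc <- spec$x_origin + (seq_len(spec$n_cols) - 0.5) * s
  yc <- spec$y_origin - (seq_len(spec$n_rows) - 0.5) * s
  list(x = xc, y = yc)
}

# Internal: map coordinates -> (row, col), half-open cells, east/south grid
# edge clamped inward. Returns row/col = NA for points outside the grid.
xy_to_rowcol <- function(spec, x, y) {
  s <- spec$cell_size
  col <- floor((x - spec$x_origin) / s) + 1
  row <- floor((spec$y_origin - y) / s) + 1
  xmax <- spec$x_origin + spec$n_cols * s
  ymin <- spec$y_origin - spec$n_rows * s
  col[x == xmax] <- spec$n_cols
  row[y == ymin] <- spec$n_rows
  # north edge: y == y_origin belongs to row 1 per the half-open convention
  row[y == spec$y_origin] <- 1
  inside <- x >= spec$x_origin & x <= xmax & y >= ymin & y <= spec$y_origin
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Read a raster layer from disk
#'
#' Supports the ESRI ASCII grid format (keywords `ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`, all case-insensitive). GeoTIFF is not supported in this
#' build and is rejected with a clear message.
#'
#' @param path file path (`.asc`/`.txt` ESRI ASCII).
#' @param kind `"continuous"` or `"categorical"`.
#' @param name layer name; defaults to the file base name.
#' @return a `px_layer` (its `spec` field carries the `grid_spec`).
#' @export
read_raster <- function(path, kind = c("continuous", "categorical"),
                        name = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported in this build; ",
         "convert to ESRI ASCII grid (.asc)")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  read_ascii_grid(path, kind = kind, name = name)
}

read_ascii_grid <- function(path, kind, name) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(nodata_value = -9999)
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value", "dx", "dy"))
      break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]])) stop("ESRI ASCII header missing ", req)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("non-square cells (dx != dy) are not supported")
  s <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - s / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - s / 2
  if (is.null(xll) || is.null(yll)) stop("ESRI ASCII header missing origin")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  spec <- grid_spec(x_origin = xll, y_origin = yll + nr * s, cell_size = s,
                    n_rows = nr, n_cols = nc, nodata = hdr$nodata_value)
  px_layer(name, m, spec, kind = kind)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a `px_layer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  spec <- layer$spec
  m <- layer$values
  m[is.na(m)] <- spec$nodata
  hdr <- c(sprintf("ncols %d", spec$n_cols),
           sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.10g", spec$x_origin),
           sprintf("yllcorner %.10g", spec$y_origin -
                     spec$n_rows * spec$cell_size),
           sprintf("cellsize %.10g", spec$cell_size),
           sprintf("NODATA_value %.10g", spec$nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a layer onto a target grid
#'
#' Continuous layers use bilinear interpolation between source cell centers
#' (output bounded by the input range); categorical layers must use
#' nearest-neighbour (the value set of the output is a subset of the
#' input's). Any nodata among the contributing source cells yields nodata.
#'
#' @param layer a `px_layer`.
#' @param to target `grid_spec`.
#' @param method `"bilinear"` or `"nearest"`; bilinear is rejected for
#'   categorical layers.
#' @return a `px_layer` on `to`.
#' @export
resample_layer <- function(layer, to, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (layer$kind == "categorical" && method == "bilinear")
    stop("bilinear resampling is not valid for categorical layer '",
         layer$name, "'; use nearest")
  from <- layer$spec
  tc <- cell_center_xy(to)
  # fractional source center-space coordinates of every target center
  u <- (rep(tc$x, each = to$n_rows) - from$x_origin) / from$cell_size - 0.5
  v <- (from$y_origin - rep(tc$y, times = to$n_cols)) / from$cell_size - 0.5
  u <- pmin(pmax(u, 0), from$n_cols - 1)
  v <- pmin(pmax(v, 0), from$n_rows - 1)
  if (method == "nearest") {
    ci <- round(u) + 1
    ri <- round(v) + 1
    out <- layer$values[cbind(ri, ci)]
  } else {
    c0 <- pmin(floor(u), from$n_cols - 2); c0 <- pmax(c0, 0)
    r0 <- pmin(floor(v), from$n_rows - 2); r0 <- pmax(r0, 0)
    if (from$n_cols == 1) c0 <- rep(0, length(u))
    if (from$n_rows == 1) r0 <- rep(0, length(v))
    fu <- u - c0
    fv <- v - r0
    c1 <- pmin(c0 + 1, from$n_cols - 1)
    r1 <- pmin(r0 + 1, from$n_rows - 1)
    z00 <- layer$values[cbind(r0 + 1, c0 + 1)]
    z01 <- layer$values[cbind(r0 + 1, c1 + 1)]
    z10 <- layer$values[cbind(r1 + 1, c0 + 1)]
    z11 <- layer$values[cbind(r1 + 1, c1 + 1)]
    out <- (1 - fv) * ((1 - fu) * z00 + fu * z01) +
      fv * ((1 - fu) * z10 + fu * z11)
  }
  px_layer(layer$name, matrix(out, to$n_rows, to$n_cols), to,
           kind = layer$kind)
}

#' Extract layer values at point locations
#'
#' Looks up, for every `(x, y)` point, the containing grid cell and each
#' layer's value there. Points outside the grid get an error record
#' (`inside = FALSE`) rather than being dropped; points on cells where any
#' layer is nodata are flagged `valid = FALSE`.
#'
#' @param stack a `layer_stack`.
#' @param xy data frame or matrix with columns `x`, `y`.
#' @return data frame with columns `x`, `y`, `row`, `col`, `inside`, `valid`
#'   then one column per layer.
#' @export
extract_at_points <- function(stack, xy) {
  xy <- as.data.frame(xy)
  stopifnot(all(c("x", "y") %in% names(xy)))
  rc <- xy_to_rowcol(stack$spec, xy$x, xy$y)
  vm <- valid_mask(stack)
  idx <- cbind(rc$row, rc$col)
  valid <- rep(FALSE, nrow(xy))
  ok <- rc$inside
  valid[ok] <- vm[idx[ok, , drop = FALSE]]
  out <- data.frame(x = xy$x, y = xy$y, row = rc$row, col = rc$col,
                    inside = rc$inside, valid = valid)
  for (l in stack$layers) {
    v <- rep(NA_real_, nrow(xy))
    v[ok] <- l$values[idx[ok, , drop = FALSE]]
    out[[l$name]] <- v
  }
  out
}

#' Sample background cells
#'
#' Draws `n` distinct valid cells uniformly without replacement, optionally
#' restricted to a bias-correction mask (e.g. a 10-km road buffer from
#' [buffer_mask()]). One background point per cell, at the cell center.
#'
#' @param stack a `layer_stack`.
#' @param n number of background cells.
#' @param bias_mask optional 0/1 `px_layer`; only cells with mask value 1 are
#'   eligible.
#' @param seed integer seed; same seed, same sample.
#' @return list with `cells` (integer matrix row/col), `xy` (data frame of
#'   cell-center coordinates) and `features` (per-cell layer table).
#' @export
sample_background <- function(stack, n, bias_mask = NULL, seed = 1L) {
  vm <- valid_mask(stack)
  if (!is.null(bias_mask)) {
    if (!spec_aligned(bias_mask$spec, stack$spec))
      stop("bias_mask grid is not aligned with the stack")
    vm <- vm & !is.na(bias_mask$values) & bias_mask$values == 1
  }
  pool <- which(vm)
  if (n > length(pool))
    stop("requested ", n, " background cells but only ", length(pool),
         " valid cells are available (deficit ", n - length(pool), ")")
  sel <- pool[with_seed(seed, sample.int(length(pool), n))]
  rc <- arrayInd(sel, dim(vm))
  ctr <- cell_center_xy(stack$spec)
  xy <- data.frame(x = ctr$x[rc[, 2]], y = ctr$y[rc[, 1]])
  feats <- as.data.frame(lapply(stack$layers, function(l) l$values[rc]))
  names(feats) <- names(stack$layers)
  list(cells = rc, xy = xy, features = feats)
}

#' Assemble an occurrence set
#'
#' Binds presence coordinates and a background sample together with their
#' extracted feature tables. Presence points must fall inside the grid on
#' valid cells; offending points are reported by index.
#'
#' @param stack a `layer_stack`.
#' @param presence_xy data frame with columns `x`, `y`.
#' @param background result of [sample_background()].
#' @return list of class `occurrence_set` with `presence_xy`,
#'   `background_cells`, `features_presence`, `features_background`.
#' @export
occurrence_set <- function(stack, presence_xy, background) {
  ext <- extract_at_points(stack, presence_xy)
  if (any(!ext$inside))
    stop("presence points outside the grid: index ",
         paste(which(!ext$inside), collapse = ", "))
  if (any(!ext$valid))
    stop("presence points on nodata cells: index ",
         paste(which(!ext$valid), collapse = ", "))
  structure(list(presence_xy = ext[, c("x", "y")],
                 background_cells = background$cells,
                 features_presence = ext[, names(stack$layers), drop = FALSE],
                 features_background = background$features),
            class = "occurrence_set")
}

#' Read occurrence points from CSV
#'
#' Expects a header with columns `x,y` (extra columns are carried along).
#'
#' @param path CSV path.
#' @return data frame with at least columns `x` and `y`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("occurrence CSV must have columns 'x' and 'y'")
  df
}
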