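# Shared toy fixtures, all built in code at test time.

toy_spec <- function(nr = 4, nc = 4, s = 1, x0 = 0, y0 = nr * s) {
  grid_spec(x_origin = x0, y_origin = y0, cell_size = s,
            n_rows = nr, n_cols = nc)
}

# small two-layer stack with one nodata hole at (2, 3)
toy_stack <- function() {
  sp <- toy_spec(3, 4)
  a <- matrix(as.double(1:12), 3, 4)
  b <- matrix(as.double(101:112), 3, 4)
  a[2, 3] <- NA
  layer_stack(list(px_layer("alpha", a, sp),
                   px_layer("beta", b, sp)))
}

# scaled-down synthetic world for fast pipeline tests (not the acceptance
# profile): 50 x 50 km, 40 presences, small lake
small_world_config <- function() {
  study_config(list(
    n_rows = 50, n_cols = 50, y_origin = 50,
    lake = list(cx = 32, cy = 20, rx = 9, ry = 6),
    n_presence = 40,
    n_residents = 8))
}

small_run_config <- function(overrides = list()) {
  base <- list(background_n = 600, n_reps = 3, n_knots = 10, seed = 1L)
  run_config(utils::modifyList(base, overrides))
}
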