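test_that("slope/aspect: flat, analytic plane, and Horn kernel oracle", {
  sp <- toy_spec(5, 5)
  flat <- slope_aspect(px_layer("dem", matrix(3, 5, 5), sp))
  expect_true(all(flat$slope$values == 0))
  expect_true(all(flat$aspect$values == -1))

  # plane z = x: 1 unit rise per 1-unit cell -> 45 degrees, downslope west
  xs <- matrix(rep((1:5) - 0.5, each = 5), 5, 5)
  pl <- slope_aspect(px_layer("dem", xs, sp))
  expect_equal(pl$slope$values[2:4, 2:4], matrix(45, 3, 3))
  expect_equal(pl$aspect$values[2:4, 2:4], matrix(270, 3, 3))

  # random DEM vs an independent per-cell Horn computation
  set.seed(5)
  z <- matrix(rnorm(25), 5, 5)
  got <- slope_aspect(px_layer("dem", z, sp))
  zp <- rbind(z[1, ], z, z[5, ]); zp <- cbind(zp[, 1], zp, zp[, ncol(zp)])
  for (r in 2:4) for (c in 2:4) {
    i <- r + 1; j <- c + 1
    gx <- ((zp[i - 1, j + 1] + 2 * zp[i, j + 1] + zp[i + 1, j + 1]) -
             (zp[i - 1, j - 1] + 2 * zp[i, j - 1] + zp[i + 1, j - 1])) / 8
    gy <- ((zp[i - 1, j - 1] + 2 * zp[i - 1, j] + zp[i - 1, j + 1]) -
             (zp[i + 1, j - 1] + 2 * zp[i + 1, j] + zp[i + 1, j + 1])) / 8
    expect_equal(got$slope$values[r, c],
                 atan(sqrt(gx^2 + gy^2)) * 180 / pi)
    expect_equal(got$aspect$values[r, c],
                 (atan2(-gx, -gy) * 180 / pi + 360) %% 360)
  }

  expect_error(slope_aspect(px_layer("d", matrix(1, 2, 2), toy_spec(2, 2))),
               "3 x 3")
})

test_that("TWI: trough monotonicity, ridge closed form, 4x4 D8 trace", {
  # inclined trough down the middle column: downstream cells accumulate more
  sp <- toy_spec(5, 3)
  z <- matrix(10, 5, 3)
  z[, 2] <- c(5, 4, 3, 2, 1)
  tw <- twi(px_layer("dem", z, sp))
  # interior rows share the same Horn slope; accumulation alone drives TWI
  expect_true(all(diff(tw$values[2:4, 2]) > 0))

  # uniform plane: ridge-top cells (zero upstream) satisfy the closed form
  # TWI = ln(cell_size / tan(beta)) with a = (0 + 1) * cell_size
  xs <- matrix(rep((1:5) - 0.5, each = 5), 5, 5)
  plane <- px_layer("dem", xs, toy_spec(5, 5))
  tw2 <- twi(plane)
  acc <- pikasdm:::d8_accumulation(plane)
  sl <- slope_aspect(plane)$slope$values
  ridge <- which(acc == 0, arr.ind = TRUE)
  expect_gt(nrow(ridge), 0)  # the high (east) edge drains west
  for (i in seq_len(nrow(ridge)))
    expect_equal(tw2$values[ridge[i, 1], ridge[i, 2]],
                 log(1 / max(tan(sl[ridge[i, 1], ridge[i, 2]] * pi / 180),
                             0.001)))

  # 4x4 synthetic DEM vs a hand-traced D8 accumulation. Receivers, traced
  # by steepest drop/distance with the clockwise-from-north tie-break:
  # (1,1)->SE(2,2)  (1,2)->S(2,2)  (1,3)->S(2,3)   (1,4)->SW(2,3)
  # (2,1)->E(2,2)   (2,2)->SE(3,3) (2,3)->S(3,3)   (2,4)->SW(3,3)
  # (3,1)->E(3,2)   (3,2)->E(3,3)  (3,3)->SE(4,4)  (3,4)->S(4,4)
  # (4,1)->NE(3,2)  (4,2)->NE(3,3) (4,3)->E(4,4)   (4,4) outlet
  z4 <- matrix(c(9, 8, 7, 6,
                 8, 5, 4, 5,
                 7, 4, 2, 3,
                 6, 5, 3, 1), 4, 4, byrow = TRUE)
  dem4 <- px_layer("dem", z4, toy_spec(4, 4))
  acc4 <- pikasdm:::d8_accumulation(dem4)
  acc_hand <- matrix(c(0, 0,  0,  0,
                       0, 3,  2,  0,
                       0, 2, 12,  0,
                       0, 0,  0, 15), 4, 4, byrow = TRUE)
  expect_equal(acc4, acc_hand)
  tw4 <- twi(dem4)
  sl4 <- slope_aspect(dem4)$slope$values
  expect_equal(tw4$values,
               log((acc_hand + 1) * 1 / pmax(tan(sl4 * pi / 180), 0.001)))
})

test_that("TWI responds monotonically to accumulation and slope", {
  # same slope, different accumulation: see trough test; here fixed
  # accumulation, steeper slope -> smaller TWI
  sp <- toy_spec(5, 5)
  mk <- function(k) {
    xs <- matrix(rep((1:5) - 0.5, each = 5), 5, 5) * k
    twi(px_layer("dem", xs, sp))$values[3, 3]
  }
  expect_gt(mk(0.5), mk(2))
})

test_that("euclidean distance: geometry basics and dense-sampling oracle", {
  sp <- toy_spec(5, 5)
  pt <- vector_features("points", list(matrix(c(2.5, 2.5), 1)), "resident")
  d <- euclidean_distance(pt, sp)
  expect_equal(d$values[3, 3], 0)          # center on the feature
  expect_equal(d$values[3, 4], 1)          # horizontally adjacent
  expect_equal(d$values[2, 4], sqrt(2))    # diagonal
  expect_equal(d$name, "dis_to_resident")

  expect_error(euclidean_distance(vector_features("points", list(), "x"),
                                  sp), "empty")

  # random polyline on a 20x20 grid vs dense sampling of its segments
  sp20 <- toy_spec(20, 20)
  set.seed(9)
  line <- cbind(runif(6, 0, 20), runif(6, 0, 20))
  vf <- vector_features("polylines", list(line), "road")
  d <- euclidean_distance(vf, sp20)
  dense <- do.call(rbind, lapply(1:5, function(i) {
    t <- seq(0, 1, length.out = 20000)
    cbind(line[i, 1] + t * (line[i + 1, 1] - line[i, 1]),
          line[i, 2] + t * (line[i + 1, 2] - line[i, 2]))
  }))
  for (probe in list(c(1, 1), c(10, 7), c(20, 20), c(4, 17))) {
    cx <- probe[2] - 0.5; cy <- 20 - probe[1] + 0.5
    oracle <- sqrt(min((dense[, 1] - cx)^2 + (dense[, 2] - cy)^2))
    expect_lt(abs(d$values[probe[1], probe[2]] - oracle), 1e-6)
  }

  # 1-Lipschitz across adjacent centers
  expect_true(all(abs(diff(d$values)) <= 1 + 1e-12))
  expect_true(all(abs(t(diff(t(d$values)))) <= 1 + 1e-12))
})

test_that("buffer mask thresholds the distance layer", {
  sp <- toy_spec(6, 6)
  pt <- vector_features("points", list(matrix(c(2.5, 3.5), 1)), "road")
  m <- buffer_mask(pt, sp, radius = 0.4)
  expect_equal(sum(m$values), 1)           # only the containing cell
  expect_equal(m$values[3, 3], 1)
  big <- buffer_mask(pt, sp, radius = 100)
  expect_true(all(big$values == 1))
  d <- euclidean_distance(pt, sp)
  r <- 2.2
  expect_equal(buffer_mask(pt, sp, r)$values, (d$values <= r) * 1)
})

test_that("Savitzky-Golay reproduces low-order polynomials and smooths noise", {
  sp <- toy_spec(2, 2)
  tt <- 1:15
  quad <- 0.3 + 0.5 * tt - 0.02 * tt^2
  vals <- array(rep(quad, 4), dim = c(15, 2, 2))
  cube <- ts_cube(sp, tt, vals)
  sm <- savitzky_golay(cube, window = 5, order = 2)
  expect_equal(sm$values, cube$values, tolerance = 1e-10)

  const <- ts_cube(sp, tt, array(4, dim = c(15, 2, 2)))
  expect_equal(savitzky_golay(const, 5, 2)$values, const$values,
               tolerance = 1e-12)

  expect_error(savitzky_golay(cube, window = 4, order = 2), "odd")
  expect_error(savitzky_golay(cube, window = 5, order = 5), "order")

  # noisy sine: smoothed deviation about the truth shrinks
  set.seed(11)
  truth <- sin(2 * pi * tt / 15)
  noisy <- array(rep(truth, 4), dim = c(15, 2, 2)) +
    array(rnorm(60, sd = 0.3), dim = c(15, 2, 2))
  smn <- savitzky_golay(ts_cube(sp, tt, noisy), 5, 2)
  err_in <- mean((noisy - rep(truth, 4))^2)
  err_out <- mean((smn$values - rep(truth, 4))^2)
  expect_lt(err_out, err_in)
})

test_that("series statistics: closed forms and per-cell loop oracle", {
  sp <- toy_spec(3, 3)
  vals <- array(NA_real_, dim = c(3, 3, 3))
  vals[, 1, 1] <- c(2, 4, 6)
  vals[, 2, 2] <- c(5, 5, 5)
  set.seed(21)
  vals[, 3, ] <- rnorm(9)
  vals[, 1, 2] <- rnorm(3); vals[, 2, 1] <- rnorm(3)
  vals[, 1, 3] <- rnorm(3); vals[, 2, 3] <- rnorm(3)
  # cell (3, 3) wholly nodata? no: leave one all-NA cell
  vals[, 3, 3] <- NA
  st <- series_stats(ts_cube(sp, 1:3, vals), name = "evi")
  expect_equal(st$mean$values[1, 1], 4)
  expect_equal(st$max$values[1, 1], 6)
  expect_equal(st$min$values[1, 1], 2)
  expect_equal(st$std$values[1, 1], sqrt(8 / 3))  # population divisor
  expect_equal(st$std$values[2, 2], 0)
  expect_true(is.na(st$mean$values[3, 3]))
  expect_true(is.na(st$std$values[3, 3]))
  expect_equal(st$mean$name, "evi_mean")

  for (r in 1:3) for (c in 1:3) {
    v <- vals[, r, c]
    if (all(is.na(v))) next
    expect_equal(st$mean$values[r, c], mean(v))
    expect_equal(st$std$values[r, c],
                 sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
    expect_lte(st$min$values[r, c], st$mean$values[r, c])
    expect_lte(st$mean$values[r, c], st$max$values[r, c])
  }
})

test_that("vector feature IO round-trips through GeoJSON and CSV", {
  lines <- list(cbind(c(0, 3, 5), c(1, 2, 0)), cbind(c(1, 1), c(0, 4)))
  vf <- vector_features("polylines", lines, "road")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_features(vf, f)
  back <- read_features(f, label = "road")
  expect_equal(back$kind, "polylines")
  expect_equal(back$coordinates[[1]], vf$coordinates[[1]],
               ignore_attr = TRUE)

  pts <- vector_features("points", list(cbind(c(1, 2), c(3, 4))), "resident")
  write_features(pts, f)
  backp <- read_features(f)
  expect_equal(backp$kind, "points")
  expect_equal(do.call(rbind, backp$coordinates),
               pts$coordinates[[1]], ignore_attr = TRUE)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,vertex_index,x,y",
               "1,1,0,0", "1,2,2,2", "2,1,5,5", "2,2,6,7"), csv)
  vcsv <- read_features(csv, "river")
  expect_equal(vcsv$kind, "polylines")
  expect_equal(length(vcsv$coordinates), 2)
})

test_that("terrain covariates support both processing orders", {
  sp <- toy_spec(10, 10, s = 1)
  set.seed(3)
  base <- gaussian_random_field(sp, 4, seed = 2, name = "dem")
  coarse <- grid_spec(1, 9, 2, 4, 4)
  a <- terrain_covariates(base, coarse, order = "derive_first")
  b <- terrain_covariates(base, coarse, order = "resample_first")
  expect_true(spec_aligned(a$slope$spec, coarse))
  expect_true(spec_aligned(b$twi$spec, coarse))
  # the two orders are genuinely different operations
  expect_false(isTRUE(all.equal(a$slope$values, b$slope$values)))
})
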