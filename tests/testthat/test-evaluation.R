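# brute-force O(nm) AUC oracle: pairwise wins plus half-ties
auc_pairs <- function(p, b) {
  s <- 0
  for (x in p) s <- s + sum(x > b) + 0.5 * sum(x == b)
  s / (length(p) * length(b))
}

test_that("AUC: separation, ties, pairwise oracle, monotone invariance", {
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(auc(numeric(0), 1), "non-empty")

  set.seed(31)
  for (k in 1:20) {
    p <- round(runif(5), 1)  # rounding forces ties
    b <- round(runif(8), 1)
    expect_equal(auc(p, b), auc_pairs(p, b), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(auc(exp(2 * p), exp(2 * b)), auc(p, b), tolerance = 1e-12)
  }
})

test_that("TSS curve: confusion tallies, perfect and null cases", {
  # 6 presences + 10 pseudo-absences, hand-tallied at every decile
  p <- c(0.95, 0.8, 0.65, 0.5, 0.3, 0.15)
  a <- c(0.05, 0.1, 0.1, 0.2, 0.25, 0.3, 0.4, 0.55, 0.6, 0.85)
  curve <- tss_curve(p, a)
  for (i in seq_len(nrow(curve))) {
    t <- curve$threshold[i]
    tp <- sum(p >= t); tn <- sum(a < t)
    expect_equal(curve$sensitivity[i], tp / 6)
    expect_equal(curve$specificity[i], tn / 10)
    expect_equal(curve$tss[i], tp / 6 + tn / 10 - 1)
  }

  # perfect separation reaches TSS 1 at some grid threshold
  perf <- tss_curve(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(max(perf$tss), 1)

  # identical score distributions: TSS 0 at every interior threshold
  same <- tss_curve(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_true(all(abs(same$tss[2:10]) < 1e-12))
})

test_that("optimal threshold: argmax, tie toward smaller, coarse <= fine", {
  p <- c(0.95, 0.8, 0.65, 0.5, 0.3, 0.15)
  a <- c(0.05, 0.1, 0.1, 0.2, 0.25, 0.3, 0.4, 0.55, 0.6, 0.85)
  curve <- tss_curve(p, a)
  opt <- optimal_threshold(curve)
  i_best <- which.max(curve$tss)
  expect_equal(opt$tss, max(curve$tss))
  expect_equal(opt$threshold, curve$threshold[i_best])

  flat <- data.frame(threshold = c(0.1, 0.2, 0.3), tss = c(0.4, 0.4, 0.4))
  expect_equal(optimal_threshold(flat)$threshold, 0.1)

  # grid coarseness only loses skill, never gains
  fine <- tss_curve(p, a, thresholds = seq(0, 1, length.out = 1001))
  expect_lte(opt$tss, max(fine$tss) + 1e-12)
})

test_that("grades follow the published boundaries", {
  expect_equal(grade(0.90, "auc"), "good")
  expect_equal(grade(0.67, "tss"), "good")
  expect_equal(grade(0.5, "auc"), "worse than random")
  expect_equal(grade(0.95, "auc"), "excellent")
  expect_equal(grade(0.6, "auc"), "failed")     # right-closed intervals
  expect_equal(grade(0.2, "tss"), "bad")
  expect_equal(grade(-0.3, "tss"), "worse than random")
  expect_error(grade(1.2, "auc"), "0, 1")
})

test_that("split plans: sizes, disjointness, determinism, pairing", {
  plans <- make_split_plans(77, 10, fraction = 0.5, seed = 4)
  expect_length(plans, 10)
  for (pl in plans) {
    expect_length(pl$train, 38)
    expect_length(pl$test, 39)
    expect_equal(sort(c(pl$train, pl$test)), 1:77)
  }
  again <- make_split_plans(77, 10, fraction = 0.5, seed = 4)
  expect_identical(plans, again)
  other <- make_split_plans(77, 10, fraction = 0.5, seed = 5)
  expect_false(identical(plans[[1]]$train, other[[1]]$train))
})

test_that("Wilcoxon signed-rank: degenerate, closed-form and oracle cases", {
  expect_warning(w0 <- wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_equal(w0$p_value, 1)
  expect_equal(w0$statistic, 0)

  # n = 6, all differences positive: two-sided p = 2/64
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6) - 0:5)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$direction, "greater")

  expect_error(wilcoxon_signed_rank(1:3, c(2, 3, 5)), "at least 5")

  # exact p equals enumeration over all 2^n sign vectors (with ties)
  set.seed(33)
  for (k in 1:8) {
    n <- sample(6:12, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)
    d <- a - b; d <- d[d != 0]
    if (length(d) < 5) next
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    Ws <- signs %*% r
    p_exact <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, p_exact, tolerance = 1e-12)
  }

  # tie-free exact case agrees with the standard implementation
  set.seed(34)
  a <- rnorm(15); b <- rnorm(15)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)

  # large-sample normal path tracks the reference closely
  set.seed(35)
  a <- rnorm(60); b <- rnorm(60, 0.3)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(ours$method, "normal approximation")
})

# shared small synthetic world for the model-level evaluation tests
eval_world <- local({
  st <- generate_study(small_world_config(), seed = 2)
  occ <- build_occurrences(st, small_run_config())
  list(st = st, occ = occ)
})

test_that("run_replicates: single-run identity, reproducibility, pairing", {
  st <- eval_world$st; occ <- eval_world$occ
  cfg <- list(n_knots = 10)
  r1 <- run_replicates(occ, st$kinds, config = cfg, n_reps = 1, seed = 7)
  expect_equal(nrow(r1$replicates), 1)
  # single replicate: report equals a direct fit on the same split
  pl <- make_split_plans(nrow(occ$features_presence), 1, 0.5, seed = 7)[[1]]
  ex <- build_expansion(occ$features_background, st$kinds,
                        classes = feature_classes_auto(length(pl$train)),
                        n_knots = 10)
  fit <- maxent_fit(occ$features_presence[pl$train, ],
                    occ$features_background, ex)
  sc_b <- predict_logistic(fit, occ$features_background)
  sc_tr <- predict_logistic(fit, occ$features_presence[pl$train, ])
  sc_te <- predict_logistic(fit, occ$features_presence[pl$test, ])
  expect_equal(r1$replicates$train_auc, auc(sc_tr, sc_b), tolerance = 1e-10)
  expect_equal(r1$replicates$test_auc, auc(sc_te, sc_b), tolerance = 1e-10)
  opt <- optimal_threshold(tss_curve(sc_te, sc_b))
  expect_equal(r1$replicates$max_tss, opt$tss, tolerance = 1e-10)

  r2 <- run_replicates(occ, st$kinds, config = cfg, n_reps = 2, seed = 9)
  r3 <- run_replicates(occ, st$kinds, config = cfg, n_reps = 2, seed = 9)
  expect_identical(r2$replicates, r3$replicates)
  expect_equal(r2$summary$sd, c(stats::sd(r2$replicates$train_auc),
                                stats::sd(r2$replicates$test_auc),
                                stats::sd(r2$replicates$max_tss)))
})

test_that("jackknife: symmetry for duplicated variables, noise is null", {
  st <- eval_world$st; occ <- eval_world$occ
  pres <- occ$features_presence[, c("dis_to_road", "bio8")]
  bg <- occ$features_background[, c("dis_to_road", "bio8")]
  # duplicate the informative variable and add pure noise
  set.seed(41)
  pres$road_copy <- pres$dis_to_road
  bg$road_copy <- bg$dis_to_road
  pres$noise <- rnorm(nrow(pres))
  bg$noise <- rnorm(nrow(bg))
  occ2 <- occ
  occ2$features_presence <- pres
  occ2$features_background <- bg
  kinds <- c(dis_to_road = "continuous", bio8 = "continuous",
             road_copy = "continuous", noise = "continuous")
  jk <- jackknife(occ2, kinds, config = list(n_knots = 10))
  tab <- jk$table
  g <- function(v) tab$gain_with_only[tab$variable == v]
  expect_equal(g("road_copy"), g("dis_to_road"), tolerance = 1e-6)
  expect_lt(g("noise"), 0.05)
  expect_gt(g("dis_to_road"), 10 * g("noise") + 0.05)
  # omitting one of a duplicated pair costs (almost) nothing
  w <- function(v) tab$gain_without[tab$variable == v]
  expect_equal(w("dis_to_road"), jk$gain_all, tolerance = 0.05)
  expect_error(jackknife(occ2, kinds, variables = "bio8"), "at least 2")
})

test_that("permutation contribution: identity, normalisation, noise floor", {
  st <- eval_world$st; occ <- eval_world$occ
  bg <- occ$features_background[, c("dis_to_road", "bio8")]
  pres <- occ$features_presence[, c("dis_to_road", "bio8")]
  set.seed(43)
  pres$noise <- rnorm(nrow(pres)); bg$noise <- rnorm(nrow(bg))
  kinds <- c(dis_to_road = "continuous", bio8 = "continuous",
             noise = "continuous")
  ex <- build_expansion(bg, kinds, classes = c("linear", "hinge"),
                        n_knots = 10)
  m <- maxent_fit(pres, bg, ex)
  co <- contribution(m, pres, bg, seed = 5)
  expect_equal(sum(co), 100, tolerance = 0.01)
  expect_lt(co[["noise"]], 0.5)
  expect_gt(co[["dis_to_road"]], 50)

  ex1 <- build_expansion(bg["dis_to_road"], kinds, classes = "linear")
  m1 <- maxent_fit(pres["dis_to_road"], bg["dis_to_road"], ex1)
  expect_equal(unname(contribution(m1, pres["dis_to_road"],
                                   bg["dis_to_road"])), 100)
})

test_that("variable selection: correlation pruning then contribution floor", {
  st <- eval_world$st; occ <- eval_world$occ
  # construct a 3-variable case: A and B nearly collinear, C independent
  bg <- occ$features_background
  pres <- occ$features_presence
  set.seed(45)
  tabs <- list(
    A = list(p = pres$dis_to_road, b = bg$dis_to_road),
    B = list(p = pres$dis_to_road + rnorm(nrow(pres), 0, 1),
             b = bg$dis_to_road + rnorm(nrow(bg), 0, 1)),
    C = list(p = pres$bio8, b = bg$bio8))
  occ3 <- occ
  occ3$features_presence <- data.frame(A = tabs$A$p, B = tabs$B$p,
                                       C = tabs$C$p)
  occ3$features_background <- data.frame(A = tabs$A$b, B = tabs$B$b,
                                         C = tabs$C$b)
  kinds <- c(A = "continuous", B = "continuous", C = "continuous")
  expect_gt(abs(cor(occ3$features_background$A,
                    occ3$features_background$B)), 0.9)
  jk <- jackknife(occ3, kinds, config = list(n_knots = 10))
  sel <- select_variables(occ3, kinds, jk, r_cut = 0.75,
                          config = list(n_knots = 10))
  gains <- stats::setNames(jk$table$gain_with_only, jk$table$variable)
  keeper <- if (gains[["A"]] >= gains[["B"]]) "A" else "B"
  loser <- setdiff(c("A", "B"), keeper)
  expect_true(keeper %in% sel$retained)
  expect_equal(sel$removed_correlation, loser)
  expect_false(loser %in% sel$retained)

  # identical layers: exactly one survives
  occ2 <- occ
  occ2$features_presence <- data.frame(A = tabs$A$p, A2 = tabs$A$p)
  occ2$features_background <- data.frame(A = tabs$A$b, A2 = tabs$A$b)
  k2 <- c(A = "continuous", A2 = "continuous")
  jk2 <- jackknife(occ2, k2, config = list(n_knots = 10))
  sel2 <- select_variables(occ2, k2, jk2, config = list(n_knots = 10))
  expect_length(sel2$retained, 1)
})
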