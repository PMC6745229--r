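test_that("sine chaotic map follows its closed form and stays in (0,1)", {
  s <- sine_map_state(0.7)
  s1 <- sine_map_next(s)
  expect_equal(s1$p, sin(0.7 * pi), tolerance = 1e-12)
  expect_equal(s1$p, 0.809017, tolerance = 1e-6)
  expect_equal(s1$q, 1L)

  # p = 0.5 maps to 1.0 and the guard perturbs back into (0, 1)
  g <- sine_map_next(sine_map_state(0.5))
  expect_true(g$p > 0 && g$p < 1)

  # small-angle limit p' ~ pi * p
  tiny <- sine_map_next(sine_map_state(1e-5))
  expect_equal(tiny$p, pi * 1e-5, tolerance = 1e-4)

  p <- sine_map_state(0.7)
  in_range <- TRUE
  for (i in 1:1000) {
    p <- sine_map_next(p)
    in_range <- in_range && p$p > 0 && p$p < 1
  }
  expect_true(in_range)
})

test_that("position updates follow the flight equation or resample", {
  cfg <- ccsa_config(AwPr = 0.1, fl = 2)

  # direct substitution in the flight equation
  y <- update_position(0.2, 0.7, C_j = 0.5, C_z = 0.9, cfg)
  expect_equal(y, 0.2 + 0.5 * 2 * (0.7 - 0.2))
  expect_equal(y, 0.7)

  # fl = 0 freezes the follower
  cfg0 <- ccsa_config(AwPr = 0.1, fl = 0)
  expect_equal(update_position(c(0.2, 0.8), c(0.9, 0.1), 0.5, 0.9, cfg0),
               c(0.2, 0.8))

  # awareness triggered: uniform resample, independent of y and N
  set.seed(4)
  r1 <- update_position(rep(0.2, 6), rep(0.9, 6), 0.5, 0.05, cfg)
  set.seed(4)
  r2 <- update_position(rep(0.8, 6), rep(0.1, 6), 0.9, 0.01, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))

  # results clipped to the unit box
  big <- update_position(0.9, 1, C_j = 0.9, C_z = 0.9,
                         ccsa_config(fl = 10))
  expect_lte(big, 1)
})

test_that("awareness probability extremes flip every update branch", {
  set.seed(6)
  draws <- runif(200, 1e-4, 1 - 1e-4)
  y <- rep(0.25, 4); N <- rep(0.75, 4)

  # AwPr = 0: never a random reposition; always the deterministic step
  cfg_exploit <- ccsa_config(AwPr = 0, fl = 2)
  step <- pmin(pmax(y + 0.5 * 2 * (N - y), 0), 1)
  n_step <- sum(vapply(draws, function(cz)
    isTRUE(all.equal(update_position(y, N, 0.5, cz, cfg_exploit), step)),
    logical(1)))
  expect_equal(n_step, length(draws))

  # AwPr = 1: every update is a uniform resample (pure random search)
  cfg_explore <- ccsa_config(AwPr = 1, fl = 2)
  outs <- vapply(draws, function(cz)
    update_position(y, N, 0.5, cz, cfg_explore), numeric(4))
  expect_true(all(outs >= 0 & outs <= 1))
  n_equal <- sum(apply(outs, 2, function(o) isTRUE(all.equal(o, step))))
  expect_equal(n_equal, 0)
})

test_that("position binarization thresholds at 0.5 and never empties", {
  expect_equal(binarize_position(c(0.7, 0.2, 0.5)), c(1L, 0L, 1L))
  expect_equal(binarize_position(c(0.1, 0.4, 0.3)), c(0L, 1L, 0L))
  expect_equal(binarize_position(c(0.9, 0.5, 0.6)), c(1L, 1L, 1L))
})

test_that("wrapper fitness trades accuracy against subset length", {
  set.seed(13)
  n <- 40
  sep <- c(rnorm(n, -3), rnorm(n, 3))          # perfectly separable
  X <- cbind(sep, matrix(rnorm(2 * n * 12), 2 * n, 12))
  y <- factor(rep(c("a", "b"), each = n))
  cfg <- ccsa_config()
  folds <- withr::with_seed(1, caret::createFolds(y, k = 5))

  f_single <- ccsa_fitness(c(1, rep(0, 12)), X, y, cfg, folds = folds)
  f_full <- ccsa_fitness(rep(1, 13), X, y, cfg, folds = folds)
  expect_lt(f_single, f_full)

  # identical accuracy (duplicated column): smaller cardinality wins
  Xdup <- cbind(sep, sep)
  f1 <- ccsa_fitness(c(1, 0), Xdup, y, cfg, folds = folds)
  f2 <- ccsa_fitness(c(1, 1), Xdup, y, cfg, folds = folds)
  expect_lt(f1, f2)

  # chance-level features, no length penalty: fitness near w_acc * 0.5
  cfg_acc <- ccsa_config(w_acc = 1, w_len = 0)
  accs <- sapply(1:10, function(s) {
    tab <- generate_feature_table(feature_table_spec(
      n_per_class = 50, effect_size = 0, seed = 400 + s))
    ccsa_fitness(rep(1, 13), tab$X, tab$labels, cfg_acc, seed = s)
  })
  expect_gt(mean(accs), 0.38)
  expect_lt(mean(accs), 0.62)

  expect_error(ccsa_fitness(rep(0, 13), X, y, cfg), "empty")
})

test_that("crow-search selection is elitist, deterministic and bounded", {
  tab <- generate_feature_table(feature_table_spec(n_per_class = 25,
                                                   seed = 2))
  cfg <- ccsa_config(M = 8, t_max = 12)
  sel1 <- select_features(tab$X, tab$labels, cfg, seed = 5)
  sel2 <- select_features(tab$X, tab$labels, cfg, seed = 5)
  expect_identical(sel1$selected_idx, sel2$selected_idx)
  expect_identical(sel1$history, sel2$history)

  expect_true(length(sel1$selected_idx) >= 1)
  expect_equal(length(sel1$history), cfg$t_max)
  expect_true(all(diff(sel1$history) <= 0))     # monotone non-increasing
  expect_equal(sel1$best_fitness, min(sel1$history))

  # boundary configuration terminates with a valid mask
  tiny <- select_features(tab$X, tab$labels,
                          ccsa_config(M = 2, t_max = 1), seed = 3)
  expect_true(length(tiny$selected_idx) >= 1)
  expect_equal(length(tiny$history), 1L)

  expect_error(select_features(tab$X[, 1, drop = FALSE], tab$labels),
               "at least 2 features")
  expect_error(select_features(tab$X, rep("a", nrow(tab$X))),
               "degenerate labels")
})

test_that("selection beats random masks of equal size on planted tables", {
  cfg <- ccsa_config(M = 10, t_max = 15)
  diffs <- sapply(1:10, function(s) {
    tab <- generate_feature_table(feature_table_spec(n_per_class = 50,
                                                     effect_size = 1.5,
                                                     seed = 500 + s))
    sel <- select_features(tab$X, tab$labels, cfg, seed = s)
    folds <- withr::with_seed(s, caret::createFolds(tab$labels, k = 5))
    cfg_acc <- ccsa_config(w_acc = 1, w_len = 0)
    acc_sel <- 1 - ccsa_fitness(sel$mask, tab$X, tab$labels, cfg_acc,
                                folds = folds)
    rand_mask <- withr::with_seed(1000 + s, {
      m <- integer(13)
      m[sample(13, length(sel$selected_idx))] <- 1L
      m
    })
    acc_rand <- 1 - ccsa_fitness(rand_mask, tab$X, tab$labels, cfg_acc,
                                 folds = folds)
    acc_sel - acc_rand
  })
  expect_gt(mean(diffs), 0)
})
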