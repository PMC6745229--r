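#' Chaotic crow-search configuration
#'
#' Hyper-parameters of the chaotic-binary crow-search selector:
#' population size `M = 25`, awareness probability `AwPr = 0.1`,
#' flight length `fl = 2` and `t_max = 50` iterations, with the sine
#' chaotic map (control parameter `c = 4`, start `p0 = 0.7`) replacing
#' the algorithm's uniform random draws. The wrapper fitness (lower is
#' better) combines cross-validated PNN error and subset length:
#' `w_acc * (1 - accuracy) + w_len * |subset| / D`.
#'
#' @param M number of crows (>= 2).
#' @param AwPr awareness probability in `[0, 1]`: the probability that
#'   the followed crow notices pursuit and the follower jumps to a
#'   random position (exploration); otherwise the follower steps
#'   toward the followed crow's memorized best position
#'   (exploitation).
#' @param fl flight length (step multiplier toward the followed
#'   memory).
#' @param t_max maximum iterations (>= 1).
#' @param p0,c sine-map initial value and control parameter.
#' @param binarization_threshold cut-off mapping continuous positions
#'   in `[0, 1]` to feature masks.
#' @param w_acc,w_len fitness weights on error and subset length.
#' @param eval_folds folds of the internal stratified PNN
#'   cross-validation used by the wrapper fitness.
#' @param spread PNN smoothing parameter used inside the fitness.
#' @return an object of class `ccsa_config`.
#' @export
ccsa_config <- function(M = 25L, AwPr = 0.1, fl = 2, t_max = 50L,
                        p0 = 0.7, c = 4, binarization_threshold = 0.5,
                        w_acc = 0.99, w_len = 0.01,
                        eval_folds = 5L, spread = 0.1) {
  stopifnot_scalar_number(M, "M", min = 2, integer = TRUE)
  stopifnot_scalar_number(AwPr, "AwPr", min = 0, max = 1)
  stopifnot_scalar_number(fl, "fl", min = 0)
  stopifnot_scalar_number(t_max, "t_max", min = 1, integer = TRUE)
  stopifnot_scalar_number(p0, "p0", min = 1e-12, max = 1 - 1e-12)
  stopifnot_scalar_number(binarization_threshold, "binarization_threshold",
                          min = 0, max = 1)
  structure(list(M = as.integer(M), AwPr = AwPr, fl = fl,
                 t_max = as.integer(t_max), p0 = p0, c = c,
                 binarization_threshold = binarization_threshold,
                 w_acc = w_acc, w_len = w_len,
                 eval_folds = as.integer(eval_folds), spread = spread),
            class = "ccsa_config")
}

#' Create a sine chaotic map state
#'
#' @param p0 initial map value in (0, 1).
#' @param c control parameter (4 gives fully chaotic behaviour).
#' @return an object of class `sine_map_state` with elements `p`
#'   (current value), `c`, and step index `q`.
#' @export
sine_map_state <- function(p0 = 0.7, c = 4) {
  stopifnot_scalar_number(p0, "p0", min = 1e-12, max = 1 - 1e-12)
  structure(list(p = p0, c = c, q = 0L), class = "sine_map_state")
}

#' Advance the sine chaotic map one step
#'
#' Applies `p' = (c / 4) * sin(pi * p)`. Because `p = 0.5` maps to 1
#' and then to the absorbing point 0, a guard re-seeds values falling
#' within `1e-6` of the interval ends to `0.7` plus a small
#' deterministic jitter derived from the step index, keeping the
#' sequence in (0, 1) and non-degenerate.
#'
#' @param state a [sine_map_state()].
#' @return the advanced state (`q` incremented).
#' @examples
#' s <- sine_map_state(0.7)
#' sine_map_next(s)$p   # sin(0.7 * pi) = 0.8090
#' @export
sine_map_next <- function(state) {
  if (!inherits(state, "sine_map_state"))
    stop("`state` must be a sine_map_state", call. = FALSE)
  q <- state$q + 1L
  p <- (state$c / 4) * sin(pi * state$p)
  if (!is.finite(p) || p <= 1e-6 || p >= 1 - 1e-6)
    p <- 0.7 + (q %% 9L + 1L) / 1000
  structure(list(p = p, c = state$c, q = q), class = "sine_map_state")
}

#' One crow-search position update
#'
#' With probability `AwPr` -- realized when the chaotic draw `C_z` is
#' at most `AwPr` -- the followed crow has noticed pursuit and the
#' follower repositions uniformly at random on `[0, 1]^D`
#' (exploration). Otherwise the follower steps toward the followed
#' crow's memorized best position,
#' `y' = y + C_j * fl * (N_best - y)`, and is clipped to `[0, 1]^D`
#' (exploitation).
#'
#' @param y current position vector in `[0, 1]^D`.
#' @param N_best followed crow's memorized best position, same length.
#' @param C_j,C_z chaotic draws in (0, 1).
#' @param cfg a [ccsa_config()] (supplies `AwPr` and `fl`).
#' @return updated position vector in `[0, 1]^D`. Random repositioning
#'   draws from the caller's RNG stream.
#' @export
update_position <- function(y, N_best, C_j, C_z, cfg = ccsa_config()) {
  if (length(y) != length(N_best))
    stop("`y` and `N_best` must have equal length", call. = FALSE)
  if (C_z <= cfg$AwPr) {
    runif(length(y))
  } else {
    pmin(pmax(y + C_j * cfg$fl * (N_best - y), 0), 1)
  }
}

#' Map a continuous position to a feature mask
#'
#' Components at or above `threshold` are selected. An all-zero mask
#' is promoted to the singleton at the largest component, so the
#' selected subset is never empty.
#'
#' @param y position vector in `[0, 1]^D`.
#' @param threshold cut-off (default 0.5).
#' @return integer 0/1 mask of length `D`.
#' @export
binarize_position <- function(y, threshold = 0.5) {
  m <- as.integer(y >= threshold)
  if (!any(m == 1L)) m[which.max(y)] <- 1L
  m
}

make_stratified_folds <- function(labels, k) {
  caret::createFolds(labels, k = k, list = TRUE, returnTrain = FALSE)
}

cv_pnn_accuracy <- function(X, labels, folds, spread) {
  correct <- 0L
  for (test in folds) {
    model <- pnn_train(X[-test, , drop = FALSE], labels[-test],
                       spread = spread)
    pred <- predict(model, X[test, , drop = FALSE])
    correct <- correct + sum(pred == labels[test])
  }
  correct / length(labels)
}

#' Wrapper fitness of a feature mask
#'
#' Evaluates a candidate feature subset by the stratified k-fold PNN
#' cross-validated accuracy on the masked columns, combined with a
#' parsimony term:
#' `w_acc * (1 - accuracy) + w_len * |mask| / D`. Lower is better;
#' among subsets with equal accuracy the smaller one wins.
#'
#' @param mask 0/1 vector over features (non-empty).
#' @param X numeric feature matrix.
#' @param labels class factor.
#' @param cfg a [ccsa_config()].
#' @param folds optional precomputed fold index list (test indices);
#'   built from `seed` when omitted.
#' @param seed seed for fold construction when `folds` is `NULL`.
#' @return scalar fitness (lower is better).
#' @export
ccsa_fitness <- function(mask, X, labels, cfg = ccsa_config(),
                         folds = NULL, seed = 1L) {
  if (!any(mask == 1)) stop("empty feature mask", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (is.null(folds))
    folds <- with_seed(seed, make_stratified_folds(labels, cfg$eval_folds))
  acc <- cv_pnn_accuracy(X[, mask == 1, drop = FALSE], labels, folds,
                         cfg$spread)
  cfg$w_acc * (1 - acc) + cfg$w_len * sum(mask) / length(mask)
}

#' Select features with the chaotic-binary crow-search algorithm
#'
#' Runs the full chaotic crow-search loop: `M` crows hold continuous
#' positions on `[0, 1]^D` (initialized uniformly, memories set to the
#' initial positions); at every iteration each crow draws two sine-map
#' values (`C_j`, then `C_z`), picks a random crow `z` to follow, and
#' updates its position with [update_position()]. Positions are
#' binarized with [binarize_position()] and scored with
#' [ccsa_fitness()]; a crow's memory is replaced only on strict
#' fitness improvement (elitism), so the best-memory history is
#' monotone non-increasing. Identical data, config and seed give
#' identical results.
#'
#' @param X numeric feature matrix (`D >= 2` columns).
#' @param labels class factor with at least two classes.
#' @param cfg a [ccsa_config()].
#' @param seed integer seed driving initialization, crow pairing,
#'   random repositioning and the internal fitness folds.
#' @return an object of class `ccsa_selection`: `selected_idx`,
#'   `selected_names`, `mask`, `best_fitness`, `history` (best fitness
#'   after each iteration), `cv_accuracy` of the winning subset,
#'   `n_fitness_evaluations`, `seed` and `config`.
#' @examples
#' tab <- generate_feature_table(feature_table_spec(n_per_class = 20, seed = 2))
#' sel <- select_features(tab$X, tab$labels,
#'                        ccsa_config(M = 5, t_max = 3), seed = 1)
#' sel$selected_idx
#' @export
select_features <- function(X, labels, cfg = ccsa_config(), seed = 1L) {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  D <- ncol(X)
  if (D < 2L) stop("need at least 2 features", call. = FALSE)
  if (nlevels(labels) < 2L)
    stop("degenerate labels: need at least 2 classes", call. = FALSE)

  with_seed(seed, {
    folds <- make_stratified_folds(labels, cfg$eval_folds)
    cache <- new.env(parent = emptyenv())
    n_evals <- 0L
    fit <- function(mask) {
      key <- paste(mask, collapse = "")
      val <- get0(key, envir = cache, inherits = FALSE)
      if (!is.null(val)) return(val)
      n_evals <<- n_evals + 1L
      val <- ccsa_fitness(mask, X, labels, cfg, folds = folds)
      assign(key, val, envir = cache)
      val
    }

    pos <- matrix(runif(cfg$M * D), cfg$M, D)
    mem <- pos
    mem_fit <- apply(mem, 1, function(y)
      fit(binarize_position(y, cfg$binarization_threshold)))
    chaos <- sine_map_state(cfg$p0, cfg$c)
    history <- numeric(cfg$t_max)

    for (t in seq_len(cfg$t_max)) {
      for (j in seq_len(cfg$M)) {
        z <- sample.int(cfg$M, 1L)
        chaos <- sine_map_next(chaos); C_j <- chaos$p
        chaos <- sine_map_next(chaos); C_z <- chaos$p
        pos[j, ] <- update_position(pos[j, ], mem[z, ], C_j, C_z, cfg)
        f <- fit(binarize_position(pos[j, ], cfg$binarization_threshold))
        if (f < mem_fit[j]) {
          mem[j, ] <- pos[j, ]
          mem_fit[j] <- f
        }
      }
      history[t] <- min(mem_fit)
    }

    best <- which.min(mem_fit)
    mask <- binarize_position(mem[best, ], cfg$binarization_threshold)
    acc <- cv_pnn_accuracy(X[, mask == 1, drop = FALSE], labels, folds,
                           cfg$spread)
    structure(list(
      selected_idx = which(mask == 1L),
      selected_names = colnames(X)[mask == 1L],
      mask = mask,
      best_fitness = mem_fit[best],
      history = history,
      cv_accuracy = acc,
      n_fitness_evaluations = n_evals,
      seed = as.integer(seed),
      config = cfg), class = "ccsa_selection")
  })
}

#' @export
print.ccsa_selection <- function(x, ...) {
  cat(sprintf("CCSA selection: %d of %d features, best fitness %.4f, cv accuracy %.3f\n",
              length(x$selected_idx), length(x$mask), x$best_fitness,
              x$cv_accuracy))
  cat("selected:", paste(x$selected_names %||% x$selected_idx,
                         collapse = ", "), "\n")
  invisible(x)
}
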