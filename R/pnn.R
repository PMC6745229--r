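#' Radial basis transfer function
#'
#' `radbas(n) = exp(-n^2)`, applied element-wise: 1 at `n = 0`,
#' decaying symmetrically in `|n|`.
#'
#' @param n numeric scalar, vector or array.
#' @return same shape as `n`.
#' @export
radbas <- function(n) exp(-(n^2))

#' Train a probabilistic neural network
#'
#' One-pass training of a Bayes-Parzen classifier: the (optionally
#' z-scored) training vectors are stored verbatim as the rows of the
#' radial-basis weight matrix `W`; no iterative optimization occurs.
#' The class-membership matrix `M` is one-hot by label, and every
#' radial-basis neuron shares the bias `b = sqrt(-ln 0.5) / spread`,
#' so a stored pattern at Euclidean distance `spread` from a query
#' produces activation 0.5.
#'
#' @param X numeric matrix, one training vector per row.
#' @param labels factor (or coercible) of length `nrow(X)`; every
#'   level must have at least one sample.
#' @param spread smoothing parameter (Gaussian kernel bandwidth) > 0.
#' @param standardize z-score features with training statistics
#'   (default `TRUE`; distance kernels need comparable scales).
#' @return an object of class `pnn` with elements `W`, `M`, `b`,
#'   `center`, `scale`, `levels`, `R`, `Q`, `spread`.
#' @examples
#' tab <- generate_feature_table(feature_table_spec(n_per_class = 15, seed = 1))
#' model <- pnn_train(tab$X, tab$labels)
#' predict(model, tab$X[1:3, , drop = FALSE])
#' @export
pnn_train <- function(X, labels, spread = 0.1, standardize = TRUE) {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(X))
    stop("`labels` length must match rows of `X`", call. = FALSE)
  if (nlevels(labels) < 1L || any(table(labels) < 1L))
    stop("every class needs at least one training sample", call. = FALSE)
  stopifnot_scalar_number(spread, "spread", min = .Machine$double.eps)
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    center <- rep(0, ncol(X))
    scl <- rep(1, ncol(X))
  }
  W <- sweep(sweep(X, 2, center), 2, scl, "/")
  Q <- nrow(W)
  M <- matrix(0, nlevels(labels), Q,
              dimnames = list(levels(labels), NULL))
  M[cbind(as.integer(labels), seq_len(Q))] <- 1
  structure(list(W = W, M = M,
                 b = rep(sqrt(-log(0.5)) / spread, Q),
                 center = center, scale = scl,
                 levels = levels(labels),
                 R = ncol(W), Q = Q, spread = spread),
            class = "pnn")
}

#' @export
print.pnn <- function(x, ...) {
  cat(sprintf("PNN: %d stored patterns, %d features, %d classes, spread = %g\n",
              x$Q, x$R, length(x$levels), x$spread))
  invisible(x)
}

#' Radial-basis layer activations for one input vector
#'
#' `a_i = radbas(||w_i - p|| * b_i)` with Euclidean distance: a stored
#' pattern identical to the query activates at exactly 1, and every
#' activation lies in (0, 1].
#'
#' @param model a [pnn_train()] model.
#' @param p numeric vector of length `model$R` (on the original
#'   feature scale; standardization is applied internally).
#' @return numeric activation vector of length `model$Q`.
#' @export
radial_layer <- function(model, p) {
  if (!inherits(model, "pnn")) stop("`model` must be a pnn", call. = FALSE)
  if (length(p) != model$R)
    stop(sprintf("input has length %d but the network expects R = %d",
                 length(p), model$R), call. = FALSE)
  ps <- (as.numeric(p) - model$center) / model$scale
  d <- sqrt(rowSums(sweep(model$W, 2, ps)^2))
  radbas(d * model$b)
}

#' Predict classes with a probabilistic neural network
#'
#' The competitive layer sums the radial-basis activations per class
#' (`d = M %*% a`) and returns the class with the largest score; ties
#' resolve to the lowest class index. For numerical robustness at
#' small spreads the summed-exponential scores are computed with a
#' per-query shift of the squared distances, which rescales every
#' class score by the same positive factor and therefore preserves
#' the argmax while avoiding underflow.
#'
#' @param object a `pnn` model.
#' @param newdata numeric matrix (rows = queries) or single vector.
#' @param type `"class"` (default) for labels, `"score"` for the raw
#'   per-class summed activations.
#' @param ... unused.
#' @return factor of predicted labels, or a classes x queries score
#'   matrix for `type = "score"`.
#' @export
predict.pnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$R)
    stop(sprintf("newdata has %d columns but the network expects R = %d",
                 ncol(newdata), object$R), call. = FALSE)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  b2 <- object$b[1]^2
  D2 <- outer(rowSums(object$W^2), rep(1, nrow(Xs))) +
    outer(rep(1, object$Q), rowSums(Xs^2)) -
    2 * object$W %*% t(Xs)
  D2[D2 < 0] <- 0
  if (type == "score") {
    scores <- object$M %*% exp(-D2 * b2)
    colnames(scores) <- rownames(newdata)
    return(scores)
  }
  shift <- matrix(apply(D2, 2, min), object$Q, ncol(D2), byrow = TRUE)
  scores <- object$M %*% exp(-(D2 - shift) * b2)
  idx <- apply(scores, 2, which.max)
  factor(object$levels[idx], levels = object$levels)
}
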