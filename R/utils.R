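#' @useDynLib lungtexsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var
#' @importFrom utils write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the
#' caller's RNG state afterwards, so seeded generators do not perturb
#' the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("`%s` must be in [%s, %s]", name, min, max), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

# Derive a bounded child seed from a top-level seed; keeps every derived
# seed a valid 32-bit integer.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 12345 * as.numeric(k)) %% 2147483647)
}

assert_gray_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(img)
}

assert_binary_image <- function(img, name = "img") {
  assert_gray_image(img, name)
  if (!all(img %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  invisible(img)
}
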