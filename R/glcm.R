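#' Canonical ordering of the 13 Haralick feature names
#'
#' @format character vector of length 13.
#' @keywords internal
haralick_feature_names <- c(
  "angular_second_moment", "contrast", "correlation", "variance",
  "inverse_difference_moment", "sum_average", "sum_variance",
  "sum_entropy", "entropy", "difference_variance", "difference_entropy",
  "info_measure_correlation", "homogeneity")

#' GLCM configuration
#'
#' @param offsets list of integer `(dr, dc)` displacements; the default
#'   pairs every pixel with the pixel two rows down and, separately,
#'   the pixel two columns right.
#' @param levels number of gray-level quantization bins (>= 2).
#' @param symmetric if `TRUE`, transposed pairs are also counted.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(offsets = list(c(2L, 0L), c(0L, 2L)),
                        levels = 8L, symmetric = FALSE) {
  if (!length(offsets)) stop("`offsets` must be non-empty", call. = FALSE)
  offsets <- lapply(offsets, function(o) {
    o <- as.integer(o)
    if (length(o) != 2L) stop("each offset must be (dr, dc)", call. = FALSE)
    o
  })
  stopifnot_scalar_number(levels, "levels", min = 2, integer = TRUE)
  structure(list(offsets = offsets, levels = as.integer(levels),
                 symmetric = isTRUE(symmetric)),
            class = "glcm_config")
}

#' Quantize an intensity image into equal-width gray levels
#'
#' Bins the observed intensity range (over the mask, if given) into
#' `levels` equal-width bins; returns an integer level image with
#' values `1..levels` and `NA` at masked-out pixels (excluded from
#' co-occurrence pairing). A constant region occupies a single level.
#'
#' @param img numeric matrix.
#' @param mask optional 0/1 matrix; pixels with 0 are excluded.
#' @param levels number of bins.
#' @return integer matrix of levels with `NA` outside the mask.
#' @export
quantize <- function(img, mask = NULL, levels = 8L) {
  assert_gray_image(img)
  stopifnot_scalar_number(levels, "levels", min = 2, integer = TRUE)
  keep <- if (is.null(mask)) rep(TRUE, length(img)) else {
    assert_binary_image(mask, "mask")
    as.vector(mask) == 1
  }
  if (!any(keep)) stop("mask excludes every pixel", call. = FALSE)
  x <- as.vector(img)
  mn <- min(x[keep]); mx <- max(x[keep])
  lv <- if (mx == mn) rep(1L, length(x)) else
    pmin(floor((x - mn) / (mx - mn) * levels) + 1L, levels)
  lv[lv < 1L] <- 1L            # pixels below the masked range, if any
  lv[!keep] <- NA_integer_
  matrix(as.integer(lv), nrow(img), ncol(img))
}

#' Gray-level co-occurrence matrices for a set of offsets
#'
#' For each offset `(dr, dc)`, `counts[i, j]` is the number of pixel
#' positions `p` with level `i` at `p` and level `j` at `p + (dr, dc)`;
#' out-of-bounds and masked (`NA`) pairs are skipped. Probabilities are
#' the counts normalized to sum to 1.
#'
#' @param levels_img integer level matrix from [quantize()].
#' @param offsets list of `(dr, dc)` displacements.
#' @param symmetric if `TRUE`, add transposed counts.
#' @param n_levels number of levels (defaults to the maximum observed).
#' @return an object of class `glcm_set`: lists `counts` and `probs`
#'   (one `n_levels x n_levels` matrix per offset), plus the offsets.
#' @export
cooccurrence <- function(levels_img, offsets, symmetric = FALSE,
                         n_levels = NULL) {
  if (!is.matrix(levels_img)) stop("`levels_img` must be a matrix", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(levels_img, na.rm = TRUE)
  L <- as.integer(n_levels)
  nr <- nrow(levels_img); nc <- ncol(levels_img)
  counts <- probs <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1]; dc <- offsets[[k]][2]
    r <- seq_len(nr); r <- r[r + dr >= 1 & r + dr <= nr]
    cc <- seq_len(nc); cc <- cc[cc + dc >= 1 & cc + dc <= nc]
    cm <- matrix(0, L, L)
    if (length(r) && length(cc)) {
      a <- levels_img[r, cc, drop = FALSE]
      b <- levels_img[r + dr, cc + dc, drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        tab <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
        cm <- matrix(tab, L, L, byrow = TRUE)
      }
    } else {
      warning(sprintf("offset (%d, %d) exceeds image extent: zero counts",
                      dr, dc))
    }
    if (symmetric) cm <- cm + t(cm)
    counts[[k]] <- cm
    tot <- sum(cm)
    probs[[k]] <- if (tot > 0) cm / tot else cm
  }
  structure(list(counts = counts, probs = probs, offsets = offsets,
                 levels = L, symmetric = isTRUE(symmetric)),
            class = "glcm_set")
}

entropy0 <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

haralick_one <- function(P) {
  if (sum(P) <= 0) stop("empty GLCM", call. = FALSE)
  L <- nrow(P)
  i <- seq_len(L)
  ii <- matrix(i, L, L)
  jj <- t(ii)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))

  s <- as.vector(ii + jj)
  psum <- as.vector(rowsum(as.vector(P), s))       # k = 2 .. 2L
  ksum <- sort(unique(s))
  d <- as.vector(abs(ii - jj))
  pdiff <- as.vector(rowsum(as.vector(P), d))      # k = 0 .. L-1
  kdiff <- sort(unique(d))

  sum_avg <- sum(ksum * psum)
  mu_d <- sum(kdiff * pdiff)
  hxy <- entropy0(P)
  hx <- entropy0(px); hy <- entropy0(py)
  pxy <- as.vector(outer(px, py))
  pv <- as.vector(P)
  hxy1 <- -sum(pv[pv > 0] * log(pxy[pv > 0]))

  c(angular_second_moment = sum(P^2),
    contrast = sum((ii - jj)^2 * P),
    correlation = if (sx > 0 && sy > 0)
      (sum(ii * jj * P) - mux * muy) / (sx * sy) else 0,
    variance = sum((ii - mux)^2 * P),
    inverse_difference_moment = sum(P / (1 + (ii - jj)^2)),
    sum_average = sum_avg,
    sum_variance = sum((ksum - sum_avg)^2 * psum),
    sum_entropy = entropy0(psum),
    entropy = hxy,
    difference_variance = sum((kdiff - mu_d)^2 * pdiff),
    difference_entropy = entropy0(pdiff),
    info_measure_correlation = if (max(hx, hy) > 0)
      (hxy - hxy1) / max(hx, hy) else 0,
    homogeneity = sum(P / (1 + abs(ii - jj))))
}

#' The 13 classical Haralick texture statistics
#'
#' Computes, for each offset's normalized co-occurrence matrix, the 13
#' classical second-order texture statistics: angular second moment,
#' contrast, correlation, variance (sum of squares about the row-mean
#' level), inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy, the
#' first information measure of correlation, and homogeneity.
#' Logarithms are natural and `0 * log 0` is taken as 0; sum variance
#' is centred on the sum average; correlation and the information
#' measure are defined as 0 for degenerate (zero-spread / zero-entropy)
#' matrices.
#'
#' @param g a `glcm_set` from [cooccurrence()].
#' @return 13 x n_offsets numeric matrix, rows named and ordered
#'   canonically.
#' @export
haralick_features <- function(g) {
  if (!inherits(g, "glcm_set")) stop("`g` must be a glcm_set", call. = FALSE)
  out <- vapply(g$probs, haralick_one, numeric(13L))
  out <- matrix(out, nrow = 13L,
                dimnames = list(haralick_feature_names,
                                vapply(g$offsets, paste, "", collapse = ",")))
  out
}

#' Extract the aggregated 13-feature texture vector of an image
#'
#' Quantizes the (optionally masked) image, accumulates one GLCM per
#' configured offset, computes the 13 Haralick statistics per offset,
#' and aggregates them across offsets by arithmetic mean, yielding the
#' single 13-vector consumed by feature selection and classification.
#'
#' @param img numeric intensity matrix.
#' @param mask optional 0/1 matrix restricting which pixels pair.
#' @param cfg a [glcm_config()].
#' @return named numeric vector of length 13, canonically ordered,
#'   with attribute `per_offset` holding the pre-aggregation matrix.
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 96, seed = 5))
#' extract_features(ph$image, ph$lung_mask)
#' @export
extract_features <- function(img, mask = NULL, cfg = glcm_config()) {
  lv <- quantize(img, mask, cfg$levels)
  g <- cooccurrence(lv, cfg$offsets, cfg$symmetric, n_levels = cfg$levels)
  per_offset <- haralick_features(g)
  out <- rowMeans(per_offset)
  attr(out, "per_offset") <- per_offset
  out
}
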