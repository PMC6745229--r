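#' Preprocessing / segmentation configuration
#'
#' Collects the tunables of the lung-field segmentation chain: the
#' adaptive median filter's maximum window, the periodic-line
#' structuring-element size `L` and direction, and the connectivity
#' used when clearing border-connected structures.
#'
#' @param max_window odd integer >= 3; adaptive-median window cap.
#' @param se_L periodic-line size parameter (the element has
#'   `2 * (L + 1)` members about its origin).
#' @param se_direction integer `(dr, dc)` direction of the periodic
#'   line.
#' @param border_connectivity 4 or 8; connectivity used by
#'   [clear_border()].
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_window = 7L, se_L = 2L,
                              se_direction = c(1L, 1L),
                              border_connectivity = 8L) {
  stopifnot_scalar_number(max_window, "max_window", min = 3, integer = TRUE)
  if (max_window %% 2 == 0)
    stop("`max_window` must be odd", call. = FALSE)
  stopifnot_scalar_number(se_L, "se_L", min = 0, integer = TRUE)
  if (!border_connectivity %in% c(4, 8))
    stop("`border_connectivity` must be 4 or 8", call. = FALSE)
  structure(list(max_window = as.integer(max_window),
                 se_L = as.integer(se_L),
                 se_direction = as.integer(se_direction),
                 border_connectivity = as.integer(border_connectivity)),
            class = "preprocess_config")
}

#' Adaptive median filter for impulse-noise removal
#'
#' Classical two-stage adaptive median filter: at each pixel the
#' window grows from 3x3 up to `max_window` until its median is not a
#' window extremum (stage A); the pixel is then kept unless it is
#' itself a window extremum, i.e. an impulse, in which case the window
#' median replaces it (stage B). Windows are clipped at the image
#' border. Non-impulse pixels are preserved, which retains fine detail
#' that a plain median filter would blur.
#'
#' @param img numeric matrix of intensities.
#' @param max_window odd integer >= 3.
#' @return filtered matrix, same shape.
#' @examples
#' img <- matrix(100, 9, 9); img[5, 5] <- 255
#' filtered <- adaptive_median_filter(img, 7)
#' filtered[5, 5]
#' @export
adaptive_median_filter <- function(img, max_window = 7L) {
  assert_gray_image(img)
  stopifnot_scalar_number(max_window, "max_window", min = 3, integer = TRUE)
  if (max_window %% 2 == 0)
    stop("`max_window` must be odd", call. = FALSE)
  .adaptive_median_cpp(img, as.integer(max_window))
}

#' Automatic threshold minimizing intra-class intensity variance
#'
#' Scans every candidate split of the intensity histogram and returns
#' the threshold `t` whose two classes (`<= t` and `> t`) have minimal
#' weighted within-class variance -- equivalently, maximal
#' between-class variance. This is the mixture-model/Otsu criterion.
#' Ties resolve to the smallest threshold.
#'
#' @param img numeric matrix with at least two distinct intensities.
#' @return scalar threshold (one of the observed intensity values).
#' @examples
#' mixture_threshold(matrix(c(50, 50, 50, 200), 2))
#' @export
mixture_threshold <- function(img) {
  assert_gray_image(img)
  u <- sort(unique(as.vector(img)))
  if (length(u) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  n <- tabulate(match(as.vector(img), u), nbins = length(u))
  ntot <- sum(n)
  cw <- cumsum(n)                       # class-0 counts for t = u[k]
  cm <- cumsum(n * u)                   # class-0 intensity sums
  k <- seq_len(length(u) - 1L)
  w0 <- cw[k] / ntot
  w1 <- 1 - w0
  mu0 <- cm[k] / cw[k]
  mu1 <- (cm[length(u)] - cm[k]) / (ntot - cw[k])
  between <- w0 * w1 * (mu0 - mu1)^2
  u[k[which.max(between)]]
}

#' Binarize an intensity image at a threshold
#'
#' Pixels strictly greater than `t` map to 1, all others (including
#' pixels equal to `t`) map to 0.
#'
#' @param img numeric matrix.
#' @param t scalar threshold.
#' @return 0/1 matrix, same shape.
#' @export
binarize <- function(img, t) {
  assert_gray_image(img)
  stopifnot_scalar_number(t, "t")
  (img > t) * 1
}

#' Periodic-line structuring element
#'
#' A flat element whose `2 * (L + 1)` members lie at integer multiples
#' `k * direction`, `k = -(L+1) .. -1, 1 .. (L+1)`, of a direction
#' vector about the origin. The origin itself is not counted as a
#' member but is included when the element is applied, anchoring the
#' neighbourhood on the processed pixel.
#'
#' @param L size parameter (>= 0).
#' @param direction integer `(dr, dc)`, not `(0, 0)`.
#' @return an object of class `strel` with an `offsets` matrix
#'   (member displacements, one `(dr, dc)` row each).
#' @examples
#' periodic_line_strel(2, c(1, 1))
#' @export
periodic_line_strel <- function(L = 2L, direction = c(1L, 1L)) {
  stopifnot_scalar_number(L, "L", min = 0, integer = TRUE)
  direction <- as.integer(direction)
  if (length(direction) != 2L || all(direction == 0L))
    stop("`direction` must be a non-zero (dr, dc) pair", call. = FALSE)
  k <- c(-(seq_len(L + 1L)), seq_len(L + 1L))
  offsets <- cbind(dr = k * direction[1], dc = k * direction[2])
  structure(list(offsets = offsets, L = as.integer(L),
                 direction = direction),
            class = "strel")
}

#' @export
print.strel <- function(x, ...) {
  cat(sprintf("periodic-line structuring element: L = %d, direction = (%d, %d), %d members\n",
              x$L, x$direction[1], x$direction[2], nrow(x$offsets)))
  invisible(x)
}

# Translate a binary matrix so out[p] = img[p + (dr, dc)], filling
# vacated cells with `fill`.
translate_bin <- function(img, dr, dc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  r_src <- max(1, 1 + dr):min(nr, nr + dr)
  c_src <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(r_src) < 1 || length(c_src) < 1 ||
      max(1, 1 + dr) > min(nr, nr + dr) || max(1, 1 + dc) > min(nc, nc + dc))
    return(out)
  out[r_src - dr, c_src - dc] <- img[r_src, c_src]
  out
}

se_offsets <- function(se) {
  if (inherits(se, "strel")) rbind(se$offsets, c(0L, 0L)) else
    rbind(as.matrix(se), c(0L, 0L))
}

erode_bin <- function(img, offsets) {
  out <- matrix(1, nrow(img), ncol(img))
  for (r in seq_len(nrow(offsets)))
    out <- out * translate_bin(img, offsets[r, 1], offsets[r, 2], fill = 0)
  out
}

dilate_bin <- function(img, offsets) {
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(offsets)))
    out <- pmax(out, translate_bin(img, -offsets[r, 1], -offsets[r, 2],
                                   fill = 0))
  out
}

#' Morphological opening of a binary image
#'
#' Erosion followed by dilation with the same structuring element
#' (the dilation uses the reflected element, so the result is the
#' union of all element translates fully contained in the input).
#' Opening is anti-extensive (`open(X)` is a subset of `X`) and
#' idempotent; it removes structures thinner than the element, such
#' as 1-px vessels and pleural tails.
#'
#' @param img 0/1 matrix.
#' @param se a [periodic_line_strel()] (or a matrix of `(dr, dc)`
#'   offset rows; the origin is always included).
#' @return opened 0/1 matrix.
#' @export
morphological_open <- function(img, se) {
  assert_binary_image(img)
  off <- se_offsets(se)
  dilate_bin(erode_bin(img, off), off)
}

conn_offsets <- function(connectivity) {
  if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
}

#' Remove connected components touching the image border
#'
#' Foreground components 4- or 8-connected to any image edge are
#' deleted by geodesic reconstruction from border seeds; interior
#' components are untouched. Never adds foreground pixels.
#'
#' @param img 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return 0/1 matrix with border-connected components removed.
#' @export
clear_border <- function(img, connectivity = 8) {
  assert_binary_image(img)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  nr <- nrow(img); nc <- ncol(img)
  seed <- matrix(0, nr, nc)
  seed[c(1, nr), ] <- 1
  seed[, c(1, nc)] <- 1
  seed <- seed * img
  # geodesic dilation: the origin is part of the neighbourhood so the
  # reconstruction grows monotonically from the seed
  off <- rbind(conn_offsets(connectivity), c(0, 0))
  repeat {
    grown <- pmin(dilate_bin(seed, off), img)
    if (all(grown == seed)) break
    seed <- grown
  }
  img * (1 - seed)
}

#' Segment the lung fields of a CT-like slice
#'
#' Runs the full morphological segmentation chain: adaptive median
#' filtering, automatic (intra-class-variance-minimizing) threshold,
#' binarization, periodic-line opening, complement, and clearing of
#' border-connected structures. On a chest slice with bright chest
#' wall and dark lung fields, the complement turns the lung fields
#' into interior components while the surrounding air ring is removed
#' with the border, leaving a lung-field mask.
#'
#' @param img numeric intensity matrix.
#' @param cfg a [preprocess_config()].
#' @return 0/1 lung-field mask.
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 96, seed = 2))
#' mask <- segment_lungs(ph$image)
#' dice_coefficient(mask, ph$lung_mask)
#' @export
segment_lungs <- function(img, cfg = preprocess_config()) {
  assert_gray_image(img)
  filtered <- adaptive_median_filter(img, cfg$max_window)
  t <- mixture_threshold(filtered)
  bin <- binarize(filtered, t)
  opened <- morphological_open(bin, periodic_line_strel(cfg$se_L,
                                                        cfg$se_direction))
  clear_border(1 - opened, cfg$border_connectivity)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return `2|A & B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  assert_binary_image(a, "a"); assert_binary_image(b, "b")
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}
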