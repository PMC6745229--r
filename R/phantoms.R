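#' Phantom specification for synthetic CT-like slices
#'
#' Describes a square chest-slice phantom: a bright thorax disk on a dark
#' (air) background, two dark axis-aligned lung-field ellipses, and
#' optionally one nodule of a given archetype rendered bright inside a
#' lung field. The four archetypes mirror the nodule taxonomy used in
#' lung-CT CAD work: well-circumscribed (isolated disk), juxta-pleural
#' (disk on the pleural boundary), vascularized (disk with attached
#' vessel segments) and pleural-tail (disk joined to the pleura by a
#' thin tail).
#'
#' Intensities are 8-bit means; `noise_sigma` is the standard deviation
#' of additive Gaussian noise and `impulse_density` the fraction of
#' pixels hit by salt-and-pepper noise (the impulse noise the adaptive
#' median stage exists to remove).
#'
#' @param image_size side length in pixels of the square slice.
#' @param lung_ellipses list of two ellipses, each
#'   `c(row, col, semi_row, semi_col)` in pixels.
#' @param nodule_type one of `"well_circumscribed"`, `"juxta_pleural"`,
#'   `"vascularized"`, `"pleural_tail"`, `"none"`.
#' @param nodule_radius nodule disk radius in pixels; must be smaller
#'   than the smallest lung semi-axis.
#' @param intensity named numeric vector with entries `background`,
#'   `lung`, `nodule`, `thorax` (8-bit means).
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param impulse_density fraction of pixels corrupted by impulse noise,
#'   in `[0, 1]`.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_size = 256L,
                         lung_ellipses = NULL,
                         nodule_type = c("well_circumscribed",
                                         "juxta_pleural",
                                         "vascularized",
                                         "pleural_tail",
                                         "none"),
                         nodule_radius = NULL,
                         intensity = c(background = 40, lung = 100,
                                       nodule = 180, thorax = 220),
                         noise_sigma = 4,
                         impulse_density = 0,
                         seed = 1L) {
  nodule_type <- match.arg(nodule_type)
  stopifnot_scalar_number(image_size, "image_size", min = 32, integer = TRUE)
  s <- image_size
  if (is.null(lung_ellipses)) {
    # keep the chest-wall strip clearly wider than the default
    # periodic-line element even at small render sizes
    lung_ellipses <- list(
      c(row = 0.51 * s, col = 0.33 * s, semi_row = 0.26 * s, semi_col = 0.13 * s),
      c(row = 0.51 * s, col = 0.67 * s, semi_row = 0.26 * s, semi_col = 0.13 * s)
    )
  }
  if (length(lung_ellipses) != 2L)
    stop("`lung_ellipses` must list exactly two ellipses", call. = FALSE)
  lung_ellipses <- lapply(lung_ellipses, function(e) {
    e <- as.numeric(e)
    if (length(e) != 4L || any(e[3:4] <= 0))
      stop("each ellipse must be c(row, col, semi_row, semi_col) with positive semi-axes",
           call. = FALSE)
    names(e) <- c("row", "col", "semi_row", "semi_col")
    e
  })
  min_semi <- min(vapply(lung_ellipses, function(e) min(e[3:4]), numeric(1)))
  if (is.null(nodule_radius)) nodule_radius <- max(3, round(0.2 * min_semi))
  stopifnot_scalar_number(nodule_radius, "nodule_radius", min = 1)
  if (nodule_type != "none" && nodule_radius >= min_semi)
    stop(sprintf(
      "nodule_radius (%.1f px) must be smaller than the smallest lung semi-axis (%.1f px): the nodule would not fit inside a lung field",
      nodule_radius, min_semi), call. = FALSE)
  stopifnot_scalar_number(impulse_density, "impulse_density", min = 0, max = 1)
  stopifnot_scalar_number(noise_sigma, "noise_sigma", min = 0)
  needed <- c("background", "lung", "nodule", "thorax")
  if (!all(needed %in% names(intensity)))
    stop("`intensity` needs named entries background, lung, nodule, thorax",
         call. = FALSE)
  structure(list(
    image_size = as.integer(s),
    lung_ellipses = lung_ellipses,
    nodule_type = nodule_type,
    nodule_radius = nodule_radius,
    intensity = intensity[needed],
    noise_sigma = noise_sigma,
    impulse_density = impulse_density,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

ellipse_mask <- function(s, e) {
  r <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  ((r - e["row"]) / e["semi_row"])^2 + ((cc - e["col"]) / e["semi_col"])^2 <= 1
}

disk_mask <- function(s, row, col, radius) {
  r <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  (r - row)^2 + (cc - col)^2 <= radius^2
}

# Integer Bresenham segment between two pixel centres; returns a
# two-column matrix of (row, col) coordinates.
bresenham_line <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dr - dc
  out <- matrix(0L, dr + dc + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r0 <- r0 + sr }
    if (e2 < dr)  { err <- err + dr; c0 <- c0 + sc }
  }
  out[seq_len(n), , drop = FALSE]
}

paint_line <- function(mask, pts) {
  s <- nrow(mask)
  keep <- pts[, 1] >= 1 & pts[, 1] <= s & pts[, 2] >= 1 & pts[, 2] <= s
  mask[pts[keep, , drop = FALSE]] <- TRUE
  mask
}

#' Generate a synthetic CT-like slice with ground-truth masks
#'
#' Renders the phantom described by a [phantom_spec()]: thorax disk,
#' two lung-field ellipses, one nodule of the requested archetype, then
#' additive Gaussian noise and (optionally) impulse noise. The nodule
#' is always placed in the first lung ellipse and its mask is clipped
#' to the lung region, so `nodule_mask` is a subset of `lung_mask`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with class `phantom`: `image` (numeric matrix,
#'   0--255), `lung_mask` and `nodule_mask` (0/1 matrices), and the
#'   generating `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 96, seed = 7))
#' sum(ph$nodule_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  s <- spec$image_size
  with_seed(spec$seed, {
    body <- ellipse_mask(s, c(row = 0.5 * s, col = 0.5 * s,
                              semi_row = 0.45 * s, semi_col = 0.47 * s))
    lung <- ellipse_mask(s, spec$lung_ellipses[[1]]) |
      ellipse_mask(s, spec$lung_ellipses[[2]])
    lung <- lung & body

    nodule <- matrix(FALSE, s, s)
    if (spec$nodule_type != "none") {
      e <- spec$lung_ellipses[[1]]
      rad <- spec$nodule_radius
      theta <- runif(1, 0, 2 * pi)
      if (spec$nodule_type == "juxta_pleural") {
        ctr <- c(e["row"] + e["semi_row"] * cos(theta),
                 e["col"] + e["semi_col"] * sin(theta))
        nodule <- disk_mask(s, ctr[1], ctr[2], rad)
      } else {
        # interior placement with margin so the disk itself stays off
        # the pleural boundary
        f <- if (spec$nodule_type == "pleural_tail") 0.55 else
          runif(1, 0, 0.35)
        ctr <- c(e["row"] + f * (e["semi_row"] - rad - 2) * cos(theta),
                 e["col"] + f * (e["semi_col"] - rad - 2) * sin(theta))
        nodule <- disk_mask(s, ctr[1], ctr[2], rad)
        if (spec$nodule_type == "vascularized") {
          for (k in 1:3) {
            ang <- runif(1, 0, 2 * pi)
            len <- runif(1, 2 * rad, 4 * rad)
            nodule <- paint_line(nodule, bresenham_line(
              ctr[1] + rad * cos(ang) * 0.9, ctr[2] + rad * sin(ang) * 0.9,
              ctr[1] + len * cos(ang), ctr[2] + len * sin(ang)))
          }
        }
        if (spec$nodule_type == "pleural_tail") {
          bnd <- c(e["row"] + (e["semi_row"] + 2) * cos(theta),
                   e["col"] + (e["semi_col"] + 2) * sin(theta))
          nodule <- paint_line(nodule,
                               bresenham_line(ctr[1], ctr[2], bnd[1], bnd[2]))
        }
      }
      nodule <- nodule & lung
      if (!any(nodule))
        stop("nodule fell entirely outside the lung region; enlarge the lung ellipses or shrink the nodule",
             call. = FALSE)
    }

    iv <- spec$intensity
    img <- matrix(iv["background"], s, s)
    img[body] <- iv["thorax"]
    img[lung] <- iv["lung"]
    img[nodule] <- iv["nodule"]
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(s * s, 0, spec$noise_sigma), s, s)
    img <- pmin(pmax(round(img), 0), 255)
    if (spec$impulse_density > 0)
      img <- add_impulse_noise(img, spec$impulse_density,
                               seed = derive_seed(spec$seed, 99L))
    structure(list(image = img,
                   lung_mask = lung * 1,
                   nodule_mask = nodule * 1,
                   spec = spec),
              class = "phantom")
  })
}

#' Corrupt an image with salt-and-pepper (impulse) noise
#'
#' Each pixel is independently corrupted with probability `density`;
#' a corrupted pixel is set to the minimum or maximum representable
#' intensity with equal probability.
#'
#' @param img numeric matrix.
#' @param density corruption probability per pixel, in `[0, 1]`.
#' @param seed integer seed.
#' @param lo,hi intensity extremes used for pepper/salt (default 8-bit
#'   0 and 255).
#' @return corrupted matrix, same shape.
#' @export
add_impulse_noise <- function(img, density, seed = 1L, lo = 0, hi = 255) {
  assert_gray_image(img)
  stopifnot_scalar_number(density, "density", min = 0, max = 1)
  if (density == 0) return(img)
  with_seed(seed, {
    hit <- runif(length(img)) < density
    salt <- runif(length(img)) < 0.5
    img[hit & salt] <- hi
    img[hit & !salt] <- lo
    img
  })
}

#' Specification of a labelled feature table with planted signal
#'
#' Describes a balanced two-class feature matrix in which only the
#' columns in `informative_idx` carry class signal: their
#' class-conditional means differ by `effect_size * noise_sigma`,
#' while every other column is pure Gaussian noise. This emulates the
#' setting where a handful of texture features out of the full GLCM
#' set are diagnostic and the rest are redundant.
#'
#' @param n_per_class samples per class.
#' @param n_features number of feature columns (default 13, the
#'   Haralick set size).
#' @param informative_idx indices of signal-carrying columns; the
#'   default marks angular second moment, contrast, correlation,
#'   variance, entropy and homogeneity in the canonical 13-feature
#'   ordering.
#' @param effect_size standardized between-class mean shift.
#' @param noise_sigma within-class standard deviation.
#' @param seed integer seed.
#' @return an object of class `feature_table_spec`.
#' @export
feature_table_spec <- function(n_per_class = 100L,
                               n_features = 13L,
                               informative_idx = c(1L, 2L, 3L, 4L, 9L, 13L),
                               effect_size = 3,
                               noise_sigma = 1,
                               seed = 1L) {
  stopifnot_scalar_number(n_per_class, "n_per_class", min = 2, integer = TRUE)
  stopifnot_scalar_number(n_features, "n_features", min = 1, integer = TRUE)
  informative_idx <- sort(unique(as.integer(informative_idx)))
  if (length(informative_idx) &&
      (min(informative_idx) < 1 || max(informative_idx) > n_features))
    stop("`informative_idx` must index columns 1..n_features", call. = FALSE)
  stopifnot_scalar_number(effect_size, "effect_size", min = 0)
  stopifnot_scalar_number(noise_sigma, "noise_sigma", min = 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 informative_idx = informative_idx,
                 effect_size = effect_size,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Generate a labelled feature table with a planted informative subset
#'
#' @param spec a [feature_table_spec()].
#' @return list with `X` (numeric matrix, named columns), `labels`
#'   (factor with levels `normal`, `cancer`), and `informative_idx`.
#' @examples
#' tab <- generate_feature_table(feature_table_spec(n_per_class = 20, seed = 3))
#' table(tab$labels)
#' @export
generate_feature_table <- function(spec) {
  if (!inherits(spec, "feature_table_spec"))
    stop("`spec` must be a feature_table_spec", call. = FALSE)
  n <- spec$n_per_class
  d <- spec$n_features
  with_seed(spec$seed, {
    X <- matrix(rnorm(2 * n * d, 0, spec$noise_sigma), 2 * n, d)
    shift <- spec$effect_size * spec$noise_sigma
    labels <- factor(rep(c("normal", "cancer"), each = n),
                     levels = c("normal", "cancer"))
    for (j in spec$informative_idx) {
      X[labels == "normal", j] <- X[labels == "normal", j] - shift / 2
      X[labels == "cancer", j] <- X[labels == "cancer", j] + shift / 2
    }
    colnames(X) <- if (d == 13L) haralick_feature_names else
      paste0("f", seq_len(d))
    list(X = X, labels = labels, informative_idx = spec$informative_idx)
  })
}

#' Write a phantom's image and masks as 8-bit PNG files
#'
#' @param phantom result of [generate_phantom()].
#' @param prefix file path prefix; writes `<prefix>_image.png`,
#'   `<prefix>_lung_mask.png`, `<prefix>_nodule_mask.png`.
#' @return invisibly, the written paths.
#' @export
write_phantom_png <- function(phantom, prefix) {
  paths <- paste0(prefix, c("_image.png", "_lung_mask.png", "_nodule_mask.png"))
  png::writePNG(phantom$image / 255, paths[1])
  png::writePNG(phantom$lung_mask, paths[2])
  png::writePNG(phantom$nodule_mask, paths[3])
  invisible(paths)
}
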