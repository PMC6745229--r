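# Independent brute-force oracles. These deliberately use plain loops
# and never share code with the package implementations they check.

# Two-stage adaptive-median decision rule, evaluated per pixel with
# clipped windows.
oracle_adaptive_median <- function(img, max_window) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    z <- img[i, j]
    zmed <- z
    decided <- FALSE
    for (w in seq(3, max_window, by = 2)) {
      h <- (w - 1) / 2
      win <- img[max(1, i - h):min(nr, i + h),
                 max(1, j - h):min(nc, j + h)]
      zmin <- min(win); zmax <- max(win); zmed <- median(win)
      if (zmin < zmed && zmed < zmax) {
        out[i, j] <- if (zmin < z && z < zmax) z else zmed
        decided <- TRUE
        break
      }
    }
    if (!decided) out[i, j] <- zmed
  }
  out
}

# Exhaustive intra-class-variance scan over every candidate threshold.
oracle_threshold <- function(img) {
  u <- sort(unique(as.vector(img)))
  x <- as.vector(img)
  best_t <- NA_real_
  best_v <- Inf
  for (k in seq_len(length(u) - 1)) {
    lo <- x[x <= u[k]]
    hi <- x[x > u[k]]
    v0 <- if (length(lo) > 1) var(lo) * (length(lo) - 1) / length(lo) else 0
    v1 <- if (length(hi) > 1) var(hi) * (length(hi) - 1) / length(hi) else 0
    wv <- (length(lo) * v0 + length(hi) * v1) / length(x)
    if (wv < best_v - 1e-12) { best_v <- wv; best_t <- u[k] }
  }
  best_t
}

# Erosion-then-dilation with explicit per-pixel loops. `offsets` are the
# structuring-element member displacements; the origin is included.
oracle_open <- function(img, offsets) {
  offsets <- rbind(offsets, c(0, 0))
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    keep <- TRUE
    for (r in seq_len(nrow(offsets))) {
      ii <- i + offsets[r, 1]; jj <- j + offsets[r, 2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || img[ii, jj] == 0) {
        keep <- FALSE
        break
      }
    }
    ero[i, j] <- as.numeric(keep)
  }
  dil <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (r in seq_len(nrow(offsets))) {
      ii <- i - offsets[r, 1]; jj <- j - offsets[r, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && ero[ii, jj] == 1) {
        dil[i, j] <- 1
        break
      }
    }
  }
  dil
}

# Breadth-first flood fill from the border over foreground pixels.
oracle_clear_border <- function(img, connectivity = 8) {
  nr <- nrow(img); nc <- ncol(img)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)) else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  visited <- matrix(FALSE, nr, nc)
  queue <- which(img == 1 &
                   (row(img) %in% c(1, nr) | col(img) %in% c(1, nc)))
  visited[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    for (r in seq_len(nrow(nb))) {
      ii <- i + nb[r, 1]; jj <- j + nb[r, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          img[ii, jj] == 1 && !visited[ii, jj]) {
        visited[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * nr + ii)
      }
    }
  }
  out <- img
  out[visited] <- 0
  out
}

# Pair counting by explicit double loop.
oracle_cooccurrence <- function(lv, dr, dc, L) {
  nr <- nrow(lv); nc <- ncol(lv)
  cm <- matrix(0, L, L)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + dr; jj <- j + dc
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
        !is.na(lv[i, j]) && !is.na(lv[ii, jj]))
      cm[lv[i, j], lv[ii, jj]] <- cm[lv[i, j], lv[ii, jj]] + 1
  }
  cm
}

# The 13 Haralick statistics by straight loops over the grid.
oracle_haralick <- function(P) {
  L <- nrow(P)
  lg <- function(x) if (x > 0) log(x) else 0
  px <- py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px))
  sy <- sqrt(sum(((1:L) - muy)^2 * py))
  psum <- numeric(2 * L); pdiff <- numeric(L)   # indices k and k+1
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  asm <- con <- cor_num <- vari <- idm <- ent <- hom <- hxy1 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    vari <- vari + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    hom <- hom + p / (1 + abs(i - j))
    if (p > 0) hxy1 <- hxy1 - p * lg(px[i] * py[j])
  }
  savg <- sum((2:(2 * L)) * psum[2:(2 * L)])
  svar <- sum(((2:(2 * L)) - savg)^2 * psum[2:(2 * L)])
  sent <- -sum(vapply(psum, function(p) p * lg(p), 0))
  mud <- sum((0:(L - 1)) * pdiff)
  dvar <- sum(((0:(L - 1)) - mud)^2 * pdiff)
  dent <- -sum(vapply(pdiff, function(p) p * lg(p), 0))
  hx <- -sum(vapply(px, function(p) p * lg(p), 0))
  hy <- -sum(vapply(py, function(p) p * lg(p), 0))
  c(angular_second_moment = asm,
    contrast = con,
    correlation = if (sx > 0 && sy > 0) (cor_num - mux * muy) / (sx * sy) else 0,
    variance = vari,
    inverse_difference_moment = idm,
    sum_average = savg,
    sum_variance = svar,
    sum_entropy = sent,
    entropy = ent,
    difference_variance = dvar,
    difference_entropy = dent,
    info_measure_correlation = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    homogeneity = hom)
}

# Equal-prior Parzen/Bayes classifier with Gaussian kernels of
# bandwidth h (matching a PNN with b = sqrt(-ln 0.5)/spread when
# h = 1 / (b * sqrt(2))).
oracle_parzen <- function(Xtr, ytr, Xte, h) {
  ytr <- as.factor(ytr)
  pred <- character(nrow(Xte))
  for (q in seq_len(nrow(Xte))) {
    best <- -Inf; best_c <- levels(ytr)[1]
    for (cl in levels(ytr)) {
      dens <- 0
      idx <- which(ytr == cl)
      for (i in idx) {
        d2 <- sum((Xtr[i, ] - Xte[q, ])^2)
        dens <- dens + exp(-d2 / (2 * h^2))
      }
      dens <- dens / length(idx)
      if (dens > best) { best <- dens; best_c <- cl }
    }
    pred[q] <- best_c
  }
  factor(pred, levels = levels(ytr))
}

random_prob_grid <- function(L) {
  g <- matrix(runif(L * L), L, L)
  g / sum(g)
}
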