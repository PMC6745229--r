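test_that("adaptive median filter removes impulses and keeps detail", {
  const <- matrix(120, 10, 10)
  expect_identical(adaptive_median_filter(const, 7), const)

  img <- matrix(100, 11, 11)
  img[6, 6] <- 255
  out <- adaptive_median_filter(img, 7)
  expect_equal(out[6, 6], 100)
  expect_identical(out[-6, ], img[-6, ])
  expect_identical(out[6, -6], img[6, -6])

  expect_error(adaptive_median_filter(img, 6), "odd")
})

test_that("adaptive median filter matches the per-pixel decision-rule oracle", {
  # noise-free ramp: every interior pixel sits strictly between its
  # window extremes and is preserved; border pixels tie with a clipped
  # window's extremum and follow the median path of the rule, which the
  # oracle reproduces
  ramp <- matrix(seq(10, 120, length.out = 12), nrow = 9, ncol = 12,
                 byrow = TRUE)
  out <- adaptive_median_filter(ramp, 7)
  expect_identical(out, oracle_adaptive_median(ramp, 7))
  expect_identical(out[2:8, 2:11], ramp[2:8, 2:11])

  set.seed(42)
  for (rep in 1:3) {
    img <- matrix(sample(40:200, 12 * 10, replace = TRUE), 12, 10)
    img <- add_impulse_noise(img, 0.15, seed = rep)
    for (mw in c(3, 5, 7))
      expect_equal(adaptive_median_filter(img, mw),
                   oracle_adaptive_median(img, mw))
  }
})

test_that("mixture threshold separates bimodal intensity populations", {
  half <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t1 <- mixture_threshold(half)
  expect_true(all(half[half <= t1] == 10))
  expect_true(all(half[half > t1] == 200))

  two <- matrix(c(0, 255), 1, 2)
  t2 <- mixture_threshold(two)
  expect_true(0 <= t2 && t2 < 255)
  expect_equal(binarize(two, t2), matrix(c(0, 1), 1, 2))

  four <- matrix(c(50, 50, 50, 200), 2, 2)
  t3 <- mixture_threshold(four)
  expect_true(all(c(50, 50, 50) <= t3) && 200 > t3)

  expect_error(mixture_threshold(matrix(7, 3, 3)), "degenerate histogram")
})

test_that("mixture threshold equals the exhaustive intra-class-variance scan", {
  set.seed(7)
  agree <- logical(100)
  for (i in 1:100) {
    img <- matrix(sample(0:255, 64, replace = TRUE,
                         prob = runif(256)^2), 8, 8)
    agree[i] <- length(unique(as.vector(img))) < 2 ||
      isTRUE(all.equal(mixture_threshold(img), oracle_threshold(img)))
  }
  expect_true(all(agree))
})

test_that("binarization maps > t to one, everything else to zero", {
  img <- matrix(c(10, 200, 100, 100), 2, 2)
  expect_equal(binarize(img, 100), matrix(c(0, 1, 0, 0), 2, 2))
  expect_equal(binarize(img, 5), matrix(1, 2, 2))
  expect_equal(binarize(img, 250), matrix(0, 2, 2))
})

test_that("periodic-line elements have 2*(L+1) symmetric members", {
  se <- periodic_line_strel(2, c(1, 1))
  expect_equal(nrow(se$offsets), 6)
  got <- se$offsets[order(se$offsets[, 1]), ]
  want <- cbind(dr = c(-3, -2, -1, 1, 2, 3), dc = c(-3, -2, -1, 1, 2, 3))
  expect_equal(got, want)

  se0 <- periodic_line_strel(0, c(0, 1))
  expect_equal(nrow(se0$offsets), 2)
  expect_setequal(se0$offsets[, 2], c(-1, 1))
  expect_true(all(se0$offsets[, 1] == 0))

  # closed under negation
  for (L in 0:3) {
    off <- periodic_line_strel(L, c(1, -2))$offsets
    expect_equal(nrow(off), 2 * (L + 1))
    key <- paste(off[, 1], off[, 2])
    neg <- paste(-off[, 1], -off[, 2])
    expect_setequal(key, neg)
  }

  expect_error(periodic_line_strel(2, c(0, 0)), "non-zero")
})

test_that("opening is anti-extensive, idempotent and removes thin structure", {
  se <- periodic_line_strel(1, c(0, 1))
  set.seed(3)
  for (i in 1:10) {
    img <- matrix(rbinom(100, 1, 0.5), 10, 10)
    opened <- morphological_open(img, se)
    expect_true(all(opened <= img))                     # anti-extensive
    expect_equal(morphological_open(opened, se), opened) # idempotent
  }

  lone <- matrix(0, 7, 7); lone[4, 4] <- 1
  expect_equal(sum(morphological_open(lone, se)), 0)

  rect <- matrix(0, 12, 12); rect[3:10, 2:11] <- 1
  expect_equal(morphological_open(rect, se),
               oracle_open(rect, se$offsets))
})

test_that("opening equals the erosion-dilation oracle on all 4x4 images", {
  se <- periodic_line_strel(0, c(0, 1))   # 2-member element
  img <- matrix(0, 4, 4)
  mismatches <- 0L
  for (code in 0:65535) {
    img[] <- as.numeric(bitwAnd(bitwShiftR(code, 0:15), 1L))
    if (!identical(morphological_open(img, se), oracle_open(img, se$offsets)))
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("border clearing removes exactly the border-connected components", {
  img <- matrix(0, 5, 5)
  img[3, 3] <- 1   # interior
  img[1, 1] <- 1   # corner
  out <- clear_border(img)
  expect_equal(sum(out), 1)
  expect_equal(out[3, 3], 1)

  expect_equal(clear_border(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_equal(clear_border(matrix(1, 4, 4)), matrix(0, 4, 4))

  # diagonal chain to the border: removed under 8-connectivity only
  diag_img <- matrix(0, 5, 5)
  diag_img[cbind(1:3, 1:3)] <- 1
  expect_equal(sum(clear_border(diag_img, 8)), 0)
  expect_equal(sum(clear_border(diag_img, 4)), 2)

  set.seed(11)
  for (i in 1:10) {
    img <- matrix(rbinom(64, 1, 0.4), 8, 8)
    for (conn in c(4, 8)) {
      out <- clear_border(img, conn)
      expect_true(all(out <= img))   # never adds foreground
      expect_equal(out, oracle_clear_border(img, conn))
    }
  }
})

test_that("lung segmentation recovers the phantom lung fields", {
  ph <- generate_phantom(phantom_spec(image_size = 128, seed = 4))
  mask <- segment_lungs(ph$image)
  expect_gt(dice_coefficient(mask, ph$lung_mask), 0.9)

  # robust to moderate impulse noise: masks differ in < 1% of pixels
  ph_noisy <- generate_phantom(phantom_spec(image_size = 128, seed = 4,
                                            impulse_density = 0.05))
  mask_noisy <- segment_lungs(ph_noisy$image)
  expect_lt(mean(mask != mask_noisy), 0.01)

  # output is contained in the opened-binarization complement's support
  filt <- adaptive_median_filter(ph$image, 7)
  opened <- morphological_open(binarize(filt, mixture_threshold(filt)),
                               periodic_line_strel(2, c(1, 1)))
  expect_true(all(mask <= 1 - opened))

  expect_error(segment_lungs(matrix(50, 32, 32)), "degenerate histogram")
})
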