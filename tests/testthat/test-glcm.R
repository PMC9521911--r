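test_that("quantization follows floor(v L / 256) and is monotone", {
  v <- 0:255
  expect_identical(quantize(array(v, c(1, 16, 16)), 256),
                   array(v, c(1, 16, 16)))
  expect_identical(quantize(matrix(c(127L, 128L), 1), 2),
                   matrix(c(0L, 1L), 1))
  for (L in c(2L, 8L, 32L, 64L)) {
    q <- quantize(array(v, c(1, 1, 256)), L)
    expect_true(all(diff(as.vector(q)) >= 0))
    expect_equal(range(q), c(0L, L - 1L))
  }
  expect_error(quantize(array(0L, c(1, 1, 1)), 1), "L")
  expect_error(quantize(array(0L, c(1, 1, 1)), 300), "256")
})

test_that("direction sets have the stated counts and no 3D antipodes", {
  d2 <- direction_offsets(2)
  expect_equal(nrow(d2$offsets), 8L)
  # angular order: 0 deg east, 90 deg north (row up), 180 west, 270 south
  expect_equal(unname(d2$offsets[1, ]), c(0L, 1L))
  expect_equal(unname(d2$offsets[3, ]), c(-1L, 0L))
  expect_equal(unname(d2$offsets[5, ]), c(0L, -1L))
  expect_equal(unname(d2$offsets[7, ]), c(1L, 0L))

  d3 <- direction_offsets(3)
  expect_equal(nrow(d3$offsets), 13L)
  for (i in seq_len(13)) {
    neg <- -d3$offsets[i, ]
    expect_false(any(apply(d3$offsets, 1, function(o) all(o == neg))))
  }
  expect_error(direction_offsets(4), "2 or 3")
})

test_that("single-offset GLCM matches hand counts and the brute-force oracle", {
  m <- matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE)
  expect_equal(glcm_single(m, c(0, 1), L = 2), matrix(c(1, 0, 0, 1), 2))

  const <- matrix(2L, 4, 4)
  g <- glcm_single(const, c(1, 0), L = 4, normalize = TRUE)
  expect_equal(sum(g), 1)
  expect_equal(g[3, 3], 1)

  # 200 random small images across offsets and L
  cases <- 0
  for (seed in 1:25) {
    for (L in c(2L, 4L, 8L)) {
      img2 <- glcmfusion:::with_seed(seed * 100 + L, rand_img(c(6, 7), L))
      off2 <- direction_offsets(2)$offsets
      for (k in sample(1:8, 2)) {
        expect_equal(glcm_single(img2, off2[k, ], L),
                     naive_glcm(img2, off2[k, ], L))
        cases <- cases + 1
      }
      img3 <- glcmfusion:::with_seed(seed * 200 + L, rand_img(c(3, 4, 5), L))
      off3 <- direction_offsets(3)$offsets
      for (k in sample(1:13, 2)) {
        expect_equal(glcm_single(img3, off3[k, ], L, symmetric = TRUE),
                     naive_glcm(img3, off3[k, ], L, symmetric = TRUE))
        cases <- cases + 1
      }
    }
  }
  expect_gte(cases, 200)
})

test_that("raw pair totals match the closed form for full rectangles", {
  img <- glcmfusion:::with_seed(4, rand_img(c(9, 12), 4))
  for (k in 1:8) {
    off <- direction_offsets(2)$offsets[k, ]
    tot <- sum(glcm_single(img, off, 4))
    expect_equal(tot, unname((9 - abs(off[1])) * (12 - abs(off[2]))))
  }
})

test_that("2D stacks: 8 matrices, 180-degree transpose, rotation permutation", {
  img <- glcmfusion:::with_seed(6, rand_img(c(12, 12), 8))
  st <- glcm_2d(img, 8)
  expect_length(st$matrices, 8)
  expect_true(all(vapply(st$matrices, function(m) abs(sum(m) - 1) < 1e-12,
                         logical(1))))

  # transpose identity on raw counts: angle + 180 = t(angle)
  offs <- direction_offsets(2)$offsets
  for (k in 1:4) {
    raw_a <- glcm_single(img, offs[k, ], 8)
    raw_b <- glcm_single(img, offs[k + 4, ], 8)
    expect_equal(raw_b, t(raw_a))
  }

  # constant slice: every matrix a single unit mass
  cst <- glcm_2d(matrix(3L, 5, 5), 8)
  for (m in cst$matrices) expect_equal(m[4, 4], 1)

  # rotating the slice 90 deg CCW shifts the direction stack by -90 deg:
  # new angle k maps to old angle k + 270 deg (index (k-1+6) %% 8 + 1)
  rot <- matrix(0L, 12, 12)
  for (r in 1:12) for (c in 1:12) rot[r, c] <- img[c, 12 + 1 - r]
  for (k in 1:8) {
    raw_rot <- glcm_single(rot, offs[k, ], 8)
    raw_orig <- glcm_single(img, offs[(k - 1 + 6) %% 8 + 1, ], 8)
    expect_equal(raw_rot, raw_orig)
  }
})

test_that("volume-space partition: counts, remainder rule, order", {
  vol <- array(seq_len(9 * 2 * 2), c(9, 2, 2))
  vss <- partition_volume_spaces(vol, 3)
  expect_length(vss, 3)
  expect_equal(dim(vss[[2]])[1], 3L)
  expect_equal(vss[[1]][1, 1, 1], vol[1, 1, 1])
  expect_equal(vss[[3]][3, 1, 1], vol[9, 1, 1])

  vol10 <- array(0L, c(10, 2, 2))
  vss10 <- partition_volume_spaces(vol10, 3)
  expect_length(vss10, 4)
  expect_equal(dim(vss10[[4]])[1], 1L)

  expect_error(partition_volume_spaces(array(0, c(1, 2, 2))), "2 slices")
})

test_that("3D stacks: 13 matrices, one-hot constants, VS boundary accounting", {
  slab <- glcmfusion:::with_seed(9, rand_img(c(6, 5, 5), 4))
  st <- glcm_3d_vs(slab, 4)
  expect_length(st$matrices, 13)
  expect_true(all(vapply(st$matrices, function(m) abs(sum(m) - 1) < 1e-12,
                         logical(1))))

  cst <- glcm_3d_vs(array(1L, c(3, 4, 4)), 4)
  for (m in cst$matrices) expect_equal(m[2, 2], 1)

  # whole-slab counts = per-VS counts + boundary-crossing pairs
  off <- c(1L, 0L, 0L)
  whole <- glcm_single(slab, off, 4, symmetric = TRUE)
  a <- glcm_single(slab[1:3, , , drop = FALSE], off, 4, symmetric = TRUE)
  b <- glcm_single(slab[4:6, , , drop = FALSE], off, 4, symmetric = TRUE)
  cross <- matrix(0, 4, 4)
  for (r in 1:5) for (c in 1:5) {
    i <- slab[3, r, c]; j <- slab[4, r, c]
    cross[i + 1, j + 1] <- cross[i + 1, j + 1] + 1
  }
  expect_equal(whole, a + b + cross + t(cross))
})

test_that("Haralick descriptors: closed forms and independent summation", {
  onehot <- matrix(0, 4, 4); onehot[2, 2] <- 1
  hd <- haralick_descriptors(onehot)
  expect_length(hd, 16)
  expect_equal(hd[["energy"]], 1)
  expect_equal(hd[["contrast"]], 0)
  expect_equal(hd[["entropy"]], 0)
  expect_equal(hd[["mcc"]], 0)  # single-level support

  unif <- matrix(0.25, 2, 2)
  hu <- haralick_descriptors(unif)
  expect_equal(hu[["energy"]], 0.25)
  expect_equal(hu[["entropy"]], 2)   # 2 bits
  expect_equal(hu[["mcc"]], 0)       # independent marginals
  expect_equal(hu[["imc1"]], 0)

  # perfectly correlated diagonal GLCM: correlation and MCC reach 1
  diag_p <- diag(4) / 4
  hdg <- haralick_descriptors(diag_p)
  expect_equal(hdg[["correlation"]], 1)
  expect_equal(hdg[["mcc"]], 1, tolerance = 1e-8)

  # random normalized matrix vs direct double-sum oracle
  for (seed in 1:5) {
    p <- glcmfusion:::with_seed(seed, {
      raw <- matrix(stats::rexp(36), 6, 6)
      raw / sum(raw)
    })
    got <- haralick_descriptors(p)
    L <- 6
    en <- 0; con <- 0; idm <- 0; ent <- 0; dis <- 0; sij <- 0
    for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
      pij <- p[i + 1, j + 1]
      en <- en + pij^2
      con <- con + (i - j)^2 * pij
      idm <- idm + pij / (1 + (i - j)^2)
      dis <- dis + abs(i - j) * pij
      if (pij > 0) ent <- ent - pij * log2(pij)
      sij <- sij + i * j * pij
    }
    px <- rowSums(p); py <- colSums(p)
    mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
    sdx <- sqrt(sum(((0:(L - 1)) - mux)^2 * px))
    sdy <- sqrt(sum(((0:(L - 1)) - muy)^2 * py))
    expect_equal(got[["energy"]], en)
    expect_equal(got[["contrast"]], con)
    expect_equal(got[["idm"]], idm)
    expect_equal(got[["entropy"]], ent)
    expect_equal(got[["dissimilarity"]], dis)
    expect_equal(got[["correlation"]], (sij - mux * muy) / (sdx * sdy))
    expect_equal(got[["variance"]], sum(outer(((0:(L-1)) - mux)^2,
                                              rep(1, L)) * p))
    expect_equal(got[["max_prob"]], max(p))
    # sum / difference distributions
    psum <- vapply(0:(2 * L - 2), function(k) {
      s <- 0
      for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
        if (i + j == k) s <- s + p[i + 1, j + 1]
      }
      s
    }, numeric(1))
    sa <- sum((0:(2 * L - 2)) * psum)
    expect_equal(got[["sum_average"]], sa)
    expect_equal(got[["sum_variance"]], sum(((0:(2 * L - 2)) - sa)^2 * psum))
    expect_true(all(is.finite(got)))
  }

  expect_error(haralick_descriptors(matrix(1, 2, 2)), "normalized")
})

test_that("feature sequences have the stated shapes, padding and order", {
  vol <- glcmfusion:::with_seed(10, {
    ct_volume(rand_img(c(9, 10, 10), 8), domain = "quantized", levels = 8)
  })
  fs3 <- build_feature_sequence(vol, "glcm3d", slices_per_vs = 3)
  expect_equal(fs3$n_real, 3L)
  expect_equal(fs3$f, 13L * 64L)
  expect_true(all(fs3$mask))

  slice <- vol$voxels[1, , , drop = TRUE]
  fs2 <- build_feature_sequence(slice, "glcm2d", L = 8)
  expect_equal(dim(fs2$steps), c(8L, 64L))
  expect_true(all(fs2$mask))
  # vectorization is row-major flattening in direction order
  st <- glcm_2d(slice, 8)
  expect_equal(fs2$steps[1, ], as.vector(t(st$matrices[[1]])))
  expect_equal(fs2$steps[8, ], as.vector(t(st$matrices[[8]])))

  fs25 <- build_feature_sequence(vol, "glcm2_5d")
  expect_equal(fs25$n_real, 9L)
  expect_equal(fs25$f, 8L * 64L)

  fsd <- build_feature_sequence(vol, "descriptors")
  expect_equal(fsd$n_real, 3L)
  expect_equal(fsd$f, 13L * 16L)

  padded <- build_feature_sequence(vol, "glcm3d", max_len = 5)
  expect_equal(sum(padded$mask), 3L)
  expect_true(all(padded$steps[4:5, ] == 0))

  expect_error(build_feature_sequence(vol, "glcm3d", max_len = 2),
               "refusing to truncate")
})
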