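test_that("intensity features follow the stated conventions", {
  w <- matrix(1:9, 3, 3)
  f <- intensity_features(w)
  expect_equal(unname(f[c("i1", "i2", "i3", "i5", "i6")]), c(5, 5, 5, 1, 9))
  expect_equal(unname(f["i4"]), sqrt(7.5), tolerance = 1e-6)  # n-1 SD
  expect_equal(unname(f["i7"]), 2.0)  # (Q3 - Q1) / 2, type-7 interpolation
  expect_equal(unname(intensity_features(matrix(3.5, 3, 3))),
               c(3.5, 3.5, 3.5, 0, 3.5, 3.5, 0))
})

test_that("Sobel gradients have the documented sign, scale and symmetry", {
  const <- matrix(5, 6, 7)
  G <- sobel_gradients(const)
  expect_true(all(G$gx == 0) && all(G$gy == 0))
  ramp <- matrix(rep(1:7, each = 6), 6, 7)  # unit ramp along x (columns)
  Gr <- sobel_gradients(ramp)
  expect_true(all(Gr$gx[2:5, 2:6] == 8))
  expect_true(all(Gr$gy == 0))
  set.seed(31)
  m <- matrix(rnorm(30), 5, 6)
  Gm <- sobel_gradients(m)
  Gt <- sobel_gradients(t(m))
  expect_equal(Gt$gx, t(Gm$gy), tolerance = 1e-12)
  expect_equal(Gt$gy, t(Gm$gx), tolerance = 1e-12)
})

test_that("gradient features match their analytic values on ramps", {
  ramp <- matrix(rep(1:7, each = 6), 6, 7)
  G <- sobel_gradients(ramp)
  f <- gradient_features(G$gx[2:4, 3:5], G$gy[2:4, 3:5])
  expect_equal(unname(f["g2"]), 72)       # 9 pixels x |G| = 8
  expect_equal(unname(f["g3"]), 8)
  expect_equal(unname(f["g5"]), 0)
  expect_equal(unname(f["g1"]), 72)       # gy = 0 so L1 = |gx|
  expect_equal(unname(f["g10"]), 8)       # mean ||gx| - |gy|| = 8
  z <- gradient_features(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_true(all(z == 0))
  # norm inequality g1 >= g2 on random windows
  set.seed(32)
  for (i in 1:20) {
    gx <- matrix(rnorm(9), 3, 3); gy <- matrix(rnorm(9), 3, 3)
    f <- gradient_features(gx, gy)
    expect_gte(f[["g1"]], f[["g2"]] - 1e-12)
  }
})

test_that("GLCM features match the checkerboard and constant cases", {
  cb <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  f <- glcm_features(cb, 2)
  expect_equal(unname(f), c(0.5, 0, 0.5, 0.75), tolerance = 1e-12)
  fc <- glcm_features(matrix(3, 3, 3), 8)
  expect_equal(unname(fc[c("f1", "f3", "f4")]), c(0, 1, 1))
  expect_true(is.na(fc["f2"]))
  expect_error(glcm_features(cb, 1), class = "bmetex_param_error")
})

test_that("GLCM features equal brute-force pair enumeration on random windows", {
  set.seed(33)
  for (L in c(2L, 4L, 8L)) {
    for (i in 1:40) {
      w <- matrix(sample(0:(L - 1), 9, TRUE), 3, 3)
      got <- glcm_features(w, L)
      want <- oracle_glcm(w, L)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("symmetric-permutation invariance of order-statistic features", {
  set.seed(34)
  for (i in 1:20) {
    w <- matrix(rnorm(9), 3, 3)
    # shuffle everything except the centre
    idx <- c(1:4, 6:9)
    v <- as.vector(w)
    v[idx] <- v[sample(idx)]
    wp <- matrix(v, 3, 3)
    a <- intensity_features(w); b <- intensity_features(wp)
    expect_equal(a[c("i2", "i4", "i5", "i6", "i7")],
                 b[c("i2", "i4", "i5", "i6", "i7")], tolerance = 1e-12)
  }
})

test_that("feature table has 21 feature columns and respects the border rule", {
  spec <- small_spec()
  s <- generate_scan(spec, "P020", "baseline", "control")
  d <- dim(s$volume$data)
  centres <- array(FALSE, d)
  centres[10, 10, 2] <- TRUE   # interior voxel
  ft <- extract_feature_table(s$volume, s$truth$labelmap, centres = centres)
  expect_identical(nrow(ft), 1L)
  expect_identical(sum(names(ft) %in% feature_names()), 21L)
  expect_true(all(!is.na(ft[, setdiff(feature_names(), "f2")])))

  centres[1, 5, 2] <- TRUE     # border voxel: excluded with a message
  expect_message(
    ft2 <- extract_feature_table(s$volume, s$truth$labelmap,
                                 centres = centres),
    "border"
  )
  expect_identical(nrow(ft2), 1L)
  expect_identical(attr(ft2, "n_excluded_border"), 1L)

  # row count equals the number of interior mask voxels
  ft3 <- extract_feature_table(s$volume, s$truth$labelmap)
  marrow <- s$truth$marrow
  co <- which(marrow, arr.ind = TRUE)
  n_int <- sum(co[, 1] >= 2 & co[, 1] <= d[1] - 1 &
                 co[, 2] >= 2 & co[, 2] <= d[2] - 1)
  expect_identical(nrow(ft3), as.integer(n_int))
  expect_identical(unname(table(ft3$status)[["BME"]]),
                   as.integer(sum(s$truth$lesion)))
})

test_that("the vectorized extractor equals the per-window reference ops", {
  spec <- small_spec(rician_sigma = 4)
  s <- generate_scan(spec, "P021", "week11", "HIIT")
  ft <- suppressMessages(extract_feature_table(s$volume, s$truth$labelmap))
  set.seed(35)
  q <- quantize_levels(s$volume$data, 8)
  for (i in sample(nrow(ft), 25)) {
    r <- ft[i, ]
    sl <- s$volume$data[, , r$slice]
    win <- sl[(r$row - 1):(r$row + 1), (r$col - 1):(r$col + 1)]
    expect_equal(unname(unlist(r[paste0("i", 1:7)])),
                 unname(intensity_features(win)), tolerance = 1e-10)
    G <- sobel_gradients(sl)
    gw <- gradient_features(G$gx[(r$row - 1):(r$row + 1),
                                 (r$col - 1):(r$col + 1)],
                            G$gy[(r$row - 1):(r$row + 1),
                                 (r$col - 1):(r$col + 1)])
    expect_equal(unname(unlist(r[paste0("g", 1:10)])), unname(gw),
                 tolerance = 1e-10)
    fw <- glcm_features(q[(r$row - 1):(r$row + 1),
                          (r$col - 1):(r$col + 1), r$slice], 8)
    expect_equal(unname(unlist(r[paste0("f", 1:4)])), unname(fw),
                 tolerance = 1e-10)
  }
})

test_that("healthy sampling avoids lesions and their neighbourhood", {
  spec <- small_spec(lesion_count_range = c(2L, 3L))
  s <- generate_scan(spec, "P022", "baseline", "control")
  hs <- sample_healthy(s$truth$labelmap, 50, seed = 9)
  expect_identical(sum(hs), 50L)
  expect_false(any(hs & s$truth$lesion))
  # not adjacent either: check a dilated lesion mask
  expect_false(any(hs & bmetex:::dilate26(s$truth$lesion)))
  hs2 <- sample_healthy(s$truth$labelmap, 50, seed = 9)
  expect_identical(hs, hs2)
  expect_warning(sample_healthy(s$truth$labelmap, 1e6, seed = 1),
                 "candidates")
})
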