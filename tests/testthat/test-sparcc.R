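test_that("a fully positive spine scores the SPARCC maximum of 108", {
  fp <- fully_positive()
  res <- sparcc_total(fp$lesions, fp$image, fp$ann)
  expect_identical(res$total, 108L)
  expect_true(all(res$per_unit$score[res$per_unit$selected] == 18L))
})

test_that("unit scores count quadrant, depth and intensity bits correctly", {
  spec <- small_spec(rician_sigma = 0, bias_amplitude = 0,
                     lesion_count_range = c(0L, 0L))
  s <- generate_scan(spec, "U", "baseline", "control")
  ann <- s$truth$annotation
  u <- ann$units[[1]]
  lm <- s$truth$labelmap
  img <- s$truth$clean

  # empty unit scores 0
  expect_identical(score_unit(lm, img, u, 1:3,
                              csf_med = 200)$score, 0L)

  # one small dim shallow lesion in one quadrant of one slice -> exactly 1
  q <- u$quadrants$sa
  lm1 <- lm
  lm1$labels[q$rows[2], q$cols[1], 2] <- 2L   # next to the endplate: shallow
  img1 <- img
  img1$data[q$rows[2], q$cols[1], 2] <- 120   # dim: below 0.75 * 200
  parts <- score_unit(lm1, img1, u, 1:3, csf_med = 200)
  expect_identical(parts$quadrant, 1L)
  expect_identical(parts$depth, 0L)
  expect_identical(parts$intensity, 0L)

  # bright and deep lesion filling the superior vertebra: adds bonuses
  lm2 <- lm
  lm2$labels[u$vert_sup_rows[1]:u$vert_sup_rows[2],
             u$cols[1]:u$cols[2], 2] <- 2L
  img2 <- img
  img2$data[u$vert_sup_rows[1]:u$vert_sup_rows[2],
            u$cols[1]:u$cols[2], 2] <- 160
  parts2 <- score_unit(lm2, img2, u, 1:3, csf_med = 200)
  expect_identical(parts2$quadrant, 2L)   # both superior quadrants, 1 slice
  expect_identical(parts2$depth, 1L)      # 9 voxels x 1.2 mm = 10.8 mm
  expect_identical(parts2$intensity, 1L)  # 160 >= 150
  expect_identical(parts2$score, 4L)
})

test_that("the six highest units are summed and scoring is monotone", {
  spec <- small_spec(lesion_count_range = c(0L, 0L), rician_sigma = 0,
                     bias_amplitude = 0)
  s <- generate_scan(spec, "M", "baseline", "control")
  ann <- s$truth$annotation
  lm <- s$truth$labelmap
  u2 <- ann$units[[2]]
  # one quadrant on two slices plus another quadrant on one slice -> 3
  lm$labels[u2$quadrants$ia$rows[1], u2$quadrants$ia$cols[1], 2:3] <- 2L
  lm$labels[u2$quadrants$sp$rows[1], u2$quadrants$sp$cols[1], 3] <- 2L
  res <- sparcc_total(lm, NULL, ann)
  expect_identical(res$total, 3L)
  expect_identical(res$per_unit$score[res$per_unit$unit == "V2-V3"], 3L)

  # adding lesion voxels never decreases the total
  lm_more <- lm
  lm_more$labels[u2$quadrants$sa$rows, u2$quadrants$sa$cols, 1] <- 2L
  expect_gte(sparcc_total(lm_more, NULL, ann)$total, res$total)
})

test_that("the best consecutive slice triple is chosen deterministically", {
  spec <- small_spec(lesion_count_range = c(0L, 0L))
  s <- generate_scan(spec, "T", "baseline", "control")
  ann <- s$truth$annotation
  u <- ann$units[[1]]
  lm <- s$truth$labelmap
  # lesions on slices 4..6 only; triple 4:6 must win over earlier ones
  lm$labels[u$quadrants$sa$rows[1], u$quadrants$sa$cols[1], 4:6] <- 2L
  res <- sparcc_total(lm, NULL, ann)
  expect_identical(res$per_unit$slice_start[1], 4L)
  expect_identical(res$per_unit$score[1], 3L)
})

test_that("change categorization applies the minimally important change", {
  expect_identical(categorize_change(39, 50), "increased")  # +11
  expect_identical(categorize_change(4, 8), "no_change")    # +4 < 5
  expect_identical(categorize_change(10, 5), "reduced")     # boundary -5
  expect_identical(categorize_change(0, 0), "no_change")
  # antisymmetry under swapping baseline and follow-up
  set.seed(41)
  for (i in 1:25) {
    a <- sample(0:108, 1); b <- sample(0:108, 1)
    fwd <- categorize_change(a, b)
    rev <- categorize_change(b, a)
    expect_identical(
      fwd,
      switch(rev, increased = "reduced", reduced = "increased",
             no_change = "no_change")
    )
  }
  expect_error(categorize_change(-1, 5), class = "bmetex_param_error")
  expect_error(categorize_change(3, 200), class = "bmetex_param_error")
})

test_that("BME positivity needs two sites and/or two slices", {
  spec <- small_spec(lesion_count_range = c(0L, 0L))
  s <- generate_scan(spec, "B", "baseline", "control")
  ann <- s$truth$annotation
  lm0 <- s$truth$labelmap
  expect_false(bme_positive(lm0, ann))

  u <- ann$units[[1]]
  one <- lm0
  one$labels[u$quadrants$sa$rows[1], u$quadrants$sa$cols[1], 2] <- 2L
  expect_false(bme_positive(one, ann))   # one unit, one slice

  two_slices <- one
  two_slices$labels[u$quadrants$sa$rows[1], u$quadrants$sa$cols[1], 3] <- 2L
  expect_true(bme_positive(two_slices, ann))

  u3 <- ann$units[[3]]
  two_units <- one
  two_units$labels[u3$quadrants$ip$rows[1], u3$quadrants$ip$cols[1], 2] <- 2L
  expect_true(bme_positive(two_units, ann))
})

test_that("ground-truth lesion records agree with mask-based scoring", {
  spec <- small_spec(lesion_count_range = c(1L, 3L))
  for (pid in c("G1", "G2", "G3")) {
    s <- generate_scan(spec, pid, "baseline", "control")
    res <- sparcc_total(s$truth$labelmap, s$volume, s$truth$annotation)
    units_hit <- unique(s$truth$lesions$level)
    scored <- res$per_unit$unit[res$per_unit$score > 0]
    expect_true(all(units_hit %in% scored))
    expect_gte(res$total, length(units_hit))
    expect_lte(res$total, 108L)
  }
})
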