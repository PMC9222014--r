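test_that("diffusion parameters enforce the stability bound", {
  p <- diffusion_params()
  expect_equal(p$integration_constant * p$time_step, 1 / 700)
  expect_error(diffusion_params(time_step = 2), class = "bmetex_param_error")
  expect_error(diffusion_params(conductance = 0), class = "bmetex_param_error")
  expect_s3_class(diffusion_params(integration_constant = 1, time_step = 0.25),
                  "bme_diffusion_params")
})

test_that("Perona-Malik conserves slice sums and leaves constants untouched", {
  const <- volume(array(42, c(8, 8, 3)))
  out <- diffuse_pm(const, diffusion_params())
  expect_identical(out$data, const$data)

  set.seed(21)
  v <- volume(array(abs(rnorm(12 * 10 * 4, 100, 20)), c(12, 10, 4)))
  expect_identical(diffuse_pm(v, diffusion_params(iterations = 0))$data,
                   v$data)
  out <- diffuse_pm(v, diffusion_params())
  sums_in <- apply(v$data, 3, sum)
  sums_out <- apply(out$data, 3, sum)
  expect_lt(max(abs(sums_out - sums_in) / sums_in), 1e-6)
})

test_that("Perona-Malik equals a dense per-pixel oracle on small slices", {
  p <- diffusion_params(integration_constant = 1, time_step = 0.1,
                        iterations = 15L)
  coef <- p$integration_constant * p$time_step
  # step edge
  step <- matrix(rep(c(0, 0, 0, 0, 10, 10, 10, 10), each = 8), 8, 8)
  set.seed(22)
  cases <- list(step, matrix(rnorm(64, 100, 15), 8, 8),
                matrix(runif(64, 0, 1), 8, 8))
  for (sl in cases) {
    v <- volume(array(rep(sl, 3), c(8, 8, 3)))
    got <- diffuse_pm(v, p)$data[, , 2]
    want <- oracle_pm(sl, coef, p$conductance, p$iterations)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # edge-preserving smoothing does not widen the intensity range
  v <- volume(array(rep(step, 3), c(8, 8, 3)))
  sm <- diffuse_pm(v, p)$data[, , 1]
  expect_lte(max(sm) - min(sm), 10)
  expect_lt(abs(sum(sm) - sum(step)) / sum(step), 1e-6)
})

test_that("total variation decreases monotonically under diffusion", {
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  set.seed(23)
  sl <- matrix(rnorm(100, 50, 10), 10, 10)
  p1 <- diffusion_params(integration_constant = 1, time_step = 0.2,
                         iterations = 1L)
  cur <- sl
  tvs <- tv(cur)
  for (i in 1:10) {
    cur <- diffuse_pm(volume(array(rep(cur, 3), c(10, 10, 3))), p1)$data[, , 2]
    tvs <- c(tvs, tv(cur))
  }
  expect_true(all(diff(tvs) <= 1e-9))
})

test_that("bias correction recovers injected fields and is homogeneous", {
  spec <- small_spec(rician_sigma = 2, bias_amplitude = 0.2)
  s <- generate_scan(spec, "P010", "baseline", "control")
  cb <- correct_bias(s$volume, s$truth$labelmap)
  marrow <- s$truth$marrow
  expect_gt(cor(cb$field$field[marrow], s$truth$true_bias[marrow]), 0.9)
  expect_true(all(cb$field$field > 0))
  expect_lt(abs(mean(cb$field$field[marrow | s$truth$lesion]) - 1), 1e-6)

  # bias-free input: nothing to correct
  spec0 <- small_spec(rician_sigma = 0, bias_amplitude = 0)
  s0 <- generate_scan(spec0, "P010", "baseline", "control")
  cb0 <- correct_bias(s0$volume, s0$truth$labelmap)
  expect_lt(max(abs(cb0$field$field - 1)), 0.05)

  # homogeneity: scaling the input scales the output, field unchanged
  v2 <- s$volume
  v2$data <- v2$data * 2
  cb2 <- correct_bias(v2, s$truth$labelmap)
  expect_equal(cb2$field$field, cb$field$field, tolerance = 1e-8)
  expect_equal(cb2$volume$data, cb$volume$data * 2, tolerance = 1e-8)

  # idempotence: re-correcting changes voxels by < 1% RMS
  cb_again <- correct_bias(cb$volume, s$truth$labelmap)
  rel_rms <- sqrt(mean((cb_again$volume$data - cb$volume$data)^2)) /
    sqrt(mean(cb$volume$data^2))
  expect_lt(rel_rms, 0.01)

  empty <- s$truth$labelmap
  empty$labels[] <- 0L
  expect_error(correct_bias(s$volume, empty), class = "bmetex_roi_error")
})

test_that("histogram matching is identity to self, inverts shifts, monotone", {
  spec <- small_spec(rician_sigma = 3)
  s <- generate_scan(spec, "P011", "baseline", "control")
  m <- s$truth$labelmap

  self <- match_histogram(s$volume, m, s$volume, m)
  expect_equal(self$data, s$volume$data, tolerance = 1e-9)

  shifted <- s$volume
  shifted$data <- shifted$data + 50
  un <- match_histogram(shifted, m, s$volume, m)
  roi <- bmetex:::mask_role(m, "marrow") | bmetex:::mask_role(m, "lesion")
  expect_lt(abs(mean(un$data[roi]) - mean(s$volume$data[roi])), 1)

  # monotone non-decreasing over the observed range
  xs <- sort(sample(as.vector(s$volume$data), 500))
  probe <- shifted
  ord <- match_histogram(probe, m, s$volume, m)
  mapped <- ord$data[order(shifted$data)]
  expect_true(all(diff(sort(mapped)) >= -1e-12))

  const <- s$volume
  const$data[] <- 5
  expect_error(match_histogram(const, m, s$volume, m),
               class = "bmetex_roi_error")
})

test_that("the preprocessing pipeline composes and preserves the grid", {
  spec <- small_spec()
  s <- generate_scan(spec, "P012", "baseline", "control")
  a <- generate_scan(spec, "P013", "baseline", "control")
  pre <- preprocess_scan(s$volume, s$truth$labelmap, a$volume,
                         a$truth$labelmap)
  expect_identical(dim(pre$data), dim(s$volume$data))
  expect_identical(attr(pre, "stages"), c("bias", "match", "diffuse"))
  off <- preprocess_scan(s$volume, s$truth$labelmap, bias = FALSE,
                         match = FALSE, diffuse = FALSE)
  expect_identical(off$data, s$volume$data)
})
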