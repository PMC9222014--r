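test_that("Bonferroni correction caps, scales and preserves order", {
  expect_equal(bonferroni(0.062, 21), 1)       # capped
  expect_equal(bonferroni(0, 21), 0)
  expect_equal(bonferroni(0.001, 21), 0.021)
  p <- sort(runif(10))
  q <- bonferroni(p, 10)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 1) && all(q >= p))
  expect_error(bonferroni(1.2, 3), class = "bmetex_param_error")
})

test_that("exact Wilcoxon matches closed forms and the sign-enumeration oracle", {
  w <- wilcoxon_paired(rep(0, 5), 1:5)
  expect_equal(w$p, 0.0625)  # 2 / 2^5
  expect_identical(w$method, "exact enumeration")

  expect_warning(wd <- wilcoxon_paired(1:4, 1:4), "zero")
  expect_equal(wd$p, 1)

  set.seed(51)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    before <- rnorm(n)
    after <- before + rnorm(n)
    # include ties in |d| occasionally
    if (i %% 3 == 0) after[2] <- before[2] + (after[1] - before[1])
    got <- suppressMessages(wilcoxon_paired(before, after))$p
    want <- oracle_signed_rank(after - before)
    expect_equal(got, want, tolerance = 1e-12)
  }

  # tie-free exact branch agrees with stats::wilcox.test
  set.seed(52)
  b <- rnorm(12); a <- b + rnorm(12)
  expect_equal(wilcoxon_paired(b, a)$p,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-10)

  # large-sample branch is a sane approximation
  set.seed(53)
  b <- rnorm(40); a <- b + rnorm(40, 0.5)
  big <- wilcoxon_paired(b, a)
  expect_identical(big$method, "normal approximation")
  expect_equal(big$p,
               wilcox.test(a, b, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("Freeman-Halton Fisher test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  t22 <- matrix(c(0, 3, 17, 17), 2)
  expect_equal(fisher_exact(t22), oracle_fisher(t22), tolerance = 1e-12)
  t23 <- matrix(c(17, 17, 0, 1, 0, 2), 2)
  expect_equal(fisher_exact(t23), oracle_fisher(t23), tolerance = 1e-12)
  expect_equal(fisher_exact(t23), fisher.test(t23)$p.value, tolerance = 1e-7)
  # degenerate margins
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1)

  set.seed(54)
  for (i in 1:50) {
    C <- sample(2:3, 1)
    t <- matrix(rpois(2 * C, 3), 2, C)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact(t), oracle_fisher(t), tolerance = 1e-10)
    expect_equal(fisher_exact(t), fisher.test(t)$p.value, tolerance = 1e-6)
  }
})

test_that("the voxel-status model recovers exact and noisy effects", {
  rows <- simulate_status_rows(n_pat = 4, n_vox = 5, effect = 2,
                               sd_pat = 0, sd_scan = 0, sd_res = 0)
  rows$i1 <- 10 + 2 * (rows$status == "BME")
  fit <- suppressWarnings(lmm_status(rows, "i1"))
  expect_equal(fit$estimate, 2.0, tolerance = 1e-6)
  expect_true(fit$singular)

  set.seed(55)
  covered <- 0
  for (i in 1:25) {
    rows <- simulate_status_rows(n_pat = 12, n_vox = 20, effect = 1)
    rows$i1 <- rows$y
    f <- suppressWarnings(lmm_status(rows, "i1"))
    ci <- f$estimate + c(-1.96, 1.96) * f$std_error
    covered <- covered + (ci[1] <= 1 && 1 <= ci[2])
  }
  expect_gte(covered, 20)  # ~95% coverage over 25 replicates

  td <- tidy(suppressWarnings(lmm_status(rows, "i1")))
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  gl <- glance(suppressWarnings(lmm_status(rows, "i1")))
  expect_identical(gl$model, "voxel_status")
})

test_that("the change model is null on identical trajectories and sign-symmetric", {
  sm <- expand.grid(patient_id = sprintf("P%02d", 1:8),
                    timepoint = c("baseline", "week11"),
                    stringsAsFactors = FALSE)
  sm$group <- ifelse(as.integer(sub("P", "", sm$patient_id)) <= 4,
                     "HIIT", "control")
  # identical group trajectories, noise-free
  sm$i2 <- 5 + 1 * (sm$timepoint == "week11")
  f0 <- suppressWarnings(lmm_change(sm, "i2"))
  expect_equal(f0$estimate, 0, tolerance = 1e-6)

  set.seed(56)
  sm$i2 <- sm$i2 + 2 * (sm$timepoint == "week11" & sm$group == "HIIT") +
    rnorm(nrow(sm), 0, 0.2)
  f1 <- suppressWarnings(lmm_change(sm, "i2"))
  sm_sw <- sm
  sm_sw$group <- ifelse(sm$group == "HIIT", "control", "HIIT")
  f2 <- suppressWarnings(lmm_change(sm_sw, "i2"))
  expect_equal(f1$estimate, -f2$estimate, tolerance = 1e-8)
  expect_equal(abs(f1$estimate), abs(f2$estimate), tolerance = 1e-8)

  # patients missing a timepoint are dropped with a message
  sm_drop <- sm[-1, ]
  expect_message(suppressWarnings(lmm_change(sm_drop, "i2")), "dropped")
})

test_that("feature summaries report means, SDs and pairwise-complete counts", {
  rows <- tibble::tibble(
    patient_id = "P1", scan_id = "S1", timepoint = "baseline",
    group = c("HIIT", "HIIT", "control", "control"),
    status = c("BME", "healthy", "BME", "healthy"),
    i1 = c(10, 2, 14, 4), f2 = c(0.5, NA, 0.7, 0.1)
  )
  s <- summarize_features(rows, "status")
  i1 <- s[s$feature == "i1", ]
  expect_equal(i1$mean[i1$status == "BME"], 12)
  expect_equal(i1$sd[i1$status == "BME"], sd(c(10, 14)))
  f2 <- s[s$feature == "f2", ]
  expect_identical(f2$n[f2$status == "healthy"], 1L)
  expect_true(f2$degenerate[f2$status == "healthy"])
  expect_equal(f2$sd[f2$status == "healthy"], 0)

  g <- summarize_features(rows, "group")  # lesion rows only
  expect_true(all(g$n == 1))
  expect_equal(g$mean[g$feature == "i1" & g$group == "control"], 14)
})

test_that("change reports tabulate categories and attach Fisher p-values", {
  cats <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    group = rep(c("HIIT", "control"), each = 5),
    category = c("no_change", "no_change", "increased", "no_change",
                 "reduced", rep("no_change", 5))
  )
  rep1 <- build_change_report(cats, "sparcc")
  expect_identical(sum(rep1$table), 10L)
  expect_identical(rep1$table["HIIT", "increased"], 1L)
  expect_equal(rep1$fisher_p, fisher_exact(rep1$table), tolerance = 1e-12)
  expect_true(rep1$fisher_p_2x2 <= 1 && rep1$fisher_p_2x2 >= 0)

  allnc <- cats
  allnc$category <- "no_change"
  expect_equal(build_change_report(allnc)$fisher_p, 1)

  bad <- cats
  bad$group[1] <- "other"
  expect_error(build_change_report(bad), class = "bmetex_param_error")
})
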