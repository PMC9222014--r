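# Independent brute-force oracles, coded separately from the package paths
# they check.

# Small phantom configuration used across tests (kept small so suites stay
# fast; the scientific parameters match the package defaults).
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(48L, 40L, 6L), n_vertebrae = 4L,
         lesion_radius_mm_range = c(2, 4),
         lesion_count_range = c(1L, 3L), n_per_group = 2L),
    list(...)
  )
  do.call(phantom_spec, args)
}

# Fully positive spine: every marrow voxel lesioned and set to the lesion
# intensity so all quadrant, depth and intensity elements fire.
fully_positive <- function(spec = phantom_spec(rician_sigma = 0,
                                               bias_amplitude = 0)) {
  s <- generate_scan(spec, "FP", "baseline", "control")
  lm <- s$truth$labelmap
  lm$labels[s$truth$marrow] <- 2L
  img <- s$truth$clean
  img$data[s$truth$marrow] <- spec$marrow_mean + spec$lesion_delta
  list(lesions = lm, image = img, ann = s$truth$annotation)
}

# --- GLCM oracle: exhaustive ordered-pair enumeration per orientation ------
oracle_glcm <- function(w, levels) {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  f <- matrix(NA_real_, 4, 4)
  for (k in seq_along(offsets)) {
    off <- offsets[[k]]
    pairs <- list()
    for (r in 1:3) for (c in 1:3) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= 3 && c2 >= 1 && c2 <= 3) {
        pairs[[length(pairs) + 1]] <- c(w[r, c], w[r2, c2])
      }
    }
    a <- vapply(pairs, `[`, 0, 1)
    b <- vapply(pairs, `[`, 0, 2)
    n <- length(a)
    contrast <- sum((a - b)^2) / n
    homog <- sum(1 / (1 + abs(a - b))) / n
    # energy: sum over distinct pair types of (count/n)^2
    key <- paste(a, b)
    energy <- sum((table(key) / n)^2)
    va <- mean(a^2) - mean(a)^2
    vb <- mean(b^2) - mean(b)^2
    corr <- if (va > 0 && vb > 0) {
      (mean(a * b) - mean(a) * mean(b)) / sqrt(va * vb)
    } else {
      NA_real_
    }
    f[k, ] <- c(contrast, corr, energy, homog)
  }
  corrs <- f[, 2]
  c(f1 = mean(f[, 1]),
    f2 = if (all(is.na(corrs))) NA_real_ else mean(corrs, na.rm = TRUE),
    f3 = mean(f[, 3]), f4 = mean(f[, 4]))
}

# --- Perona-Malik oracle: per-pixel loops on a dense slice -----------------
oracle_pm <- function(m, coef, conductance, iterations) {
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iterations)) {
    diffs <- c()
    at <- function(r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
    for (r in 1:nr) for (c in 1:nc) {
      diffs <- c(diffs, abs(at(r - 1, c) - m[r, c]),
                 abs(at(r + 1, c) - m[r, c]),
                 abs(at(r, c - 1) - m[r, c]),
                 abs(at(r, c + 1) - m[r, c]))
    }
    diffs <- diffs[diffs > 0]
    if (length(diffs) == 0) next
    K <- conductance * median(diffs)
    out <- m
    for (r in 1:nr) for (c in 1:nc) {
      acc <- 0
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        dd <- at(r + d[1], c + d[2]) - m[r, c]
        acc <- acc + exp(-(dd / K)^2) * dd
      }
      out[r, c] <- m[r, c] + coef * acc
    }
    m <- out
  }
  m
}

# --- Wilcoxon oracle: all 2^n sign assignments -----------------------------
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(W_all <= W_obs + 1e-9), mean(W_all >= W_obs - 1e-9)))
}

# --- Fisher oracle: factorial-form enumeration over margin tables ----------
oracle_fisher <- function(t) {
  rs <- rowSums(t); cs <- colSums(t); N <- sum(t)
  if (any(rs == 0) || any(cs == 0)) return(1)
  C <- ncol(t)
  prob_of <- function(row1) {
    row2 <- cs - row1
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
          sum(lfactorial(c(row1, row2))))
  }
  grid <- expand.grid(lapply(cs[-C], function(m) 0:m))
  probs <- c()
  for (i in seq_len(nrow(grid))) {
    head_cells <- as.numeric(grid[i, ])
    last <- rs[1] - sum(head_cells)
    if (last < 0 || last > cs[C]) next
    row1 <- c(head_cells, last)
    if (any(cs - row1 < 0)) next
    probs <- c(probs, prob_of(row1))
  }
  p_obs <- prob_of(t[1, ])
  sum(probs[probs <= p_obs * (1 + 1e-7) + 1e-12])
}

# Null simulation rows for the voxel-status model.
simulate_status_rows <- function(n_pat = 16, n_scan = 2, n_vox = 30,
                                 effect = 0, sd_pat = 1, sd_scan = 0.5,
                                 sd_res = 1) {
  rows <- expand.grid(patient = seq_len(n_pat), scan = seq_len(n_scan),
                      vox = seq_len(n_vox), status = c("healthy", "BME"),
                      stringsAsFactors = FALSE)
  pat_eff <- rnorm(n_pat, 0, sd_pat)
  scan_eff <- matrix(rnorm(n_pat * n_scan, 0, sd_scan), n_pat, n_scan)
  rows$patient_id <- sprintf("P%02d", rows$patient)
  rows$scan_id <- sprintf("P%02d_S%d", rows$patient, rows$scan)
  rows$y <- pat_eff[rows$patient] + scan_eff[cbind(rows$patient, rows$scan)] +
    effect * (rows$status == "BME") + rnorm(nrow(rows), 0, sd_res)
  rows
}
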