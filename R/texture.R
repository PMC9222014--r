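#' Per-window intensity features (i1-i7)
#'
#' The seven intensity features of one 3x3 window: centre value (i1), mean
#' (i2), median (i3), sample standard deviation with n-1 denominator (i4),
#' minimum (i5), maximum (i6), and semi-interquartile range
#' `(Q3 - Q1) / 2` with linear interpolation between order statistics (i7).
#'
#' @param w 3x3 numeric matrix, window centred on the evaluated pixel.
#' @return named numeric vector `i1..i7`.
#' @examples
#' intensity_features(matrix(1:9, 3, 3))
#' @export
intensity_features <- function(w) {
  w <- as.matrix(w)
  stopifnot(all(dim(w) == c(3L, 3L)))
  x <- as.vector(w)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(i1 = w[2, 2], i2 = mean(x), i3 = median(x), i4 = sd(x),
    i5 = min(x), i6 = max(x), i7 = (q[2] - q[1]) / 2)
}

#' Sobel directional gradients of a sagittal slice
#'
#' 3x3 Sobel kernels with replicated borders. `gx` responds positively to
#' intensity increasing along +x (columns, anterior to posterior), `gy` to
#' intensity increasing along +y (rows). On a unit ramp along x the interior
#' response is exactly 8.
#'
#' @param slice numeric matrix, at least 3x3.
#' @return list with matrices `gx`, `gy` and `mag` (`sqrt(gx^2 + gy^2)`).
#' @export
sobel_gradients <- function(slice) {
  m <- as.matrix(slice)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) {
    stopf("bmetex_param_error", "slice must be at least 3x3")
  }
  p <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]  # replicate pad
  up <- seq_len(nr); mid <- up + 1L; dn <- up + 2L
  lf <- seq_len(nc); ctr <- lf + 1L; rt <- lf + 2L
  gx <- (p[up, rt] - p[up, lf]) + 2 * (p[mid, rt] - p[mid, lf]) +
    (p[dn, rt] - p[dn, lf])
  gy <- (p[dn, lf] - p[up, lf]) + 2 * (p[dn, ctr] - p[up, ctr]) +
    (p[dn, rt] - p[up, rt])
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Per-window gradient features (g1-g10)
#'
#' Ten gradient features of one 3x3 window over the Sobel gradient maps, with
#' `|G| = sqrt(gx^2 + gy^2)`: g1 = sum(|gx| + |gy|); g2 = sum |G|;
#' g3 = mean |G|; g4 = median |G|; g5 = sample SD of |G|; g6 =
#' semi-interquartile range of |G|; g7 = centre |G|; g8 = min |G|;
#' g9 = max |G|; g10 = mean of `||gx| - |gy||`.
#'
#' @param gx,gy 3x3 windows of the directional gradient maps.
#' @return named numeric vector `g1..g10`.
#' @export
gradient_features <- function(gx, gy) {
  gx <- as.matrix(gx); gy <- as.matrix(gy)
  stopifnot(all(dim(gx) == c(3L, 3L)), all(dim(gy) == c(3L, 3L)))
  mag <- sqrt(gx^2 + gy^2)
  mg <- as.vector(mag)
  q <- quantile(mg, c(0.25, 0.75), names = FALSE, type = 7)
  c(g1 = sum(abs(gx) + abs(gy)), g2 = sum(mg), g3 = mean(mg),
    g4 = median(mg), g5 = sd(mg), g6 = (q[2] - q[1]) / 2,
    g7 = mag[2, 2], g8 = min(mg), g9 = max(mg),
    g10 = mean(abs(abs(as.vector(gx)) - abs(as.vector(gy)))))
}

# Offsets (drow, dcol) of the four co-occurrence orientations at distance 1,
# single (non-symmetric) direction each: 0, 45, 90, 135 degrees.
glcm_offsets <- list(
  deg0 = c(0L, 1L), deg45 = c(-1L, 1L), deg90 = c(-1L, 0L),
  deg135 = c(-1L, -1L)
)

#' Per-window grey-level co-occurrence features (f1-f4)
#'
#' From a quantized 3x3 window, builds one non-symmetric co-occurrence count
#' matrix per orientation (0, 45, 90, 135 degrees; distance 1 pixel),
#' normalizes it, computes contrast (f1), correlation (f2), energy (f3) and
#' homogeneity (f4), and averages the four orientations. Correlation is
#' undefined when either marginal variance is zero; undefined orientations
#' are excluded from the mean, and `f2` is `NA` when all four are undefined.
#'
#' @param w 3x3 window of integer grey levels in `[0, levels - 1]`.
#' @param levels number of grey levels (>= 2).
#' @return named numeric vector `f1..f4` (`f2` possibly `NA`).
#' @export
glcm_features <- function(w, levels = 8L) {
  w <- as.matrix(w)
  stopifnot(all(dim(w) == c(3L, 3L)))
  if (levels < 2L) {
    stopf("bmetex_param_error", "levels must be >= 2")
  }
  if (any(w != round(w)) || any(w < 0) || any(w > levels - 1L)) {
    stopf("bmetex_param_error",
          "window values must be integers in [0, levels - 1]")
  }
  per_or <- lapply(glcm_offsets, function(off) {
    glcm_props(glcm_counts(w, off, levels), levels)
  })
  f1 <- mean(vapply(per_or, `[[`, 0.0, "contrast"))
  f3 <- mean(vapply(per_or, `[[`, 0.0, "energy"))
  f4 <- mean(vapply(per_or, `[[`, 0.0, "homogeneity"))
  corrs <- vapply(per_or, `[[`, 0.0, "correlation")
  f2 <- if (all(is.na(corrs))) NA_real_ else mean(corrs, na.rm = TRUE)
  c(f1 = f1, f2 = f2, f3 = f3, f4 = f4)
}

# Co-occurrence counts of one orientation over a window (any size).
glcm_counts <- function(w, off, levels) {
  nr <- nrow(w); nc <- ncol(w)
  counts <- matrix(0L, levels, levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- w[r, c] + 1L; b <- w[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  counts
}

# Contrast, correlation, energy, homogeneity of one normalized GLCM.
glcm_props <- function(counts, levels) {
  n <- sum(counts)
  if (n == 0) {
    return(list(contrast = 0, correlation = NA_real_, energy = 0,
                homogeneity = 0))
  }
  p <- counts / n
  iv <- seq_len(levels)
  ii <- matrix(iv, levels, levels)
  jj <- t(ii)
  pa <- rowSums(p); pb <- colSums(p)
  mu_a <- sum(iv * pa); mu_b <- sum(iv * pb)
  var_a <- sum(iv^2 * pa) - mu_a^2
  var_b <- sum(iv^2 * pb) - mu_b^2
  corr <- if (var_a <= 0 || var_b <= 0) NA_real_ else {
    (sum(ii * jj * p) - mu_a * mu_b) / sqrt(var_a * var_b)
  }
  list(contrast = sum(p * (ii - jj)^2), correlation = corr,
       energy = sum(p^2), homogeneity = sum(p / (1 + abs(ii - jj))))
}

#' Quantize intensities to grey levels by global min-max scaling
#'
#' Maps intensities linearly onto integer levels `0 .. levels - 1` using the
#' global (per-scan) minimum and maximum, the quantization used for the GLCM
#' features. A constant input maps to level 0.
#'
#' @param x numeric array or vector.
#' @param levels number of grey levels.
#' @param range optional length-2 intensity range to quantize against
#'   (defaults to `range(x)`).
#' @return integer array of the same shape.
#' @export
quantize_levels <- function(x, levels = 8L, range = NULL) {
  if (levels < 2L) stopf("bmetex_param_error", "levels must be >= 2")
  rg <- range %||% base::range(x)
  if (rg[2] <= rg[1]) {
    q <- array(0L, dim(as.array(x)))
    return(q)
  }
  q <- floor((x - rg[1]) / (rg[2] - rg[1]) * levels)
  q[q < 0] <- 0
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}
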