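# Independent oracles and small constructors shared across test files.

# Exhaustive-enumeration optimum RSS for segmenting x into exactly k runs:
# tries every choice of k-1 boundaries among the m-1 gaps.
enum_rss <- function(x, k) {
  m <- length(x)
  seg_rss <- function(idx) sum((x[idx] - mean(x[idx]))^2)
  if (k == 1L) return(seg_rss(seq_len(m)))
  best <- Inf
  combos <- utils::combn(m - 1L, k - 1L)
  for (j in seq_len(ncol(combos))) {
    ends <- c(combos[, j], m)
    starts <- c(1L, combos[, j] + 1L)
    rss <- sum(vapply(seq_len(k), function(s) {
      seg_rss(starts[s]:ends[s])
    }, numeric(1)))
    if (rss < best) best <- rss
  }
  best
}

# Subgradient optimality residual for the 1-D fused lasso with penalty lam:
# u_i = sum_{j<=i}(x_j - y_j) must satisfy u_m = 0, |u_i| <= lam, and
# u_i = +/-lam wherever the fit jumps up/down.
kkt_residual <- function(y, x, lam) {
  n <- length(y)
  u <- cumsum(x - y)
  r <- abs(u[n])
  if (n > 1L) {
    ui <- u[-n]
    d <- diff(x)
    r <- max(r, max(pmax(abs(ui) - lam, 0)))
    if (any(d > 1e-12)) r <- max(r, max(abs(ui[d > 1e-12] - lam)))
    if (any(d < -1e-12)) r <- max(r, max(abs(ui[d < -1e-12] + lam)))
  }
  r
}

# Direct transcription of the zero-one annotation loss definitions.
oracle_verdict <- function(count, a_lo, a_hi) {
  list(fp = as.integer(count > a_hi),
       fn = as.integer(count < a_lo),
       tp = as.integer(count >= a_lo),
       error = as.integer(count < a_lo | count > a_hi))
}

# Build a smoothed_profile by hand from per-lambda, per-chromosome
# breakpoint sets (list of named lists), bypassing any smoother.
make_fits <- function(profile_id, lambda, bps_by_lambda, model = "manual") {
  fits <- lapply(seq_along(lambda), function(li) {
    structure(list(smoothness = lambda[li], smoothed = NULL,
                   breakpoints = bps_by_lambda[[li]]),
              class = "smoothed_fit")
  })
  structure(list(profile_id = profile_id, model = model,
                 lambda = lambda, fits = fits),
            class = "smoothed_profile")
}

# Error curve with prescribed per-lambda errors and breakpoint totals.
make_curve <- function(errors, breakpoints = rev(seq_along(errors)),
                       lambda = seq_along(errors)) {
  segtrain:::new_error_curve(
    lambda = lambda, errors = errors, fp = errors, fn = 0 * errors,
    tp = 0 * errors,
    n_annotations = if (length(errors)) max(errors) else 0,
    n_pos = 1, n_neg = 1,
    breakpoints = breakpoints)
}

# Fake segmentation_set carrying a prescribed rss curve.
fake_seg <- function(rss, m = 10L) {
  structure(list(m = m, kmax = length(rss), rss = rss,
                 ends = vector("list", length(rss)), x = numeric(m)),
            class = "segmentation_set")
}

# One random piecewise-constant chromosome with noise, as a cn_profile.
random_chrom_profile <- function(pid = "T1", m = 60, n_seg = 3,
                                 jump = 1, sd = 0.3) {
  pos <- sort(sample.int(1e7, m))
  gaps <- if (n_seg > 1) sort(sample.int(m - 1, n_seg - 1)) else integer(0)
  means <- cumsum(c(0, jump * sample(c(-1, 1), n_seg - 1, replace = TRUE)))
  mu <- rep(means, times = diff(c(0, gaps, m)))
  cn_profile(pid, probe_series(pos, mu + rnorm(m, 0, sd)))
}
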