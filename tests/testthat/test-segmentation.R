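test_that("segment_dp solves the textbook cases", {
  x <- rnorm(15)
  seg <- segment_dp(x, 5)
  expect_equal(segmentation_means(seg, 1), rep(mean(x), 15))
  # saturated model interpolates
  y <- c(3, 1, 4, 1, 5)
  seg_sat <- segment_dp(y, 5)
  expect_equal(segmentation_means(seg_sat, 5), y)
  expect_equal(seg_sat$rss[5], 0)
  # hand-checkable 3-segment signal: bounds after probes 3 and 6
  z <- c(0, 0, 0, 5, 5, 5, 2, 2)
  seg3 <- segment_dp(z, 3)
  expect_equal(seg3$ends[[3]], c(3, 6, 8))
  expect_equal(seg3$rss[3], 0)
  expect_error(segment_dp(z, 9), "exceeds")
  expect_error(segment_dp(z, 0), ">= 1")
})

test_that("segment_dp rss matches exhaustive enumeration on random inputs", {
  set.seed(42)
  for (rep in 1:50) {
    m <- sample(2:12, 1)
    kmax <- sample(1:min(5, m), 1)
    x <- rnorm(m) + rep(c(0, 2), length.out = m)
    seg <- segment_dp(x, kmax)
    for (k in seq_len(kmax)) {
      expect_equal(seg$rss[k], enum_rss(x, k), tolerance = 1e-9)
    }
    expect_true(all(diff(seg$rss) <= 1e-12))
  }
})

test_that("penalized selection evaluates the two criteria correctly", {
  seg <- fake_seg(c(10, 2, 1.5), m = 10)
  # lambda*k + rss/m: criteria 1.3, 0.8, 1.05
  expect_equal(choose_k_lavielle(seg, 10, 0.3), 2L)
  # beta*(k-1) + rss: criteria 10, 5, 7.5
  expect_equal(choose_k_penalty(seg, 3), 2L)
  # zero penalty: smallest k attaining minimum rss
  seg_tie <- fake_seg(c(4, 1, 1), m = 6)
  expect_equal(choose_k_lavielle(seg_tie, 6, 0), 2L)
  expect_equal(choose_k_penalty(seg_tie, 0), 2L)
  # penalty large enough that one segment wins
  expect_equal(choose_k_lavielle(seg, 10, 10), 1L)
  expect_error(choose_k_lavielle(seg, 10, -1), ">= 0")
})

test_that("beta = lambda*m makes the two criteria exactly equivalent", {
  set.seed(7)
  for (rep in 1:30) {
    kmax <- sample(2:10, 1)
    m <- sample(kmax:50, 1)
    rss <- rev(cumsum(rexp(kmax)))
    seg <- fake_seg(rss, m = m)
    for (lam in 10^runif(20, -8, 4)) {
      expect_identical(choose_k_penalty(seg, lam * m),
                       choose_k_lavielle(seg, m, lam))
    }
  }
})

test_that("selected k is non-increasing in the penalty", {
  set.seed(8)
  x <- rnorm(40) + rep(c(0, 1.5, 0, 3), each = 10)
  seg <- segment_dp(x, 10)
  lams <- 10^seq(-8, 4, length.out = 60)
  ks <- vapply(lams, function(l) choose_k_lavielle(seg, seg$m, l),
               integer(1))
  expect_true(all(diff(ks) <= 0))
  betas <- lams * seg$m
  kb <- vapply(betas, function(b) choose_k_penalty(seg, b), integer(1))
  expect_true(all(diff(kb) <= 0))
})

test_that("fused_lasso_1d is the exact minimizer", {
  # hand-solved stationarity: shrink the single jump by 2*lam/2 each side
  expect_equal(fused_lasso_1d(c(0, 1), 0.25), c(0.25, 0.75))
  y <- rnorm(30)
  expect_identical(fused_lasso_1d(y, 0), y)
  expect_equal(fused_lasso_1d(y, 1e8), rep(mean(y), 30), tolerance = 1e-10)
  expect_error(fused_lasso_1d(y, -1), "non-negative")
  set.seed(9)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    yy <- rnorm(n) + cumsum(sample(c(0, 0, 1, -1), n, replace = TRUE))
    lam <- runif(1, 0, 4)
    xx <- fused_lasso_1d(yy, lam)
    expect_lt(kkt_residual(yy, xx, lam), 1e-8)
  }
})

test_that("fused lasso breakpoint count is non-increasing in the penalty", {
  set.seed(10)
  y <- rnorm(80, sd = 0.3) + rep(c(0, 1, -1, 2), each = 20)
  pos <- seq_along(y) * 10
  tol <- 1e-9 * (1 + max(abs(y)))
  nbp <- vapply(10^seq(-3, 3, length.out = 30), function(lam) {
    length(extract_breakpoints(fused_lasso_1d(y, lam), pos, tol = tol))
  }, numeric(1))
  expect_true(all(diff(nbp) <= 0))
})

test_that("flsa.norm penalty rescales by probe density", {
  expect_equal(flsa_norm_penalty(0, 100, 1e8), 0)
  expect_equal(flsa_norm_penalty(1, 100, 1e8), 1)
  expect_equal(flsa_norm_penalty(2, 50, 1e6), 100)
  expect_error(flsa_norm_penalty(1, 100, 0), "positive")
})

test_that("smooth_profile handles degenerate chromosomes and all models", {
  prof <- cn_profile("p", list(
    probe_series(5e6, 0.7, chromosome = "1", length_bp = 1e7),
    probe_series(c(1e6, 2e6, 3e6, 4e6), c(0, 0, 1, 1), chromosome = "2",
                 length_bp = 1e7)))
  for (model in c("cghseg.k", "pelt.n", "flsa", "flsa.norm")) {
    sp <- smooth_profile(prof, model = model,
                         grid = penalty_grid(c(1e-6, 1)), kmax = 3)
    for (fit in sp$fits) {
      expect_identical(fit$breakpoints[["1"]], numeric(0))
    }
  }
  expect_error(smooth_profile(prof, model = "dnacopy"), "arg")
})

test_that("noiseless two-level signal yields exactly the true midpoint", {
  prof <- cn_profile("p", probe_series(c(100, 200, 300, 400, 500, 600),
                                       c(0, 0, 0, 1, 1, 1)))
  for (model in c("cghseg.k", "flsa")) {
    sp <- smooth_profile(prof, model = model,
                         grid = penalty_grid(0.05), kmax = 6)
    expect_equal(sp$fits[[1]]$breakpoints[["1"]], 350)
  }
})

test_that("cghseg.k and pelt.n produce identical breakpoints", {
  set.seed(12)
  grid <- default_grid("cghseg.k", count = 40)
  for (rep in 1:10) {
    prof <- random_chrom_profile(m = sample(20:80, 1),
                                 n_seg = sample(1:4, 1))
    a <- smooth_profile(prof, "cghseg.k", grid = grid, kmax = 10)
    b <- smooth_profile(prof, "pelt.n", grid = grid, kmax = 10)
    for (li in seq_along(grid)) {
      expect_identical(a$fits[[li]]$breakpoints, b$fits[[li]]$breakpoints)
    }
  }
})
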