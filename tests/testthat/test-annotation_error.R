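test_that("extract_breakpoints returns inter-probe midpoints of jumps", {
  expect_identical(extract_breakpoints(c(1, 1, 1), c(10, 20, 30)),
                   numeric(0))
  expect_equal(extract_breakpoints(c(0, 0, 1, 1), c(10, 20, 30, 40)), 25)
  expect_equal(extract_breakpoints(c(0, 1, 0), c(100, 200, 300)),
               c(150, 250))
  expect_identical(extract_breakpoints(5, 100), numeric(0))
  expect_error(extract_breakpoints(c(0, 1), c(1, 2, 3)), "lengths differ")
  # fusion tolerance absorbs float noise
  expect_identical(extract_breakpoints(c(0, 1e-12), c(1, 2), tol = 1e-9),
                   numeric(0))
})

test_that("count_in_region uses closed intervals", {
  expect_equal(count_in_region(numeric(0), 0, 100), 0)
  expect_equal(count_in_region(c(25, 150), 0, 100), 1)
  expect_equal(count_in_region(25, 25, 50), 1)
  expect_equal(count_in_region(50, 25, 50), 1)
  expect_error(count_in_region(1, 10, 5), "start > end")
})

test_that("region_verdict matches the zero-one loss definitions", {
  v <- region_verdict(0, 0, 0)
  expect_equal(unlist(v[c("fp", "fn", "error")]), c(fp = 0, fn = 0,
                                                    error = 0))
  v <- region_verdict(0, 1, Inf)
  expect_equal(unlist(v[c("fp", "fn", "error")]), c(fp = 0, fn = 1,
                                                    error = 1))
  v <- region_verdict(2, 1, 1)
  expect_equal(unlist(v[c("fp", "fn", "error")]), c(fp = 1, fn = 0,
                                                    error = 1))
  # full cross product against the direct oracle
  for (count in 0:4) {
    for (a in list(c(0, 0), c(1, 1), c(1, Inf))) {
      got <- region_verdict(count, a[1], a[2])
      want <- oracle_verdict(count, a[1], a[2])
      expect_equal(got$fp, want$fp)
      expect_equal(got$fn, want$fn)
      expect_equal(got$tp, want$tp)
      expect_equal(got$error, want$error)
      expect_equal(got$fp * got$fn, 0L)
      expect_equal(got$error, got$fp + got$fn)
      if (got$tp == 1L) expect_equal(got$fn, 0L)
    }
  }
})

two_lambda_fits <- function() {
  # lambda 1: breakpoints at 150 and 450; lambda 2: none
  make_fits("p1", c(1, 2), list(
    list(`1` = c(150, 450), `2` = numeric(0)),
    list(`1` = numeric(0), `2` = numeric(0))))
}

test_that("local_error sums region verdicts per lambda", {
  fits <- two_lambda_fits()
  ann <- annotated_regions(
    c("p1", "p1", "p1"), c("1", "1", "2"),
    start = c(100, 400, 10), end = c(200, 500, 90),
    annotation = c(">0breakpoints", "1breakpoint", "0breakpoints"))
  curve <- local_error(fits, ann)
  expect_equal(curve$errors, c(0, 2))
  expect_equal(curve$fp, c(0, 0))
  expect_equal(curve$fn, c(0, 2))
  expect_equal(attr(curve, "n_annotations"), 3)
  expect_equal(attr(curve, "n_pos"), 2)
  expect_equal(attr(curve, "n_neg"), 2)  # [1,1] is both positive & negative
  expect_equal(attr(curve, "breakpoints"), c(2, 0))
  # no annotations for this profile: identically zero curve
  none <- local_error(fits, ann[0, ])
  expect_equal(none$errors, c(0, 0))
  # annotation on a chromosome absent from the fit is an error
  bad <- annotated_regions("p1", "17", 1, 10, annotation = "0breakpoints")
  expect_error(local_error(fits, bad), "absent chromosome: profile p1")
})

test_that("global_error is the pointwise sum over profiles", {
  fits1 <- two_lambda_fits()
  fits2 <- make_fits("p2", c(1, 2), list(
    list(`1` = 500), list(`1` = numeric(0))))
  ann <- annotated_regions(
    c("p1", "p1", "p2"), c("1", "1", "1"),
    start = c(100, 300, 400), end = c(200, 350, 600),
    annotation = c(">0breakpoints", "0breakpoints", "0breakpoints"))
  c1 <- local_error(fits1, ann)
  c2 <- local_error(fits2, ann)
  g <- global_error(list(c1, c2))
  expect_equal(g$errors, c1$errors + c2$errors)
  expect_equal(g$errors, c(1, 1))
  expect_equal(attr(g, "n_annotations"), 3)
  # single profile: identical to its local curve
  g1 <- global_error(list(c1))
  expect_equal(g1$errors, c1$errors)
  # mismatched grids rejected
  c3 <- local_error(make_fits("p2", c(1, 3), list(
    list(`1` = 500), list(`1` = numeric(0)))), ann)
  expect_error(global_error(list(c1, c3)), "different smoothness grids")
})

test_that("roc_curve computes TPR and FPR from the proper subsets", {
  # 2 positives (counts 1, 0) + 2 negatives [0,0] (counts 0, 1)
  fits <- make_fits("p", 1, list(
    list(`1` = c(50, 350))))
  ann <- annotated_regions(
    rep("p", 4), rep("1", 4),
    start = c(0, 100, 200, 300), end = c(99, 199, 299, 399),
    annotation = c(">0breakpoints", ">0breakpoints", "0breakpoints",
                   "0breakpoints"))
  roc <- roc_curve(local_error(fits, ann))
  expect_equal(roc$tpr, 0.5)
  expect_equal(roc$fpr, 0.5)
  # a model with zero breakpoints everywhere sits at (0, 0)
  none <- make_fits("p", 1, list(list(`1` = numeric(0))))
  roc0 <- roc_curve(local_error(none, ann))
  expect_equal(c(roc0$fpr, roc0$tpr), c(0, 0))
  # perfect model sits at (0, 1)
  perfect <- make_fits("p", 1, list(list(`1` = c(50, 150))))
  roc1 <- roc_curve(local_error(perfect, ann))
  expect_equal(c(roc1$fpr, roc1$tpr), c(0, 1))
  # undefined rates name the offending set
  only_neg <- ann[3:4, ]
  expect_error(roc_curve(local_error(fits, only_neg)), "positive")
  only_pos <- annotated_regions("p", "1", c(0, 100), c(99, 199),
                                annotation = rep(">0breakpoints", 2))
  expect_error(roc_curve(local_error(fits, only_pos)), "negative")
})
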