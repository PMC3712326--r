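test_that("profile CSV round trip preserves positions and values", {
  set.seed(11)
  sim <- simulate_profiles(n_profiles = 2, chrom_count = 2,
                           m_range = c(20, 30), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(sim$profiles, path)
  back <- read_profiles(path)
  expect_setequal(names(back), names(sim$profiles))
  for (pid in names(sim$profiles)) {
    for (chr in names(sim$profiles[[pid]]$chromosomes)) {
      a <- sim$profiles[[pid]]$chromosomes[[chr]]
      b <- back[[pid]]$chromosomes[[chr]]
      expect_equal(b$positions, a$positions)
      expect_equal(b$logratio, a$logratio, tolerance = 1e-11)
    }
  }
})

test_that("bedGraph probes land on interval midpoints", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("track type=bedGraph",
               "chr2 100 200 0.5",
               "chr2 200 300 -0.25",
               "chr3 0 10 1.5"), path)
  prof <- read_profiles(path, format = "bedgraph", profile_id = "s1")
  expect_named(prof, "s1")
  s <- prof$s1$chromosomes
  expect_equal(s$chr2$positions, c(150, 250))
  expect_equal(s$chr2$logratio, c(0.5, -0.25))
  expect_equal(s$chr3$positions, 5)
})

test_that("non-finite logratios are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(profile_id = "p", chromosome = "1",
                   position = 1:10 * 100,
                   logratio = c(rnorm(5), NA, rnorm(4)))
  write.csv(df, path, row.names = FALSE)
  expect_message(prof <- read_profiles(path), "dropping 1 probes")
  expect_equal(length(prof$p$chromosomes[["1"]]$positions), 9)
})

test_that("duplicate probes and empty files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(profile_id = "p", chromosome = "7",
                   position = c(100, 200, 200), logratio = c(1, 2, 3))
  write.csv(df, path, row.names = FALSE)
  expect_error(read_profiles(path), "profile p chromosome 7 position 200")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("profile_id,chromosome,position,logratio", empty)
  expect_error(read_profiles(empty), "empty")
  eb <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(0), eb)
  expect_error(read_profiles(eb, format = "bedgraph"), "empty")
})

test_that("annotation labels map to the three canonical intervals", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(profile_id = "p", chromosome = "1",
                   start = c(1, 100, 200), end = c(50, 150, 250),
                   annotation = c("0breakpoints", "1breakpoint",
                                  ">0breakpoints"))
  write.csv(df, path, row.names = FALSE)
  ann <- read_annotations(path)
  expect_equal(ann$min_breakpoints, c(0, 1, 1))
  expect_equal(ann$max_breakpoints, c(0, 1, Inf))
  # every row matches exactly one canonical interval
  canon <- paste(ann$min_breakpoints, ann$max_breakpoints)
  expect_true(all(canon %in% c("0 0", "1 1", "1 Inf")))
})

test_that("explicit bounds honor the blank-means-unbounded rule", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("profile_id,chromosome,start,end,min_breakpoints,max_breakpoints",
               "p,1,1,50,1,", "p,1,60,90,0,0", "p,1,95,99,1,Inf"), path)
  ann <- read_annotations(path)
  expect_equal(ann$max_breakpoints, c(Inf, 0, Inf))
})

test_that("malformed annotations are rejected", {
  expect_error(annotated_regions("p", "1", 1, 10, annotation = "2breaks"),
               "unknown annotation label")
  expect_error(annotated_regions("p", "1", 1, 10, min_breakpoints = 2,
                                 max_breakpoints = 1),
               "min_breakpoints > max_breakpoints")
  expect_error(annotated_regions("p", "1", 10, 1, min_breakpoints = 0,
                                 max_breakpoints = 0),
               "start > end")
})

test_that("write_segments emits BED-like runs and round-trips breakpoints", {
  prof <- cn_profile("p", probe_series(c(10, 20, 30, 40), c(0, 0, 2, 2),
                                       chromosome = "5"))
  sp <- smooth_profile(prof, model = "cghseg.k",
                       grid = penalty_grid(c(1e-4, 100)), kmax = 2)
  seg_path <- withr::local_tempfile(fileext = ".bed")
  bp_path <- withr::local_tempfile(fileext = ".txt")
  # constant fit at the heavy penalty: one segment, no breakpoints
  write_segments(sp$fits[[2]], prof, seg_path, bp_path)
  segs <- read.table(seg_path, sep = "\t")
  expect_equal(nrow(segs), 1)
  expect_equal(length(read_breakpoints(bp_path)), 0)
  # one jump at the light penalty: two rows sharing the boundary
  write_segments(sp$fits[[1]], prof, seg_path, bp_path)
  segs <- read.table(seg_path, sep = "\t")
  expect_equal(nrow(segs), 2)
  expect_equal(segs$V3[1], segs$V2[2])  # shared breakpoint boundary
  expect_equal(segs$V4, c(0, 2))
  rt <- read_breakpoints(bp_path)
  expect_equal(rt[["5"]], sp$fits[[1]]$breakpoints[["5"]])
})
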