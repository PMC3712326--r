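#' Simulate copy number profiles with known breakpoints
#'
#' Generates piecewise-constant logratio signals with Gaussian probe noise
#' on irregular probe layouts.  Per chromosome, probe positions are drawn
#' uniformly over the chromosome, sorted and deduplicated; a segment count
#' is drawn from \code{segments_per_chrom_range}; segment boundaries are
#' placed at distinct inter-probe gaps so that every segment contains at
#' least one probe; the true breakpoint position is the midpoint between
#' the flanking probes, matching the convention of
#' \code{\link{extract_breakpoints}}, so exact recovery is possible.
#' Adjacent segment means differ by at least \code{jump_min} (jump
#' magnitudes uniform in \code{[jump_min, 2 jump_min]}, random sign).
#'
#' @param n_profiles Number of profiles.
#' @param chrom_count Chromosomes per profile (labeled \code{"1"},
#'   \code{"2"}, ...).
#' @param m_range Length-2 range of probe counts per chromosome, within
#'   \code{[8, 1e5]}.
#' @param segments_per_chrom_range Length-2 range of segment counts per
#'   chromosome.
#' @param jump_min Minimum absolute difference between adjacent segment
#'   means (logratio units).
#' @param noise_sd Gaussian noise standard deviation; 0 gives noiseless
#'   piecewise-constant profiles.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param heavy_tails If \code{TRUE}, draw noise from a scaled Student t
#'   with 3 degrees of freedom instead of a Gaussian (robustness
#'   exploration only; not used by any shipped benchmark).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list with \code{profiles} (named list of
#'   \code{\link{cn_profile}}) and \code{truth}, an object of class
#'   \code{synthetic_truth}: list with \code{breakpoints} (data frame
#'   \code{profile_id}, \code{chromosome}, \code{position}),
#'   \code{segments} (data frame with per-segment probe index bounds and
#'   means), \code{chrom_length_bp}, \code{noise_sd} and \code{seed}.
#' @export
simulate_profiles <- function(n_profiles = 50L, chrom_count = 4L,
                              m_range = c(150L, 250L),
                              segments_per_chrom_range = c(1L, 4L),
                              jump_min = 1.0, noise_sd = 0.25,
                              chrom_length_bp = 1e8,
                              heavy_tails = FALSE, seed = 1L) {
  if (jump_min <= 0) stop("jump_min must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  m_range <- as.integer(round(m_range))
  if (m_range[1] < 8L || m_range[2] > 1e5 || m_range[1] > m_range[2]) {
    stop("m_range must be an increasing range within [8, 1e5]")
  }
  s_range <- as.integer(round(segments_per_chrom_range))
  if (s_range[1] < 1L || s_range[1] > s_range[2]) {
    stop("segments_per_chrom_range must be an increasing range of ",
         "positive integers")
  }
  if (s_range[2] > m_range[1]) {
    stop("infeasible segment count: up to ", s_range[2],
         " segments requested but as few as ", m_range[1],
         " probes per chromosome")
  }
  with_seed(seed, {
    profiles <- vector("list", n_profiles)
    bp_rows <- list()
    seg_rows <- list()
    for (i in seq_len(n_profiles)) {
      pid <- sprintf("P%03d", i)
      series <- vector("list", chrom_count)
      for (ci in seq_len(chrom_count)) {
        chr <- as.character(ci)
        m_target <- sample(m_range[1]:m_range[2], 1L)
        pos <- sort(unique(round(stats::runif(m_target, 1,
                                              chrom_length_bp))))
        m <- length(pos)
        s <- sample(s_range[1]:s_range[2], 1L)
        if (s > m) stop("infeasible segment count ", s, " for m = ", m)
        gap_idx <- if (s > 1L) sort(sample.int(m - 1L, s - 1L)) else {
          integer(0)
        }
        starts <- c(1L, gap_idx + 1L)
        ends <- c(gap_idx, m)
        jumps <- if (s > 1L) {
          stats::runif(s - 1L, jump_min, 2 * jump_min) *
            sample(c(-1, 1), s - 1L, replace = TRUE)
        } else numeric(0)
        means <- cumsum(c(stats::rnorm(1, 0, 0.25), jumps))
        mu <- rep(means, times = ends - starts + 1L)
        noise <- if (noise_sd == 0) 0 else if (heavy_tails) {
          noise_sd * stats::rt(m, df = 3) / sqrt(3)
        } else {
          stats::rnorm(m, 0, noise_sd)
        }
        series[[ci]] <- probe_series(pos, mu + noise, chromosome = chr,
                                     length_bp = chrom_length_bp)
        if (s > 1L) {
          bp_rows[[length(bp_rows) + 1L]] <- data.frame(
            profile_id = pid, chromosome = chr,
            position = (pos[gap_idx] + pos[gap_idx + 1L]) / 2,
            stringsAsFactors = FALSE)
        }
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          profile_id = pid, chromosome = chr,
          first_probe = starts, last_probe = ends, mean = means,
          stringsAsFactors = FALSE)
      }
      profiles[[i]] <- cn_profile(pid, series)
    }
    names(profiles) <- vapply(profiles, `[[`, character(1), "profile_id")
    truth <- structure(
      list(breakpoints = if (length(bp_rows)) do.call(rbind, bp_rows) else {
        data.frame(profile_id = character(0), chromosome = character(0),
                   position = numeric(0))
      },
      segments = do.call(rbind, seg_rows),
      profile_ids = names(profiles),
      chromosomes = as.character(seq_len(chrom_count)),
      chrom_length_bp = chrom_length_bp, noise_sd = noise_sd,
      seed = seed),
      class = "synthetic_truth")
    list(profiles = profiles, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$profile_ids), "profiles,",
      length(x$chromosomes), "chromosomes,",
      nrow(x$breakpoints), "true breakpoints\n")
  invisible(x)
}

truth_count <- function(truth, pid, chr, start, end) {
  b <- truth$breakpoints
  sum(b$profile_id == pid & b$chromosome == chr &
        b$position >= start & b$position <= end)
}

#' Derive breakpoint-region annotations from a simulation truth
#'
#' Emulates the two expert annotation protocols.  Under the
#' \code{systematic} protocol the same fixed regions (deterministic,
#' evenly spaced along each chromosome, the same on every profile) are
#' labeled \code{[0,0]} or \code{[1,Inf)} according to the true breakpoint
#' count, mimicking a 0/1 spreadsheet over a fixed region set.  Under the
#' \code{any} protocol, regions are placed uniformly at random without
#' overlap, independently per profile, and labeled \code{[0,0]},
#' \code{[1,1]} (only when \code{exact_counts} is \code{TRUE} and the
#' region holds exactly one true breakpoint) or \code{[1,Inf)}.  By
#' construction the true segmentation has zero annotation error on every
#' generated region.
#'
#' @param truth A \code{synthetic_truth} from
#'   \code{\link{simulate_profiles}}.
#' @param protocol \code{"systematic"} or \code{"any"}.
#' @param n_regions Number of regions per profile, distributed round-robin
#'   over chromosomes.
#' @param region_width Region width in base pairs; default 8\% of the
#'   chromosome length.
#' @param exact_counts \code{any} protocol only: label single-breakpoint
#'   regions with the exact count \code{[1,1]} rather than \code{[1,Inf)}.
#' @param max_retries \code{any} protocol only: attempts to place a
#'   non-overlapping region before giving up with an error.
#' @param seed Seed for the random placement (\code{any} protocol).
#' @return An \code{annotation_df}; see \code{\link{annotated_regions}}.
#' @export
annotate_from_truth <- function(truth, protocol = c("systematic", "any"),
                                n_regions = 6L, region_width = NULL,
                                exact_counts = TRUE, max_retries = 100L,
                                seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  protocol <- match.arg(protocol)
  L <- truth$chrom_length_bp
  if (is.null(region_width)) region_width <- 0.08 * L
  if (region_width >= L) stop("region_width must fit within the chromosome")
  chroms <- truth$chromosomes
  nc <- length(chroms)
  region_chrom <- chroms[((seq_len(n_regions) - 1L) %% nc) + 1L]
  rows <- list()
  add <- function(pid, chr, start, end, count) {
    a_lo <- if (count == 0L) 0 else 1
    a_hi <- if (count == 0L) 0 else {
      if (count == 1L && protocol == "any" && exact_counts) 1 else Inf
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      profile_id = pid, chromosome = chr, start = start, end = end,
      min_breakpoints = a_lo, max_breakpoints = a_hi,
      stringsAsFactors = FALSE)
  }
  if (protocol == "systematic") {
    # fixed region layout shared by every profile
    per_chrom <- table(factor(region_chrom, levels = chroms))
    layout <- do.call(rbind, lapply(chroms, function(chr) {
      q <- per_chrom[[chr]]
      if (q == 0L) return(NULL)
      centers <- L * seq_len(q) / (q + 1)
      data.frame(chromosome = chr,
                 start = pmax(1, centers - region_width / 2),
                 end = pmin(L, centers + region_width / 2),
                 stringsAsFactors = FALSE)
    }))
    for (pid in truth$profile_ids) {
      for (k in seq_len(nrow(layout))) {
        cnt <- truth_count(truth, pid, layout$chromosome[k],
                           layout$start[k], layout$end[k])
        add(pid, layout$chromosome[k], layout$start[k], layout$end[k], cnt)
      }
    }
  } else {
    with_seed(seed, {
      for (pid in truth$profile_ids) {
        placed <- lapply(chroms, function(chr) {
          matrix(numeric(0), ncol = 2)
        })
        names(placed) <- chroms
        for (k in seq_len(n_regions)) {
          chr <- region_chrom[k]
          done <- FALSE
          for (try in seq_len(max_retries)) {
            start <- stats::runif(1, 1, L - region_width)
            end <- start + region_width
            prev <- placed[[chr]]
            overlaps <- nrow(prev) > 0 &&
              any(start <= prev[, 2] & end >= prev[, 1])
            if (!overlaps) {
              placed[[chr]] <- rbind(prev, c(start, end))
              cnt <- truth_count(truth, pid, chr, start, end)
              add(pid, chr, start, end, cnt)
              done <- TRUE
              break
            }
          }
          if (!done) {
            stop("could not place non-overlapping region ", k,
                 " on chromosome ", chr, " after ", max_retries,
                 " retries; reduce n_regions or region_width")
          }
        }
      }
    })
  }
  df <- do.call(rbind, rows)
  annotated_regions(df$profile_id, df$chromosome, df$start, df$end,
                    df$min_breakpoints, df$max_breakpoints)
}

#' The shipped synthetic benchmark
#'
#' The fixed stated world used by this package's acceptance tests: 50
#' profiles of 4 chromosomes, around 200 probes per chromosome (uniform in
#' 150--250), 1--4 segments per chromosome, minimum jump 1.0 logratio,
#' Gaussian noise sd 0.25, annotated under both protocols (6 systematic
#' regions plus 4 any-protocol regions with exact counts per profile).
#'
#' @param seed Integer seed; sub-seeds for simulation and annotation
#'   placement are derived from it.
#' @return List with \code{profiles}, \code{truth} and \code{annotations}
#'   (both protocols row-bound into one \code{annotation_df}).
#' @export
synthetic_benchmark <- function(seed = 1L) {
  seed <- as.integer(seed)
  sim <- simulate_profiles(n_profiles = 50L, chrom_count = 4L,
                           m_range = c(150L, 250L),
                           segments_per_chrom_range = c(1L, 4L),
                           jump_min = 1.0, noise_sd = 0.25,
                           seed = seed)
  ann_sys <- annotate_from_truth(sim$truth, "systematic", n_regions = 6L)
  ann_any <- annotate_from_truth(sim$truth, "any", n_regions = 4L,
                                 exact_counts = TRUE, seed = seed + 1L)
  ann <- rbind(ann_sys, ann_any)
  class(ann) <- c("annotation_df", "data.frame")
  list(profiles = sim$profiles, truth = sim$truth, annotations = ann)
}
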