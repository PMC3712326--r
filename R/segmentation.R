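#' Exact least-squares segmentation for 1..kmax segments
#'
#' Computes, for every segment count \eqn{k = 1, \dots, kmax}, the
#' piecewise-constant signal \eqn{\mu^k} minimizing the residual sum of
#' squares \eqn{\sum_i (x_i - \mu^k_i)^2} over all signals with at most
#' \eqn{k} constant runs, by exact dynamic programming in
#' \eqn{O(kmax \cdot m^2)} time and \eqn{O(kmax \cdot m)} memory.  Fitted
#' values within a segment equal the segment mean.
#'
#' @param x Numeric vector of logratio values (one chromosome).
#' @param kmax Maximum number of segments, \code{1 <= kmax <= length(x)}.
#' @return An object of class \code{segmentation_set}: list with elements
#'   \code{m}, \code{kmax}, \code{rss} (length-\code{kmax} vector of optimal
#'   residual sums of squares), \code{ends} (list; \code{ends[[k]]} gives the
#'   probe indices ending each of the \code{k} segments, last element
#'   \code{m}) and \code{x} (the input).
#' @seealso \code{\link{segmentation_means}} to materialize \eqn{\mu^k}.
#' @export
segment_dp <- function(x, kmax = 20L) {
  x <- as.numeric(x)
  m <- length(x)
  if (m < 1L) stop("x must have at least one value")
  if (any(!is.finite(x))) stop("x must be finite")
  kmax <- as.integer(kmax)
  if (kmax < 1L) stop("kmax must be >= 1")
  if (kmax > m) stop("kmax (", kmax, ") exceeds number of probes (", m, ")")
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  # rss of the single segment covering probes i..j (i, j 1-based)
  seg_cost <- function(i, j) {
    n <- j - i + 1
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / n
  }
  V <- matrix(Inf, nrow = kmax, ncol = m)
  B <- matrix(NA_integer_, nrow = kmax, ncol = m)
  V[1, ] <- seg_cost(1L, seq_len(m))
  if (kmax > 1L) {
    for (k in 2:kmax) {
      for (j in k:m) {
        i <- k:j                      # candidate start of the last segment
        val <- V[k - 1, i - 1] + seg_cost(i, j)
        best <- which.min(val)
        V[k, j] <- val[best]
        B[k, j] <- i[best]
      }
    }
  }
  ends <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    e <- integer(k)
    j <- m
    kk <- k
    while (kk > 1L) {
      e[kk] <- j
      j <- B[kk, j] - 1L
      kk <- kk - 1L
    }
    e[1] <- j
    ends[[k]] <- e
  }
  rss <- pmax(V[, m], 0)              # guard tiny negative rounding
  structure(list(m = m, kmax = kmax, rss = rss, ends = ends, x = x),
            class = "segmentation_set")
}

#' Fitted values of a segmentation
#'
#' @param seg A \code{segmentation_set} from \code{\link{segment_dp}}.
#' @param k Number of segments.
#' @return Numeric vector \eqn{\mu^k} of per-probe segment means.
#' @export
segmentation_means <- function(seg, k) {
  stopifnot(inherits(seg, "segmentation_set"))
  k <- as.integer(k)
  if (k < 1L || k > seg$kmax) stop("k out of range 1..", seg$kmax)
  e <- seg$ends[[k]]
  starts <- c(1L, e[-k] + 1L)
  mu <- numeric(seg$m)
  for (s in seq_len(k)) {
    idx <- starts[s]:e[s]
    mu[idx] <- mean(seg$x[idx])
  }
  mu
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat("segmentation_set: m =", x$m, ", kmax =", x$kmax, "\n")
  invisible(x)
}

#' Select the number of segments by a per-probe-normalized penalty
#'
#' Chooses \eqn{k^*(\lambda) = \arg\min_k \lambda k + RSS(k)/m}, the
#' penalized model-selection rule used by the \code{cghseg.k} model.  Ties
#' are broken toward the smallest \eqn{k}.
#'
#' @param seg A \code{segmentation_set}.
#' @param m Number of probes used in the normalization (defaults to
#'   \code{seg$m}).
#' @param lam Penalty scale \eqn{\lambda \ge 0}.
#' @return Selected integer segment count.
#' @export
choose_k_lavielle <- function(seg, m = seg$m, lam) {
  if (lam < 0) stop("lam must be >= 0")
  k <- seq_len(seg$kmax)
  crit <- lam * k + seg$rss / m
  which.min(crit)
}

#' Select the number of segments by a per-breakpoint penalty
#'
#' Chooses \eqn{k^*(\beta) = \arg\min_k \beta (k - 1) + RSS(k)}, the
#' PELT-style penalized likelihood rule used by the \code{pelt.n} model.
#' With \eqn{\beta = \lambda m} this is mathematically equivalent to
#' \code{\link{choose_k_lavielle}}.  Ties are broken toward the smallest
#' \eqn{k}.
#'
#' @param seg A \code{segmentation_set}.
#' @param beta Penalty per additional segment, \eqn{\beta \ge 0}.
#' @return Selected integer segment count.
#' @export
choose_k_penalty <- function(seg, beta) {
  if (beta < 0) stop("beta must be >= 0")
  k <- seq_len(seg$kmax)
  crit <- beta * (k - 1) + seg$rss
  which.min(crit)
}

#' Exact 1-D fused lasso (total variation) smoother
#'
#' Returns the unique minimizer of
#' \deqn{\frac12 \sum_{i=1}^m (x_i - \mu_i)^2 +
#'       \lambda_2 \sum_{i=1}^{m-1} |\mu_i - \mu_{i+1}|}
#' computed by a direct non-iterative taut-string style algorithm (Condat's
#' method), exact up to floating point.  At \code{lam2 = 0} the output is
#' \code{x}; for \code{lam2} at or above the total-variation saturation
#' threshold the output is constant at \code{mean(x)}.
#'
#' @param x Numeric vector.
#' @param lam2 Fusion penalty \eqn{\lambda_2 \ge 0}.
#' @return Numeric vector of fitted values, same length as \code{x}.
#' @export
fused_lasso_1d <- function(x, lam2) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(lam2) != 1L || is.na(lam2) || lam2 < 0) {
    stop("lam2 must be a single non-negative number")
  }
  N <- length(x)
  if (N < 1L) stop("x must have at least one value")
  if (N == 1L || lam2 == 0) return(x)
  # the constant fit is optimal iff lam2 >= max |cumsum(x - mean(x))|;
  # handling it analytically avoids cancellation at huge penalties
  xbar <- mean(x)
  if (lam2 >= max(abs(cumsum(x - xbar)[-N]))) return(rep(xbar, N))
  tv_denoise_condat(x, lam2)
}

# Direct 1-D total variation denoising (Condat 2013, Algorithm 1).
# Scans once, maintaining candidate lower/upper segment levels vmin/vmax
# and running slacks umin/umax; emits a segment whenever a jump is forced.
tv_denoise_condat <- function(y, lam) {
  N <- length(y)
  out <- numeric(N)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam
  vmax <- y[1] + lam
  umin <- lam
  umax <- -lam
  repeat {
    if (k == N) {
      # end of signal: flush pending segments, then the last one
      if (umin < 0) {
        out[k0:km] <- vmin
        k <- k0 <- km <- km + 1L
        vmin <- y[k]
        umin <- lam
        umax <- y[k] + lam - vmax
        if (k == N) next
      } else if (umax > 0) {
        out[k0:kp] <- vmax
        k <- k0 <- kp <- kp + 1L
        vmax <- y[k]
        umax <- -lam
        umin <- y[k] - lam - vmin
        if (k == N) next
      } else {
        out[k0:N] <- vmin + umin / (k - k0 + 1)
        return(out)
      }
    }
    if (y[k + 1] + umin < vmin - lam) {
      # forced negative jump: the running lower level is a final segment
      out[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]
      vmax <- y[k] + 2 * lam
      umin <- lam
      umax <- -lam
    } else if (y[k + 1] + umax > vmax + lam) {
      # forced positive jump
      out[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lam
      vmax <- y[k]
      umin <- lam
      umax <- -lam
    } else {
      # extend the current segment
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lam) {
        vmin <- vmin + (umin - lam) / (k - k0 + 1)
        umin <- lam
        km <- k
      }
      if (umax <= -lam) {
        vmax <- vmax + (umax + lam) / (k - k0 + 1)
        umax <- -lam
        kp <- k
      }
    }
  }
}

#' Chromosome-length-normalized fused lasso penalty
#'
#' The \code{flsa.norm} model rescales the smoothness parameter by probe
#' density: \eqn{\lambda_2 = \lambda m \times 10^6 / l}, where \eqn{m} is
#' the number of probes on the chromosome and \eqn{l} its length in base
#' pairs, so one unit of \eqn{\lambda} corresponds to the penalty per probe
#' per megabase.
#'
#' @param lam Smoothness parameter \eqn{\lambda}.
#' @param m Number of probes on the chromosome.
#' @param l Chromosome length in base pairs, \code{l > 0}.
#' @return The fusion penalty \eqn{\lambda_2}.
#' @export
flsa_norm_penalty <- function(lam, m, l) {
  if (any(l <= 0)) stop("chromosome length l must be positive")
  if (any(m < 1)) stop("m must be >= 1")
  lam * m * 1e6 / l
}

#' Validate a penalty grid
#'
#' @param values Strictly increasing, finite, non-negative smoothness
#'   parameter values.
#' @return The validated numeric vector, classed \code{penalty_grid}.
#' @export
penalty_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("penalty grid must be non-empty")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("penalty grid values must be finite and non-negative")
  }
  if (length(values) > 1L && any(diff(values) <= 0)) {
    stop("penalty grid values must be strictly increasing")
  }
  structure(values, class = "penalty_grid")
}

#' Default smoothness grids
#'
#' For the penalized segmentation models (\code{cghseg.k}, \code{pelt.n})
#' the default is 100 logarithmically spaced values in
#' \eqn{[10^{-8}, 10^{4}]}; for the fused lasso models (\code{flsa},
#' \code{flsa.norm}) 100 logarithmically spaced values in
#' \eqn{[10^{-5}, 10^{12}]}.
#'
#' @param model Model name.
#' @param count Number of grid points.
#' @return A \code{\link{penalty_grid}}.
#' @export
default_grid <- function(model = c("cghseg.k", "pelt.n", "flsa", "flsa.norm"),
                         count = 100L) {
  model <- match.arg(model)
  rng <- if (model %in% c("flsa", "flsa.norm")) c(-5, 12) else c(-8, 4)
  penalty_grid(10^seq(rng[1], rng[2], length.out = count))
}

#' Smooth a whole profile over a grid of smoothness parameters
#'
#' Each chromosome is smoothed independently.  For the \code{cghseg.k} and
#' \code{pelt.n} models the exact segmentations for \eqn{k = 1..kmax} are
#' computed once per chromosome by \code{\link{segment_dp}} and reused for
#' every grid value; \code{cghseg.k} selects \eqn{k} via
#' \code{\link{choose_k_lavielle}} and \code{pelt.n} via
#' \code{\link{choose_k_penalty}} with \eqn{\beta = \lambda m}.  The
#' \code{flsa} model applies \code{\link{fused_lasso_1d}} with
#' \eqn{\lambda_2 = \lambda}; \code{flsa.norm} first rescales by probe
#' density via \code{\link{flsa_norm_penalty}}.  Breakpoints are the
#' midpoints between adjacent probes whose fitted values differ (for the
#' fused lasso, differ by more than a fusion tolerance that absorbs float
#' noise).
#'
#' @param profile A \code{\link{cn_profile}}.
#' @param model One of \code{"cghseg.k"}, \code{"pelt.n"}, \code{"flsa"},
#'   \code{"flsa.norm"}.
#' @param grid \code{\link{penalty_grid}} of smoothness values; defaults to
#'   \code{default_grid(model)}.
#' @param kmax Maximum segments per chromosome for the penalized models
#'   (clipped to the chromosome probe count).
#' @param fusion_tolerance Relative tolerance deciding that two adjacent
#'   fused-lasso fitted values are equal; scaled by \code{1 + max(abs(x))}.
#' @return An object of class \code{smoothed_profile}: list with
#'   \code{profile_id}, \code{model}, \code{lambda} and \code{fits}, a
#'   per-lambda list of \code{smoothed_fit} objects (fields
#'   \code{smoothness}, \code{smoothed}, \code{breakpoints}, keyed by
#'   chromosome).
#' @export
smooth_profile <- function(profile,
                           model = c("cghseg.k", "pelt.n", "flsa",
                                     "flsa.norm"),
                           grid = default_grid(model), kmax = 20L,
                           fusion_tolerance = 1e-9) {
  stopifnot(inherits(profile, "cn_profile"))
  model <- match.arg(model)
  grid <- penalty_grid(unclass(grid))
  nl <- length(grid)
  chroms <- names(profile$chromosomes)
  per_chrom <- lapply(profile$chromosomes, function(s) {
    x <- s$logratio
    p <- s$positions
    m <- length(x)
    mids <- if (m > 1L) (p[-m] + p[-1]) / 2 else numeric(0)
    if (model %in% c("cghseg.k", "pelt.n")) {
      seg <- segment_dp(x, min(kmax, m))
      smoothed <- vector("list", nl)
      bps <- vector("list", nl)
      for (li in seq_len(nl)) {
        lam <- grid[li]
        k <- if (model == "cghseg.k") {
          choose_k_lavielle(seg, m, lam)
        } else {
          choose_k_penalty(seg, lam * m)
        }
        smoothed[[li]] <- segmentation_means(seg, k)
        e <- seg$ends[[k]]
        bps[[li]] <- if (k > 1L) mids[e[-k]] else numeric(0)
      }
      list(smoothed = smoothed, breakpoints = bps)
    } else {
      tol <- fusion_tolerance * (1 + max(abs(x)))
      smoothed <- vector("list", nl)
      bps <- vector("list", nl)
      for (li in seq_len(nl)) {
        lam2 <- if (model == "flsa") grid[li] else {
          flsa_norm_penalty(grid[li], m, s$length_bp)
        }
        mu <- fused_lasso_1d(x, lam2)
        smoothed[[li]] <- mu
        bps[[li]] <- if (m > 1L) mids[abs(diff(mu)) > tol] else numeric(0)
      }
      list(smoothed = smoothed, breakpoints = bps)
    }
  })
  fits <- lapply(seq_len(nl), function(li) {
    structure(
      list(smoothness = grid[li],
           smoothed = lapply(per_chrom, function(pc) pc$smoothed[[li]]),
           breakpoints = lapply(per_chrom, function(pc) {
             pc$breakpoints[[li]]
           })),
      class = "smoothed_fit")
  })
  structure(list(profile_id = profile$profile_id, model = model,
                 lambda = as.numeric(grid), fits = fits),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat("smoothed_profile", x$profile_id, ":", x$model, "model,",
      length(x$lambda), "smoothness values\n")
  invisible(x)
}
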