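#' Breakpoints of a smoothed signal
#'
#' A model predicts a breakpoint at the midpoint between two adjacent probes
#' whose fitted values differ:
#' \eqn{\hat b = \{(p_j + p_{j+1})/2 : \hat x_j \ne \hat x_{j+1}\}}.
#'
#' @param values Fitted (smoothed) values \eqn{\hat x}.
#' @param positions Probe positions, strictly increasing, same length.
#' @param tol Absolute tolerance below which adjacent values count as equal
#'   (0 for exactly piecewise-constant fits; use a small positive value for
#'   fused-lasso output).
#' @return Numeric vector of breakpoint positions (possibly half-integers).
#' @export
extract_breakpoints <- function(values, positions, tol = 0) {
  m <- length(values)
  if (length(positions) != m) {
    stop("values and positions lengths differ (", m, " vs ",
         length(positions), ")")
  }
  if (m > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (m < 2L) return(numeric(0))
  jump <- abs(diff(values)) > tol
  ((positions[-m] + positions[-1]) / 2)[jump]
}

#' Count predicted breakpoints inside a region
#'
#' Regions are closed intervals: a breakpoint exactly on a bound counts as
#' inside.
#'
#' @param breakpoints Numeric vector of breakpoint positions.
#' @param start,end Region bounds (closed interval).
#' @return Non-negative integer count \eqn{|\hat b \cap r|}.
#' @export
count_in_region <- function(breakpoints, start, end) {
  if (start > end) stop("malformed region: start > end")
  sum(breakpoints >= start & breakpoints <= end)
}

#' Zero-one annotation error of a predicted breakpoint count
#'
#' Compares the predicted breakpoint count in a region with the annotated
#' interval \eqn{a = [a_{lo}, a_{hi}]}: a false positive when the count
#' exceeds \eqn{a_{hi}}, a false negative when it falls below \eqn{a_{lo}},
#' a true positive (used by ROC curves) when the count reaches at least
#' \eqn{a_{lo}}.  The error is \code{fp + fn}, which is 0 exactly when the
#' count lies inside the annotated interval and 1 otherwise.
#'
#' @param count Predicted breakpoint count(s), vectorized.
#' @param min_breakpoints,max_breakpoints Annotated interval bounds
#'   (recycled); \code{max_breakpoints} may be \code{Inf}.
#' @return A \code{data.frame} with integer columns \code{fp}, \code{fn},
#'   \code{tp}, \code{error}.
#' @export
region_verdict <- function(count, min_breakpoints, max_breakpoints) {
  if (any(count < 0)) stop("count must be >= 0")
  fp <- as.integer(count > max_breakpoints)
  fn <- as.integer(count < min_breakpoints)
  tp <- as.integer(count >= min_breakpoints)
  data.frame(fp = fp, fn = fn, tp = tp, error = fp + fn)
}

# Per-annotation verdict matrices (regions x lambda) for one smoothed
# profile; the building block shared by error curves and cross-validation.
verdict_matrices <- function(fits, annotations) {
  stopifnot(inherits(fits, "smoothed_profile"))
  ann <- annotations[annotations$profile_id == fits$profile_id, ,
                     drop = FALSE]
  nl <- length(fits$lambda)
  nr <- nrow(ann)
  counts <- matrix(0L, nrow = nr, ncol = nl)
  chroms <- names(fits$fits[[1]]$breakpoints)
  if (nr > 0L) {
    absent <- !(ann$chromosome %in% chroms)
    if (any(absent)) {
      a <- ann[absent, , drop = FALSE][1, ]
      stop("annotation on absent chromosome: profile ", a$profile_id,
           " chromosome ", a$chromosome, " [", a$start, ",", a$end, "]")
    }
    for (li in seq_len(nl)) {
      bps <- fits$fits[[li]]$breakpoints
      for (ri in seq_len(nr)) {
        counts[ri, li] <- count_in_region(bps[[ann$chromosome[ri]]],
                                          ann$start[ri], ann$end[ri])
      }
    }
  }
  fp <- counts > ann$max_breakpoints   # recycles columnwise: nr x nl
  fn <- counts < ann$min_breakpoints
  tp <- counts >= ann$min_breakpoints
  bp_total <- vapply(fits$fits, function(f) {
    sum(lengths(f$breakpoints))
  }, numeric(1))
  list(profile_id = fits$profile_id, lambda = fits$lambda,
       annotations = ann, counts = counts,
       fp = fp + 0L, fn = fn + 0L, tp = tp + 0L, err = (fp | fn) + 0L,
       bp_total = bp_total,
       n_pos = sum(ann$min_breakpoints >= 1),
       n_neg = sum(is.finite(ann$max_breakpoints)))
}

new_error_curve <- function(lambda, errors, fp, fn, tp, n_annotations,
                            n_pos, n_neg, breakpoints, model = NA_character_,
                            scope = "local") {
  df <- data.frame(lambda = lambda, errors = errors, fp = fp, fn = fn,
                   tp = tp)
  structure(df, class = c("error_curve", "data.frame"),
            n_annotations = n_annotations, n_pos = n_pos, n_neg = n_neg,
            breakpoints = breakpoints, model = model, scope = scope)
}

#' Local (single-profile) annotation error curve
#'
#' Sums the zero-one annotation error over all annotated regions of one
#' profile, for every smoothness value of the fit:
#' \eqn{E_i(\lambda) = \sum_{r} e(\hat b^\lambda, r, a)}.
#'
#' @param fits A \code{smoothed_profile} for profile \eqn{i}.
#' @param annotations An \code{annotation_df}; only rows for this profile
#'   are used.  Annotations referencing a chromosome absent from the fit are
#'   an error.
#' @return An \code{error_curve}: data frame with columns \code{lambda},
#'   \code{errors}, \code{fp}, \code{fn}, \code{tp}, and attributes
#'   \code{n_annotations}, \code{n_pos}, \code{n_neg} (sizes of the
#'   positive/negative annotation sets) and \code{breakpoints} (total
#'   predicted breakpoints per lambda, used for tie-breaking).
#' @export
local_error <- function(fits, annotations) {
  vm <- verdict_matrices(fits, annotations)
  pos <- vm$annotations$min_breakpoints >= 1   # tp total counts A+ only
  new_error_curve(
    lambda = vm$lambda,
    errors = colSums(vm$err), fp = colSums(vm$fp), fn = colSums(vm$fn),
    tp = colSums(vm$tp[pos, , drop = FALSE]),
    n_annotations = nrow(vm$annotations), n_pos = vm$n_pos,
    n_neg = vm$n_neg, breakpoints = vm$bp_total,
    model = fits$model, scope = "local")
}

#' Global annotation error curve
#'
#' Pointwise sum of per-profile error curves over a collection of profiles:
#' \eqn{E^{global}(\lambda) = \sum_i E_i(\lambda)}.  All curves must share
#' the same smoothness grid.
#'
#' @param curves List of \code{error_curve} objects (or a single one).
#' @return An \code{error_curve} with aggregated totals.
#' @export
global_error <- function(curves) {
  if (inherits(curves, "error_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("need at least one error curve")
  lam <- curves[[1]]$lambda
  for (cu in curves) {
    if (length(cu$lambda) != length(lam) ||
        any(cu$lambda != lam)) {
      stop("error curves computed on different smoothness grids")
    }
  }
  sum_attr <- function(name) {
    sum(vapply(curves, function(cu) attr(cu, name), numeric(1)))
  }
  new_error_curve(
    lambda = lam,
    errors = Reduce(`+`, lapply(curves, function(cu) cu$errors)),
    fp = Reduce(`+`, lapply(curves, function(cu) cu$fp)),
    fn = Reduce(`+`, lapply(curves, function(cu) cu$fn)),
    tp = Reduce(`+`, lapply(curves, function(cu) cu$tp)),
    n_annotations = sum_attr("n_annotations"),
    n_pos = sum_attr("n_pos"), n_neg = sum_attr("n_neg"),
    breakpoints = Reduce(`+`, lapply(curves, function(cu) {
      attr(cu, "breakpoints")
    })),
    model = attr(curves[[1]], "model"), scope = "global")
}

#' ROC curve of an error curve
#'
#' The true positive rate at each smoothness value is the fraction of
#' positive annotations (\eqn{a_{lo} \ge 1}) whose region contains at least
#' one predicted breakpoint count reaching \eqn{a_{lo}}; the false positive
#' rate is the fraction of negative annotations (finite \eqn{a_{hi}}) with
#' a false positive.  Note a \code{1breakpoint} annotation \eqn{[1,1]}
#' belongs to both sets.
#'
#' @param curve An \code{error_curve}.
#' @return Data frame with columns \code{lambda}, \code{fpr}, \code{tpr},
#'   ordered by lambda.
#' @export
roc_curve <- function(curve) {
  stopifnot(inherits(curve, "error_curve"))
  n_pos <- attr(curve, "n_pos")
  n_neg <- attr(curve, "n_neg")
  if (n_pos == 0) {
    stop("true positive rate undefined: the positive annotation set ",
         "(min_breakpoints >= 1) is empty")
  }
  if (n_neg == 0) {
    stop("false positive rate undefined: the negative annotation set ",
         "(finite max_breakpoints) is empty")
  }
  data.frame(lambda = curve$lambda, fpr = curve$fp / n_neg,
             tpr = curve$tp / n_pos)
}

#' Write an error curve as CSV
#' @param curve An \code{error_curve}.
#' @param path Output path.
#' @param model Model name column (defaults to the curve's own).
#' @export
write_error_curve <- function(curve, path, model = attr(curve, "model")) {
  df <- data.frame(model = model, lambda = curve$lambda,
                   errors = curve$errors, fp = curve$fp, fn = curve$fn,
                   tp = curve$tp,
                   n_annotations = attr(curve, "n_annotations"))
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
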