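#' @rdname train_global
#' @export
train_local <- function(curve, order = attr(curve, "breakpoints")) {
  train_curve(curve, order, scope = "local")
}

#' Train the smoothness parameter on an annotation error curve
#'
#' \code{train_global} minimizes the global error curve
#' \eqn{\hat\lambda = \arg\min_\lambda E^{global}(\lambda)};
#' \code{train_local} minimizes a single profile's local curve
#' \eqn{\hat\lambda_i = \arg\min_\lambda E_i(\lambda)}.  Because a local
#' training set is small, several smoothness values typically attain the
#' minimum; ties are resolved on the error curve re-ordered from most to
#' fewest predicted breakpoints (the smoothness parameter is assumed
#' monotonic in breakpoint count):
#' \enumerate{
#'   \item minimum attained on an interior plateau: take the middle element;
#'   \item plateau reaches the most-breakpoints end of the grid: take the
#'     minimizer with fewest breakpoints (guards the false positive rate);
#'   \item plateau reaches the fewest-breakpoints end: take the minimizer
#'     with most breakpoints (guards the false negative rate).
#' }
#' A plateau touching both ends (constant curve) falls under rule 1.  For a
#' non-contiguous argmin set the rules apply to the ordered argmin list as a
#' whole.  The same rules serve both scopes.
#'
#' @param curve An \code{error_curve}.
#' @param order Numeric vector of total predicted breakpoints at each grid
#'   value, used to order the grid; defaults to the curve's own
#'   \code{breakpoints} attribute.  Ties in breakpoint count are ordered by
#'   lambda.
#' @return An object of class \code{trained_smoothness}: list with
#'   \code{chosen} (the selected lambda), \code{scope},
#'   \code{achieved_error}, \code{argmin} (all grid values attaining the
#'   minimum) and \code{rule} (which tie-break applied; 0 for a unique
#'   minimizer).
#' @export
train_global <- function(curve, order = attr(curve, "breakpoints")) {
  train_curve(curve, order, scope = "global")
}

train_curve <- function(curve, order, scope) {
  stopifnot(inherits(curve, "error_curve"))
  lambda <- curve$lambda
  errors <- curve$errors
  n <- length(lambda)
  if (n < 1L) stop("empty smoothness grid")
  if (is.null(order)) order <- rep(0, n)
  if (length(order) != n) stop("order must match the grid length")
  # grid positions from most to fewest predicted breakpoints
  ord <- base::order(-order, lambda)
  err_o <- errors[ord]
  amin <- which(err_o == min(err_o))
  if (length(amin) == 1L) {
    pick <- amin
    rule <- 0L
  } else {
    touches_most <- 1L %in% amin
    touches_fewest <- n %in% amin
    if (touches_most && !touches_fewest) {
      pick <- amin[length(amin)]       # rule 2: fewest breakpoints
      rule <- 2L
    } else if (touches_fewest && !touches_most) {
      pick <- amin[1L]                 # rule 3: most breakpoints
      rule <- 3L
    } else {
      pick <- amin[ceiling(length(amin) / 2)]   # rule 1: middle
      rule <- 1L
    }
  }
  idx <- ord[pick]
  structure(list(chosen = lambda[idx], index = idx, scope = scope,
                 achieved_error = errors[idx], argmin = lambda[ord[amin]],
                 rule = rule),
            class = "trained_smoothness")
}

#' @export
print.trained_smoothness <- function(x, ...) {
  cat("trained_smoothness (", x$scope, "): lambda = ",
      format(x$chosen), ", error = ", x$achieved_error,
      ", |argmin| = ", length(x$argmin), "\n", sep = "")
  invisible(x)
}
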