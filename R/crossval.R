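# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Evaluate a smoothing model against annotations, once
#'
#' Smooths every profile over the grid and scores every annotated region at
#' every smoothness value.  The result caches per-annotation verdicts so
#' that training and both cross-validation protocols can be run repeatedly
#' (different folds, holdouts, seeds) without refitting the model; both
#' \code{\link{loocv_annotation}} and \code{\link{nt_fold_cv}} accept it in
#' place of the raw profiles.
#'
#' @param profiles List of \code{\link{cn_profile}} objects.
#' @param annotations An \code{annotation_df} covering (a subset of) the
#'   profiles.
#' @param model,grid,kmax,fusion_tolerance Passed to
#'   \code{\link{smooth_profile}}.
#' @return An object of class \code{segtrain_eval}.
#' @export
evaluate_models <- function(profiles, annotations,
                            model = c("cghseg.k", "pelt.n", "flsa",
                                      "flsa.norm"),
                            grid = default_grid(model), kmax = 20L,
                            fusion_tolerance = 1e-9) {
  model <- match.arg(model)
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  per_profile <- lapply(profiles, function(p) {
    fits <- smooth_profile(p, model = model, grid = grid, kmax = kmax,
                           fusion_tolerance = fusion_tolerance)
    verdict_matrices(fits, annotations)
  })
  names(per_profile) <- vapply(per_profile, `[[`, character(1), "profile_id")
  structure(list(model = model, lambda = as.numeric(unclass(grid)),
                 per_profile = per_profile),
            class = "segtrain_eval")
}

#' Score externally computed breakpoints against annotations
#'
#' Adapter for smoothing models not implemented in this package: takes a
#' per-smoothness breakpoint table (columns \code{model}, \code{lambda},
#' \code{profile_id}, \code{chromosome}, \code{position}) such as the one
#' written by the \code{segment} subcommand, and builds the same evaluation
#' object as \code{\link{evaluate_models}}, so external models can be
#' trained and cross-validated identically.  A (profile, lambda,
#' chromosome) combination with no rows predicts zero breakpoints there.
#'
#' @param breakpoints Data frame of predicted breakpoints.
#' @param annotations An \code{annotation_df}.
#' @return An object of class \code{segtrain_eval}.
#' @export
evaluate_breakpoints <- function(breakpoints, annotations) {
  need <- c("model", "lambda", "profile_id", "chromosome", "position")
  missing_cols <- setdiff(need, names(breakpoints))
  if (length(missing_cols)) {
    stop("breakpoint table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  lambda <- sort(unique(breakpoints$lambda))
  pids <- unique(c(as.character(breakpoints$profile_id),
                   as.character(annotations$profile_id)))
  model <- as.character(breakpoints$model[1])
  per_profile <- lapply(pids, function(pid) {
    sub <- breakpoints[breakpoints$profile_id == pid, , drop = FALSE]
    chroms <- unique(c(
      as.character(sub$chromosome),
      as.character(annotations$chromosome[annotations$profile_id == pid])))
    fits <- lapply(lambda, function(lam) {
      sl <- sub[sub$lambda == lam, , drop = FALSE]
      bps <- lapply(chroms, function(chr) {
        sort(sl$position[sl$chromosome == chr])
      })
      names(bps) <- chroms
      structure(list(smoothness = lam, smoothed = NULL, breakpoints = bps),
                class = "smoothed_fit")
    })
    sp <- structure(list(profile_id = pid, model = model, lambda = lambda,
                         fits = fits),
                    class = "smoothed_profile")
    verdict_matrices(sp, annotations)
  })
  names(per_profile) <- pids
  structure(list(model = model, lambda = lambda,
                 per_profile = per_profile),
            class = "segtrain_eval")
}

#' @export
print.segtrain_eval <- function(x, ...) {
  cat("segtrain_eval:", x$model, "model,", length(x$per_profile),
      "profiles,", length(x$lambda), "smoothness values\n")
  invisible(x)
}

# error_curve over a subset of annotation rows of a subset of profiles;
# rows_by_profile: named list of integer row indices (NULL = all rows).
# Breakpoint-count ordering always uses whole-profile totals, because the
# predicted breakpoints do not depend on which annotations are in scope.
curve_from_rows <- function(eval, profile_ids = names(eval$per_profile),
                            rows_by_profile = NULL, scope = "global") {
  nl <- length(eval$lambda)
  errors <- fp <- fn <- tp <- bp <- numeric(nl)
  n_ann <- n_pos <- n_neg <- 0
  for (pid in profile_ids) {
    vm <- eval$per_profile[[pid]]
    rows <- if (is.null(rows_by_profile)) seq_len(nrow(vm$annotations)) else {
      rows_by_profile[[pid]]
    }
    bp <- bp + vm$bp_total
    if (length(rows) == 0L) next
    errors <- errors + colSums(vm$err[rows, , drop = FALSE])
    fp <- fp + colSums(vm$fp[rows, , drop = FALSE])
    fn <- fn + colSums(vm$fn[rows, , drop = FALSE])
    pos <- rows[vm$annotations$min_breakpoints[rows] >= 1]
    tp <- tp + colSums(vm$tp[pos, , drop = FALSE])
    n_ann <- n_ann + length(rows)
    n_pos <- n_pos + length(pos)
    n_neg <- n_neg + sum(is.finite(vm$annotations$max_breakpoints[rows]))
  }
  new_error_curve(eval$lambda, errors, fp, fn, tp, n_ann, n_pos, n_neg,
                  breakpoints = bp, model = eval$model, scope = scope)
}

new_cv_result <- function(protocol, scope, per_fold_errors, fp_rate,
                          fn_rate, t = NA_integer_, V = NA_integer_,
                          seed = NA_integer_, n_test = NA_integer_) {
  structure(list(protocol = protocol, scope = scope,
                 per_fold_errors = per_fold_errors,
                 mean = mean(per_fold_errors),
                 sd = stats::sd(per_fold_errors),
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 t = t, V = V, seed = seed, n_test = n_test),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result [", x$protocol, "/", x$scope, "]: mean error ",
      sprintf("%.4f", x$mean), " (sd ", sprintf("%.4f", x$sd),
      "), fp ", sprintf("%.4f", x$fp_rate),
      ", fn ", sprintf("%.4f", x$fn_rate), "\n", sep = "")
  invisible(x)
}

resolve_eval <- function(x, annotations, model, grid, kmax) {
  if (inherits(x, "segtrain_eval")) x else {
    evaluate_models(x, annotations, model = model, grid = grid, kmax = kmax)
  }
}

#' Leave-one-annotation-out cross-validation
#'
#' Estimates and compares the breakpoint-detection error of globally and
#' locally trained smoothness parameters.  In each of \code{V} repetitions,
#' one annotated region per profile is held out uniformly at random; the
#' smoothness parameter is trained on all remaining annotations (a single
#' shared lambda for the global scope, a per-profile lambda for the local
#' scope) and errors are counted on the held-out regions only.  The final
#' estimate is the average over repetitions.
#'
#' Profiles with fewer than two annotations cannot both contribute a
#' training annotation and a held-out one; they are excluded from the
#' holdout (their annotations stay in the global training set) and listed
#' in the \code{excluded_profiles} attribute with a message.
#'
#' @param profiles List of \code{cn_profile} objects, or a precomputed
#'   \code{\link{evaluate_models}} result (in which case \code{annotations},
#'   \code{model}, \code{grid} and \code{kmax} are ignored).
#' @param annotations An \code{annotation_df}.
#' @param model,grid,kmax Passed to \code{\link{evaluate_models}}.
#' @param V Number of repetitions.
#' @param seed Integer seed driving every random holdout choice; the same
#'   seed reproduces the result bit for bit.
#' @return Named list with elements \code{global} and \code{local}, each a
#'   \code{cv_result} (fields \code{per_fold_errors} — one test-error
#'   fraction per repetition — \code{mean}, \code{sd}, \code{fp_rate},
#'   \code{fn_rate}).
#' @export
loocv_annotation <- function(profiles, annotations = NULL,
                             model = "cghseg.k",
                             grid = default_grid(model), kmax = 20L,
                             V = 10L, seed = 1L) {
  if (V < 1L) stop("V must be >= 1")
  eval <- resolve_eval(profiles, annotations, model, grid, kmax)
  pids <- names(eval$per_profile)
  n_ann <- vapply(eval$per_profile, function(vm) nrow(vm$annotations),
                  integer(1))
  eligible <- pids[n_ann >= 2L]
  excluded <- pids[n_ann < 2L]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " profile(s) with < 2 annotations from the holdout: ",
            paste(excluded, collapse = ", "))
  }
  if (length(eligible) == 0L) {
    stop("no profile has >= 2 annotations; leave-one-out impossible")
  }
  nl <- length(eval$lambda)
  res <- with_seed(seed, {
    per_rep <- list(global = numeric(V), local = numeric(V))
    tot <- list(global = c(fp = 0, fn = 0, n = 0),
                local = c(fp = 0, fn = 0, n = 0))
    for (r in seq_len(V)) {
      held <- vapply(eligible, function(pid) {
        sample.int(nrow(eval$per_profile[[pid]]$annotations), 1L)
      }, integer(1))
      # global scope: one lambda trained on everything not held out
      train_rows <- lapply(pids, function(pid) {
        nr <- nrow(eval$per_profile[[pid]]$annotations)
        if (pid %in% eligible) setdiff(seq_len(nr), held[[pid]]) else {
          seq_len(nr)
        }
      })
      names(train_rows) <- pids
      gcurve <- curve_from_rows(eval, pids, train_rows, scope = "global")
      ghat <- train_global(gcurve)
      gi <- ghat$index
      gerr <- gfp <- gfn <- 0
      for (pid in eligible) {
        vm <- eval$per_profile[[pid]]
        gerr <- gerr + vm$err[held[[pid]], gi]
        gfp <- gfp + vm$fp[held[[pid]], gi]
        gfn <- gfn + vm$fn[held[[pid]], gi]
      }
      per_rep$global[r] <- gerr / length(eligible)
      tot$global <- tot$global + c(gfp, gfn, length(eligible))
      # local scope: per-profile lambda trained on the profile's remainder
      lerr <- lfp <- lfn <- 0
      for (pid in eligible) {
        vm <- eval$per_profile[[pid]]
        lcurve <- curve_from_rows(eval, pid,
                                  stats::setNames(train_rows[pid], pid),
                                  scope = "local")
        lhat <- train_local(lcurve)
        li <- lhat$index
        lerr <- lerr + vm$err[held[[pid]], li]
        lfp <- lfp + vm$fp[held[[pid]], li]
        lfn <- lfn + vm$fn[held[[pid]], li]
      }
      per_rep$local[r] <- lerr / length(eligible)
      tot$local <- tot$local + c(lfp, lfn, length(eligible))
    }
    list(per_rep = per_rep, tot = tot)
  })
  out <- lapply(c(global = "global", local = "local"), function(sc) {
    new_cv_result("loo_annotation", sc, res$per_rep[[sc]],
                  fp_rate = res$tot[[sc]][["fp"]] / res$tot[[sc]][["n"]],
                  fn_rate = res$tot[[sc]][["fn"]] / res$tot[[sc]][["n"]],
                  V = V, seed = seed, n_test = res$tot[[sc]][["n"]])
  })
  attr(out, "excluded_profiles") <- excluded
  out
}

#' Fold-based cross-validation with small training sets
#'
#' Estimates how well a global model trained on only \code{t} annotated
#' profiles generalizes to un-annotated profiles.  The \code{n} profiles
#' are partitioned (seeded shuffle) into \code{floor(n/t)} folds of
#' approximately \code{t} profiles; each fold in turn serves as the
#' \emph{training} set for a global smoothness parameter, which is then
#' scored on all annotations of all other folds.  Note the inversion with
#' respect to conventional cross-validation: the small part is the training
#' set.
#'
#' @inheritParams loocv_annotation
#' @param t Number of training profiles per fold, \code{1 <= t < n} with
#'   \code{floor(n/t) >= 2}.  When \code{t} does not divide \code{n}, the
#'   remainder profiles are distributed one per fold starting from the
#'   first.
#' @return A \code{cv_result} with one test-error fraction per fold, plus
#'   aggregate \code{mean}, \code{sd}, \code{fp_rate} and \code{fn_rate}.
#' @export
nt_fold_cv <- function(profiles, annotations = NULL, model = "cghseg.k",
                       grid = default_grid(model), kmax = 20L,
                       t = 10L, seed = 1L) {
  eval <- resolve_eval(profiles, annotations, model, grid, kmax)
  pids <- names(eval$per_profile)
  n <- length(pids)
  t <- as.integer(t)
  if (t < 1L || t >= n) stop("need 1 <= t < number of profiles (", n, ")")
  nf <- n %/% t
  if (nf < 2L) {
    stop("floor(n/t) = ", nf, " folds: no test set possible; decrease t")
  }
  sizes <- rep(t, nf)
  rem <- n - nf * t
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  res <- with_seed(seed, {
    shuffled <- sample(pids)
    fold_of <- rep(seq_len(nf), times = sizes)
    folds <- split(shuffled, fold_of)
    per_fold <- numeric(nf)
    tot_fp <- tot_fn <- tot_n <- 0
    for (f in seq_len(nf)) {
      train_ids <- folds[[f]]
      test_ids <- setdiff(pids, train_ids)
      gcurve <- curve_from_rows(eval, train_ids, scope = "global")
      ghat <- train_global(gcurve)
      gi <- ghat$index
      err <- fp <- fn <- nt <- 0
      for (pid in test_ids) {
        vm <- eval$per_profile[[pid]]
        if (nrow(vm$annotations) == 0L) next
        err <- err + sum(vm$err[, gi])
        fp <- fp + sum(vm$fp[, gi])
        fn <- fn + sum(vm$fn[, gi])
        nt <- nt + nrow(vm$annotations)
      }
      per_fold[f] <- err / nt
      tot_fp <- tot_fp + fp
      tot_fn <- tot_fn + fn
      tot_n <- tot_n + nt
    }
    list(per_fold = per_fold, fp = tot_fp, fn = tot_fn, n = tot_n)
  })
  new_cv_result("nt_fold", "global", res$per_fold,
                fp_rate = res$fp / res$n, fn_rate = res$fn / res$n,
                t = t, seed = seed, n_test = res$n)
}
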