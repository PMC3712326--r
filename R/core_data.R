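#' One chromosome of probe measurements
#'
#' A probe series holds the sorted base-pair positions and logratio values of
#' the copy number probes on a single chromosome of a single profile.  All
#' smoothing models in this package operate chromosome by chromosome on this
#' container.
#'
#' @param positions Numeric vector of 1-based base-pair coordinates, strictly
#'   increasing.  Half-integer coordinates are allowed (they arise from
#'   bedGraph interval midpoints).
#' @param logratio Numeric vector of finite logratio measurements, same
#'   length as \code{positions}.
#' @param chromosome Chromosome label (opaque string; no genome build is
#'   assumed).
#' @param length_bp Chromosome extent in base pairs, used only by the
#'   \code{flsa.norm} penalty normalization.  Defaults to the last probe
#'   position when unknown.
#' @return An object of class \code{probe_series}.
#' @export
probe_series <- function(positions, logratio, chromosome = "1",
                         length_bp = NULL) {
  positions <- as.numeric(positions)
  logratio <- as.numeric(logratio)
  m <- length(positions)
  if (m < 1L) stop("probe_series needs at least one probe")
  if (length(logratio) != m) {
    stop("positions and logratio lengths differ (", m, " vs ",
         length(logratio), ")")
  }
  if (anyNA(positions) || any(!is.finite(positions))) {
    stop("probe positions must be finite")
  }
  if (m > 1L && any(diff(positions) <= 0)) {
    stop("probe positions must be strictly increasing on chromosome ",
         chromosome)
  }
  if (any(!is.finite(logratio))) {
    stop("logratio values must be finite; drop or filter missing probes ",
         "before constructing a probe_series")
  }
  if (is.null(length_bp)) length_bp <- positions[m]
  if (length_bp < positions[m]) {
    stop("length_bp (", length_bp, ") smaller than last probe position (",
         positions[m], ")")
  }
  structure(
    list(chromosome = as.character(chromosome), positions = positions,
         logratio = logratio, length_bp = as.numeric(length_bp)),
    class = "probe_series")
}

#' A copy number profile
#'
#' A profile is a named collection of \code{\link{probe_series}}, one per
#' chromosome, for a single sample.
#'
#' @param profile_id Profile label.
#' @param series List of \code{probe_series}; names are taken from each
#'   series' chromosome label.
#' @return An object of class \code{cn_profile}.
#' @export
cn_profile <- function(profile_id, series) {
  if (inherits(series, "probe_series")) series <- list(series)
  if (length(series) < 1L) stop("a profile needs at least one chromosome")
  ok <- vapply(series, inherits, logical(1), "probe_series")
  if (!all(ok)) stop("all elements of series must be probe_series objects")
  chroms <- vapply(series, function(s) s$chromosome, character(1))
  if (anyDuplicated(chroms)) {
    stop("duplicated chromosome label in profile ", profile_id, ": ",
         chroms[duplicated(chroms)][1])
  }
  names(series) <- chroms
  structure(list(profile_id = as.character(profile_id), chromosomes = series),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  m <- vapply(x$chromosomes, function(s) length(s$positions), integer(1))
  cat("cn_profile", x$profile_id, ":", length(m), "chromosomes,",
      sum(m), "probes\n")
  invisible(x)
}

total_probes <- function(profile) {
  sum(vapply(profile$chromosomes, function(s) length(s$positions),
             integer(1)))
}

profiles_from_table <- function(df, source = "input") {
  need <- c("profile_id", "chromosome", "position", "logratio")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(source, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !is.finite(df$logratio)
  if (any(bad)) {
    message("dropping ", sum(bad), " probes with non-finite logratio from ",
            source)
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop(source, " contains no usable probes")
  key <- paste(df$profile_id, df$chromosome, df$position, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate probe in ", source, ": profile ", d$profile_id,
         " chromosome ", d$chromosome, " position ", d$position)
  }
  out <- list()
  for (pid in unique(as.character(df$profile_id))) {
    sub <- df[df$profile_id == pid, , drop = FALSE]
    series <- lapply(unique(as.character(sub$chromosome)), function(chr) {
      s <- sub[sub$chromosome == chr, , drop = FALSE]
      o <- order(s$position)
      probe_series(s$position[o], s$logratio[o], chromosome = chr)
    })
    out[[pid]] <- cn_profile(pid, series)
  }
  out
}

#' Read copy number profiles
#'
#' Reads per-probe logratio profiles from a CSV file (columns
#' \code{profile_id}, \code{chromosome}, \code{position}, \code{logratio})
#' or from a bedGraph file holding a single profile.  bedGraph intervals are
#' 0-based half-open per the standard; each probe is placed at the interval
#' midpoint.  Probes with non-finite logratio are dropped with a message.
#'
#' @param path Path to the input file.
#' @param format \code{"csv"} or \code{"bedgraph"}.
#' @param profile_id Profile label used for bedGraph input (one profile per
#'   file); defaults to the file name without extension.
#' @return A named list of \code{\link{cn_profile}} objects.
#' @export
read_profiles <- function(path, format = c("csv", "bedgraph"),
                          profile_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("profile file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty profile file: ", path)
    return(profiles_from_table(df, source = path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty bedGraph file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed bedGraph line in ", path, ": ",
         lines[which(nf < 4L)[1]])
  }
  df <- data.frame(
    profile_id = if (is.null(profile_id)) {
      sub("\\.[^.]*$", "", basename(path))
    } else profile_id,
    chromosome = vapply(fields, `[`, character(1), 1L),
    position = (as.numeric(vapply(fields, `[`, character(1), 2L)) +
                  as.numeric(vapply(fields, `[`, character(1), 3L))) / 2,
    logratio = as.numeric(vapply(fields, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  profiles_from_table(df, source = path)
}

#' Write profiles to CSV
#'
#' Inverse of \code{\link{read_profiles}} for the CSV format.
#'
#' @param profiles A \code{cn_profile} or list of them.
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles_to_table(profiles)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

profiles_to_table <- function(profiles) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(p$chromosomes, function(s) {
      data.frame(profile_id = p$profile_id, chromosome = s$chromosome,
                 position = s$positions, logratio = s$logratio,
                 stringsAsFactors = FALSE)
    }))
  }))
}

format_num_df <- function(df, digits = 12) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  df
}

canonical_labels <- c(`0breakpoints` = 0, `1breakpoint` = 1,
                      `>0breakpoints` = 2)

#' Construct breakpoint-region annotations
#'
#' An annotation is a closed base-pair interval on a chromosome of a
#' profile, together with an interval-valued expected breakpoint count
#' \eqn{[a_{lo}, a_{hi}]}.  The three named annotation labels map to
#' \code{0breakpoints} = [0,0], \code{1breakpoint} = [1,1] and
#' \code{>0breakpoints} = [1,Inf).
#'
#' @param profile_id,chromosome,start,end Vectors describing each region;
#'   regions are closed intervals in 1-based coordinates and a breakpoint on
#'   a bound counts as inside.
#' @param min_breakpoints,max_breakpoints Integer lower/upper expected
#'   breakpoint counts; \code{max_breakpoints} may be \code{Inf}.
#' @param annotation Optional character vector of named labels used instead
#'   of the explicit bounds.
#' @return A \code{data.frame} of class \code{annotation_df} with columns
#'   \code{profile_id}, \code{chromosome}, \code{start}, \code{end},
#'   \code{min_breakpoints}, \code{max_breakpoints}.
#' @export
annotated_regions <- function(profile_id, chromosome, start, end,
                              min_breakpoints = NULL, max_breakpoints = NULL,
                              annotation = NULL) {
  n <- length(start)
  if (!is.null(annotation)) {
    annotation <- as.character(annotation)
    bad <- !(annotation %in% names(canonical_labels))
    if (any(bad)) {
      stop("unknown annotation label: ", annotation[bad][1],
           " (expected one of ",
           paste(names(canonical_labels), collapse = ", "), ")")
    }
    min_breakpoints <- ifelse(annotation == "0breakpoints", 0, 1)
    max_breakpoints <- ifelse(annotation == "0breakpoints", 0,
                              ifelse(annotation == "1breakpoint", 1, Inf))
  }
  min_breakpoints <- as.numeric(min_breakpoints)
  max_breakpoints <- as.numeric(max_breakpoints)
  # blank / NA upper bound means unbounded
  max_breakpoints[is.na(max_breakpoints)] <- Inf
  if (anyNA(min_breakpoints)) stop("min_breakpoints must be given")
  if (any(min_breakpoints < 0)) stop("min_breakpoints must be >= 0")
  if (any(min_breakpoints > max_breakpoints)) {
    stop("annotation with min_breakpoints > max_breakpoints rejected")
  }
  if (any(start > end)) stop("annotation region with start > end rejected")
  df <- data.frame(profile_id = as.character(profile_id),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   min_breakpoints = min_breakpoints,
                   max_breakpoints = max_breakpoints,
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_df", "data.frame")
  df
}

#' Read breakpoint-region annotations from CSV
#'
#' The file must have columns \code{profile_id}, \code{chromosome},
#' \code{start}, \code{end} and either explicit \code{min_breakpoints} /
#' \code{max_breakpoints} columns (blank or \code{Inf} upper bound means
#' unbounded) or an \code{annotation} column of named labels.
#'
#' @param path CSV path.
#' @return An \code{annotation_df}; see \code{\link{annotated_regions}}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty annotation file: ", path)
  need <- c("profile_id", "chromosome", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if ("annotation" %in% names(df)) {
    annotated_regions(df$profile_id, df$chromosome, df$start, df$end,
                      annotation = df$annotation)
  } else {
    if (!"min_breakpoints" %in% names(df)) {
      stop(path, " needs either an annotation column or min/max_breakpoints")
    }
    mx <- if ("max_breakpoints" %in% names(df)) {
      suppressWarnings(as.numeric(df$max_breakpoints))
    } else NA_real_
    annotated_regions(df$profile_id, df$chromosome, df$start, df$end,
                      min_breakpoints = df$min_breakpoints,
                      max_breakpoints = mx)
  }
}

#' Write annotations to CSV
#' @param annotations An \code{annotation_df}.
#' @param path Output CSV path.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a smoothed fit as BED-like segment and breakpoint files
#'
#' Segments are maximal constant runs of the fitted signal; they are written
#' 0-based half-open per the BED convention, with the fitted segment mean in
#' the fourth column.  Breakpoint positions (inter-probe midpoints) are
#' written to a companion file.
#'
#' @param fit A \code{\link{smoothed_fit}} for one smoothness value.
#' @param profile The \code{cn_profile} the fit was computed from.
#' @param segments_path,breakpoints_path Output paths.
#' @export
write_segments <- function(fit, profile, segments_path, breakpoints_path) {
  seg_rows <- list()
  bp_rows <- list()
  for (chr in names(profile$chromosomes)) {
    s <- profile$chromosomes[[chr]]
    xhat <- fit$smoothed[[chr]]
    if (is.null(xhat) || length(xhat) != length(s$positions)) {
      stop("fit does not correspond to profile on chromosome ", chr)
    }
    bps <- fit$breakpoints[[chr]]
    # adjacent segments share the breakpoint coordinate in half-open output
    starts0 <- c(s$positions[1] - 1, bps)
    ends0 <- c(bps, s$positions[length(s$positions)])
    run_start <- c(1L, vapply(bps, function(b) {
      which(s$positions > b)[1]
    }, integer(1)))
    for (k in seq_along(run_start)) {
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chromosome = chr, start = starts0[k], end = ends0[k],
        mean = xhat[run_start[k]], stringsAsFactors = FALSE)
    }
    if (length(bps)) {
      bp_rows[[length(bp_rows) + 1L]] <- data.frame(
        chromosome = chr, position = bps, stringsAsFactors = FALSE)
    }
  }
  seg_df <- do.call(rbind, seg_rows)
  utils::write.table(format_num_df(seg_df), segments_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  bp_df <- if (length(bp_rows)) do.call(rbind, bp_rows) else {
    data.frame(chromosome = character(0), position = numeric(0))
  }
  utils::write.table(format_num_df(bp_df), breakpoints_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(list(segments = segments_path, breakpoints = breakpoints_path))
}

#' Read a breakpoints file written by \code{\link{write_segments}}
#' @param path Tab-separated file with chromosome and position columns.
#' @return Named list of numeric breakpoint position vectors, one per
#'   chromosome (empty list for an empty file).
#' @export
read_breakpoints <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chromosome", "position")),
    error = function(e) data.frame(chromosome = character(0),
                                   position = numeric(0)))
  split(df$position, df$chromosome)
}
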