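#' Cells-by-frames fluorescence trace container
#'
#' Bundles a cells x frames fluorescence matrix with its uniformly spaced
#' frame times and per-cell metadata (micropattern shape group, agonist
#' concentration, well, replicate). All cells share one frame grid.
#'
#' @param values Numeric matrix, one row per cell, one column per frame.
#' @param times Frame times in seconds; strictly increasing with uniform
#'   spacing. Defaults to `(0:(nframes-1)) * dt`.
#' @param metadata Data frame with one row per cell; a `cell_id` column is
#'   added when absent.
#' @param dt Sampling interval in seconds, used when `times` is missing.
#' @return An object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(values, times = NULL, metadata = NULL, dt = 30) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  nf <- ncol(values)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf)
    stop("'times' length must equal the number of frames", call. = FALSE)
  d <- diff(times)
  if (nf > 1 && (any(d <= 0) || diff(range(d)) > 1e-9 * max(d)))
    stop("'times' must be strictly increasing with uniform spacing",
         call. = FALSE)
  if (is.null(metadata))
    metadata <- data.frame(cell_id = sprintf("cell_%03d", seq_len(nrow(values))))
  if (nrow(metadata) != nrow(values))
    stop("'metadata' must have one row per cell", call. = FALSE)
  if (is.null(metadata$cell_id))
    metadata$cell_id <- sprintf("cell_%03d", seq_len(nrow(values)))
  structure(list(values = values, times = as.numeric(times),
                 metadata = metadata),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("trace_matrix: %d cells x %d frames, dt = %g s (t = %g..%g s)\n",
              nrow(x$values), ncol(x$values),
              if (ncol(x$values) > 1) diff(x$times[1:2]) else NA_real_,
              x$times[1], x$times[length(x$times)]))
  if (!is.null(x$metadata$shape_group))
    print(table(shape_group = x$metadata$shape_group))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Drop the first acquired frame
#'
#' The first image of each time-lapse is discarded before any analysis
#' (it predates stable acquisition); times are re-anchored so the first
#' retained frame sits at t = 0. A 61-frame acquisition at 30 s spacing
#' (30 min inclusive of t = 0) therefore yields the 60 analysed frames.
#'
#' @param tm A [trace_matrix()] with at least two frames.
#' @return A [trace_matrix()] with one fewer frame; metadata unchanged.
#' @export
drop_first_frame <- function(tm) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (ncol(tm$values) < 2)
    stop("cannot drop the first frame of a single-frame trace", call. = FALSE)
  values <- tm$values[, -1, drop = FALSE]
  times <- tm$times[-1] - tm$times[2]
  trace_matrix(values, times, tm$metadata)
}

#' Normalise traces to relative fluorescence change
#'
#' Converts each cell's trace to `(F - F0) / F0` where `F0` is the mean of
#' the stated baseline frames, the standard relative change for
#' fluorescent calcium indicators. Invariant to multiplying a whole trace
#' by a positive constant.
#'
#' @param tm A [trace_matrix()] of raw fluorescence.
#' @param baseline_frames 1-based frame indices of the pre-agonist
#'   baseline; default `1:8`.
#' @return A [trace_matrix()] of relative-change values on the same
#'   frame grid.
#' @export
normalize_dff <- function(tm, baseline_frames = 1:8) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (max(baseline_frames) > ncol(tm$values))
    stop("baseline frames exceed the trace length", call. = FALSE)
  f0 <- rowMeans(tm$values[, baseline_frames, drop = FALSE])
  if (any(f0 <= 0))
    stop(sprintf("non-positive baseline mean for %d cell(s); relative change is undefined",
                 sum(f0 <= 0)), call. = FALSE)
  trace_matrix(sweep(sweep(tm$values, 1, f0, "-"), 1, f0, "/"),
               tm$times, tm$metadata)
}

#' Split one trace into baseline and baseline-subtracted transient
#'
#' The baseline is the mean of frames 1..8 (the pre-agonist window); the
#' transient segment runs from frame 9 to the end with that mean
#' subtracted, so the model's time origin t = 0 is the transient onset.
#'
#' @param y Numeric fluorescence trace for one cell.
#' @param baseline_frames 1-based indices of the baseline frames.
#' @return List with `baseline_mean`, `transient` (numeric vector) and
#'   `start_index` (1-based index of the first transient frame).
#' @export
baseline_split <- function(y, baseline_frames = 1:8) {
  if (!is.numeric(y) || anyNA(y))
    stop("'y' must be numeric with no missing values", call. = FALSE)
  n_base <- max(baseline_frames)
  if (length(y) < n_base + 1L)
    stop(sprintf("trace needs at least %d frames for a %d-frame baseline plus transient",
                 n_base + 1L, n_base), call. = FALSE)
  m <- mean(y[baseline_frames])
  list(baseline_mean = m,
       transient = y[(n_base + 1L):length(y)] - m,
       start_index = n_base + 1L)
}

#' Windowed summary statistics of a normalised trace
#'
#' Computes the trapezoidal area under the curve in an early and a late
#' window split at `boundary` seconds (the boundary sample is shared by
#' both trapezoids, so the two areas sum to the full-window area), plus
#' the maximum and the final-frame value.
#'
#' @param dff Numeric normalised trace (relative change) for one cell.
#' @param times Frame times in seconds, same length as `dff`.
#' @param boundary Window split in seconds; must lie inside the time range.
#' @return List with `auc_early`, `auc_late` (relative-change x seconds),
#'   `max_dff` and `last_dff`.
#' @export
summary_stats <- function(dff, times, boundary = 750) {
  if (length(dff) != length(times))
    stop("'dff' and 'times' must have the same length", call. = FALSE)
  if (boundary <= times[1] || boundary >= times[length(times)])
    stop("'boundary' must lie strictly inside the time range", call. = FALSE)
  early <- times <= boundary
  late <- times >= boundary
  if (!any(times == boundary)) {
    # boundary between samples: include flanking points so the trapezoids
    # still tile the full window (interpolate the boundary value)
    yb <- stats::approx(times, dff, xout = boundary)$y
    t_early <- c(times[early], boundary); y_early <- c(dff[early], yb)
    t_late <- c(boundary, times[late]);   y_late <- c(yb, dff[late])
  } else {
    t_early <- times[early]; y_early <- dff[early]
    t_late <- times[late];   y_late <- dff[late]
  }
  list(auc_early = pracma::trapz(t_early, y_early),
       auc_late = pracma::trapz(t_late, y_late),
       max_dff = max(dff),
       last_dff = dff[length(dff)])
}

#' Summary statistics for every cell of a normalised trace matrix
#'
#' @param tm A [trace_matrix()] of normalised values (see [normalize_dff()]).
#' @param boundary Window split in seconds.
#' @return Data frame: cell metadata plus `auc_early`, `auc_late`,
#'   `max_dff`, `last_dff`.
#' @export
summarize_cohort <- function(tm, boundary = 750) {
  stopifnot(inherits(tm, "trace_matrix"))
  stats_list <- apply(tm$values, 1, summary_stats, times = tm$times,
                      boundary = boundary)
  cbind(tm$metadata,
        do.call(rbind, lapply(stats_list, as.data.frame)),
        row.names = NULL)
}

#' Read / write the delimited trace-matrix format
#'
#' Tab-separated text, one row per cell: metadata columns (`cell_id`,
#' `shape_group`, `concentration_uM`, `well`, `replicate` - whichever are
#' present) followed by frame columns named `f<seconds>`.
#'
#' @param tm A [trace_matrix()].
#' @param path File path.
#' @return `write_trace_matrix` returns `path` invisibly;
#'   `read_trace_matrix` returns a [trace_matrix()].
#' @export
write_trace_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  vals <- as.data.frame(tm$values)
  names(vals) <- sprintf("f%g", tm$times)
  utils::write.table(cbind(tm$metadata, vals), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_matrix
#' @export
read_trace_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  frame_cols <- grep("^f[0-9.]+$", names(df))
  if (length(frame_cols) < 1)
    stop("no frame columns (named f<seconds>) found in ", path, call. = FALSE)
  times <- as.numeric(sub("^f", "", names(df)[frame_cols]))
  trace_matrix(as.matrix(df[, frame_cols, drop = FALSE]),
               times = times,
               metadata = df[, -frame_cols, drop = FALSE])
}
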