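#' Component time-series container
#'
#' Bundles one subject-session's T x C matrix of ICA component activations
#' with its repetition time and nuisance information. All preprocessing and
#' connectivity estimators accept and return this container (or a bare
#' matrix, in which case defaults are filled in).
#'
#' @param values numeric T x C matrix, rows are timepoints (TRs).
#' @param tr_seconds repetition time in seconds (default 2.2).
#' @param subject_id subject identifier.
#' @param session session label.
#' @param motion optional T x 6 matrix of realignment parameters.
#' @param mean_fd optional mean framewise displacement (mm).
#' @return an object of class `cts`.
#' @export
component_ts <- function(values, tr_seconds = 2.2, subject_id = "s01",
                         session = "task", motion = NULL, mean_fd = NA_real_) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("component time-series contains missing values")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(values))
      stopf("motion regressors have %d rows, time-series has %d",
            nrow(motion), nrow(values))
  }
  structure(list(values = values, tr_seconds = tr_seconds,
                 subject_id = subject_id, session = session,
                 motion = motion, mean_fd = mean_fd),
            class = "cts")
}

as_cts <- function(x, ...) {
  if (inherits(x, "cts")) x else component_ts(x, ...)
}

#' @export
print.cts <- function(x, ...) {
  cat(sprintf("<cts> subject %s, session %s: %d TRs x %d components (TR = %gs)\n",
              x$subject_id, x$session, nrow(x$values), ncol(x$values),
              x$tr_seconds))
  invisible(x)
}

# apply a column-wise matrix transform while preserving metadata
cts_map <- function(ts, f) {
  ts <- as_cts(ts)
  v <- f(ts$values)
  dimnames(v) <- dimnames(ts$values)
  ts$values <- v
  ts
}
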