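#' Read a control schedule from CSV
#'
#' Two dialects are supported. `proportional`: columns `time`, `u_f`, `u_e`
#' with strictly increasing times and excitations in `[0, 1]`; played back
#' with zero-order hold. `bang_bang`: columns `t_on`, `t_off`, `side`
#' defining on-intervals for one side each. Violations are reported with
#' their row number.
#'
#' @param path CSV file path.
#' @param kind `"proportional"` or `"bang_bang"`.
#' @return An object of class `control_schedule`: list with `kind` and
#'   `data`.
#' @export
read_control_schedule <- function(path,
                                  kind = c("proportional", "bang_bang")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop_validation(sprintf("no such schedule file: %s", path))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (kind == "proportional") {
    if (!all(c("time", "u_f", "u_e") %in% names(d))) {
      stop_validation("proportional schedule needs columns time,u_f,u_e")
    }
    if (nrow(d) == 0) stop_validation("schedule has no rows")
    bad_t <- which(diff(d$time) <= 0)
    if (length(bad_t) > 0) {
      stop_validation(sprintf(
        "times must be strictly increasing (row %d)", bad_t[1] + 1))
    }
    for (col in c("u_f", "u_e")) {
      bad <- which(!is.finite(d[[col]]) | d[[col]] < 0 | d[[col]] > 1)
      if (length(bad) > 0) {
        stop_validation(sprintf(
          "%s outside [0, 1] (row %d)", col, bad[1]))
      }
    }
  } else {
    bad <- tryCatch({
      .validate_bang_bang_schedule(d)
      NULL
    }, elbowsim_validation_error = function(e) e)
    if (!is.null(bad)) stop_validation(conditionMessage(bad))
  }
  structure(list(kind = kind, data = d), class = "control_schedule")
}

#' Expand a schedule to a sampled excitation stream
#'
#' Proportional schedules are expanded to the `dt` grid with zero-order
#' hold (each grid sample takes the most recent scheduled value, zero
#' before the first row); bang-bang schedules go through
#' [bang_bang_stream()].
#'
#' @param schedule a [read_control_schedule()] object.
#' @param dt sample period (s).
#' @param duration stream duration (s).
#' @param level bang-bang excitation level; `NULL` takes the schedule
#'   file's own `level` column if present, else 1.
#' @return A `control_stream` data frame with `round(duration/dt) + 1`
#'   rows.
#' @export
schedule_to_stream <- function(schedule, dt = 1 / 150, duration,
                               level = NULL) {
  if (schedule$kind == "bang_bang") {
    if (is.null(level)) {
      level <- if ("level" %in% names(schedule$data)) {
        schedule$data$level[1]
      } else {
        1
      }
    }
    return(bang_bang_stream(schedule$data, level = level, dt = dt,
                            duration = duration))
  }
  d <- schedule$data
  n <- round(duration / dt) + 1
  time <- (seq_len(n) - 1) * dt
  idx <- findInterval(time, d$time)
  u_f <- ifelse(idx == 0, 0, d$u_f[pmax(idx, 1)])
  u_e <- ifelse(idx == 0, 0, d$u_e[pmax(idx, 1)])
  structure(data.frame(time = time, u_f = u_f, u_e = u_e),
            class = c("control_stream", "data.frame"))
}

#' Write a trial record to CSV
#'
#' One row per simulation step with every logged variable; plain RFC-4180
#' CSV, no row names.
#'
#' @param record a [run_trial()] record.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_record <- function(record, path) {
  utils::write.csv(record$series, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial record series back from CSV
#'
#' @param path CSV written by [write_trial_record()].
#' @return The series data frame.
#' @export
read_trial_record <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("no such trial file: %s", path))
  }
  utils::read.csv(path)
}

#' Write a session to a directory
#'
#' Emits `trial_<k>.csv` per trial plus `summary.csv` with the per-trial
#' outcome table.
#'
#' @param records list of [run_trial()] records.
#' @param dir output directory (created if missing).
#' @param tp [task_params()] used for the summary's terminal error.
#' @return The summary data frame, invisibly.
#' @export
write_session <- function(records, dir, tp = task_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(records)) {
    write_trial_record(records[[k]], file.path(dir,
                                               sprintf("trial_%d.csv", k)))
  }
  summary <- summarize_session(records, tp)
  utils::write.csv(summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(summary)
}
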