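#' Generate demonstration fixtures
#'
#' Writes a self-contained set of demonstration inputs into `dir`:
#' \itemize{
#'   \item `config.yaml` -- the default configuration;
#'   \item `bang_bang_schedule.csv` -- a flex-then-brake keyboard schedule
#'     tuned by [tune_bang_bang_schedule()] to complete the task;
#'   \item `proportional_schedule.csv` -- the excitation stream recorded
#'     from a successful run of the co-activating proportional controller;
#'   \item `emg_envelope_flexor.csv` / `emg_envelope_extensor.csv` --
#'     quantized linear envelopes (columns `time,volts`) synthesized from a
#'     smooth activation profile through the full EMG chain;
#'   \item `calibration.csv` -- rest/MVC envelope levels measured from
#'     dedicated synthetic rest and maximal-contraction recordings.
#' }
#' Everything is deterministic given the seed.
#'
#' @param dir output directory (created if missing).
#' @param model a [run_config()]; defaults to [default_run_config()].
#' @param seed integer seed for the EMG synthesis.
#' @return Invisibly, a list with the schedules, calibration and file
#'   paths.
#' @export
make_fixtures <- function(dir, model = default_run_config(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  save_config(model, file.path(dir, "config.yaml"))

  sched <- tune_bang_bang_schedule(model)
  sched_out <- cbind(sched, level = attr(sched, "level"))
  utils::write.csv(sched_out, file.path(dir, "bang_bang_schedule.csv"),
                   row.names = FALSE)

  prop_rec <- run_trial(controller_proportional(model$task), model)
  prop <- prop_rec$series[, c("time", "u_f", "u_e")]
  # stamp each change half a step early: zero-order-hold replay then takes
  # the recorded value at the recorded sample, immune to text round-off
  prop$time <- pmax(prop$time - model$sim$dt / 2, 0)
  utils::write.csv(prop, file.path(dir, "proportional_schedule.csv"),
                   row.names = FALSE)

  # EMG: smooth flexion bursts on the flexor, late stabilizing burst on
  # the extensor, pushed through sensor -> envelope -> ADC
  p <- model$emg
  p$noise_seed <- seed
  dur <- 10
  t <- seq(0, dur, by = 1 / p$fs_raw)
  act_f <- demo_activation_trace(t)
  act_e <- pmin(pmax(0.4 * exp(-((t - 4.2) / 1.0)^2), 0), 1)
  env_of <- function(act, sub_seed) {
    pp <- p
    pp$noise_seed <- seed + sub_seed
    adc_quantize(linear_envelope(synthesize_raw_emg(act, pp), pp), pp)
  }
  env_f <- env_of(act_f, 1L)
  env_e <- env_of(act_e, 2L)
  utils::write.csv(data.frame(time = t, volts = env_f),
                   file.path(dir, "emg_envelope_flexor.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = t, volts = env_e),
                   file.path(dir, "emg_envelope_extensor.csv"),
                   row.names = FALSE)

  cal <- measure_calibration(p, seed = seed)
  utils::write.csv(
    data.frame(baseline_f = cal$baseline_f, baseline_e = cal$baseline_e,
               mvc_f = cal$mvc_f, mvc_e = cal$mvc_e),
    file.path(dir, "calibration.csv"), row.names = FALSE)

  invisible(list(dir = dir, bang_bang = sched, proportional = prop,
                 calibration = cal))
}

#' Smooth demonstration activation profile
#'
#' Two Gaussian effort bursts over a 10 s horizon, emulating the slow
#' graded contractions of a voluntary reaching session. Used as the
#' canonical input of the synthetic EMG chain demonstrations.
#'
#' @param t time points (s); vectorized.
#' @return Activation values in `[0, 1]`.
#' @export
demo_activation_trace <- function(t) {
  pmin(pmax(0.6 * exp(-((t - 3) / 1.2)^2) +
              0.3 * exp(-((t - 7) / 1.5)^2), 0), 1)
}

#' Measure an EMG calibration from synthetic rest and MVC recordings
#'
#' Emulates the usual normalization session: a rest recording (zero
#' activation) fixes the baseline and a sustained maximal contraction
#' fixes the MVC level, both read from the steady tail of the quantized
#' envelope.
#'
#' @param p an [emg_chain_params()].
#' @param seed integer seed for the recordings.
#' @param duration recording length per condition (s).
#' @return An [emg_calibration()].
#' @export
measure_calibration <- function(p, seed = 1L, duration = 3) {
  n <- round(duration * p$fs_raw) + 1
  tail_idx <- seq(floor(n / 2), n)
  level <- function(act_level, sub_seed) {
    pp <- p
    pp$noise_seed <- as.integer(seed) + sub_seed
    env <- adc_quantize(
      linear_envelope(synthesize_raw_emg(rep(act_level, n), pp), pp), pp)
    mean(env[tail_idx])
  }
  emg_calibration(
    baseline_f = level(0, 11L), baseline_e = level(0, 12L),
    mvc_f = level(1, 13L), mvc_e = level(1, 14L)
  )
}

#' Read a calibration CSV
#'
#' @param path CSV with columns `baseline_f`, `baseline_e`, `mvc_f`,
#'   `mvc_e` (one row).
#' @return An [emg_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("no such calibration file: %s", path))
  }
  d <- utils::read.csv(path)
  emg_calibration(d$baseline_f[1], d$baseline_e[1], d$mvc_f[1], d$mvc_e[1])
}
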