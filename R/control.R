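#' One control sample
#'
#' Flexor and extensor excitations at one timestep, both in `[0, 1]`.
#'
#' @param u_f flexor excitation.
#' @param u_e extensor excitation.
#' @return An object of class `control_sample`.
#' @export
control_sample <- function(u_f = 0, u_e = 0) {
  check_num(u_f, "u_f", 0, 1, len = 1)
  check_num(u_e, "u_e", 0, 1, len = 1)
  structure(list(u_f = u_f, u_e = u_e), class = "control_sample")
}

.validate_bang_bang_schedule <- function(schedule) {
  if (!is.data.frame(schedule) ||
      !all(c("t_on", "t_off", "side") %in% names(schedule))) {
    stop_validation("schedule needs columns t_on, t_off, side")
  }
  if (nrow(schedule) == 0) return(schedule)
  if (!all(schedule$side %in% c("flexor", "extensor"))) {
    stop_validation("schedule side must be 'flexor' or 'extensor'")
  }
  check_num(schedule$t_on, "t_on", 0)
  check_num(schedule$t_off, "t_off", 0)
  if (any(schedule$t_off <= schedule$t_on)) {
    stop_validation("each interval needs t_on < t_off")
  }
  for (side in c("flexor", "extensor")) {
    iv <- schedule[schedule$side == side, , drop = FALSE]
    if (nrow(iv) > 1) {
      iv <- iv[order(iv$t_on), ]
      if (any(iv$t_on[-1] < iv$t_off[-nrow(iv)])) {
        stop_validation(sprintf("overlapping %s intervals", side))
      }
    }
  }
  schedule
}

#' Bang-bang excitation stream
#'
#' Keyboard/mouse-style on-off control: inside each scheduled interval the
#' named side is excited at the fixed `level`, zero outside. At most one
#' side is active per sample; when intervals on opposite sides collide, the
#' later-starting interval wins.
#'
#' @param schedule data frame with columns `t_on`, `t_off` (s) and `side`
#'   (`"flexor"`/`"extensor"`); same-side intervals must not overlap.
#' @param level fixed excitation level in `(0, 1]`.
#' @param dt sample period (s).
#' @param duration stream duration (s); the stream has
#'   `round(duration/dt) + 1` samples.
#' @return A data frame of class `control_stream` with columns `time`,
#'   `u_f`, `u_e`.
#' @export
bang_bang_stream <- function(schedule, level = 1, dt = 1 / 150, duration) {
  check_num(level, "level", 0, 1, closed_lower = FALSE, len = 1)
  check_num(dt, "dt", 0, closed_lower = FALSE, len = 1)
  check_num(duration, "duration", 0, len = 1)
  .validate_bang_bang_schedule(schedule)
  n <- round(duration / dt) + 1
  time <- (seq_len(n) - 1) * dt
  u_f <- numeric(n)
  u_e <- numeric(n)
  if (nrow(schedule) > 0) {
    for (i in order(schedule$t_on)) {
      on <- time >= schedule$t_on[i] & time < schedule$t_off[i]
      if (schedule$side[i] == "flexor") {
        u_f[on] <- level
        u_e[on] <- 0
      } else {
        u_e[on] <- level
        u_f[on] <- 0
      }
    }
  }
  structure(data.frame(time = time, u_f = u_f, u_e = u_e),
            class = c("control_stream", "data.frame"))
}

#' Synthetic EMG chain parameters
#'
#' Settings of the emulated sensor-to-controller chain: raw sampling rate,
#' linear-envelope low-pass cutoff, amplifier gain, ADC resolution and full
#' scale, and the noise seed of the raw-EMG generator.
#'
#' @param fs_raw raw EMG sample rate (Hz, >= 500).
#' @param f_env envelope low-pass cutoff (Hz), below Nyquist.
#' @param gain amplifier gain (V per unit activation).
#' @param adc_bits quantizer resolution (bits).
#' @param v_ref ADC full-scale voltage (V).
#' @param noise_seed random seed for the raw-EMG generator.
#' @return An object of class `emg_chain_params`.
#' @export
emg_chain_params <- function(fs_raw = 1000, f_env = 2, gain = 5,
                             adc_bits = 10, v_ref = 5, noise_seed = 1) {
  check_num(fs_raw, "fs_raw", 500, len = 1)
  check_num(f_env, "f_env", 0, fs_raw / 2, closed_lower = FALSE,
            closed_upper = FALSE, len = 1)
  check_num(gain, "gain", 0, closed_lower = FALSE, len = 1)
  check_num(adc_bits, "adc_bits", 1, 32, len = 1)
  check_num(v_ref, "v_ref", 0, closed_lower = FALSE, len = 1)
  check_num(noise_seed, "noise_seed", len = 1)
  structure(
    list(fs_raw = fs_raw, f_env = f_env, gain = gain,
         adc_bits = as.integer(adc_bits), v_ref = v_ref,
         noise_seed = as.integer(noise_seed)),
    class = "emg_chain_params"
  )
}

#' EMG normalization calibration
#'
#' Resting and maximal-voluntary-contraction (MVC) envelope levels per
#' channel, used to map envelopes linearly into excitations in `[0, 1]`.
#'
#' @param baseline_f,baseline_e resting envelope levels (V).
#' @param mvc_f,mvc_e maximal envelope levels (V); must exceed the baseline.
#' @return An object of class `emg_calibration`.
#' @export
emg_calibration <- function(baseline_f = 0, baseline_e = 0, mvc_f, mvc_e) {
  check_num(baseline_f, "baseline_f", 0, len = 1)
  check_num(baseline_e, "baseline_e", 0, len = 1)
  check_num(mvc_f, "mvc_f", 0, closed_lower = FALSE, len = 1)
  check_num(mvc_e, "mvc_e", 0, closed_lower = FALSE, len = 1)
  if (mvc_f <= baseline_f || mvc_e <= baseline_e) {
    stop_config("MVC level must exceed the baseline on both channels")
  }
  structure(
    list(baseline_f = baseline_f, baseline_e = baseline_e,
         mvc_f = mvc_f, mvc_e = mvc_e),
    class = "emg_calibration"
  )
}

# run expr with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthesize a raw surface-EMG voltage trace
#'
#' Raw EMG is modeled as zero-mean Gaussian noise whose instantaneous
#' amplitude is modulated by the activation trace and scaled by the
#' amplifier gain: `raw[i] = gain * act[i] * z[i]`, `z ~ N(0, 1)`. The
#' generator is seeded from `p$noise_seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param activation_trace activation samples in `[0, 1]` at `fs_raw`.
#' @param p an [emg_chain_params()].
#' @return Voltage trace, same length as the input.
#' @export
synthesize_raw_emg <- function(activation_trace, p) {
  check_num(activation_trace, "activation_trace", 0, 1)
  .with_seed(p$noise_seed, {
    p$gain * activation_trace * stats::rnorm(length(activation_trace))
  })
}

#' Linear envelope of a raw EMG trace
#'
#' Full-wave rectification followed by a first-order low-pass at `f_env`
#' (exact discretization of the RC integrator: DC gain 1, pole at
#' `exp(-2 pi f_env / fs_raw)`), emulating an integration amplifier.
#'
#' @param raw raw voltage trace.
#' @param p an [emg_chain_params()].
#' @return Non-negative envelope trace, same length as the input.
#' @export
linear_envelope <- function(raw, p) {
  check_num(raw, "raw")
  rect <- abs(raw)
  pole <- exp(-2 * pi * p$f_env / p$fs_raw)
  as.numeric(stats::filter((1 - pole) * rect, pole, method = "recursive"))
}

#' Quantize a voltage trace as an n-bit ADC would
#'
#' Clips to `[0, v_ref]` and rounds to the nearest of `2^adc_bits` uniform
#' levels (`v_ref` maps to the top code, 1023 for 10 bits). The output is
#' returned on the voltage scale, so the operation is idempotent.
#'
#' @param trace voltage trace.
#' @param p an [emg_chain_params()].
#' @return Quantized voltage trace.
#' @export
adc_quantize <- function(trace, p) {
  check_num(trace, "trace")
  levels <- 2^p$adc_bits - 1
  counts <- round(pmin(pmax(trace, 0), p$v_ref) / p$v_ref * levels)
  counts * p$v_ref / levels
}

#' Normalize quantized envelopes into an excitation stream
#'
#' Per channel, `u = clip((env - baseline) / (mvc - baseline), 0, 1)`,
#' resampled from the raw rate to the simulation rate by averaging all raw
#' samples falling inside each output interval. Both channels may be
#' nonzero at once, so co-activation of the flexor and extensor survives
#' the mapping.
#'
#' @param env_f,env_e quantized envelope traces (V) sampled at `p$fs_raw`,
#'   equal length.
#' @param cal an [emg_calibration()].
#' @param p an [emg_chain_params()].
#' @param dt_out output sample period (s), e.g. the simulation step.
#' @return A `control_stream` data frame with columns `time`, `u_f`, `u_e`.
#' @export
emg_to_excitation <- function(env_f, env_e, cal, p, dt_out = 1 / 150) {
  check_num(env_f, "env_f")
  check_num(env_e, "env_e")
  check_num(dt_out, "dt_out", 0, closed_lower = FALSE, len = 1)
  if (length(env_f) != length(env_e)) {
    stop_validation("envelope traces must have equal length")
  }
  if (cal$mvc_f <= cal$baseline_f || cal$mvc_e <= cal$baseline_e) {
    stop_config("MVC level must exceed the baseline on both channels")
  }
  norm <- function(env, base, mvc) pmin(pmax((env - base) / (mvc - base), 0), 1)
  u_f_raw <- norm(env_f, cal$baseline_f, cal$mvc_f)
  u_e_raw <- norm(env_e, cal$baseline_e, cal$mvc_e)
  t_raw <- (seq_along(env_f) - 1) / p$fs_raw
  duration <- t_raw[length(t_raw)]
  n_out <- round(duration / dt_out) + 1
  bin <- pmin(floor(t_raw / dt_out), n_out - 1) + 1
  avg <- function(u) {
    s <- tapply(u, bin, mean)
    out <- rep(NA_real_, n_out)
    out[as.integer(names(s))] <- s
    # carry the last seen value across any empty trailing bins
    for (k in seq_len(n_out)) if (is.na(out[k])) out[k] <- out[max(k - 1, 1)]
    out
  }
  structure(
    data.frame(time = (seq_len(n_out) - 1) * dt_out,
               u_f = avg(u_f_raw), u_e = avg(u_e_raw)),
    class = c("control_stream", "data.frame")
  )
}
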