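# memoized fixtures shared across test files: the default model is solved
# once and the bang-bang tuner (the expensive closed-loop calibration) runs
# at most once per test session
.cache <- new.env(parent = emptyenv())

default_model <- function(mode = "muscle") {
  key <- paste0("model_", mode)
  if (is.null(.cache[[key]])) .cache[[key]] <- default_run_config(mode)
  .cache[[key]]
}

tuned_schedule <- function() {
  if (is.null(.cache$sched)) {
    .cache$sched <- tune_bang_bang_schedule(default_model())
  }
  .cache$sched
}

tuned_bang_bang_trial <- function() {
  if (is.null(.cache$bb_trial)) {
    s <- tuned_schedule()
    .cache$bb_trial <- run_trial(
      controller_bang_bang(s, attr(s, "level")), default_model())
  }
  .cache$bb_trial
}

proportional_trial <- function() {
  if (is.null(.cache$prop_trial)) {
    m <- default_model()
    .cache$prop_trial <- run_trial(controller_proportional(m$task), m)
  }
  .cache$prop_trial
}

# small reference muscle used by closed-form unit tests
ref_muscle <- function() muscle_params()

ref_geometry <- function(side = "flexor") {
  path_geometry(0.15, 0.03, side)
}
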