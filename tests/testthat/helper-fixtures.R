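# Shared fixtures, generated once per test run and memoised. The short
# trial keeps the protocol's structure (pre / perturbed-with-catches /
# post) at reduced block lengths so whole-pipeline properties stay cheap.

.fx <- new.env(parent = emptyenv())

# block durations (minutes) giving pre/perturb/post = 15/20/7 strides at
# the default cadence (stride period 1.1 s)
short_blocks <- function(pre = 15, perturb = 20, post = 7, T = 1.1) {
  c(pre = pre * T / 60, perturb = perturb * T / 60, post = post * T / 60)
}

fixture_trial <- function() {
  if (is.null(.fx$trial))
    .fx$trial <- generate_trial(gait_config(noise_sd = 0),
                                perturbation_spec("none"),
                                blocks = short_blocks(), seed = 7)
  .fx$trial
}

fixture_result <- function() {
  if (is.null(.fx$result)) .fx$result <- process_trial(fixture_trial())
  .fx$result
}

fixture_noisy_trial <- function() {
  if (is.null(.fx$noisy))
    .fx$noisy <- generate_trial(gait_config(noise_sd = 0.001),
                                perturbation_spec("none"),
                                blocks = short_blocks(), seed = 11)
  .fx$noisy
}

fixture_noisy_result <- function() {
  if (is.null(.fx$noisy_res)) .fx$noisy_res <- process_trial(fixture_noisy_trial())
  .fx$noisy_res
}

# event-frame errors of detected vs ground-truth events, per event type
event_errors <- function(result, trial) {
  ev <- result$events
  truth <- trial$truth$events
  m <- match(ev$truth_stride, truth$stride)
  ok <- !is.na(m)
  lapply(c(rhs = "rhs", lto = "lto", lhs = "lhs", rto = "rto"),
         function(col) ev[[col]][ok] - truth[[col]][m[ok]])
}
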