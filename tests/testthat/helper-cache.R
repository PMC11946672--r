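# Shared simulation artifacts, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

# 100 noisy trials of the calibration grid at default settings: the
# fixation table feeds the precision-recovery and pupil-direction checks.
grid_run_100 <- function() {
  if (is.null(.sim_cache$grid100)) {
    cfg <- run_config(n_trials = 100, seed = 77)
    .sim_cache$grid100 <- run_accuracy_precision(cfg)
  }
  .sim_cache$grid100
}
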