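# Shared fixture builders: everything is generated in code at test time.

# A corrected trace wrapping a given z (or dff) series on a uniform grid.
make_trace <- function(z = NULL, dff = z, fs = 100, t0 = 0) {
  n <- length(dff)
  structure(list(time = t0 + (seq_len(n) - 1) / fs, dff = dff, z = z,
                 fit_slope = 1, fit_intercept = 0, sampling_rate = fs,
                 events = data.frame(label = character(), time_s = numeric()),
                 epoch_window = NULL),
            class = "corrected_trace")
}

# Unit-peak difference-of-exponentials kernel (independent reimplementation
# for constructing expected traces in tests).
test_kernel <- function(t, rise = 0.1, decay = 0.8) {
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  pk <- exp(-tpk / decay) - exp(-tpk / rise)
  ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / pk, 0)
}

# A kinematics trace computed from scripted positions.
make_kin <- function(x, y = rep(10, length(x)), fs = 30, smooth = 0,
                     geometry = arena_geometry()) {
  tr <- tracking_trace((seq_along(x) - 1) / fs, x, y, geometry)
  compute_kinematics(tr, smooth_window = smooth)
}

# Scaled-down behavior template for tests that need many sessions: short
# exploration/post spans; all analysis windows still fully covered.
fast_behav <- function(...) {
  behavior_sim_params(exploration_min = 20, trigger_delay = c(5, 9),
                      post_duration = 25, ...)
}

fast_config <- function() loom_config(behavior = list(exploration_min = 20))
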