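# shared fixtures, built once per test run and cached in this environment
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# small geometry whose stimulus-pixel grid is exactly the 15 x 15 crop
tiny_geometry <- function() stim_geometry(60L, 60L, 4L, 7.5, 85)

# desk geometry used by the synthetic experiments
desk_geometry <- function() stim_geometry(120L, 160L, 4L, 7.5, 85)

# a quick fit configuration with reduced epoch budgets for tests
quick_cfg <- function(ensemble, seed, max_epochs = 60L,
                      early_stop = 15L, sched = 8L, ...) {
  fit_config(ensemble, max_epochs = max_epochs,
             early_stop_patience = early_stop, scheduler_patience = sched,
             seed = seed, ...)
}

# one midget-like group specification
midget_group <- function(n, adapt_scale = 1.3) {
  list(list(type = "midget_like", n = as.integer(n), polarity = "OFF",
            center_sigma = c(1.2, 1.8), center_scale_nm = adapt_scale,
            surround_wn = c(0.05, 0.12), surround_nm = c(0.35, 0.55)))
}

# 5 minutes of desk-scale white noise, shared across recovery tests
fixture_wn5min <- function() {
  fixture("wn5min", function()
    generate_white_noise(desk_geometry(), n_trials = 5L, train_seconds = 60,
                         test_seconds = 5, seed = 7101))
}

# a movie surrogate on a 60 x 60 spectral grid for spectrum tests
fixture_nm_spectral <- function() {
  fixture("nm_spectral", function()
    generate_natural_surrogate(stim_geometry(240L, 240L, 4L), n_trials = 2L,
                               train_seconds = 4, test_seconds = 1,
                               seed = 7301))
}

# a DoG-rendered spatiotemporal RF with a known surround, for RF tests
make_test_dog <- function(sig = 1.5, surround = 0.35, polarity = -1,
                          alpha = 10, beta = -0.5) {
  dog_ln_params(
    polarity = polarity, mean = c(8, 8),
    amp1 = polarity * 1, amp2 = polarity * surround,
    cov1 = diag(2) * sig^2, cov2 = diag(2) * (2.2 * sig)^2,
    t1 = temporal_kernel_test(3.5), t2 = temporal_kernel_test(6, 0.2),
    alpha = alpha, beta = beta, crop_center = c(8L, 8L)
  )
}

# biphasic kernel mirroring the generator's parameterization
temporal_kernel_test <- function(peak, trough_gain = 0.5) {
  lag <- 0:29
  k <- (lag / peak)^2 * exp(-lag / peak) -
    trough_gain * (lag / 8)^2 * exp(-lag / 8)
  k / sqrt(sum(k^2))
}
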