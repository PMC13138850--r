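#' Generate a spatiotemporal white-noise stimulus
#'
#' Draws independent contrast values per stimulus pixel and frame (binary
#' +/-contrast by default, optionally Gaussian), arranged into trials of
#' non-repeating (training) frames followed by a repeating (test) segment
#' whose content is identical across trials.
#'
#' @param geometry A [stim_geometry()]; screen dimensions must be divisible
#'   by `stim_pixel_factor`.
#' @param n_trials Number of trials.
#' @param train_seconds,test_seconds Per-trial durations of the non-repeating
#'   and repeating segments, in seconds.
#' @param contrast Contrast amplitude; binary pixels are +/- `contrast`,
#'   Gaussian pixels have standard deviation `contrast`.
#' @param distribution Marginal distribution of pixel values.
#' @param seed Integer seed; identical seeds give identical stimuli.
#' @return An `rgc_stimulus` with `ensemble = "white_noise"`.
#' @examples
#' g <- stim_geometry(40, 40, 4)
#' s <- generate_white_noise(g, n_trials = 2, train_seconds = 1,
#'                           test_seconds = 0.5, seed = 1)
#' @export
generate_white_noise <- function(geometry, n_trials = 6L, train_seconds = 20,
                                 test_seconds = 5, contrast = 1,
                                 distribution = c("binary", "gaussian"),
                                 seed = 1L) {
  distribution <- match.arg(distribution)
  if (contrast <= 0) stop("contrast must be > 0")
  d <- stim_grid_dims(geometry, require_divisible = TRUE)
  h <- unname(d["h"]); w <- unname(d["w"])
  n_train <- round(train_seconds * geometry$frame_rate)
  n_test <- round(test_seconds * geometry$frame_rate)
  draw <- function(n) {
    v <- if (distribution == "binary")
      sample(c(-contrast, contrast), n * h * w, replace = TRUE)
    else rnorm(n * h * w, sd = contrast)
    array(v, c(n, h, w))
  }
  set.seed(seed)
  test_block <- draw(n_test)
  train_blocks <- lapply(seq_len(n_trials), function(k) draw(n_train))
  assemble_trials(train_blocks, test_block, geometry, "white_noise")
}

# one latent pink-noise field: real image whose power spectrum falls as 1/f^2
# (amplitude ~ 1/f), unit pixel variance before scaling by `contrast`
pink_field <- function(nr, nc, contrast) {
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  r <- sqrt(outer(fr^2, rep(1, nc)) + outer(rep(1, nr), fc^2))
  amp <- ifelse(r > 0, 1 / r, 0)
  wn <- matrix(rnorm(nr * nc), nr, nc)
  field <- Re(fft(fft(wn) * amp, inverse = TRUE)) / (nr * nc)
  # Var(field) = sum(amp^2) / N for unit-variance white input
  sd_theory <- sqrt(sum(amp^2) / (nr * nc))
  field * contrast / sd_theory
}

#' Generate a naturalistic-movie surrogate stimulus
#'
#' Produces frames with a 1/f^2 spatial power spectrum viewed through a
#' jittered window over a larger latent pink-noise image: successive frames
#' are shifted views following a seeded random-walk gaze path (step standard
#' deviation `jitter_sd` pixels, rounded to integer shifts, periodic
#' boundary), while the latent content itself evolves as a stationary AR(1)
#' process with per-frame correlation `temporal_corr`.  Trial structure
#' matches [generate_white_noise()]: the repeating segment (gaze path and
#' content) is identical across trials.
#'
#' @inheritParams generate_white_noise
#' @param jitter_sd Gaze random-walk step standard deviation in stimulus
#'   pixels (>= 0; 0 freezes the gaze).
#' @param temporal_corr Per-frame latent-content correlation in `[0, 1]`;
#'   1 freezes the content.
#' @return An `rgc_stimulus` with `ensemble = "natural_surrogate"`.
#' @export
generate_natural_surrogate <- function(geometry, n_trials = 6L,
                                       train_seconds = 20, test_seconds = 5,
                                       contrast = 1, jitter_sd = 2,
                                       temporal_corr = 0.9, seed = 1L) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (temporal_corr < 0 || temporal_corr > 1)
    stop("temporal_corr must be in [0, 1]")
  d <- stim_grid_dims(geometry, require_divisible = FALSE)
  h <- unname(d["h"]); w <- unname(d["w"])
  Lh <- 2L * h; Lw <- 2L * w
  n_train <- round(train_seconds * geometry$frame_rate)
  n_test <- round(test_seconds * geometry$frame_rate)
  rho <- temporal_corr
  mix <- sqrt(max(0, 1 - rho^2))

  segment <- function(n) {
    latent <- pink_field(Lh, Lw, contrast)
    pos <- c(1L, 1L)
    out <- array(0, c(n, h, w))
    for (t in seq_len(n)) {
      if (t > 1) {
        if (mix > 0)
          latent <- rho * latent + mix * pink_field(Lh, Lw, contrast)
        step <- as.integer(round(rnorm(2, 0, jitter_sd)))
        pos <- (pos - 1L + step) %% c(Lh, Lw) + 1L
      }
      ri <- ((pos[1] - 1L + 0:(h - 1L)) %% Lh) + 1L
      ci <- ((pos[2] - 1L + 0:(w - 1L)) %% Lw) + 1L
      out[t, , ] <- latent[ri, ci]
    }
    out
  }
  set.seed(seed)
  test_block <- segment(n_test)
  train_blocks <- lapply(seq_len(n_trials), function(k) segment(n_train))
  assemble_trials(train_blocks, test_block, geometry, "natural_surrogate")
}

#' Simulate an LN-Poisson ganglion cell response
#'
#' Runs the cell's generative LN model forward on a stimulus (using the
#' parameter set matching the stimulus ensemble), interprets the softplus
#' output as a firing rate in Hz, and draws independent Poisson spike counts
#' per bin with mean `rate / frame_rate`.  Bins without a full 30-frame
#' history (the first 29 of each segment) receive zero counts.  Because
#' draws are independent, repeating segments get fresh noise on every trial.
#'
#' @param cell A ground-truth cell from [make_ground_truth_population()].
#' @param stimulus An `rgc_stimulus` whose ensemble has matching parameters.
#' @param seed Integer seed for the Poisson draws.
#' @return A `spike_response`: list with `counts` (one per frame) and
#'   `cell_id`.
#' @export
simulate_rgc <- function(cell, stimulus, seed = 1L) {
  params <- switch(stimulus$ensemble,
    white_noise = cell$params_wn,
    natural_surrogate = cell$params_nm,
    stop("no ground-truth parameters for ensemble '", stimulus$ensemble, "'")
  )
  crop <- crop_stimulus(stimulus, params$crop_center, size = 15L)
  segs <- stimulus_segments(stimulus, "all")
  rate <- predict_rate(params, crop$X, segments = segs)
  lambda <- rate / stimulus$geometry$frame_rate
  set.seed(seed)
  counts <- integer(length(lambda))
  ok <- !is.na(lambda)
  counts[ok] <- rpois(sum(ok), lambda[ok])
  structure(list(counts = counts, cell_id = cell$cell_id),
            class = "spike_response")
}

# biphasic/monophasic temporal kernels on a most-recent-first lag axis,
# unit-normalized; lags in frames (lag 0 = most recent)
temporal_kernel <- function(peak = 4, trough = 8, trough_gain = 0.5,
                            n = 30L) {
  lag <- 0:(n - 1L)
  k <- (lag / peak)^2 * exp(-lag / peak) -
    trough_gain * (lag / trough)^2 * exp(-lag / trough)
  k / sqrt(sum(k^2))
}

# rotated anisotropic covariance from axis sds and angle
rot_cov <- function(s1, s2, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  R %*% diag(c(s1^2, s2^2)) %*% t(R)
}

#' Default synthetic population specification
#'
#' Cell groups loosely emulating primate RGC types: midget-like cells with
#' small centers that (when `adapt = TRUE`) enlarge under the movie
#' surrogate, and parasol-like / large-OFF-like cells whose centers are
#' stable while all groups strengthen their surrounds under the movie.
#' Center-sigma ranges are in stimulus pixels.
#'
#' @return A list of group specifications.
#' @export
default_population_spec <- function() {
  list(
    list(type = "midget_like", n = 6L, polarity = "OFF",
         center_sigma = c(1.2, 1.8), center_scale_nm = 1.3,
         surround_wn = c(0.05, 0.12), surround_nm = c(0.35, 0.55)),
    list(type = "parasol_like", n = 4L, polarity = "ON",
         center_sigma = c(2.0, 2.6), center_scale_nm = 1.0,
         surround_wn = c(0.05, 0.12), surround_nm = c(0.35, 0.55)),
    list(type = "large_off_like", n = 2L, polarity = "OFF",
         center_sigma = c(2.4, 3.0), center_scale_nm = 1.0,
         surround_wn = c(0.05, 0.12), surround_nm = c(0.35, 0.55))
  )
}

# scale DoG amplitudes so the linear drive on unit-contrast white noise has
# the requested standard deviation (drive sd = Frobenius norm of R for
# pixelwise-independent unit-variance stimuli)
scale_drive <- function(params, target_sd = 1.5) {
  rf <- build_spatiotemporal_rf(params)
  sc <- target_sd / sqrt(sum(rf^2))
  params$amp1 <- params$amp1 * sc
  params$amp2 <- params$amp2 * sc
  params
}

#' Build a ground-truth LN-Poisson cell population
#'
#' Draws per-cell difference-of-Gaussians LN parameters for the white-noise
#' ensemble and, depending on `adapt`, either copies them for the movie
#' surrogate (`adapt = FALSE`, the null population) or enlarges the center
#' (midget-like groups only, via `center_scale_nm`) and strengthens the
#' surround for the movie parameters (`adapt = TRUE`).
#'
#' @param spec A list of group specifications, see
#'   [default_population_spec()].
#' @param geometry A [stim_geometry()] used to place receptive-field centers
#'   so that a 15 x 15 crop always fits.
#' @param adapt Logical; whether movie-ensemble parameters differ.
#' @param seed Integer seed.
#' @param target_drive_sd Linear-drive standard deviation on unit-contrast
#'   white noise used to scale filter amplitudes.
#' @return A list of ground-truth cells (fields `cell_id`,
#'   `cell_type_label`, `polarity`, `params_wn`, `params_nm`).
#' @export
make_ground_truth_population <- function(spec = default_population_spec(),
                                         geometry = stim_geometry(),
                                         adapt = TRUE, seed = 1L,
                                         target_drive_sd = 1.5) {
  d <- stim_grid_dims(geometry, require_divisible = FALSE)
  half <- 7L
  if (d["h"] < 15 || d["w"] < 15)
    stop("geometry too small for a 15x15 crop")
  set.seed(seed)
  cells <- list()
  id <- 0L
  for (g in spec) {
    if (g$n < 0) stop("group counts must be >= 0")
    for (k in seq_len(g$n)) {
      id <- id + 1L
      pol <- if (identical(g$polarity, "OFF")) -1 else 1
      sig <- runif(1, g$center_sigma[1], g$center_sigma[2])
      aniso <- runif(1, 0, 0.15)
      th <- runif(1, 0, pi)
      cov_c <- rot_cov(sig * (1 + aniso), sig * (1 - aniso), th)
      s_wn <- runif(1, g$surround_wn[1], g$surround_wn[2])
      s_nm <- runif(1, g$surround_nm[1], g$surround_nm[2])
      ctr <- c(sample(half + 1:(d["h"] - 14L), 1),
               sample(half + 1:(d["w"] - 14L), 1))
      mu <- c(8, 8) + runif(2, -1, 1)
      t1 <- temporal_kernel(peak = 3.5 + runif(1, -0.5, 0.5))
      t2 <- temporal_kernel(peak = 6 + runif(1, -0.5, 0.5),
                            trough_gain = 0.2)
      alpha <- 10 * exp(runif(1, -0.2, 0.2))
      beta <- -0.5

      mk <- function(sig_scale, surr) {
        p <- dog_ln_params(
          polarity = pol, mean = mu,
          amp1 = pol * 1, amp2 = pol * surr,
          cov1 = cov_c * sig_scale^2, cov2 = cov_c * sig_scale^2 * 2.2^2,
          t1 = t1, t2 = t2, alpha = alpha, beta = beta,
          crop_center = ctr
        )
        scale_drive(p, target_drive_sd)
      }
      params_wn <- mk(1, s_wn)
      params_nm <- if (adapt) mk(g$center_scale_nm, s_nm) else params_wn
      cells[[id]] <- list(
        cell_id = sprintf("cell_%03d", id),
        cell_type_label = g$type,
        polarity = if (pol > 0) "ON" else "OFF",
        params_wn = params_wn, params_nm = params_nm
      )
    }
  }
  cells
}
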