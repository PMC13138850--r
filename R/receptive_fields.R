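#' Receptive-field center size from DoG parameters
#'
#' The area `S = 4 * pi * sqrt(lambda1 * lambda2)` of the two-standard-
#' deviation ellipse of the center Gaussian, where the lambdas are the
#' eigenvalues of its covariance matrix.
#'
#' @param params A `dog_ln_params`, or a 2 x 2 covariance matrix.
#' @return Area in stimulus pixels squared.
#' @examples
#' center_size_dog(diag(2))   # 4 * pi
#' @export
center_size_dog <- function(params) {
  cov <- if (inherits(params, "dog_ln_params")) params$cov1 else params
  check_spd2(cov)
  4 * pi * sqrt(det(cov))
}

.pol_num <- function(polarity) {
  if (is.character(polarity))
    polarity <- if (toupper(polarity) == "OFF") -1 else 1
  p <- sign(polarity)
  if (is.na(p) || p == 0) stop("polarity must be ON/OFF or +1/-1")
  p
}

.rf_center <- function(rf, center) {
  if (is.null(center)) center <- attr(rf, "center")
  if (is.null(center)) center <- (dim(rf)[2:3] + 1L) %/% 2L
  ctr <- as.integer(round(center))
  pmin(pmax(ctr, 1L), dim(rf)[2:3])
}

#' Locate the max frame and surround frame of a spatiotemporal RF
#'
#' The max frame is the temporal slice in which the center-coordinate pixel
#' is maximal (ON) or minimal (OFF).  Candidate surround frames lie within
#' `window` frames of the max frame (clipped to the temporal range) and
#' must retain the cell's polarity at the center pixel; among them the
#' surround frame is the one containing the largest-magnitude pixel of the
#' opposite polarity.  `NA` is returned when no candidate frame holds any
#' opposite-polarity pixel.  Ties break toward the earliest frame.
#'
#' @param rf A `30 x 15 x 15` spatiotemporal RF array.
#' @param polarity `"ON"`/`"OFF"` or +1/-1.
#' @param window Half-width of the temporal search window in frames.
#' @param center Optional crop-local `(row, col)` center pixel; defaults to
#'   the RF's stored center, else the crop middle.
#' @return List with `max_frame` and `surround_frame` (`NA` if none).
#' @export
find_surround_frame <- function(rf, polarity, window = 6L, center = NULL) {
  pol <- .pol_num(polarity)
  ctr <- .rf_center(rf, center)
  trace <- pol * rf[, ctr[1], ctr[2]]
  max_frame <- which.max(trace)
  cand <- max(1L, max_frame - window):min(dim(rf)[1], max_frame + window)
  cand <- cand[pol * rf[cand, ctr[1], ctr[2]] > 0]
  best <- NA_integer_; best_val <- 0
  for (t in cand) {
    opp <- max(-pol * rf[t, , ])
    if (opp > best_val) { best_val <- opp; best <- t }
  }
  list(max_frame = max_frame, surround_frame = best)
}

#' Surround amplitude of a spatiotemporal RF
#'
#' Normalizes the RF so the center pixel at the max frame has magnitude 1,
#' then returns the magnitude of the most extreme opposite-polarity pixel
#' in the surround frame (0 when no surround frame exists).  The
#' normalization makes surround strengths comparable across cells and
#' models, since the softplus absorbs overall filter scale.
#'
#' @inheritParams find_surround_frame
#' @return A nonnegative scalar.
#' @export
surround_amplitude <- function(rf, polarity, window = 6L, center = NULL) {
  pol <- .pol_num(polarity)
  ctr <- .rf_center(rf, center)
  fr <- find_surround_frame(rf, polarity, window, center)
  cval <- rf[fr$max_frame, ctr[1], ctr[2]]
  if (cval == 0) stop("center pixel is exactly zero at the max frame")
  if (is.na(fr$surround_frame)) return(0)
  max(-pol * rf[fr$surround_frame, , ]) / abs(cval)
}

# integer-shift a matrix, filling vacated pixels with `fill` (mean gray = 0)
shift_matrix <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Aligned mean receptive field across cells
#'
#' Each cell's RF is rescaled so the extremum of its center-pixel temporal
#' trace is +1 (ON) or -1 (OFF); its surround-frame spatial slice (max
#' frame when no surround frame exists) is shifted by integer pixels to a
#' common center, with vacated pixels set to mean gray (0), and the slices
#' are averaged pixelwise.
#'
#' @param rfs List of spatiotemporal RF arrays (one cell type).
#' @param polarities Vector of polarities, one per cell (recycled if
#'   length 1).
#' @param centers List (or 2-column matrix) of crop-local `(row, col)`
#'   centers, one per cell; defaults to each RF's stored center.
#' @param window Temporal search window for the surround frame.
#' @return A `15 x 15` mean spatial receptive field.
#' @export
mean_receptive_field <- function(rfs, polarities, centers = NULL,
                                 window = 6L) {
  n <- length(rfs)
  if (n < 1) stop("need at least one receptive field")
  if (length(polarities) == 1) polarities <- rep(polarities, n)
  target <- (dim(rfs[[1]])[2:3] + 1L) %/% 2L
  acc <- matrix(0, dim(rfs[[1]])[2], dim(rfs[[1]])[3])
  for (i in seq_len(n)) {
    rf <- rfs[[i]]
    pol <- .pol_num(polarities[i])
    ctr <- .rf_center(rf, if (is.null(centers)) NULL else
      if (is.matrix(centers)) centers[i, ] else centers[[i]])
    trace <- pol * rf[, ctr[1], ctr[2]]
    ext <- max(trace)
    if (ext <= 0) stop("center trace has no excursion of the cell's polarity")
    rfn <- rf / ext           # center-trace extremum becomes +1 (ON) / -1 (OFF)
    fr <- find_surround_frame(rfn, pol, window, ctr)
    sl <- if (is.na(fr$surround_frame)) fr$max_frame else fr$surround_frame
    acc <- acc + shift_matrix(rfn[sl, , ], target[1] - ctr[1],
                              target[2] - ctr[2])
  }
  acc / n
}

# evaluate a DoG (difference of two shared-mean Gaussians) on an n x n grid
.dog_image <- function(ac, as_, mu, cov_c, cov_s, n) {
  matrix(.gauss_render(ac, mu, cov_c, n)$G - .gauss_render(as_, mu, cov_s, n)$G,
         n, n)
}

#' Post-hoc difference-of-Gaussians fit to a spatial filter
#'
#' Fits `DoG(x) = Ac exp(-(x-mu)' covc^-1 (x-mu)/2) -
#' As exp(-(x-mu)' covs^-1 (x-mu)/2)` to a learned spatial filter by
#' bounded least squares (Levenberg-Marquardt), with a shared mean,
#' positivity constraints on the covariance diagonals, and matched
#' amplitude signs.  Initial values: `Ac = As = 0.5` (signed by the
#' filter's peak), `sigma_cx = sigma_cy = 1.2`, `sigma_sx = sigma_sy =
#' 1.5`, off-diagonals `1e-3`, mean at the crop center.
#'
#' @param spatial A square spatial-filter matrix (15 x 15 for the rank-one
#'   model).
#' @param polarity Optional sign of the amplitudes; inferred from the
#'   filter's extremum when missing.
#' @param multistart If `TRUE`, restart from 5 jittered initializations and
#'   keep the best fit (off by default).
#' @return A `posthoc_dog_fit`: amplitudes `a_c`, `a_s`, shared `mu`,
#'   covariances `cov_c`, `cov_s`, residual `mse`, `center_size` (the
#'   2-SD ellipse area of `cov_c`), `surround_strength` (opposite-sign
#'   extremum of the max-abs-normalized fitted DoG), `converged`.
#' @export
fit_dog_posthoc <- function(spatial, polarity = NULL, multistart = FALSE) {
  spatial <- as.matrix(spatial)
  n <- nrow(spatial)
  if (!all(is.finite(spatial))) stop("spatial filter must be finite")
  s <- if (is.null(polarity)) sign(spatial[which.max(abs(spatial))])
       else .pol_num(polarity)
  ctr <- (n + 1) / 2
  target <- as.vector(spatial)

  build <- function(p) {
    cov_c <- matrix(c(p[5]^2, p[7], p[7], p[6]^2), 2, 2)
    cov_s <- matrix(c(p[8]^2, p[10], p[10], p[9]^2), 2, 2)
    list(cov_c = cov_c, cov_s = cov_s,
         ok = det(cov_c) > 1e-8 && det(cov_s) > 1e-8)
  }
  resid_fun <- function(p) {
    cv <- build(p)
    if (!cv$ok) return(rep(1e3, length(target)))
    img <- .gauss_render(s * p[1], p[3:4], cv$cov_c, n)$G -
      .gauss_render(s * p[2], p[3:4], cv$cov_s, n)$G
    img - target
  }
  lower <- c(0, 0, -Inf, -Inf, 1e-3, 1e-3, -Inf, 1e-3, 1e-3, -Inf)
  init0 <- c(0.5, 0.5, ctr, ctr, 1.2, 1.2, 1e-3, 1.5, 1.5, 1e-3)
  inits <- list(init0)
  if (multistart)
    for (k in 1:4)
      inits[[k + 1]] <- init0 * exp(stats::rnorm(10, 0, 0.1))
  best <- NULL
  for (init in inits) {
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = init, lower = lower, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500)))
    mse <- mean(fit$fvec^2)
    if (is.null(best) || mse < best$mse)
      best <- list(par = fit$par, mse = mse,
                   converged = fit$info %in% 1:4)
  }
  p <- best$par
  cv <- build(p)
  img <- .dog_image(s * p[1], s * p[2], p[3:4], cv$cov_c, cv$cov_s, n)
  imgn <- img / max(abs(img))
  structure(list(
    a_c = s * p[1], a_s = s * p[2], mu = p[3:4],
    cov_c = cv$cov_c, cov_s = cv$cov_s, mse = best$mse,
    center_size = 4 * pi * sqrt(det(cv$cov_c)),
    surround_strength = max(0, max(-s * imgn)),
    converged = best$converged
  ), class = "posthoc_dog_fit")
}

# separable Kaiser window (outer product of 1-D windows spanning the crop)
.kaiser2d <- function(n, beta = 7) {
  k <- signal::kaiser(n, beta)
  outer(k, k)
}

# 8-connected component of a logical mask containing a seed pixel
.connected_component <- function(mask, seed_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  stack <- list(seed_rc)
  comp[seed_rc[1], seed_rc[2]] <- TRUE
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          mask[r, c] && !comp[r, c]) {
        comp[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  comp
}

#' Threshold-based receptive-field center size
#'
#' Nonparametric center-size estimate: the filter is windowed with a
#' separable Kaiser window (`beta = 7`) to suppress edge artifacts,
#' normalized by its maximal absolute value, and binarized at 20% of the
#' peak value (maximum for ON, minimum for OFF, same sign); the pixel count
#' of the 8-connected component containing the peak is the center area.
#'
#' @param spatial Square spatial-filter matrix (not identically zero).
#' @param polarity `"ON"`/`"OFF"` or +1/-1.
#' @param beta Kaiser window shape parameter.
#' @return Center area in pixels squared (a pixel count).
#' @export
threshold_center_size <- function(spatial, polarity, beta = 7) {
  spatial <- as.matrix(spatial)
  if (all(spatial == 0)) stop("spatial filter is identically zero")
  pol <- .pol_num(polarity)
  w <- spatial * .kaiser2d(nrow(spatial), beta)
  w <- w / max(abs(w))
  sp <- pol * w
  peak <- which(sp == max(sp), arr.ind = TRUE)[1, ]
  mask <- sp >= 0.2 * max(sp)
  sum(.connected_component(mask, peak))
}

# separable Gaussian smoothing, zero-padded 'same' convolution
.gauss_smooth <- function(img, sigma = 1.5) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    p <- c(rep(0, r), v, rep(0, r))
    as.vector(stats::embed(p, 2 * r + 1) %*% rev(k))
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(tmp, 1, pad_conv))
}

#' Smoothing-based surround amplitude
#'
#' Complements [threshold_center_size()]: the Kaiser-windowed,
#' max-abs-normalized filter is smoothed with a Gaussian kernel
#' (`sigma = 1.5` px) and the magnitude of the opposite-polarity extremum
#' of the smoothed filter (maximum for OFF, minimum for ON) is returned
#' (0 when no opposite-polarity value exists).  Normalization-first makes
#' the estimate invariant to filter rescaling.
#'
#' @inheritParams threshold_center_size
#' @param sigma Gaussian smoothing kernel standard deviation in pixels.
#' @return A nonnegative scalar.
#' @export
smoothed_surround_amplitude <- function(spatial, polarity, beta = 7,
                                        sigma = 1.5) {
  spatial <- as.matrix(spatial)
  if (all(spatial == 0)) stop("spatial filter is identically zero")
  pol <- .pol_num(polarity)
  w <- spatial * .kaiser2d(nrow(spatial), beta)
  w <- w / max(abs(w))
  sm <- .gauss_smooth(w, sigma)
  max(0, max(-pol * sm))
}

#' Receptive-field metrics of a fitted model
#'
#' Computes center size and surround amplitude by one of the three
#' estimation methods: `"dog_params"` (center size from the fitted Gaussian
#' covariance, surround amplitude from the full spatiotemporal RF),
#' `"posthoc_dog"` (post-hoc DoG fit to the surround-frame spatial slice),
#' or `"threshold"` (Kaiser window/threshold and smoothing).  Surround
#' amplitudes below `clip_below` are reported as 0.
#'
#' @param fit A `fit_result` or LN parameter object.
#' @param method Estimation method.
#' @param geometry Optional [stim_geometry()] to also report µm².
#' @param window Temporal surround-frame search window.
#' @param clip_below Surround amplitudes below this value are reported as 0.
#' @return A one-row data.frame (method, center_size_px2, optional
#'   center_size_um2, surround_amplitude, surround_frame, max_frame).
#' @export
rf_metrics <- function(fit, method = c("dog_params", "posthoc_dog",
                                       "threshold"),
                       geometry = NULL, window = 6L, clip_below = 1e-4) {
  method <- match.arg(method)
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  rf <- build_spatiotemporal_rf(params)
  pol <- if (inherits(params, "dog_ln_params")) params$polarity
         else .pol_num(attr(rf, "polarity"))
  fr <- find_surround_frame(rf, pol, window)
  slice_frame <- if (is.na(fr$surround_frame)) fr$max_frame
                 else fr$surround_frame
  if (method == "dog_params") {
    if (!inherits(params, "dog_ln_params"))
      stop("dog_params metrics require a DoG LN model")
    size <- center_size_dog(params)
    surr <- surround_amplitude(rf, pol, window)
  } else {
    slice <- rf[slice_frame, , ]
    if (method == "posthoc_dog") {
      ph <- fit_dog_posthoc(slice, polarity = pol)
      size <- ph$center_size
      surr <- ph$surround_strength
    } else {
      size <- threshold_center_size(slice, pol)
      surr <- smoothed_surround_amplitude(slice, pol)
    }
  }
  out <- data.frame(method = method, center_size_px2 = size,
                    surround_amplitude = if (surr < clip_below) 0 else surr,
                    surround_frame = fr$surround_frame,
                    max_frame = fr$max_frame)
  if (!is.null(geometry))
    out$center_size_um2 <- px2_to_um2(size, geometry)
  out
}
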