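#' Softplus nonlinearity
#'
#' The two-parameter output nonlinearity `f(x) = alpha * log(1 + exp(x +
#' beta))`, evaluated with a numerically stable log1p-exp formulation so that
#' large positive and negative drives do not overflow.
#'
#' @param x Numeric vector of linear drives.
#' @param alpha Positive output gain.
#' @param beta Input offset.
#' @return Strictly positive values of the same shape as `x`.
#' @examples
#' softplus(0)            # log(2)
#' softplus(0, 2, 1)      # 2 * log(1 + e)
#' @export
softplus <- function(x, alpha = 1, beta = 0) {
  if (alpha <= 0) stop("alpha must be > 0")
  z <- x + beta
  out <- ifelse(z > 30, z + log1p(exp(-z)), log1p(exp(pmin(z, 30))))
  alpha * out
}

# logistic sigmoid, used both as softplus derivative and for raw-parameter
# transforms
.sigmoid <- function(z) 1 / (1 + exp(-z))

# softplus and its inverse used as positivity transform for raw parameters
.sp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
.sp_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

check_spd2 <- function(cov, what = "covariance") {
  if (!isTRUE(all.equal(cov[1, 2], cov[2, 1], tolerance = 1e-8)))
    stop(what, " must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop(what, " must be positive definite")
  invisible(ev)
}

#' Render a two-dimensional Gaussian spatial filter on a pixel grid
#'
#' Evaluates `amplitude * exp(-(p - mean)' cov^-1 (p - mean) / 2)` at pixel
#' centers `(row, col)` with integer coordinates `1..grid_size`.
#'
#' @param g A list with `amplitude` (signed scalar), `mean` (length-2,
#'   (row, col) in pixels), `cov` (2 x 2 symmetric positive-definite, px^2).
#' @param grid_size Side length of the square grid.
#' @return A `grid_size x grid_size` matrix.
#' @export
render_spatial <- function(g, grid_size = 15L) {
  check_spd2(g$cov)
  matrix(.gauss_render(g$amplitude, g$mean, g$cov, grid_size)$G,
         grid_size, grid_size)
}

# Gaussian evaluation plus the per-pixel pieces needed for analytic
# gradients: q = p - mu, w = cov^-1 q, e = exp(-q'w/2), G = A*e (flattened
# column-major, matching crop_stimulus row layout)
.gauss_render <- function(A, mu, cov, n = 15L) {
  rr <- rep(seq_len(n), times = n)
  cc <- rep(seq_len(n), each = n)
  q1 <- rr - mu[1]; q2 <- cc - mu[2]
  det <- cov[1, 1] * cov[2, 2] - cov[1, 2]^2
  i11 <- cov[2, 2] / det; i22 <- cov[1, 1] / det; i12 <- -cov[1, 2] / det
  w1 <- i11 * q1 + i12 * q2
  w2 <- i12 * q1 + i22 * q2
  e <- exp(-0.5 * (q1 * w1 + q2 * w2))
  list(G = A * e, e = e, w1 = w1, w2 = w2)
}

#' Difference-of-Gaussians LN model parameters
#'
#' The rank-two, space-time separable LN model: two spatial Gaussians
#' sharing a center location and amplitude sign (center `g1`, surround
#' `g2`), two unit-norm temporal filters, and a softplus nonlinearity.  The
#' full spatiotemporal receptive field is
#' `R(x, y, t) = G1(x, y) T1(t) - G2(x, y) T2(t)`.
#'
#' @param polarity +1 (ON) or -1 (OFF); the shared sign of both amplitudes.
#' @param mean Shared Gaussian center, crop-local `(row, col)` pixels.
#' @param amp1,amp2 Signed amplitudes; their sign must equal `polarity`
#'   (`amp2 = 0` is allowed: no surround).
#' @param cov1,cov2 2 x 2 symmetric positive-definite covariances (px^2).
#' @param t1,t2 Temporal filters, 30 weights each, most recent lag first;
#'   normalized to unit Euclidean norm on construction.
#' @param alpha,beta Softplus parameters (`alpha > 0`).
#' @param crop_center Global `(row, col)` stimulus-pixel coordinates of the
#'   15 x 15 crop center.
#' @return An object of class `dog_ln_params`.
#' @export
dog_ln_params <- function(polarity, mean, amp1, amp2, cov1, cov2,
                          t1, t2, alpha, beta, crop_center = c(8L, 8L)) {
  polarity <- sign(polarity)
  if (polarity == 0) stop("polarity must be +1 or -1")
  if (amp1 * polarity < 0 || amp2 * polarity < 0)
    stop("amplitudes must share the polarity's sign")
  check_spd2(cov1, "cov1"); check_spd2(cov2, "cov2")
  if (length(t1) != 30L || length(t2) != 30L)
    stop("temporal filters must have 30 weights")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(
    polarity = polarity, mean = as.numeric(mean),
    amp1 = amp1, amp2 = amp2, cov1 = cov1, cov2 = cov2,
    t1 = t1 / sqrt(sum(t1^2)), t2 = t2 / sqrt(sum(t2^2)),
    alpha = alpha, beta = beta,
    crop_center = as.integer(round(crop_center))
  ), class = "dog_ln_params")
}

#' Rank-one LN model parameters
#'
#' The unconstrained alternative model: a free 15 x 15 spatial filter (225
#' parameters learned directly, no Gaussian parameterization), one
#' unconstrained 30-frame temporal filter, and a softplus nonlinearity.
#'
#' @param spatial 15 x 15 numeric matrix of free weights.
#' @param temporal 30-vector, most recent lag first (unconstrained norm).
#' @param alpha,beta Softplus parameters (`alpha > 0`).
#' @param crop_center Global crop-center coordinates.
#' @param polarity Optional +1/-1 label used by receptive-field analyses.
#' @return An object of class `rank_one_ln_params`.
#' @export
rank_one_ln_params <- function(spatial, temporal, alpha = 1, beta = 0,
                               crop_center = c(8L, 8L), polarity = NA) {
  spatial <- as.matrix(spatial)
  if (!all(dim(spatial) == c(15L, 15L)))
    stop("spatial filter must be 15 x 15 (225 free parameters)")
  if (length(temporal) != 30L) stop("temporal filter must have 30 weights")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(
    spatial = spatial, temporal = as.numeric(temporal),
    alpha = alpha, beta = beta,
    crop_center = as.integer(round(crop_center)), polarity = polarity
  ), class = "rank_one_ln_params")
}

#' Count free parameters of an LN model
#'
#' @param params A `dog_ln_params` or `rank_one_ln_params`.
#' @return Named integer vector with components `spatial`, `temporal`,
#'   `nonlinearity`.
#' @export
n_free_params <- function(params) UseMethod("n_free_params")

#' @export
n_free_params.rank_one_ln_params <- function(params) {
  c(spatial = length(params$spatial), temporal = length(params$temporal),
    nonlinearity = 2L)
}

#' @export
n_free_params.dog_ln_params <- function(params) {
  # shared mean (2) + two amplitudes + two covariance factors (3 each)
  c(spatial = 2L + 2L + 6L, temporal = 60L, nonlinearity = 2L)
}

#' Build the full spatiotemporal receptive field
#'
#' For the DoG model, `R[t, , ] = G1 * t1[t] - G2 * t2[t]`; for the rank-one
#' model, `R[t, , ] = spatial * temporal[t]`.  The first temporal index is
#' the most recent frame before the prediction bin.
#'
#' @param params LN model parameters.
#' @return A `30 x 15 x 15` array of class `spatiotemporal_rf` with
#'   attributes `center` (crop-local integer center) and `polarity`.
#' @export
build_spatiotemporal_rf <- function(params) UseMethod("build_spatiotemporal_rf")

#' @export
build_spatiotemporal_rf.dog_ln_params <- function(params) {
  G1 <- render_spatial(list(amplitude = params$amp1, mean = params$mean,
                            cov = params$cov1))
  G2 <- render_spatial(list(amplitude = params$amp2, mean = params$mean,
                            cov = params$cov2))
  rf <- array(0, c(30L, 15L, 15L))
  for (t in 1:30) rf[t, , ] <- G1 * params$t1[t] - G2 * params$t2[t]
  structure(rf, class = "spatiotemporal_rf",
            center = as.integer(round(params$mean)),
            polarity = params$polarity)
}

#' @export
build_spatiotemporal_rf.rank_one_ln_params <- function(params) {
  rf <- array(0, c(30L, 15L, 15L))
  for (t in 1:30) rf[t, , ] <- params$spatial * params$temporal[t]
  pk <- which.max(abs(params$spatial))
  ctr <- c((pk - 1L) %% 15L + 1L, (pk - 1L) %/% 15L + 1L)
  structure(rf, class = "spatiotemporal_rf", center = ctr,
            polarity = params$polarity)
}

# spatial filter vectors (column-major, matching crop layout) and temporal
# filters as used by the drive computation; G2/t2 are NULL for rank-one
.filter_vectors <- function(params) {
  if (inherits(params, "dog_ln_params")) {
    list(
      g1 = .gauss_render(params$amp1, params$mean, params$cov1)$G,
      g2 = .gauss_render(params$amp2, params$mean, params$cov2)$G,
      t1 = params$t1, t2 = params$t2
    )
  } else {
    list(g1 = as.vector(params$spatial), g2 = NULL,
         t1 = params$temporal, t2 = NULL)
  }
}

# linear drive over one contiguous segment: u[f] = <G, x_f> per frame, then
# valid-mode temporal filtering over 30-frame histories (most recent first).
# Returns one value per valid bin (bins 30..F of the segment).
.segment_drive <- function(Xseg, fv) {
  nf <- nrow(Xseg)
  if (nf < 30L) return(numeric(0))
  u1 <- as.vector(Xseg %*% fv$g1)
  E1 <- stats::embed(u1, 30L)
  d <- as.vector(E1 %*% fv$t1)
  if (!is.null(fv$g2)) {
    u2 <- as.vector(Xseg %*% fv$g2)
    d <- d - as.vector(stats::embed(u2, 30L) %*% fv$t2)
  }
  d
}

#' Predict the firing-rate trace of an LN model
#'
#' Computes the linear drive of the model on cropped stimulus frames by
#' valid-mode convolution over 30-frame histories and passes it through the
#' softplus nonlinearity.  The first 29 bins of each contiguous segment have
#' no full history and are returned as `NA`; segments shorter than the
#' filter are skipped with a warning.
#'
#' @param params LN model parameters (`dog_ln_params` or
#'   `rank_one_ln_params`).
#' @param cropped_stimulus Either a `frames x 15 x 15` array or a
#'   `frames x 225` matrix (as produced by [crop_stimulus()]).
#' @param segments List of `c(start, end)` frame ranges treated as
#'   contiguous; default: one segment covering all frames.
#' @param rate Logical; if `FALSE`, return the pre-nonlinearity drive.
#' @return Numeric vector with one value per frame (`NA` where no
#'   prediction is defined).
#' @export
predict_rate <- function(params, cropped_stimulus, segments = NULL,
                         rate = TRUE) {
  X <- if (length(dim(cropped_stimulus)) == 3)
    matrix(cropped_stimulus, nrow = dim(cropped_stimulus)[1])
  else cropped_stimulus
  if (ncol(X) != 225L) stop("cropped stimulus must be 15 x 15 per frame")
  if (is.null(segments)) segments <- list(c(1L, nrow(X)))
  fv <- .filter_vectors(params)
  out <- rep(NA_real_, nrow(X))
  for (seg in segments) {
    idx <- seg[1]:seg[2]
    if (length(idx) < 30L) {
      warning("segment shorter than the 30-frame filter; skipped")
      next
    }
    d <- .segment_drive(X[idx, , drop = FALSE], fv)
    out[idx[30:length(idx)]] <- d
  }
  if (rate) {
    ok <- !is.na(out)
    out[ok] <- softplus(out[ok], params$alpha, params$beta)
  }
  out
}

#' Poisson loss
#'
#' The negative-log-likelihood-style training loss
#' `sum_i p_i - r_i * log(p_i + eps)` between predicted rates `p` and
#' observed counts `r`; `eps` guards `log(0)`.
#'
#' @param pred Nonnegative predicted rates.
#' @param obs Observed spike counts, same length.
#' @param eps Stabilizer added inside the logarithm.
#' @return A scalar loss.
#' @export
poisson_loss <- function(pred, obs, eps = 1e-12) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (any(pred < 0)) stop("predictions must be nonnegative")
  sum(pred - obs * log(pred + eps))
}

#' Gradient of the Poisson loss with respect to the predictions
#'
#' @inheritParams poisson_loss
#' @return Vector of partial derivatives `1 - r_i / (p_i + eps)`.
#' @export
poisson_loss_grad <- function(pred, obs, eps = 1e-12) {
  if (any(pred < 0)) stop("predictions must be nonnegative")
  1 - obs / (pred + eps)
}

#' Serialize LN parameters to JSON
#'
#' All fields, plus the polarity/constraint bookkeeping, as a JSON string;
#' the inverse of [params_from_json()].
#'
#' @param params LN model parameters.
#' @return A JSON string.
#' @export
params_to_json <- function(params) {
  kind <- if (inherits(params, "dog_ln_params")) "dog" else "rank_one"
  jsonlite::toJSON(c(list(kind = kind), unclass(params)),
                   digits = NA, auto_unbox = TRUE)
}

#' Deserialize LN parameters from JSON
#'
#' @param txt A JSON string produced by [params_to_json()].
#' @return A `dog_ln_params` or `rank_one_ln_params`.
#' @export
params_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  if (identical(o$kind, "dog"))
    dog_ln_params(o$polarity, o$mean, o$amp1, o$amp2,
                  matrix(unlist(o$cov1), 2, 2), matrix(unlist(o$cov2), 2, 2),
                  o$t1, o$t2, o$alpha, o$beta, o$crop_center)
  else
    rank_one_ln_params(matrix(unlist(o$spatial), 15, 15), o$temporal,
                       o$alpha, o$beta, o$crop_center,
                       if (is.null(o$polarity)) NA else o$polarity)
}
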