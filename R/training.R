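#' Spike-triggered average
#'
#' Computes the spike-count-weighted average of the `delta`-frame stimulus
#' history preceding each bin, `STA = (1/N) sum_t x_{t-delta+1:t} y_t`,
#' over bins with a full history inside their segment.  The receptive-field
#' crop center is the pixel with the largest temporal variance across the
#' STA's lags (ties broken toward the smallest (row, col)).
#'
#' @param stimulus An `rgc_stimulus`.
#' @param response A `spike_response` aligned to the stimulus frames.
#' @param delta History length in frames (most recent lag first in the
#'   output).
#' @return A list with `sta` (`delta x h x w` array), `crop_center`
#'   (`(row, col)` stimulus-pixel coordinates), and `n_spikes`.
#' @export
compute_sta <- function(stimulus, response, delta = 30L) {
  if (delta < 1) stop("delta must be >= 1")
  d <- dim(stimulus$frames)
  X <- matrix(stimulus$frames, nrow = d[1])
  y <- response$counts
  if (length(y) != d[1]) stop("response length must match frame count")
  W <- matrix(0, d[1], delta)
  used <- 0
  for (seg in stimulus_segments(stimulus, "all")) {
    if (seg[2] - seg[1] + 1 < delta) next
    tt <- (seg[1] + delta - 1L):seg[2]
    used <- used + sum(y[tt])
    for (l in 0:(delta - 1L)) W[tt - l, l + 1L] <- W[tt - l, l + 1L] + y[tt]
  }
  if (used <= 0) stop("no spikes available for the STA")
  sta_mat <- crossprod(W, X) / used   # delta x (h*w), lag 0 first
  v <- apply(sta_mat, 2, stats::var)
  vm <- matrix(v, d[2], d[3])
  cand <- which(vm == max(vm), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  list(sta = array(sta_mat, c(delta, d[2], d[3])),
       crop_center = as.integer(cand[1, ]), n_spikes = used)
}

#' Shuffled train/validation split of trials
#'
#' Deterministically shuffles the trials and assigns `round(fraction * n)`
#' of them to the training set; only non-repeating segments are ever used
#' for training or validation downstream.
#'
#' @param trials A trial list (as in an `rgc_stimulus`) or a trial count.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `val`.
#' @export
split_train_val <- function(trials, fraction = 0.8, seed = 1L) {
  n <- if (is.numeric(trials) && length(trials) == 1) as.integer(trials)
       else length(trials)
  if (n < 2) stop("need at least 2 trials to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split would leave the training or validation set empty")
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[(n_train + 1):n]))
}

#' Training configuration
#'
#' Hyperparameters of the gradient-based fit: Adam with an initial learning
#' rate of 0.009 for white noise, 0.005 for the movie surrogate, and 0.001
#' for out-of-domain adaptation; a reduce-on-plateau schedule (patience 15,
#' factor `lr_decay`, floor `lr_min`) driven by the validation correlation;
#' early stopping after `early_stop_patience` epochs without improvement;
#' at most `max_epochs` epochs.
#'
#' @param ensemble Which default initial learning rate to use.
#' @param max_epochs,early_stop_patience,scheduler_patience Epoch limits.
#' @param lr_init Initial learning rate (default set by `ensemble`).
#' @param lr_min,lr_decay Learning-rate floor and plateau decay factor.
#' @param batch_bins Mini-batch size in contiguous valid bins; default 256
#'   for white noise and adaptation, 2048 for the movie surrogate (whose
#'   weakly identified spatial scale needs low-noise gradients).
#' @param val_fraction Fraction of trials assigned to training.
#' @param init_center_sigma Initial center Gaussian standard deviation in
#'   stimulus pixels (surround starts at twice this scale); set at a
#'   typical midget receptive-field scale.
#' @param seed Seed for initialization and batch shuffling.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(ensemble = c("white_noise", "natural_surrogate",
                                    "adapt"),
                       max_epochs = 500L, early_stop_patience = 30L,
                       lr_init = NULL, scheduler_patience = 15L,
                       lr_min = 1e-7, lr_decay = 0.1, batch_bins = NULL,
                       val_fraction = 0.8, init_center_sigma = 1.5,
                       seed = 1L) {
  ensemble <- match.arg(ensemble)
  if (is.null(lr_init))
    lr_init <- switch(ensemble, white_noise = 0.009,
                      natural_surrogate = 0.005, adapt = 0.001)
  # the movie ensemble needs low-noise gradients for its weakly identified
  # spatial scale; white noise benefits from many small-batch updates
  if (is.null(batch_bins))
    batch_bins <- switch(ensemble, natural_surrogate = 2048L, 256L)
  if (lr_min <= 0 || lr_min > lr_init) stop("need 0 < lr_min <= lr_init")
  if (early_stop_patience < 1 || scheduler_patience < 1)
    stop("patience values must be >= 1")
  structure(list(ensemble = ensemble, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_init = lr_init,
                 scheduler_patience = as.integer(scheduler_patience),
                 lr_min = lr_min, lr_decay = lr_decay,
                 batch_bins = as.integer(batch_bins),
                 val_fraction = val_fraction,
                 init_center_sigma = init_center_sigma,
                 seed = as.integer(seed)),
            class = "fit_config")
}

# ---- internal: raw parameter packing -------------------------------------

# DoG raw layout: mu(2) a1_raw a2_raw L1(l11r,l21,l22r) L2(...) v1(30) v2(30)
# alpha_raw beta  -> length 72.  Covariance = L L', diagonal of L kept
# positive through a softplus transform; amplitudes are polarity * softplus;
# temporal filters are v / ||v|| (exact unit norm at every step).
.chol_lower <- function(cov) {
  U <- chol(cov)
  c(.sp_inv(U[1, 1]), U[1, 2], .sp_inv(U[2, 2]))
}

.pack_dog <- function(p) {
  c(p$mean, .sp_inv(abs(p$amp1)), .sp_inv(max(abs(p$amp2), 1e-9)),
    .chol_lower(p$cov1), .chol_lower(p$cov2),
    p$t1, p$t2, .sp_inv(p$alpha), p$beta)
}

.cov_from_raw <- function(l) {
  l11 <- .sp(l[1]); l21 <- l[2]; l22 <- .sp(l[3])
  matrix(c(l11^2, l11 * l21, l11 * l21, l21^2 + l22^2), 2, 2)
}

.unpack_dog <- function(theta, polarity, crop_center) {
  t1 <- theta[11:40]; t2 <- theta[41:70]
  dog_ln_params(
    polarity = polarity, mean = theta[1:2],
    amp1 = polarity * .sp(theta[3]), amp2 = polarity * .sp(theta[4]),
    cov1 = .cov_from_raw(theta[5:7]), cov2 = .cov_from_raw(theta[8:10]),
    t1 = t1 / sqrt(sum(t1^2)), t2 = t2 / sqrt(sum(t2^2)),
    alpha = .sp(theta[71]), beta = theta[72], crop_center = crop_center
  )
}

.pack_rank1 <- function(p)
  c(as.vector(p$spatial), p$temporal, .sp_inv(p$alpha), p$beta)

.unpack_rank1 <- function(theta, crop_center, polarity = NA)
  rank_one_ln_params(matrix(theta[1:225], 15, 15), theta[226:255],
                     .sp(theta[256]), theta[257], crop_center, polarity)

# render both Gaussians of a DoG raw vector, with gradient pieces
.dog_gaussians <- function(theta, polarity) {
  mu <- theta[1:2]
  m1 <- .sp(theta[3]); m2 <- .sp(theta[4])
  c1 <- .cov_from_raw(theta[5:7]); c2 <- .cov_from_raw(theta[8:10])
  list(
    g1 = .gauss_render(polarity * m1, mu, c1),
    g2 = .gauss_render(polarity * m2, mu, c2),
    m1 = m1, m2 = m2,
    L1 = c(.sp(theta[5]), theta[6], .sp(theta[7])),
    L2 = c(.sp(theta[8]), theta[9], .sp(theta[10]))
  )
}

# chain rule from a gradient w.r.t. the rendered Gaussian pixel values back
# to (mu, a_raw, l11r, l21, l22r); returns list(mu = 2-vec, a = scalar,
# L = 3-vec of raw-factor gradients)
.gauss_chain <- function(grad_g, gr, A, a_raw, Lr, l_raw) {
  ge <- grad_g * gr$e
  g_a <- sum(ge) * sign(A) * .sigmoid(a_raw)
  g_mu <- A * c(sum(ge * gr$w1), sum(ge * gr$w2))
  gs11 <- 0.5 * A * sum(ge * gr$w1^2)
  gs22 <- 0.5 * A * sum(ge * gr$w2^2)
  gs12 <- A * sum(ge * gr$w1 * gr$w2)
  gL11 <- gs11 * 2 * Lr[1] + gs12 * Lr[2]
  gL21 <- gs12 * Lr[1] + gs22 * 2 * Lr[2]
  gL22 <- gs22 * 2 * Lr[3]
  list(mu = g_mu, a = g_a,
       L = c(gL11 * .sigmoid(l_raw[1]), gL21, gL22 * .sigmoid(l_raw[3])))
}

# loss, dL/d(drive), and nonlinearity gradients shared by all model variants
.loss_pieces <- function(drive, rb, alpha_raw, beta, eps = 1e-12) {
  alpha <- .sp(alpha_raw)
  z <- drive + beta
  spv <- ifelse(z > 30, z + log1p(exp(-z)), log1p(exp(pmin(z, 30))))
  p <- alpha * spv
  dLdp <- 1 - rb / (p + eps)
  sig <- .sigmoid(z)
  list(loss = sum(p - rb * log(p + eps)),
       delta = dLdp * alpha * sig,
       g_alpha = sum(dLdp * spv) * .sigmoid(alpha_raw),
       g_beta = sum(dLdp * alpha * sig))
}

# correlate gradient w.r.t. drive back to per-frame spatial projections:
# a[f] = sum_k t[k] delta[f - 30 + k] (delta zero-padded)
.spread_delta <- function(delta, tfilt) {
  pad <- c(rep(0, 29), delta, rep(0, 29))
  as.vector(stats::embed(pad, 30L) %*% rev(tfilt))
}

# full DoG objective on one batch (Xb has 29 extra leading history frames)
.dog_objective <- function(theta, Xb, rb, polarity) {
  G <- .dog_gaussians(theta, polarity)
  v1 <- theta[11:40]; v2 <- theta[41:70]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  t1 <- v1 / n1; t2 <- v2 / n2
  u1 <- as.vector(Xb %*% G$g1$G); u2 <- as.vector(Xb %*% G$g2$G)
  E1 <- stats::embed(u1, 30L); E2 <- stats::embed(u2, 30L)
  drive <- as.vector(E1 %*% t1 - E2 %*% t2)
  lp <- .loss_pieces(drive, rb, theta[71], theta[72])
  g_t1 <- as.vector(crossprod(E1, lp$delta))
  g_t2 <- -as.vector(crossprod(E2, lp$delta))
  g_v1 <- (g_t1 - sum(g_t1 * t1) * t1) / n1
  g_v2 <- (g_t2 - sum(g_t2 * t2) * t2) / n2
  gg1 <- as.vector(crossprod(Xb, .spread_delta(lp$delta, t1)))
  gg2 <- -as.vector(crossprod(Xb, .spread_delta(lp$delta, t2)))
  ch1 <- .gauss_chain(gg1, G$g1, polarity * G$m1, theta[3], G$L1, theta[5:7])
  ch2 <- .gauss_chain(gg2, G$g2, polarity * G$m2, theta[4], G$L2, theta[8:10])
  grad <- c(ch1$mu + ch2$mu, ch1$a, ch2$a, ch1$L, ch2$L,
            g_v1, g_v2, lp$g_alpha, lp$g_beta)
  list(loss = lp$loss, grad = grad)
}

.rank1_objective <- function(theta, Xb, rb) {
  sp_vec <- theta[1:225]; tf <- theta[226:255]
  u <- as.vector(Xb %*% sp_vec)
  E <- stats::embed(u, 30L)
  drive <- as.vector(E %*% tf)
  lp <- .loss_pieces(drive, rb, theta[256], theta[257])
  g_t <- as.vector(crossprod(E, lp$delta))
  g_s <- as.vector(crossprod(Xb, .spread_delta(lp$delta, tf)))
  list(loss = lp$loss, grad = c(g_s, g_t, lp$g_alpha, lp$g_beta))
}

# adaptation objective: spatial projections u (and their lag embeddings E)
# are fixed data; theta holds only temporal + nonlinearity parameters
.adapt_objective_dog <- function(theta, E1, E2, rb) {
  v1 <- theta[1:30]; v2 <- theta[31:60]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  t1 <- v1 / n1; t2 <- v2 / n2
  drive <- as.vector(E1 %*% t1 - E2 %*% t2)
  lp <- .loss_pieces(drive, rb, theta[61], theta[62])
  g_t1 <- as.vector(crossprod(E1, lp$delta))
  g_t2 <- -as.vector(crossprod(E2, lp$delta))
  list(loss = lp$loss,
       grad = c((g_t1 - sum(g_t1 * t1) * t1) / n1,
                (g_t2 - sum(g_t2 * t2) * t2) / n2,
                lp$g_alpha, lp$g_beta))
}

.adapt_objective_rank1 <- function(theta, E1, rb) {
  tf <- theta[1:30]
  drive <- as.vector(E1 %*% tf)
  lp <- .loss_pieces(drive, rb, theta[31], theta[32])
  list(loss = lp$loss,
       grad = c(as.vector(crossprod(E1, lp$delta)), lp$g_alpha, lp$g_beta))
}

# contiguous mini-batches of valid bins from the given segments
.make_batches <- function(X, counts, segs, batch_bins) {
  batches <- list()
  for (seg in segs) {
    if (seg[2] - seg[1] + 1 < 30L) next
    valid <- (seg[1] + 29L):seg[2]
    starts <- seq(1L, length(valid), by = batch_bins)
    for (s in starts) {
      vb <- valid[s:min(s + batch_bins - 1L, length(valid))]
      batches[[length(batches) + 1L]] <-
        list(Xb = X[(vb[1] - 29L):vb[length(vb)], , drop = FALSE],
             rb = counts[vb])
    }
  }
  if (length(batches) == 0) stop("no trainable segments of >= 30 frames")
  batches
}

# Adam with reduce-on-plateau on the validation correlation and early
# stopping; obj(theta, batch) -> list(loss, grad); val_cc(theta) -> scalar
# correlation or NA.  Returns best-epoch parameters and the history.
.run_adam <- function(theta, batches, obj, val_cc, cfg) {
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$lr_init
  step <- 0L
  best_cc <- -Inf; best_theta <- theta; best_epoch <- NA_integer_
  since_best <- 0L; since_sched <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_cc = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    total <- 0
    for (bi in sample.int(length(batches))) {
      o <- obj(theta, batches[[bi]])
      if (!is.finite(o$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; check stimulus scaling and learning rate")
      total <- total + o$loss
      step <- step + 1L
      m <- b1 * m + (1 - b1) * o$grad
      v <- b2 * v + (1 - b2) * o$grad^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    }
    cc <- val_cc(theta)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = total,
                                   val_cc = cc, lr = lr))
    if (!is.na(cc) && cc > best_cc) {
      best_cc <- cc; best_theta <- theta; best_epoch <- epoch
      since_best <- 0L; since_sched <- 0L
    } else {
      since_best <- since_best + 1L
      since_sched <- since_sched + 1L
    }
    if (since_sched >= cfg$scheduler_patience && lr > cfg$lr_min) {
      lr <- max(lr * cfg$lr_decay, cfg$lr_min)
      since_sched <- 0L
    }
    if (since_best >= cfg$early_stop_patience) break
  }
  if (is.na(best_epoch)) { best_theta <- theta; best_epoch <- epoch }
  list(theta = best_theta, history = hist, best_epoch = best_epoch,
       best_cc = best_cc)
}

# validation data: per-segment flattened crops and the aligned valid counts
.val_pieces <- function(X, counts, segs) {
  lapply(Filter(function(s) s[2] - s[1] + 1 >= 30L, segs), function(s) {
    list(Xs = X[s[1]:s[2], , drop = FALSE],
         r = counts[(s[1] + 29L):s[2]])
  })
}

.val_cc_fun <- function(pieces, drive_fun) {
  function(theta) {
    p <- unlist(lapply(pieces, function(pc) drive_fun(theta, pc$Xs)))
    r <- unlist(lapply(pieces, function(pc) pc$r))
    if (stats::sd(p) == 0 || stats::sd(r) == 0) return(NA_real_)
    stats::cor(p, r)
  }
}

#' Fit an LN model by maximum likelihood
#'
#' Crops the stimulus around the STA-derived receptive-field center (or a
#' supplied one), splits trials 80/20 into training and validation, and
#' minimizes the Poisson loss with Adam on mini-batches of contiguous valid
#' bins.  After each epoch the Pearson correlation between predictions and
#' observed counts on the validation trials' non-repeating segments is
#' logged; the learning rate decays on plateaus and training stops early
#' when the validation correlation has not improved for
#' `early_stop_patience` epochs.  The returned parameters are those of the
#' best validation epoch.
#'
#' @param model_kind `"dog"` (rank-two difference-of-Gaussians) or
#'   `"rank_one"` (free 15 x 15 spatial filter).
#' @param stimulus An `rgc_stimulus`.
#' @param response A `spike_response`.
#' @param cfg A [fit_config()].
#' @param crop_center Optional `(row, col)` crop center; computed from the
#'   STA on this stimulus when missing.
#' @param polarity Optional +1/-1; taken from the STA center sign when
#'   missing.
#' @return A `fit_result`: list with `params`, `history` (per-epoch train
#'   loss, validation correlation, learning rate), `best_epoch`,
#'   `crop_center`, `polarity`, `model_kind`, `split`.
#' @export
fit_ln <- function(model_kind = c("dog", "rank_one"), stimulus, response,
                   cfg = fit_config(stimulus$ensemble), crop_center = NULL,
                   polarity = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(crop_center) || is.null(polarity)) {
    sta <- compute_sta(stimulus, response)
    if (is.null(crop_center)) crop_center <- sta$crop_center
    tv <- sta$sta[, crop_center[1], crop_center[2]]
    if (is.null(polarity)) polarity <- sign(tv[which.max(abs(tv))])
    if (polarity == 0) polarity <- 1
  }
  crop <- crop_stimulus(stimulus, crop_center)
  split <- split_train_val(stimulus$trials, cfg$val_fraction, cfg$seed)
  nr_segs <- stimulus_segments(stimulus, "non_repeating")
  train_segs <- nr_segs[split$train]
  val_segs <- nr_segs[split$val]
  batches <- .make_batches(crop$X, response$counts, train_segs,
                           cfg$batch_bins)
  vp <- .val_pieces(crop$X, response$counts, val_segs)

  set.seed(cfg$seed)
  if (model_kind == "dog") {
    s0 <- cfg$init_center_sigma
    theta0 <- c(crop$center_local, .sp_inv(0.5), .sp_inv(0.5),
                .chol_lower(s0^2 * diag(2)), .chol_lower(4 * s0^2 * diag(2)),
                rnorm(30), rnorm(30), .sp_inv(1), 0)
    obj <- function(theta, b) .dog_objective(theta, b$Xb, b$rb, polarity)
    drive_fun <- function(theta, Xs)
      .segment_drive(Xs, .filter_vectors(.unpack_dog(theta, polarity,
                                                     crop_center)))
    unpack <- function(theta) .unpack_dog(theta, polarity, crop_center)
  } else {
    theta0 <- c(rnorm(225, sd = 0.1), rnorm(30), .sp_inv(1), 0)
    obj <- function(theta, b) .rank1_objective(theta, b$Xb, b$rb)
    drive_fun <- function(theta, Xs)
      .segment_drive(Xs, list(g1 = theta[1:225], g2 = NULL,
                              t1 = theta[226:255], t2 = NULL))
    unpack <- function(theta) .unpack_rank1(theta, crop_center, polarity)
  }
  res <- .run_adam(theta0, batches, obj, .val_cc_fun(vp, drive_fun), cfg)
  structure(list(params = unpack(res$theta), history = res$history,
                 best_epoch = res$best_epoch, crop_center = crop_center,
                 crop_offset = crop$offset, polarity = polarity,
                 model_kind = model_kind, split = split),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s model, %d epochs, best epoch %d (val cc %.3f)>\n",
              x$model_kind, nrow(x$history), x$best_epoch,
              max(x$history$val_cc, na.rm = TRUE)))
  invisible(x)
}

#' Out-of-domain adaptation with frozen spatial filters
#'
#' Re-trains only the temporal filters and the softplus parameters of a
#' fitted LN model on a target stimulus, keeping every spatial parameter
#' (Gaussian amplitudes, shared mean, covariances, or the rank-one spatial
#' matrix, and the crop center) exactly as fitted: the spatial filters are
#' rendered once from the input and treated as data, and the returned
#' parameter object reuses the input's spatial fields unchanged.  The
#' optimizer, scheduler and early stopping match [fit_ln()]; the default
#' initial learning rate is 0.001.
#'
#' @param fitted A `fit_result` from [fit_ln()] (or from a previous
#'   adaptation).
#' @param target_stimulus,target_response The target-ensemble data.
#' @param cfg A [fit_config()]; defaults to the adaptation configuration.
#' @return A `fit_result` on the target stimulus.
#' @export
adapt_ood <- function(fitted, target_stimulus, target_response,
                      cfg = fit_config("adapt")) {
  p0 <- fitted$params
  crop <- crop_stimulus(target_stimulus, p0$crop_center)
  split <- split_train_val(target_stimulus$trials, cfg$val_fraction,
                           cfg$seed)
  nr_segs <- stimulus_segments(target_stimulus, "non_repeating")
  batches <- .make_batches(crop$X, target_response$counts,
                           nr_segs[split$train], cfg$batch_bins)
  vp <- .val_pieces(crop$X, target_response$counts, nr_segs[split$val])
  fv <- .filter_vectors(p0)
  dog <- inherits(p0, "dog_ln_params")

  # fixed spatial projections per batch / validation segment
  for (i in seq_along(batches)) {
    u1 <- as.vector(batches[[i]]$Xb %*% fv$g1)
    batches[[i]]$E1 <- stats::embed(u1, 30L)
    if (dog) {
      u2 <- as.vector(batches[[i]]$Xb %*% fv$g2)
      batches[[i]]$E2 <- stats::embed(u2, 30L)
    }
    batches[[i]]$Xb <- NULL
  }
  for (i in seq_along(vp)) {
    vp[[i]]$E1 <- stats::embed(as.vector(vp[[i]]$Xs %*% fv$g1), 30L)
    if (dog)
      vp[[i]]$E2 <- stats::embed(as.vector(vp[[i]]$Xs %*% fv$g2), 30L)
  }

  set.seed(cfg$seed)
  if (dog) {
    theta0 <- c(p0$t1, p0$t2, .sp_inv(p0$alpha), p0$beta)
    obj <- function(theta, b) .adapt_objective_dog(theta, b$E1, b$E2, b$rb)
    val_cc <- function(theta) {
      t1 <- theta[1:30] / sqrt(sum(theta[1:30]^2))
      t2 <- theta[31:60] / sqrt(sum(theta[31:60]^2))
      p <- unlist(lapply(vp, function(pc)
        as.vector(pc$E1 %*% t1 - pc$E2 %*% t2)))
      r <- unlist(lapply(vp, function(pc) pc$r))
      if (stats::sd(p) == 0 || stats::sd(r) == 0) return(NA_real_)
      stats::cor(p, r)
    }
    repack <- function(theta) {
      p <- p0
      p$t1 <- theta[1:30] / sqrt(sum(theta[1:30]^2))
      p$t2 <- theta[31:60] / sqrt(sum(theta[31:60]^2))
      p$alpha <- .sp(theta[61]); p$beta <- theta[62]
      p
    }
  } else {
    theta0 <- c(p0$temporal, .sp_inv(p0$alpha), p0$beta)
    obj <- function(theta, b) .adapt_objective_rank1(theta, b$E1, b$rb)
    val_cc <- function(theta) {
      p <- unlist(lapply(vp, function(pc) as.vector(pc$E1 %*% theta[1:30])))
      r <- unlist(lapply(vp, function(pc) pc$r))
      if (stats::sd(p) == 0 || stats::sd(r) == 0) return(NA_real_)
      stats::cor(p, r)
    }
    repack <- function(theta) {
      p <- p0
      p$temporal <- theta[1:30]
      p$alpha <- .sp(theta[31]); p$beta <- theta[32]
      p
    }
  }
  res <- .run_adam(theta0, batches, obj, val_cc, cfg)
  structure(list(params = repack(res$theta), history = res$history,
                 best_epoch = res$best_epoch,
                 crop_center = p0$crop_center, crop_offset = crop$offset,
                 polarity = fitted$polarity,
                 model_kind = fitted$model_kind, split = split),
            class = "fit_result")
}

#' Equalize non-repeating frame counts between two stimuli
#'
#' Trims the stimulus with more non-repeating frames down to the other's
#' count so that models for both ensembles are trained on the same number
#' of frames.  Trailing trials' non-repeating ranges are emptied first,
#' then trailing frames of the last remaining range; repeating segments are
#' never touched.
#'
#' @param stim_a,stim_b Two `rgc_stimulus` objects.
#' @return A list with trimmed `a` and `b`.
#' @export
equalize_training_frames <- function(stim_a, stim_b) {
  na <- n_non_repeating(stim_a); nb <- n_non_repeating(stim_b)
  if (na < 1 || nb < 1) stop("both stimuli need non-repeating frames")
  target <- min(na, nb)
  trim <- function(stim, excess) {
    if (excess == 0) return(stim)
    for (k in rev(seq_along(stim$trials))) {
      seg <- stim$trials[[k]]$non_repeating
      len <- max(0L, seg[2] - seg[1] + 1L)
      if (len == 0) next
      if (excess >= len) {
        stim$trials[[k]]$non_repeating <- c(seg[1], seg[1] - 1L)
        excess <- excess - len
      } else {
        stim$trials[[k]]$non_repeating <- c(seg[1], seg[2] - excess)
        excess <- 0L
      }
      if (excess == 0) break
    }
    stim
  }
  list(a = trim(stim_a, na - target), b = trim(stim_b, nb - target))
}

#' Global receptive-field center location
#'
#' Converts a model's crop-local Gaussian center to stimulus-pixel
#' coordinates using the actual (boundary-clamped) crop window.  For a raw
#' parameter object the stimulus is needed to reconstruct the window.
#'
#' @param fit A `fit_result`, or an LN parameter object together with the
#'   `stimulus` it applies to.
#' @param stimulus Required when `fit` is a parameter object.
#' @return Global `(row, col)` coordinates in stimulus pixels.
#' @export
global_center <- function(fit, stimulus = NULL) {
  loc <- function(p) {
    if (inherits(p, "dog_ln_params")) p$mean
    else as.numeric(attr(build_spatiotemporal_rf(p), "center"))
  }
  if (inherits(fit, "fit_result"))
    return(fit$crop_offset + loc(fit$params) - 1)
  if (is.null(stimulus))
    stop("stimulus needed to locate a raw parameter object's crop window")
  crop_stimulus(stimulus, fit$crop_center)$offset + loc(fit) - 1
}
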