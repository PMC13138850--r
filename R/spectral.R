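# signed DFT frequencies (cycles/image) for an n-point axis
.fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

# radial bin index (rounded radial frequency) for every sample of an
# n x n spectrum, plus per-bin sample counts; bins cover ALL samples
# (corners included) so that total power is conserved
.radial_bins <- function(n) {
  f <- .fft_freqs(n)
  r <- sqrt(outer(f^2, rep(1, n)) + outer(rep(1, n), f^2))
  bin <- as.integer(round(r))
  list(bin = bin, nbin = max(bin) + 1L)
}

.radial_average <- function(P, bins) {
  sums <- .tabulate_sum(as.vector(bins$bin) + 1L, as.vector(P), bins$nbin)
  cnt <- tabulate(as.vector(bins$bin) + 1L, bins$nbin)
  sums / cnt
}

# grouped sums into 1..nbins (base tapply is slow in tight loops)
.tabulate_sum <- function(group, x, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

new_radial_spectrum <- function(power, counts, n, normalized = FALSE,
                                kind = "power") {
  df <- data.frame(frequency = seq_along(power) - 1, power = power)
  structure(df, counts = counts, n = n, normalized = normalized,
            kind = kind, class = c("radial_spectrum", "data.frame"))
}

#' Normalize a radial spectrum to its first non-DC bin
#'
#' @param spec A `radial_spectrum`.
#' @return The spectrum divided by the power at frequency 1 (the first
#'   data point; the DC bin reflects mean luminance, not spatial
#'   structure, and is excluded from normalization).
#' @export
normalize_spectrum <- function(spec) {
  p1 <- spec$power[spec$frequency == 1]
  if (length(p1) != 1 || p1 <= 0) stop("no positive power at frequency 1")
  spec$power <- spec$power / p1
  attr(spec, "normalized") <- TRUE
  spec
}

# mean 2-D power spectrum over frames of a stimulus (or plain array),
# center-cropped to crop x crop
.mean_power2d <- function(x, crop = NULL, frames = NULL) {
  arr <- if (inherits(x, "rgc_stimulus")) x$frames else x
  d <- dim(arr)
  if (is.null(crop)) crop <- min(d[2], d[3])
  if (crop > d[2] || crop > d[3]) stop("crop larger than the frames")
  if (is.null(frames)) frames <- seq_len(d[1])
  r0 <- (d[2] - crop) %/% 2L; c0 <- (d[3] - crop) %/% 2L
  acc <- matrix(0, crop, crop)
  for (i in frames) {
    fr <- arr[i, r0 + seq_len(crop), c0 + seq_len(crop)]
    acc <- acc + Mod(stats::fft(fr))^2
  }
  acc / length(frames)
}

#' Radially averaged spatial power spectrum of a stimulus
#'
#' Center-crops each frame to `crop x crop` pixels, takes the 2-D FFT,
#' radially averages the squared magnitudes into unit-width annuli
#' (assignment by rounded radial distance, in integer cycles/image), and
#' averages across frames.
#'
#' @param x An `rgc_stimulus` or a `frames x h x w` array.
#' @param crop Square crop size in pixels (default: the largest that
#'   fits).
#' @param frames Optional frame indices to use (default: all).
#' @param normalize If `TRUE`, normalize to the first non-DC bin.
#' @return A `radial_spectrum` data.frame (`frequency`, `power`) with
#'   attributes `counts`, `n`, `normalized`.
#' @export
stimulus_power_spectrum <- function(x, crop = NULL, frames = NULL,
                                    normalize = FALSE) {
  P <- .mean_power2d(x, crop, frames)
  n <- nrow(P)
  bins <- .radial_bins(n)
  out <- new_radial_spectrum(.radial_average(P, bins),
                             tabulate(as.vector(bins$bin) + 1L, bins$nbin),
                             n)
  if (normalize) normalize_spectrum(out) else out
}

# zero-pad a filter into the center of an n x n field
.pad_filter <- function(spatial, n) {
  spatial <- as.matrix(spatial)
  k <- nrow(spatial)
  if (k > n) stop("filter larger than the padded field")
  field <- matrix(0, n, n)
  o <- (n - k) %/% 2L
  field[o + seq_len(k), o + seq_len(k)] <- spatial
  field
}

#' Radially averaged transfer function of a spatial filter
#'
#' Zero-pads the filter (centered) into a `crop x crop` field, takes the
#' 2-D FFT, and radially averages the Fourier magnitudes.  Placement in
#' the padded field only changes phases, which the magnitude discards.
#'
#' @param spatial Spatial-filter matrix (side length <= `crop`).
#' @param crop Padded field size in pixels.
#' @param normalize If `TRUE`, normalize to the first non-DC bin.
#' @return A `radial_spectrum` with `kind = "magnitude"`.
#' @export
transfer_function <- function(spatial, crop, normalize = FALSE) {
  H <- Mod(stats::fft(.pad_filter(spatial, crop)))
  bins <- .radial_bins(crop)
  out <- new_radial_spectrum(.radial_average(H, bins),
                             tabulate(as.vector(bins$bin) + 1L, bins$nbin),
                             crop, kind = "magnitude")
  if (normalize) normalize_spectrum(out) else out
}

#' Power spectrum of a filtered stimulus
#'
#' Either circularly convolves every cropped frame with the filter and
#' computes the resulting power spectrum (`mode = "convolve"`), or
#' multiplies each frame's power spectrum with the filter's squared
#' transfer magnitude before radial averaging (`mode = "tf_product"`,
#' `domain = "power"`).  The two routes are mathematically identical by
#' the convolution theorem.  `domain = "amplitude"` multiplies with the
#' unsquared transfer magnitude instead.
#'
#' @param x An `rgc_stimulus` or a `frames x h x w` array.
#' @param spatial Spatial-filter matrix.
#' @param crop Square crop size (default: largest fitting).
#' @param mode Filtering route.
#' @param domain Transfer-magnitude domain for `tf_product`.
#' @param frames Optional frame indices.
#' @param normalize If `TRUE`, normalize to the first non-DC bin.
#' @return A `radial_spectrum`.
#' @export
filtered_spectrum <- function(x, spatial, crop = NULL,
                              mode = c("tf_product", "convolve"),
                              domain = c("power", "amplitude"),
                              frames = NULL, normalize = FALSE) {
  mode <- match.arg(mode); domain <- match.arg(domain)
  arr <- if (inherits(x, "rgc_stimulus")) x$frames else x
  d <- dim(arr)
  if (is.null(crop)) crop <- min(d[2], d[3])
  if (is.null(frames)) frames <- seq_len(d[1])
  H <- stats::fft(.pad_filter(spatial, crop))
  bins <- .radial_bins(crop)
  if (mode == "convolve") {
    r0 <- (d[2] - crop) %/% 2L; c0 <- (d[3] - crop) %/% 2L
    acc <- matrix(0, crop, crop)
    for (i in frames) {
      fr <- arr[i, r0 + seq_len(crop), c0 + seq_len(crop)]
      conv <- Re(stats::fft(stats::fft(fr) * H, inverse = TRUE)) / crop^2
      acc <- acc + Mod(stats::fft(conv))^2
    }
    P <- acc / length(frames)
  } else {
    P <- .mean_power2d(arr, crop, frames)
    P <- P * if (domain == "power") Mod(H)^2 else Mod(H)
  }
  out <- new_radial_spectrum(.radial_average(P, bins),
                             tabulate(as.vector(bins$bin) + 1L, bins$nbin),
                             crop)
  if (normalize) normalize_spectrum(out) else out
}

#' Whitening percentage of a filter
#'
#' With both spectra normalized to their first non-DC bin, the log-domain
#' distance of a spectrum from a flat reference is
#' `D(s, f) = |log10 s(f)|`.  The whitening percentage is evaluated at the
#' in-band frequency `f*` maximizing `D(unfiltered, f*) - D(filtered,
#' f*)`, and equals `100 * (D(unfiltered, f*) - D(filtered, f*)) /
#' D(unfiltered, f*)`: 100% means the filter flattened the spectrum
#' completely at the most-affected frequency, 0% means no effect, and
#' negative values mean the filter steepened it.
#'
#' @param unfiltered,filtered Radial spectra normalized to their first
#'   non-DC bin (renormalized here otherwise).
#' @param band Frequency range `c(lo, hi)` in cycles/image (non-DC).
#' @return The whitening percentage, with the chosen frequency in
#'   attribute `frequency`.
#' @export
whitening_percent <- function(unfiltered, filtered, band) {
  if (!isTRUE(attr(unfiltered, "normalized")))
    unfiltered <- normalize_spectrum(unfiltered)
  if (!isTRUE(attr(filtered, "normalized")))
    filtered <- normalize_spectrum(filtered)
  sel <- unfiltered$frequency >= max(1, band[1]) &
    unfiltered$frequency <= band[2]
  if (!any(sel)) stop("band contains no radial bins")
  f <- unfiltered$frequency[sel]
  du <- abs(log10(unfiltered$power[sel]))
  df_ <- abs(log10(filtered$power[match(f, filtered$frequency)]))
  gain <- du - df_
  i <- which.max(gain)
  if (du[i] == 0) stop("unfiltered spectrum is flat at the chosen frequency")
  structure(100 * gain[i] / du[i], frequency = f[i])
}

#' Receptive-field-relevant frequency band of a filter
#'
#' From the second radial bin up to the frequency at which the filter's
#' transfer magnitude has fallen to `threshold` of its peak.
#'
#' @param tf A transfer-function `radial_spectrum`.
#' @param threshold Fraction of the peak magnitude.
#' @return `c(lo, hi)` in cycles/image.
#' @export
band_from_transfer <- function(tf, threshold = 0.1) {
  nz <- tf$frequency >= 1
  mag <- tf$power[nz]; f <- tf$frequency[nz]
  keep <- f[mag >= threshold * max(mag)]
  c(2, max(2, max(keep)))
}

#' Construct efficient-coding simulated filters
#'
#' Builds four spatial filters from the central Gaussians of DoG fits to
#' mean receptive fields: a "white-noise" filter (small circular center,
#' no surround), a "low-pass" filter (large circular center, no surround),
#' and surround-augmented versions of both.  Centers have amplitude 1 and
#' an isotropic covariance whose diagonal equals the largest diagonal
#' entry of the corresponding fit.  Surround amplitude and isotropic width
#' are chosen by grid search (amplitude 0.05..1 step 0.05; width scale
#' 1.2..4 step 0.2 relative to the center) to minimize the in-band maximum
#' `|log10 filtered power|` of the target spectrum under transfer-function
#' filtering — a reproducible stand-in for manual tuning.
#'
#' @param fit_small,fit_large `posthoc_dog_fit`s to the mean midget-like
#'   and parasol-like receptive fields.
#' @param target_spectrum A normalized `radial_spectrum` of the movie
#'   stimulus.
#' @param band Optional frequency band; defaults to the
#'   receptive-field-relevant band of each center's transfer function.
#' @param grid_size Side length of the rendered filters.
#' @param amp_grid,width_grid Surround search grids.
#' @return A list of four `simulated_filter`s (fields `kind`, `center`,
#'   `surround` (or NULL), `image`, `objective`).
#' @export
make_simulated_filters <- function(fit_small, fit_large, target_spectrum,
                                   band = NULL, grid_size = 15L,
                                   amp_grid = seq(0.05, 1, by = 0.05),
                                   width_grid = seq(1.2, 4, by = 0.2)) {
  if (!isTRUE(attr(target_spectrum, "normalized")))
    target_spectrum <- normalize_spectrum(target_spectrum)
  n <- attr(target_spectrum, "n")
  flatness <- function(img, bd) {
    tf <- transfer_function(img, n)
    filt <- target_spectrum
    sel <- filt$frequency >= bd[1] & filt$frequency <= bd[2] &
      tf$power > 0
    p <- filt$power[sel] * tf$power[sel]^2
    p <- p / (filt$power[filt$frequency == 1] *
                tf$power[tf$frequency == 1]^2)
    max(abs(log10(p)))
  }
  one_base <- function(fit, label) {
    s2 <- max(diag(fit$cov_c))
    center <- list(amplitude = 1, mean = c((grid_size + 1) / 2,
                                           (grid_size + 1) / 2),
                   cov = s2 * diag(2))
    img_c <- render_spatial(center, grid_size)
    bd <- if (is.null(band))
      band_from_transfer(transfer_function(img_c, n)) else band
    base <- structure(list(kind = label, center = center, surround = NULL,
                           image = img_c, objective = flatness(img_c, bd),
                           band = bd),
                      class = "simulated_filter")
    best <- NULL
    for (a in amp_grid) for (wsc in width_grid) {
      surround <- list(amplitude = a, mean = center$mean,
                       cov = s2 * wsc^2 * diag(2))
      img <- img_c - render_spatial(surround, grid_size)
      obj <- flatness(img, bd)
      if (is.null(best) || obj < best$objective)
        best <- structure(list(kind = paste0(label, "_with_surround"),
                               center = center, surround = surround,
                               image = img, objective = obj, band = bd),
                          class = "simulated_filter")
    }
    if (is.null(best) || best$objective >= base$objective) {
      warning("no surround improved in-band flatness; returning the ",
              "surroundless filter")
      best <- base
      best$kind <- paste0(label, "_with_surround")
    }
    list(base, best)
  }
  c(one_base(fit_small, "white_noise_like"),
    one_base(fit_large, "low_pass"))
}
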