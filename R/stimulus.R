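#' Stimulus geometry
#'
#' Describes the presentation geometry shared by all stimuli: the screen
#' raster, the coarser stimulus-pixel grid used for white noise, the physical
#' pixel pitch and the refresh rate at which responses are binned.
#'
#' @param screen_height,screen_width Screen raster size in screen pixels.
#' @param stim_pixel_factor Screen pixels per stimulus pixel along each axis
#'   (white-noise checkers are constant on `factor x factor` blocks).
#' @param pixel_pitch Physical size of one screen pixel in micrometers.
#' @param frame_rate Stimulus refresh rate in Hz; spike counts are binned at
#'   this resolution.
#'
#' @return An object of class `stim_geometry`.
#' @examples
#' geom <- stim_geometry(120, 160, 4, 7.5, 85)
#' @export
stim_geometry <- function(screen_height = 120L, screen_width = 160L,
                          stim_pixel_factor = 4L, pixel_pitch = 7.5,
                          frame_rate = 85) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (screen_height < 1 || screen_width < 1 || stim_pixel_factor < 1)
    stop("screen dimensions and stim_pixel_factor must be positive")
  structure(list(
    screen_height = as.integer(screen_height),
    screen_width = as.integer(screen_width),
    stim_pixel_factor = as.integer(stim_pixel_factor),
    pixel_pitch = pixel_pitch,
    frame_rate = frame_rate
  ), class = "stim_geometry")
}

# stimulus-pixel grid dimensions; errors when divisibility is required but absent
stim_grid_dims <- function(geometry, require_divisible = TRUE) {
  f <- geometry$stim_pixel_factor
  if (require_divisible &&
      (geometry$screen_height %% f != 0 || geometry$screen_width %% f != 0))
    stop("screen dimensions must be divisible by stim_pixel_factor")
  c(h = geometry$screen_height %/% f, w = geometry$screen_width %/% f)
}

#' Area conversion from stimulus pixels squared to micrometers squared
#'
#' @param area_px2 Area in stimulus pixels squared.
#' @param geometry A [stim_geometry()].
#' @return Area in square micrometers.
#' @export
px2_to_um2 <- function(area_px2, geometry) {
  area_px2 * (geometry$stim_pixel_factor * geometry$pixel_pitch)^2
}

new_stimulus <- function(frames, geometry, trials, ensemble) {
  stopifnot(length(dim(frames)) == 3)
  stim <- structure(list(
    frames = frames, geometry = geometry, trials = trials,
    ensemble = ensemble
  ), class = "rgc_stimulus")
  validate_stimulus(stim)
  stim
}

validate_stimulus <- function(stim) {
  nf <- dim(stim$frames)[1]
  all_idx <- integer(0)
  for (tr in stim$trials) {
    for (seg in tr[c("non_repeating", "repeating")]) {
      if (is.null(seg) || length(seg) == 0) next
      if (seg[1] > seg[2] + 1) stop("malformed segment range")
      if (seg[2] >= seg[1]) {
        if (seg[1] < 1 || seg[2] > nf) stop("trial range out of bounds")
        all_idx <- c(all_idx, seg[1]:seg[2])
      }
    }
  }
  if (anyDuplicated(all_idx)) stop("trial ranges overlap")
  invisible(stim)
}

#' @export
print.rgc_stimulus <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<rgc_stimulus: %s, %d frames of %dx%d, %d trials>\n",
              x$ensemble, d[1], d[2], d[3], length(x$trials)))
  invisible(x)
}

#' Number of frames in a stimulus
#' @param stimulus An `rgc_stimulus`.
#' @return Integer frame count.
#' @export
n_frames <- function(stimulus) dim(stimulus$frames)[1]

#' Segment ranges of a stimulus
#'
#' Returns the frame-index ranges of the requested segment kind, one
#' `c(start, end)` per trial, skipping empty segments.
#'
#' @param stimulus An `rgc_stimulus`.
#' @param which One of `"non_repeating"`, `"repeating"`, `"all"`.
#' @return A list of integer 2-vectors.
#' @export
stimulus_segments <- function(stimulus,
                              which = c("non_repeating", "repeating", "all")) {
  which <- match.arg(which)
  kinds <- if (which == "all") c("non_repeating", "repeating") else which
  segs <- list()
  for (tr in stimulus$trials) {
    for (k in kinds) {
      seg <- tr[[k]]
      if (!is.null(seg) && length(seg) == 2 && seg[2] >= seg[1])
        segs[[length(segs) + 1L]] <- as.integer(seg)
    }
  }
  segs
}

# total non-repeating frame count
n_non_repeating <- function(stimulus) {
  sum(vapply(stimulus_segments(stimulus, "non_repeating"),
             function(s) s[2] - s[1] + 1L, integer(1)))
}

#' Expand stimulus frames to the screen-pixel raster
#'
#' Frames are stored on the stimulus-pixel grid; this reproduces the
#' screen-resolution view in which each stimulus pixel is a constant
#' `factor x factor` block of screen pixels.
#'
#' @param stimulus An `rgc_stimulus`.
#' @param idx Frame indices to expand (default: all).
#' @return Array `length(idx) x screen_height x screen_width`.
#' @export
expand_frames <- function(stimulus, idx = seq_len(n_frames(stimulus))) {
  f <- stimulus$geometry$stim_pixel_factor
  d <- dim(stimulus$frames)
  out <- array(0, c(length(idx), d[2] * f, d[3] * f))
  ones <- matrix(1, f, f)
  for (i in seq_along(idx))
    out[i, , ] <- kronecker(stimulus$frames[idx[i], , ], ones)
  out
}

#' Crop a stimulus around a receptive-field center
#'
#' Extracts a square window (default 15 x 15 stimulus pixels) around a
#' center, shifting the window inward when it would leave the frame.  The
#' cropped frames are returned flattened (one row per frame, pixels in
#' column-major (row, col) order) for efficient filtering.
#'
#' @param stimulus An `rgc_stimulus`.
#' @param center Integer `(row, col)` in stimulus-pixel coordinates.
#' @param size Window side length in stimulus pixels.
#' @return A list with `X` (frames x size^2 matrix), `size`, `offset` (the
#'   global coordinates of the window's (1,1) pixel), and `center_local`
#'   (the requested center in window-local coordinates).
#' @export
crop_stimulus <- function(stimulus, center, size = 15L) {
  d <- dim(stimulus$frames)
  if (d[2] < size || d[3] < size)
    stop("stimulus too small to crop ", size, "x", size)
  half <- (size - 1L) %/% 2L
  r0 <- min(max(as.integer(center[1]) - half, 1L), d[2] - size + 1L)
  c0 <- min(max(as.integer(center[2]) - half, 1L), d[3] - size + 1L)
  sub <- stimulus$frames[, r0:(r0 + size - 1L), c0:(c0 + size - 1L), drop = FALSE]
  X <- matrix(sub, nrow = d[1])
  list(X = X, size = as.integer(size), offset = c(r0, c0),
       center_local = c(center[1] - r0 + 1L, center[2] - c0 + 1L))
}

# assemble frames/trial bookkeeping shared by the generators:
# blocks is a list with per-trial train arrays and one shared test array
assemble_trials <- function(train_blocks, test_block, geometry, ensemble) {
  n_trials <- length(train_blocks)
  n_train <- unname(dim(train_blocks[[1]])[1])
  n_test <- unname(dim(test_block)[1])
  d <- unname(dim(test_block)[2:3])
  frames <- array(0, c(n_trials * (n_train + n_test), d[1], d[2]))
  trials <- vector("list", n_trials)
  pos <- 0L
  for (k in seq_len(n_trials)) {
    if (n_train > 0) frames[pos + seq_len(n_train), , ] <- train_blocks[[k]]
    if (n_test > 0) frames[pos + n_train + seq_len(n_test), , ] <- test_block
    trials[[k]] <- list(
      non_repeating = c(pos + 1L, pos + n_train),
      repeating = c(pos + n_train + 1L, pos + n_train + n_test)
    )
    pos <- pos + n_train + n_test
  }
  new_stimulus(frames, geometry, trials, ensemble)
}
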