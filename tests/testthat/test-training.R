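test_that("the STA is the spike-weighted history average", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 1, 3, 0, seed = 81)
  nfr <- n_frames(wn)
  t_spk <- 120L
  counts <- integer(nfr); counts[t_spk] <- 1L
  resp <- structure(list(counts = counts, cell_id = "a"),
                    class = "spike_response")
  sta <- compute_sta(wn, resp, delta = 30)
  for (l in 0:29)
    expect_equal(sta$sta[l + 1, , ], wn$frames[t_spk - l, , ])
  expect_equal(sta$n_spikes, 1)

  # scaling every count leaves the (count-normalized) STA unchanged
  set.seed(82)
  counts2 <- rpois(nfr, 0.2)
  r1 <- structure(list(counts = counts2, cell_id = "a"),
                  class = "spike_response")
  r2 <- structure(list(counts = 2L * counts2, cell_id = "a"),
                  class = "spike_response")
  expect_equal(compute_sta(wn, r1)$sta, compute_sta(wn, r2)$sta)

  r0 <- structure(list(counts = integer(nfr), cell_id = "a"),
                  class = "spike_response")
  expect_error(compute_sta(wn, r0), "no spikes")
})

test_that("the STA recovers a simulated cell's receptive field", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 1, 1200, 0, seed = 83)
  p <- make_test_dog(alpha = 25)
  cell <- list(cell_id = "c", cell_type_label = "t", polarity = "OFF",
               params_wn = p, params_nm = p)
  resp <- simulate_rgc(cell, wn, seed = 84)
  sta <- compute_sta(wn, resp, delta = 30)
  # tiny geometry: the stimulus grid IS the 15x15 crop
  rf <- build_spatiotemporal_rf(p)
  expect_gt(cor(as.vector(sta$sta), as.vector(rf)), 0.8)
  expect_lte(max(abs(sta$crop_center - c(8, 8))), 1)
})

test_that("train/validation splits are shuffled exhaustive partitions", {
  sp <- split_train_val(10, 0.8, seed = 85)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  expect_identical(sort(c(sp$train, sp$val)), 1:10)
  expect_identical(split_train_val(10, 0.8, seed = 85), sp)
  expect_false(identical(split_train_val(10, 0.8, seed = 86), sp))
  expect_error(split_train_val(1, 0.8), "at least 2")
  expect_error(split_train_val(3, 0.05), "empty")
})

test_that("fit bookkeeping: epoch bounds, best epoch, learning-rate path", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 2, 4, 1, seed = 87)
  pop <- make_ground_truth_population(midget_group(1), geom, seed = 88)
  resp <- simulate_rgc(pop[[1]], wn, seed = 89)

  f1 <- fit_ln("dog", wn, resp,
               quick_cfg("white_noise", 90, max_epochs = 1,
                         val_fraction = 0.5))
  expect_equal(nrow(f1$history), 1)

  cfg <- quick_cfg("white_noise", 90, max_epochs = 40, early_stop = 6,
                   sched = 3, val_fraction = 0.5)
  f <- fit_ln("dog", wn, resp, cfg)
  h <- f$history
  expect_equal(h$val_cc[f$best_epoch], max(h$val_cc, na.rm = TRUE))
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr >= cfg$lr_min))
  # stop no later than patience epochs past the best epoch
  expect_lte(nrow(h), f$best_epoch + cfg$early_stop_patience)
})

test_that("frame equalization trims only trailing non-repeating frames", {
  geom <- stim_geometry(40L, 40L, 4L)
  a <- generate_white_noise(geom, 2, 2, 0.5, seed = 91)    # 340 nr frames
  b <- generate_white_noise(geom, 2, 1.2, 0.5, seed = 92)  # 204 nr frames
  eq <- equalize_training_frames(a, b)
  na <- sum(vapply(stimulus_segments(eq$a, "non_repeating"),
                   function(s) s[2] - s[1] + 1L, integer(1)))
  nb <- sum(vapply(stimulus_segments(eq$b, "non_repeating"),
                   function(s) s[2] - s[1] + 1L, integer(1)))
  expect_equal(na, 204)
  expect_equal(nb, 204)
  # repeating ranges untouched; equal-count inputs pass through unchanged
  expect_identical(lapply(eq$a$trials, `[[`, "repeating"),
                   lapply(a$trials, `[[`, "repeating"))
  eq2 <- equalize_training_frames(b, eq$b)
  expect_identical(eq2$a$trials, b$trials)
  # trailing trial emptied first when the excess exceeds it
  c3 <- generate_white_noise(geom, 3, 2, 0.5, seed = 93)   # 510 nr frames
  eq3 <- equalize_training_frames(c3, b)
  expect_identical(stimulus_segments(eq3$a, "non_repeating")[[2]][2] -
                     stimulus_segments(eq3$a, "non_repeating")[[2]][1] + 1L,
                   34L)
  expect_length(stimulus_segments(eq3$a, "non_repeating"), 2)
})

test_that("adapting to the same ensemble barely changes performance", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 4, 25, 3, seed = 94)
  pop <- make_ground_truth_population(midget_group(3), geom, seed = 95)
  deltas <- vapply(seq_along(pop), function(i) {
    resp <- simulate_rgc(pop[[i]], wn, seed = 950 + i)
    f <- fit_ln("dog", wn, resp,
                quick_cfg("white_noise", 960 + i, max_epochs = 60))
    ad <- adapt_ood(f, wn, resp,
                    quick_cfg("adapt", 970 + i, max_epochs = 40))
    abs(test_correlation(ad, wn, resp)$cc -
          test_correlation(f, wn, resp)$cc)
  }, numeric(1))
  expect_lt(median(deltas), 0.02)
})

test_that("parameter recovery improves with recording length", {
  geom <- tiny_geometry()
  wn_long <- generate_white_noise(geom, 1, 600, 0, seed = 96)
  wn_short <- generate_white_noise(geom, 1, 120, 0, seed = 96)
  errs <- vapply(1:5, function(s) {
    pop <- make_ground_truth_population(midget_group(1), geom,
                                        seed = 9600 + s)
    cell <- pop[[1]]
    vapply(list(wn_short, wn_long), function(stim) {
      # single-trial stimuli cannot be split; carve the trial into two
      stim$trials <- list(
        list(non_repeating = c(1L, n_frames(stim) %/% 2L),
             repeating = c(0L, -1L)),
        list(non_repeating = c(n_frames(stim) %/% 2L + 1L, n_frames(stim)),
             repeating = c(0L, -1L)))
      resp <- simulate_rgc(cell, stim, seed = 9700 + s)
      f <- fit_ln("dog", stim, resp,
                  quick_cfg("white_noise", 9800 + s, max_epochs = 30,
                            val_fraction = 0.5))
      truth_gc <- global_center(cell$params_wn, stim)
      sqrt(sum((global_center(f) - truth_gc)^2))
    }, numeric(1))
  }, numeric(2))
  expect_lte(median(errs[2, ]), median(errs[1, ]))
})

test_that("a rank-one fit approaches the oracle correlation", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 6, 60, 3, seed = 97)
  spatial <- render_spatial(list(amplitude = -0.8, mean = c(8, 7.5),
                                 cov = diag(2) * 1.6^2), 15)
  truth <- rank_one_ln_params(spatial, temporal_kernel_test(4), alpha = 10,
                              beta = 0, crop_center = c(8L, 8L),
                              polarity = -1)
  crop <- crop_stimulus(wn, truth$crop_center)
  segs <- stimulus_segments(wn, "all")
  rate <- predict_rate(truth, crop$X, segments = segs)
  set.seed(98)
  counts <- integer(n_frames(wn))
  ok <- !is.na(rate)
  counts[ok] <- rpois(sum(ok), rate[ok] / 85)
  resp <- structure(list(counts = counts, cell_id = "r1"),
                    class = "spike_response")
  cfg <- quick_cfg("white_noise", 99, max_epochs = 150, early_stop = 30,
                   sched = 15)
  f <- fit_ln("rank_one", wn, resp, cfg)
  # oracle: validation correlation of the true parameters on the same split
  split <- split_train_val(wn$trials, 0.8, cfg$seed)
  vsegs <- stimulus_segments(wn, "non_repeating")[split$val]
  vr <- predict_rate(truth, crop$X, segments = vsegs)
  okv <- !is.na(vr)
  oracle <- cor(vr[okv], counts[okv])
  expect_gt(max(f$history$val_cc, na.rm = TRUE), oracle - 0.05)
})
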