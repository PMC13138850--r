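test_that("white noise is block-constant, trial-structured and seeded", {
  geom <- stim_geometry(40L, 40L, 4L)
  s <- generate_white_noise(geom, n_trials = 2, train_seconds = 1,
                            test_seconds = 0.5, seed = 11)
  expect_equal(dim(s$frames), c(2 * (85 + 42), 10, 10))

  # screen-resolution view is constant on 4x4 blocks by construction
  big <- expand_frames(s, idx = 1:2)
  expect_equal(big[1, , ], kronecker(s$frames[1, , ], matrix(1, 4, 4)))

  # repeating segment identical across trials, non-repeating differs
  t1 <- s$trials[[1]]; t2 <- s$trials[[2]]
  expect_identical(s$frames[t1$repeating[1]:t1$repeating[2], , ],
                   s$frames[t2$repeating[1]:t2$repeating[2], , ])
  expect_false(identical(s$frames[t1$non_repeating[1]:t1$non_repeating[2], , ],
                         s$frames[t2$non_repeating[1]:t2$non_repeating[2], , ]))

  # trial bookkeeping covers every frame exactly once
  idx <- sort(unlist(lapply(stimulus_segments(s, "all"),
                            function(r) r[1]:r[2])))
  expect_identical(idx, seq_len(n_frames(s)))

  # seeded determinism; different seeds differ
  s2 <- generate_white_noise(geom, 2, 1, 0.5, seed = 11)
  expect_identical(s$frames, s2$frames)
  s3 <- generate_white_noise(geom, 2, 1, 0.5, seed = 12)
  expect_false(identical(s$frames, s3$frames))

  # indivisible geometry is a configuration error
  expect_error(generate_white_noise(stim_geometry(42L, 40L, 4L), 2, 1, 0.5),
               "divisible")
})

test_that("white-noise sample moments match the stated marginal", {
  geom <- stim_geometry(40L, 40L, 4L)
  contrast <- 0.7
  s <- generate_white_noise(geom, 2, 2, 0.5, contrast = contrast, seed = 3)
  v <- as.vector(s$frames)          # > 4e4 block draws
  expect_true(all(v %in% c(-contrast, contrast)))
  se <- contrast / sqrt(length(v))
  expect_lt(abs(mean(v)), 3 * se)
  expect_lt(abs(var(v) - contrast^2) / contrast^2, 0.05)

  g <- generate_white_noise(geom, 2, 2, 0.5, contrast = contrast,
                            distribution = "gaussian", seed = 3)
  vg <- as.vector(g$frames)
  expect_lt(abs(mean(vg)), 3 * se)
  expect_lt(abs(var(vg) - contrast^2) / contrast^2, 0.05)
})

test_that("natural surrogate has a 1/f^2 spectrum and seeded gaze/content", {
  nm <- fixture_nm_spectral()
  sp <- stimulus_power_spectrum(nm, crop = 60,
                                frames = seq(1, n_frames(nm), by = 4))
  sel <- sp$frequency >= 3 & sp$frequency <= 20
  slope <- coef(lm(log10(sp$power[sel]) ~ log10(sp$frequency[sel])))[2]
  expect_gt(slope, -2.4)
  expect_lt(slope, -1.6)

  # radial power non-increasing after 3-bin smoothing
  nz <- sp$power[sp$frequency >= 1 & sp$frequency <= 30]
  sm <- stats::filter(nz, rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-12))

  # frames are mean-zero contrast units with the requested scale
  expect_lt(abs(mean(nm$frames)), 0.05)
  expect_lt(abs(sd(as.vector(nm$frames)) - 1), 0.1)

  # frozen gaze and frozen content => identical frames within a segment
  geom <- stim_geometry(40L, 40L, 4L)
  frozen <- generate_natural_surrogate(geom, 1, 0.5, 0.2, jitter_sd = 0,
                                       temporal_corr = 1, seed = 5)
  seg <- frozen$trials[[1]]$non_repeating
  for (i in (seg[1] + 1):seg[2])
    expect_identical(frozen$frames[i, , ], frozen$frames[seg[1], , ])

  a <- generate_natural_surrogate(geom, 2, 0.5, 0.2, seed = 9)
  b <- generate_natural_surrogate(geom, 2, 0.5, 0.2, seed = 9)
  expect_identical(a$frames, b$frames)
})

test_that("simulate_rgc realizes the LN-Poisson forward model", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 2, 3, 1, seed = 21)

  # all-zero filters: constant rate alpha * log(1 + e^beta) in every bin
  p0 <- make_test_dog(surround = 0)
  p0$amp1 <- 0; p0$amp2 <- 0
  cell0 <- list(cell_id = "z", cell_type_label = "t", polarity = "OFF",
                params_wn = p0, params_nm = p0)
  crop <- crop_stimulus(wn, p0$crop_center)
  r <- predict_rate(p0, crop$X, segments = stimulus_segments(wn, "all"))
  f0 <- p0$alpha * log1p(exp(p0$beta))
  expect_equal(unique(r[!is.na(r)]), f0)

  # empirical Poisson mean over >= 1e5 bins within 3 SE of rate/frame_rate
  long <- generate_white_noise(geom, 1, 1180, 0, seed = 22)
  resp <- simulate_rgc(cell0, long, seed = 23)
  lam <- f0 / 85
  n_valid <- n_frames(long) - 29
  expect_gte(n_valid, 1e5)
  se <- sqrt(lam / n_valid)
  expect_lt(abs(sum(resp$counts) / n_valid - lam), 3 * se)

  # doubling contrast doubles the pre-nonlinearity drive exactly
  p <- make_test_dog()
  d1 <- predict_rate(p, crop$X, rate = FALSE)
  d2 <- predict_rate(p, crop$X * 2, rate = FALSE)
  expect_equal(d2, 2 * d1)

  # determinism and trial-independent noise on the repeating segment
  cell <- list(cell_id = "c", cell_type_label = "t", polarity = "OFF",
               params_wn = p, params_nm = p)
  r1 <- simulate_rgc(cell, wn, seed = 31)
  r2 <- simulate_rgc(cell, wn, seed = 31)
  expect_identical(r1$counts, r2$counts)
  rep1 <- r1$counts[wn$trials[[1]]$repeating[1]:wn$trials[[1]]$repeating[2]]
  rep2 <- r1$counts[wn$trials[[2]]$repeating[1]:wn$trials[[2]]$repeating[2]]
  expect_false(identical(rep1, rep2))

  # an ensemble without matching ground-truth parameters is a config error
  user <- wn; user$ensemble <- "user"
  expect_error(simulate_rgc(cell, user, seed = 1), "no ground-truth")
})

test_that("ground-truth populations respect the adapt switch", {
  geom <- desk_geometry()
  pop0 <- make_ground_truth_population(geometry = geom, adapt = FALSE,
                                       seed = 41)
  for (cell in pop0) expect_identical(cell$params_wn, cell$params_nm)

  pop1 <- make_ground_truth_population(geometry = geom, adapt = TRUE,
                                       seed = 41)
  for (cell in pop1) {
    if (cell$cell_type_label == "midget_like")
      expect_gt(center_size_dog(cell$params_nm),
                center_size_dog(cell$params_wn))
    else
      expect_equal(center_size_dog(cell$params_nm),
                   center_size_dog(cell$params_wn), tolerance = 1e-8)
    # movie surround relatively stronger for every cell
    expect_gt(abs(cell$params_nm$amp2) / abs(cell$params_nm$amp1),
              abs(cell$params_wn$amp2) / abs(cell$params_wn$amp1))
    expect_equal(sign(cell$params_wn$amp1), cell$params_wn$polarity)
  }

  pop2 <- make_ground_truth_population(geometry = geom, adapt = TRUE,
                                       seed = 41)
  expect_identical(pop1, pop2)
})

test_that("simulated data favors the true parameters in likelihood", {
  geom <- tiny_geometry()
  wn <- generate_white_noise(geom, 1, 150, 0, seed = 51)
  p <- make_test_dog()
  crop <- crop_stimulus(wn, p$crop_center)
  segs <- stimulus_segments(wn, "all")
  rate_true <- predict_rate(p, crop$X, segments = segs)
  pp <- p; pp$amp1 <- pp$amp1 * 1.1           # 10% perturbation
  rate_pert <- predict_rate(pp, crop$X, segments = segs)
  ok <- !is.na(rate_true)
  lam_t <- rate_true[ok] / 85
  lam_p <- rate_pert[ok] / 85
  wins <- vapply(1:100, function(k) {
    set.seed(6000 + k)
    y <- rpois(length(lam_t), lam_t)
    sum(dpois(y, lam_t, log = TRUE)) > sum(dpois(y, lam_p, log = TRUE))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
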