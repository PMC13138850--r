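#' Default pipeline configuration
#'
#' A single declarative configuration carrying every constant of the
#' analysis as a named default: geometry (85 Hz refresh, 4x4 screen pixels
#' per stimulus pixel, 7.5 µm pitch), desk-scale trial structure (6 trials
#' of 20 s non-repeating + 5 s repeating frames per ensemble), the
#' ground-truth population, the training hyperparameters (learning rates
#' 0.009/0.005/0.001, patiences 30/15, floor 1e-7, epsilon 1e-12 inside
#' the loss), and the analysis windows (±6-frame surround search, 1e-4
#' surround clip).
#'
#' @return A nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    geometry = list(screen_height = 120L, screen_width = 160L,
                    stim_pixel_factor = 4L, pixel_pitch = 7.5,
                    frame_rate = 85),
    white_noise = list(n_trials = 6L, train_seconds = 20, test_seconds = 5,
                       contrast = 1, distribution = "binary"),
    natural_surrogate = list(n_trials = 6L, train_seconds = 20,
                             test_seconds = 5, contrast = 1, jitter_sd = 2,
                             temporal_corr = 0.9),
    population = list(adapt = TRUE, groups = NULL),
    fit = list(max_epochs = 500L, early_stop_patience = 30L,
               scheduler_patience = 15L, lr_min = 1e-7, lr_decay = 0.1,
               batch_bins = 256L, val_fraction = 0.8),
    models = "dog",
    analysis = list(window = 6L, clip_below = 1e-4, spectrum_crop = NULL,
                    spectrum_frames = 200L, band = NULL,
                    small_type = "midget_like", large_type = "parasol_like")
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override [default_run_config()] recursively.
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  utils::modifyList(default_run_config(), yaml::read_yaml(path))
}

.pipeline_stages <- c("simulate", "fit", "adapt", "evaluate", "rf",
                      "spectra", "report")

#' Deterministic per-stage child seed
#'
#' Every pipeline stage draws its randomness from a child seed derived from
#' the master seed and the stage name, so stages are reproducible in
#' isolation and a resumed run reuses the recorded seeds.
#'
#' @param master Master integer seed.
#' @param stage One of the pipeline stage names.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  idx <- match(stage, .pipeline_stages)
  as.integer((as.numeric(master) * 131 + idx * 10007) %%
               .Machine$integer.max)
}

.write_manifest <- function(out_dir, manifest) {
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
}

.geometry_from_config <- function(config) {
  do.call(stim_geometry, config$geometry)
}

.fit_cfg <- function(config, ensemble, seed) {
  do.call(fit_config, c(list(ensemble = ensemble, seed = seed),
                        config$fit))
}

.write_table <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

.spectrum_to_df <- function(spec, label) {
  data.frame(label = label, frequency = spec$frequency, power = spec$power)
}

#' Run the full synthetic adaptation analysis
#'
#' Orchestrates simulate -> fit -> adapt -> evaluate -> receptive-field
#' metrics -> spectra -> report.  Every stage draws its randomness from a
#' named child seed of the master seed, records completion in
#' `manifest.json`, writes its tabular results as CSV/JSON under
#' `out_dir`, and caches its R objects as RDS so that [resume()] can skip
#' completed stages.  Outputs: `population.json`, `fit_histories.csv`,
#' `fitted_params.json`, `evaluation.csv`, `id_ood_summary.csv`,
#' `rf_metrics.csv`, `rf_comparison.csv`, `spectra.csv`,
#' `whitening.csv`, `summary.json`.
#'
#' @param config A configuration list, see [default_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param resume Internal; use [resume()].
#' @return `out_dir`, invisibly.
#' @export
run_all <- function(config = default_run_config(), out_dir,
                    resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(config[names(config) != "out_dir"])
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- list(config_hash = hash,
                   version = as.character(utils::packageVersion("rgcadapt")),
                   seed = config$seed,
                   stage_seeds = as.list(stats::setNames(
                     vapply(.pipeline_stages, stage_seed,
                            integer(1), master = config$seed),
                     .pipeline_stages)),
                   stages = stats::setNames(
                     as.list(rep(FALSE, length(.pipeline_stages))),
                     .pipeline_stages),
                   timestamps = list())
  if (resume) {
    if (!file.exists(man_path)) stop("no manifest to resume from")
    old <- jsonlite::read_json(man_path)
    if (!identical(old$config_hash, hash))
      stop("config hash mismatch; refusing to resume")
    manifest$stages <- lapply(old$stages, isTRUE)
    manifest$timestamps <- old$timestamps
  }
  stage_files <- list(
    simulate = c("sim.rds", "population.json"),
    fit = c("fits.rds", "fit_histories.csv", "fitted_params.json"),
    adapt = "adapts.rds",
    evaluate = c("evaluation.csv", "id_ood_summary.csv"),
    rf = c("rf_metrics.csv", "rf_comparison.csv"),
    spectra = c("spectra.csv", "whitening.csv"),
    report = "summary.json")
  done <- function(stage) {
    isTRUE(manifest$stages[[stage]]) &&
      all(file.exists(file.path(out_dir, stage_files[[stage]])))
  }
  finish <- function(stage) {
    manifest$stages[[stage]] <<- TRUE
    manifest$timestamps[[stage]] <<- format(Sys.time(), tz = "UTC")
    .write_manifest(out_dir, manifest)
  }
  cache <- function(name) file.path(out_dir, paste0(name, ".rds"))
  geom <- .geometry_from_config(config)

  ## -- simulate ------------------------------------------------------------
  if (!done("simulate")) {
    s <- stage_seed(config$seed, "simulate")
    message("[simulate] generating stimuli and responses")
    wn <- do.call(generate_white_noise,
                  c(list(geometry = geom, seed = s), config$white_noise))
    nm <- do.call(generate_natural_surrogate,
                  c(list(geometry = geom, seed = s + 1L),
                    config$natural_surrogate))
    eq <- equalize_training_frames(wn, nm)
    wn <- eq$a; nm <- eq$b
    groups <- config$population$groups
    if (is.null(groups)) groups <- default_population_spec()
    pop <- make_ground_truth_population(groups, geom,
                                        adapt = isTRUE(config$population$adapt),
                                        seed = s + 2L)
    resp_wn <- lapply(seq_along(pop), function(i)
      simulate_rgc(pop[[i]], wn, seed = s + 100L + i))
    resp_nm <- lapply(seq_along(pop), function(i)
      simulate_rgc(pop[[i]], nm, seed = s + 500L + i))
    sim <- list(wn = wn, nm = nm, pop = pop, resp_wn = resp_wn,
                resp_nm = resp_nm)
    saveRDS(sim, cache("sim"))
    writeLines(vapply(pop, function(cell) as.character(jsonlite::toJSON(
      list(cell_id = cell$cell_id, type = cell$cell_type_label,
           polarity = cell$polarity,
           params_wn = jsonlite::fromJSON(params_to_json(cell$params_wn)),
           params_nm = jsonlite::fromJSON(params_to_json(cell$params_nm))),
      digits = NA, auto_unbox = TRUE)), character(1)),
      file.path(out_dir, "population.json"))
    finish("simulate")
  } else sim <- readRDS(cache("sim"))

  ## -- fit -----------------------------------------------------------------
  if (!done("fit")) {
    s <- stage_seed(config$seed, "fit")
    message("[fit] fitting LN models on both ensembles")
    fits <- list(); hists <- list()
    for (mk in config$models) {
      fits[[mk]] <- lapply(seq_along(sim$pop), function(i) {
        sta <- compute_sta(sim$wn, sim$resp_wn[[i]])
        tv <- sta$sta[, sta$crop_center[1], sta$crop_center[2]]
        pol <- sign(tv[which.max(abs(tv))]); if (pol == 0) pol <- 1
        f_wn <- fit_ln(mk, sim$wn, sim$resp_wn[[i]],
                       .fit_cfg(config, "white_noise", s + i),
                       crop_center = sta$crop_center, polarity = pol)
        f_nm <- fit_ln(mk, sim$nm, sim$resp_nm[[i]],
                       .fit_cfg(config, "natural_surrogate", s + i),
                       crop_center = sta$crop_center, polarity = pol)
        list(wn = f_wn, nm = f_nm)
      })
      for (i in seq_along(sim$pop)) for (ens in c("wn", "nm")) {
        h <- fits[[mk]][[i]][[ens]]$history
        h$model <- mk; h$cell_id <- sim$pop[[i]]$cell_id; h$ensemble <- ens
        hists[[length(hists) + 1L]] <- h
      }
    }
    saveRDS(fits, cache("fits"))
    .write_table(do.call(rbind, hists), out_dir, "fit_histories.csv")
    writeLines(unlist(lapply(names(fits), function(mk)
      vapply(seq_along(fits[[mk]]), function(i)
        as.character(jsonlite::toJSON(list(
          model = mk, cell_id = sim$pop[[i]]$cell_id,
          wn = jsonlite::fromJSON(params_to_json(fits[[mk]][[i]]$wn$params)),
          nm = jsonlite::fromJSON(params_to_json(fits[[mk]][[i]]$nm$params))),
          digits = NA, auto_unbox = TRUE)), character(1)))),
      file.path(out_dir, "fitted_params.json"))
    finish("fit")
  } else fits <- readRDS(cache("fits"))

  ## -- adapt ---------------------------------------------------------------
  if (!done("adapt")) {
    s <- stage_seed(config$seed, "adapt")
    message("[adapt] out-of-domain adaptation with frozen spatial filters")
    adapts <- lapply(fits, function(model_fits)
      lapply(seq_along(model_fits), function(i) {
        cfg <- .fit_cfg(config, "adapt", s + i)
        list(
          wn_to_nm = adapt_ood(model_fits[[i]]$wn, sim$nm,
                               sim$resp_nm[[i]], cfg),
          nm_to_wn = adapt_ood(model_fits[[i]]$nm, sim$wn,
                               sim$resp_wn[[i]], cfg)
        )
      }))
    saveRDS(adapts, cache("adapts"))
    finish("adapt")
  } else adapts <- readRDS(cache("adapts"))

  ## -- evaluate ------------------------------------------------------------
  if (!done("evaluate")) {
    message("[evaluate] test-set correlations, ID vs OOD")
    rows <- list()
    for (mk in names(fits)) for (i in seq_along(fits[[mk]])) {
      cell <- sim$pop[[i]]
      for (ens in c("wn", "nm")) {
        stim <- sim[[ens]]
        resp <- sim[[paste0("resp_", ens)]][[i]]
        id <- test_correlation(fits[[mk]][[i]][[ens]], stim, resp)
        ood_fit <- adapts[[mk]][[i]][[if (ens == "nm") "wn_to_nm"
                                      else "nm_to_wn"]]
        ood <- test_correlation(ood_fit, stim, resp)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mk, cell_id = cell$cell_id,
          cell_type = cell$cell_type_label, eval_ensemble = ens,
          cc_id = id$cc, cc_ood = ood$cc, n_test_bins = id$n_test_bins,
          reliability = odd_even_reliability(resp, stim))
      }
    }
    evaluation <- do.call(rbind, rows)
    .write_table(evaluation, out_dir, "evaluation.csv")
    summaries <- do.call(rbind, lapply(split(
      evaluation, list(evaluation$model, evaluation$eval_ensemble)),
      function(g) {
        cmp <- compare_id_ood(g)
        cmp$model <- g$model[1]; cmp$eval_ensemble <- g$eval_ensemble[1]
        cmp
      }))
    rownames(summaries) <- NULL
    .write_table(summaries, out_dir, "id_ood_summary.csv")
    finish("evaluate")
  }

  ## -- rf ------------------------------------------------------------------
  if (!done("rf")) {
    message("[rf] receptive-field center sizes and surround amplitudes")
    rows <- list()
    for (mk in names(fits)) {
      methods <- if (mk == "dog") c("dog_params", "posthoc_dog", "threshold")
                 else c("posthoc_dog", "threshold")
      for (i in seq_along(fits[[mk]])) for (ens in c("wn", "nm"))
        for (m in methods) {
          mt <- rf_metrics(fits[[mk]][[i]][[ens]], m, geometry = geom,
                           window = config$analysis$window,
                           clip_below = config$analysis$clip_below)
          mt$model <- mk; mt$cell_id <- sim$pop[[i]]$cell_id
          mt$cell_type <- sim$pop[[i]]$cell_type_label; mt$ensemble <- ens
          rows[[length(rows) + 1L]] <- mt
        }
    }
    rfm <- do.call(rbind, rows)
    .write_table(rfm, out_dir, "rf_metrics.csv")
    cmp_rows <- list()
    for (mk in unique(rfm$model)) for (m in unique(rfm$method))
      for (ty in unique(rfm$cell_type)) {
        sub <- rfm[rfm$model == mk & rfm$method == m &
                     rfm$cell_type == ty, ]
        w <- sub[sub$ensemble == "wn", ]; n <- sub[sub$ensemble == "nm", ]
        n <- n[match(w$cell_id, n$cell_id), ]
        tst <- function(x, y) {
          if (length(x) < 1 || all(x == y)) return(NA_real_)
          suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
        }
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          model = mk, method = m, cell_type = ty, n = nrow(w),
          mean_size_wn = mean(w$center_size_px2),
          mean_size_nm = mean(n$center_size_px2),
          p_size = tst(n$center_size_px2, w$center_size_px2),
          mean_surround_wn = mean(w$surround_amplitude),
          mean_surround_nm = mean(n$surround_amplitude),
          p_surround = tst(n$surround_amplitude, w$surround_amplitude),
          underpowered = nrow(w) < 5)
      }
    .write_table(do.call(rbind, cmp_rows), out_dir, "rf_comparison.csv")
    finish("rf")
  }

  ## -- spectra -------------------------------------------------------------
  if (!done("spectra")) {
    message("[spectra] power spectra, transfer functions, whitening")
    d <- dim(sim$nm$frames)
    crop <- config$analysis$spectrum_crop
    if (is.null(crop)) crop <- min(d[2], d[3])
    nfr <- min(config$analysis$spectrum_frames, d[1])
    fr_idx <- unique(round(seq(1, d[1], length.out = nfr)))
    spec_wn <- stimulus_power_spectrum(sim$wn, crop, fr_idx,
                                       normalize = TRUE)
    spec_nm <- stimulus_power_spectrum(sim$nm, crop, fr_idx,
                                       normalize = TRUE)
    sp_rows <- list(.spectrum_to_df(spec_wn, "white_noise"),
                    .spectrum_to_df(spec_nm, "natural_surrogate"))
    wh_rows <- list()
    mk <- names(fits)[1]
    rf_mean <- function(ty, ens) {
      idx <- which(vapply(sim$pop, function(cl)
        cl$cell_type_label == ty, logical(1)))
      if (length(idx) == 0) return(NULL)
      mean_receptive_field(
        lapply(idx, function(i)
          build_spatiotemporal_rf(fits[[mk]][[i]][[ens]]$params)),
        vapply(idx, function(i) sim$pop[[i]]$polarity, character(1)),
        window = config$analysis$window)
    }
    types <- unique(vapply(sim$pop, function(cl) cl$cell_type_label,
                           character(1)))
    for (ty in types) for (ens in c("wn", "nm")) {
      mrf <- rf_mean(ty, ens)
      fs <- filtered_spectrum(sim$nm, mrf, crop, mode = "tf_product",
                              frames = fr_idx, normalize = TRUE)
      sp_rows[[length(sp_rows) + 1L]] <-
        .spectrum_to_df(fs, paste0("nm_filtered_", ty, "_", ens, "_fit"))
      tfm <- transfer_function(mrf, crop)
      bd <- config$analysis$band
      if (is.null(bd)) bd <- band_from_transfer(tfm)
      wh <- tryCatch(whitening_percent(spec_nm, fs, bd),
                     error = function(e) NA_real_)
      wh_rows[[length(wh_rows) + 1L]] <- data.frame(
        filter = paste0(ty, "_", ens, "_fit"), kind = "learned",
        band_lo = bd[1], band_hi = bd[2],
        whitening_percent = as.numeric(wh))
    }
    small <- rf_mean(config$analysis$small_type, "nm")
    large <- rf_mean(config$analysis$large_type, "nm")
    if (!is.null(small) && !is.null(large)) {
      ph_s <- fit_dog_posthoc(small)
      ph_l <- fit_dog_posthoc(large)
      sims <- make_simulated_filters(ph_s, ph_l, spec_nm,
                                     band = config$analysis$band)
      for (sf in sims) {
        fs <- filtered_spectrum(sim$nm, sf$image, crop,
                                mode = "tf_product", frames = fr_idx,
                                normalize = TRUE)
        sp_rows[[length(sp_rows) + 1L]] <-
          .spectrum_to_df(fs, paste0("nm_filtered_sim_", sf$kind))
        wh <- tryCatch(whitening_percent(spec_nm, fs, sf$band),
                       error = function(e) NA_real_)
        wh_rows[[length(wh_rows) + 1L]] <- data.frame(
          filter = sf$kind, kind = "simulated",
          band_lo = sf$band[1], band_hi = sf$band[2],
          whitening_percent = as.numeric(wh))
      }
    } else {
      warning("population lacks the configured small/large cell types; ",
              "skipping simulated filters")
    }
    .write_table(do.call(rbind, sp_rows), out_dir, "spectra.csv")
    .write_table(do.call(rbind, wh_rows), out_dir, "whitening.csv")
    finish("spectra")
  }

  ## -- report --------------------------------------------------------------
  if (!done("report")) {
    message("[report] summary")
    evaluation <- utils::read.csv(file.path(out_dir, "evaluation.csv"))
    id_ood <- utils::read.csv(file.path(out_dir, "id_ood_summary.csv"))
    rfc <- utils::read.csv(file.path(out_dir, "rf_comparison.csv"))
    wh <- utils::read.csv(file.path(out_dir, "whitening.csv"))
    summary <- list(
      n_cells = length(unique(evaluation$cell_id)),
      frac_id_gt_ood = mean(evaluation$cc_id > evaluation$cc_ood,
                            na.rm = TRUE),
      id_ood = id_ood, rf_comparison = rfc, whitening = wh)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    finish("report")
  }
  invisible(out_dir)
}

#' Resume a partially completed pipeline run
#'
#' Re-runs only the stages not marked complete in the output directory's
#' manifest, using the per-stage seeds recorded there.  Refuses to resume
#' when the configuration hash does not match the manifest.
#'
#' @param config The configuration the run was started with.
#' @param out_dir The run's output directory.
#' @return `out_dir`, invisibly.
#' @export
resume <- function(config, out_dir) {
  run_all(config, out_dir, resume = TRUE)
}
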