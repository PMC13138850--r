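#' Pearson correlation between a prediction and a trial-averaged response
#'
#' The test-set performance metric: the sample Pearson correlation between
#' the model prediction and the across-trial mean response on the held-out
#' repeating segment.  Undefined values (fewer than two pairs, or a
#' constant input) are reported as `NA` and excluded from downstream
#' averages with a logged count.
#'
#' @param pred Prediction trace.
#' @param trial_avg Trial-averaged response trace of the same length.
#' @return A scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
correlation <- function(pred, trial_avg) {
  if (length(pred) != length(trial_avg)) stop("traces must have equal length")
  ok <- !is.na(pred) & !is.na(trial_avg)
  x <- pred[ok]; y <- trial_avg[ok]
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# per-trial repeating-segment count matrix (trials x bins); all repeating
# segments share identical frame content, so columns align across trials
.repeating_counts <- function(stimulus, response) {
  segs <- stimulus_segments(stimulus, "repeating")
  if (length(segs) < 1) stop("stimulus has no repeating segments")
  lens <- vapply(segs, function(s) s[2] - s[1] + 1L, integer(1))
  m <- min(lens)
  do.call(rbind, lapply(segs, function(s)
    response$counts[s[1]:(s[1] + m - 1L)]))
}

#' Odd/even trial reliability
#'
#' Correlation between the mean response over odd-indexed and even-indexed
#' repeating-segment trials (1-based trial indexing); a model-free measure
#' of a cell's intrinsic trial-to-trial reliability.
#'
#' @param response A `spike_response`.
#' @param stimulus The `rgc_stimulus` the response is aligned to.
#' @return A scalar correlation, or `NA` if undefined.
#' @export
odd_even_reliability <- function(response, stimulus) {
  cm <- .repeating_counts(stimulus, response)
  if (nrow(cm) < 2) stop("need at least 2 repeating trials")
  odd <- seq(1, nrow(cm), by = 2)
  even <- seq(2, nrow(cm), by = 2)
  correlation(colMeans(cm[odd, , drop = FALSE]),
              colMeans(cm[even, , drop = FALSE]))
}

#' Test-set correlation of a fitted model
#'
#' Predicts the repeating segment (identical frames on every trial; the
#' first 29 bins carry no prediction) and correlates the prediction with
#' the across-trial mean spike count, using the same valid-mode convention
#' as training.
#'
#' @param fit A `fit_result` (or LN parameter object).
#' @param stimulus,response The evaluation stimulus and aligned response.
#' @return List with `cc` and `n_test_bins`.
#' @export
test_correlation <- function(fit, stimulus, response) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  crop <- crop_stimulus(stimulus, params$crop_center)
  seg <- stimulus_segments(stimulus, "repeating")[[1]]
  pred <- predict_rate(params, crop$X, segments = list(seg))
  pred <- pred[(seg[1] + 29L):seg[2]]
  cm <- .repeating_counts(stimulus, response)
  avg <- colMeans(cm)[-(1:29)]
  m <- min(length(pred), length(avg))
  list(cc = correlation(pred[seq_len(m)], avg[seq_len(m)]),
       n_test_bins = m)
}

#' Compare in-domain and out-of-domain performance across cells
#'
#' Summarizes matched ID/OOD test correlations per cell group (mean and SD
#' of each, mean paired difference) and runs a two-sided Wilcoxon
#' signed-rank test on the paired differences.  Cells with an undefined
#' correlation are dropped pairwise, with counts logged in the output;
#' groups with fewer than 5 valid pairs are flagged underpowered.
#'
#' @param evals A data.frame with columns `cell_id`, `cc_id`, `cc_ood`, and
#'   the grouping column.
#' @param group_by Name of the grouping column (default `"cell_type"`).
#' @return A data.frame with one row per group: sample sizes, means, SDs,
#'   mean paired difference, Wilcoxon `V` and `p_value`, `n_dropped`,
#'   `underpowered`.
#' @export
compare_id_ood <- function(evals, group_by = "cell_type") {
  stopifnot(all(c("cc_id", "cc_ood", group_by) %in% names(evals)))
  out <- lapply(split(evals, evals[[group_by]]), function(g) {
    ok <- !is.na(g$cc_id) & !is.na(g$cc_ood)
    x <- g$cc_id[ok]; y <- g$cc_ood[ok]
    test <- if (length(x) >= 1 && any(x != y))
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(
      group = g[[group_by]][1], n = length(x), n_dropped = sum(!ok),
      mean_cc_id = mean(x), sd_cc_id = stats::sd(x),
      mean_cc_ood = mean(y), sd_cc_ood = stats::sd(y),
      mean_diff = mean(x - y),
      statistic = unname(test$statistic), p_value = test$p.value,
      underpowered = length(x) < 5
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
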