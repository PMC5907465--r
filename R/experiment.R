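#' Experiment configuration for the validation protocol
#'
#' Two modes mirror how a cause-assignment algorithm is exercised:
#' * `trained` — for each split, an empirical probbase is estimated on the
#'   75% train fold and evaluated on the Dirichlet-resampled 25% test fold.
#' * `fixed_probbase` — no training: a fixed (e.g. expert-derived) probbase
#'   is evaluated on test sets resampled from the complete dataset, each
#'   with a cause composition drawn from a flat Dirichlet.
#'
#' @param mode `"trained"` or `"fixed_probbase"`.
#' @param classifier a [classifier_config()].
#' @param n_splits number of repetitions (500 in the standard protocol).
#' @param include_hce keep health-care-experience symptoms?
#' @param train_frac train-fold fraction for `trained` mode.
#' @param alpha Dirichlet concentration for test compositions.
#' @param seed master seed; all per-split seeds derive from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mode = c("trained", "fixed_probbase"),
                              classifier = classifier_config(),
                              n_splits = 500L, include_hce = TRUE,
                              train_frac = 0.75, alpha = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(classifier, "classifier_config"), n_splits >= 2L)
  structure(
    list(mode = mode, classifier = classifier,
         n_splits = as.integer(n_splits), include_hce = include_hce,
         train_frac = train_frac, alpha = alpha, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the full validation protocol
#'
#' Executes `config$n_splits` repetitions of the split / resample / train /
#' predict / score cycle and aggregates the per-split metrics to medians
#' with 95% uncertainty intervals. In `trained` mode each repetition
#' estimates a probbase on its train fold; in `fixed_probbase` mode the
#' supplied probbase is used without training and test sets are resampled
#' from the complete dataset. The HCE mask is applied consistently to data
#' and probbase before anything else. Failed splits (e.g. a resampling pool
#' with no usable cause) are skipped and counted; more than 50% failures is
#' an error.
#'
#' @param dataset a [va_dataset()].
#' @param config an [experiment_config()].
#' @param fixed_probbase a [probbase()], required in `fixed_probbase` mode.
#' @return An `experiment_summary`: list with `per_split` (data frame of
#'   scalar metrics per split), `reports` (per-split `metric_report`s),
#'   `summary` (aggregated rows from [aggregate_metrics()]), `ccc_by_cause`
#'   (per-cause median + UI), `n_failed`, `config`.
#' @export
run_validation <- function(dataset, config, fixed_probbase = NULL) {
  stopifnot(inherits(dataset, "va_dataset"),
            inherits(config, "experiment_config"))
  if (config$mode == "fixed_probbase" && is.null(fixed_probbase) &&
      config$classifier$kind != "random") {
    stop("fixed_probbase mode requires a probbase", call. = FALSE)
  }
  dataset <- apply_hce_mask(dataset, config$include_hce)
  if (!is.null(fixed_probbase)) {
    fixed_probbase <- apply_hce_mask(fixed_probbase, config$include_hce)
  }
  causes <- as.character(dataset$cause_list)
  n_causes <- length(causes)
  all_ids <- dataset$records$record_id

  if (config$mode == "trained") {
    splits <- make_splits(dataset, config$n_splits, config$train_frac,
                          master_seed = config$seed, alpha = config$alpha)
  } else {
    # no-training design: Dirichlet-composed test sets from the full data
    seeds <- derive_seeds(config$seed, config$n_splits)
    splits <- lapply(seq_len(config$n_splits), function(i) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seeds[i])
      list(index = i, seed = seeds[i], train_ids = character(0),
           test_ids = all_ids,
           target_csmf = draw_dirichlet_csmf(n_causes, config$alpha))
    })
  }

  reports <- vector("list", config$n_splits)
  failures <- 0L
  for (sp in splits) {
    res <- tryCatch(
      run_one_split(dataset, sp, config, fixed_probbase),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- failures + 1L
    } else {
      reports[[sp$index]] <- res
    }
  }
  done <- !vapply(reports, is.null, logical(1L))
  if (failures > config$n_splits / 2) {
    stop(sprintf("%d of %d splits failed", failures, config$n_splits),
         call. = FALSE)
  }
  reports <- reports[done]

  per_split <- do.call(rbind, lapply(reports, function(r) {
    data.frame(ccc_overall_mean = r$ccc_overall_mean,
               ccc_overall_median = r$ccc_overall_median,
               csmf_accuracy = r$csmf_accuracy,
               cccsmf_accuracy = r$cccsmf_accuracy,
               sensitivity_median = r$sensitivity_median,
               specificity_median = r$specificity_median)
  }))
  ccc_mat <- do.call(rbind, lapply(reports, `[[`, "ccc_by_cause"))
  colnames(ccc_mat) <- causes

  structure(
    list(per_split = per_split,
         reports = reports,
         summary = aggregate_metrics(per_split),
         ccc_by_cause = aggregate_by_cause(ccc_mat),
         n_failed = failures,
         config = config),
    class = "experiment_summary"
  )
}

run_one_split <- function(dataset, sp, config, fixed_probbase) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sp$seed + 1L)
  if (config$mode == "trained") {
    train <- subset_records(dataset, sp$train_ids)
    pb <- estimate_probbase(train, smoothing = config$classifier$smoothing)
    prior <- switch(config$classifier$prior,
                    train_csmf = train_prior(train,
                                             config$classifier$smoothing),
                    uniform = NULL)
  } else {
    pb <- fixed_probbase
    prior <- NULL
  }
  rs <- resample_to_csmf(dataset, sp$test_ids, sp$target_csmf)
  test <- subset_records(dataset, rs$record_ids)
  preds <- predict_va(test, pb, config$classifier, prior = prior,
                      seed = sp$seed + 2L)
  metric_report(test$records$gold_cause, preds$predicted_cause,
                dataset$cause_list)
}

#' Aggregate per-split metrics to median and uncertainty interval
#'
#' The 95% uncertainty interval is the 2.5th and 97.5th percentile of the
#' per-split values, with linear interpolation. Non-finite values are
#' excluded and counted.
#'
#' @param per_split data frame of per-split scalar metrics.
#' @param percentiles lower/upper percentile bounds (in percent).
#' @return Data frame with one row per metric: `metric`, `median`, `ui_lo`,
#'   `ui_hi`, `n_splits`, `n_dropped`.
#' @export
aggregate_metrics <- function(per_split, percentiles = c(2.5, 97.5)) {
  stopifnot(nrow(per_split) >= 2L, length(percentiles) == 2L,
            percentiles[1L] < percentiles[2L])
  rows <- lapply(names(per_split), function(m) {
    v <- per_split[[m]]
    keep <- is.finite(v)
    v <- v[keep]
    q <- stats::quantile(v, probs = percentiles / 100, names = FALSE)
    data.frame(metric = m, median = stats::median(v),
               ui_lo = q[1L], ui_hi = q[2L],
               n_splits = length(v), n_dropped = sum(!keep))
  })
  do.call(rbind, rows)
}

aggregate_by_cause <- function(ccc_mat, percentiles = c(2.5, 97.5)) {
  rows <- lapply(colnames(ccc_mat), function(cz) {
    v <- ccc_mat[, cz]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(data.frame(cause = cz, median = NA_real_, ui_lo = NA_real_,
                        ui_hi = NA_real_, n_splits = 0L))
    }
    q <- stats::quantile(v, probs = percentiles / 100, names = FALSE)
    data.frame(cause = cz, median = stats::median(v),
               ui_lo = q[1L], ui_hi = q[2L], n_splits = length(v))
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("<experiment_summary> %s mode, %d splits (%d failed)\n",
              x$config$mode, nrow(x$per_split) + x$n_failed, x$n_failed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s median %6.1f%%  (UI %6.1f%%, %6.1f%%)\n",
                s$metric[i], 100 * s$median[i], 100 * s$ui_lo[i],
                100 * s$ui_hi[i]))
  }
  invisible(x)
}

#' Compare two experiment summaries
#'
#' Reports the difference in medians per scalar metric, in percentage
#' points (`a` minus `b`), and per-cause win/loss/tie counts of median
#' CCC.
#'
#' @param summary_a,summary_b `experiment_summary` objects over the same
#'   cause list and metric set.
#' @return List with `metrics` (data frame: metric, median_a, median_b,
#'   diff_pp) and `by_cause` (data frame plus win/loss/tie counts in
#'   attributes `n_higher`, `n_lower`, `n_tied`).
#' @export
compare_runs <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "experiment_summary"),
            inherits(summary_b, "experiment_summary"))
  if (!identical(summary_a$ccc_by_cause$cause, summary_b$ccc_by_cause$cause)) {
    stop("summaries have different cause lists", call. = FALSE)
  }
  if (!identical(summary_a$summary$metric, summary_b$summary$metric)) {
    stop("summaries have different metric sets", call. = FALSE)
  }
  metrics <- data.frame(
    metric = summary_a$summary$metric,
    median_a = summary_a$summary$median,
    median_b = summary_b$summary$median,
    diff_pp = 100 * (summary_a$summary$median - summary_b$summary$median)
  )
  d <- summary_a$ccc_by_cause$median - summary_b$ccc_by_cause$median
  by_cause <- data.frame(cause = summary_a$ccc_by_cause$cause,
                         median_a = summary_a$ccc_by_cause$median,
                         median_b = summary_b$ccc_by_cause$median,
                         diff_pp = 100 * d)
  structure(list(metrics = metrics, by_cause = by_cause,
                 n_higher = sum(d > 0, na.rm = TRUE),
                 n_lower = sum(d < 0, na.rm = TRUE),
                 n_tied = sum(d == 0, na.rm = TRUE)),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("<run_comparison>\n")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("per-cause median CCC: %d higher, %d lower, %d tied\n",
              x$n_higher, x$n_lower, x$n_tied))
  invisible(x)
}
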