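#' Estimate an empirical probbase from training data
#'
#' For each cause j and symptom s, computes the empirical probability of the
#' symptom being endorsed conditional on the cause, with pseudo-count
#' smoothing:
#' `P[j, s] = (yes_js + smoothing) / (observed_js + 2 * smoothing)`,
#' where missing responses count neither as endorsed nor observed. The
#' default `smoothing = 0.5` (Jeffreys-style) keeps every entry strictly
#' inside (0, 1) so downstream log-likelihoods stay finite. Causes with no
#' training records get a flat row of 0.5 and are flagged in the result's
#' `empty_causes` attribute.
#'
#' @param train a [va_dataset()] of training records.
#' @param smoothing pseudo-count >= 0 added to each of yes/no.
#' @return A [probbase()] with provenance `"trained"`; attribute
#'   `empty_causes` lists causes with zero training records.
#' @export
estimate_probbase <- function(train, smoothing = 0.5) {
  stopifnot(inherits(train, "va_dataset"), smoothing >= 0)
  if (n_records(train) == 0L) stop("training data is empty", call. = FALSE)
  causes <- as.character(train$cause_list)
  x <- train$symptoms
  cf <- factor(train$records$gold_cause, levels = causes)
  yes <- matrix(0, length(causes), ncol(x), dimnames = list(causes, NULL))
  obs <- yes
  yes_part <- rowsum(ifelse(is.na(x), 0, x), cf)         # endorsed counts
  obs_part <- rowsum((!is.na(x)) + 0, cf)                # observed counts
  yes[rownames(yes_part), ] <- yes_part
  obs[rownames(obs_part), ] <- obs_part
  P <- (yes + smoothing) / (obs + 2 * smoothing)
  empty <- causes[tabulate(cf, nbins = length(causes)) == 0L]
  P[causes %in% empty, ] <- 0.5
  if (smoothing == 0) P[obs == 0] <- 0.5                 # avoid 0/0
  out <- probbase(P, train$cause_list, train$symptom_dict,
                  provenance = "trained")
  attr(out, "empty_causes") <- empty
  out
}

#' Classifier configuration
#'
#' Reference classifiers scored against a probbase:
#' * `bayes_full` — naive Bayes using endorsed and non-endorsed symptoms:
#'   `log prior_j + sum_s [x_s log P(j,s) + (1 - x_s) log(1 - P(j,s))]`.
#' * `bayes_endorsed_only` — InterVA-style scoring from endorsed symptoms
#'   only (the `(1 - x_s)` term is dropped).
#' * `random` — uniform random cause assignment, the chance baseline.
#'
#' Missing responses are skipped in the likelihood by default
#' (`missing_policy = "skip"`); `"as_absent"` treats them as "no". Ties are
#' broken towards the lowest cause index.
#'
#' @param kind one of `"bayes_full"`, `"bayes_endorsed_only"`, `"random"`.
#' @param prior `"train_csmf"` (cause fractions of the training fold,
#'   smoothed) or `"uniform"`.
#' @param smoothing pseudo-count used when the prior is estimated from data.
#' @param missing_policy `"skip"` or `"as_absent"`.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c("bayes_full", "bayes_endorsed_only",
                                       "random"),
                              prior = c("train_csmf", "uniform"),
                              smoothing = 0.5,
                              missing_policy = c("skip", "as_absent")) {
  structure(
    list(kind = match.arg(kind), prior = match.arg(prior),
         smoothing = smoothing,
         missing_policy = match.arg(missing_policy)),
    class = "classifier_config"
  )
}

#' Smoothed prior over causes from training labels
#'
#' `(n_j + smoothing) / (n + N * smoothing)` so causes absent from the
#' training fold keep nonzero prior mass.
#'
#' @param train a [va_dataset()].
#' @param smoothing pseudo-count per cause.
#' @return Named probability vector over the cause list.
#' @export
train_prior <- function(train, smoothing = 0.5) {
  causes <- as.character(train$cause_list)
  counts <- tabulate(factor(train$records$gold_cause, levels = causes),
                     nbins = length(causes))
  p <- (counts + smoothing) / (sum(counts) + length(causes) * smoothing)
  stats::setNames(p, causes)
}

#' Predict causes for every record in a dataset
#'
#' Vectorised scoring of all records against a probbase under a
#' [classifier_config()]. Scores are computed in log space and converted to
#' posteriors by a stabilised softmax; the prediction is the argmax with
#' lowest-index tie-break. Records whose symptoms are all missing under
#' `missing_policy = "skip"` fall back to the prior argmax.
#'
#' @param dataset a [va_dataset()] to predict for.
#' @param pb a [probbase()] whose symptom dictionary matches the dataset's
#'   (not used for `kind = "random"`).
#' @param config a [classifier_config()].
#' @param prior optional explicit prior vector over causes; overrides
#'   `config$prior`. If absent, `"train_csmf"` is only meaningful when the
#'   probbase was trained alongside a prior — pass `train_prior(train)`.
#' @param seed seed for `kind = "random"`.
#' @return A [prediction_set()] with posteriors (except `random`, which has
#'   none).
#' @export
predict_va <- function(dataset, pb = NULL, config = classifier_config(),
                       prior = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "va_dataset"),
            inherits(config, "classifier_config"))
  if (n_records(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  causes_ds <- as.character(dataset$cause_list)
  n <- n_records(dataset)

  if (config$kind == "random") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pred <- causes_ds[sample.int(length(causes_ds), n, replace = TRUE)]
    return(prediction_set(dataset$records$record_id, pred,
                          dataset$cause_list))
  }

  stopifnot(inherits(pb, "probbase"))
  if (!identical(pb$symptom_dict$symptom_id, dataset$symptom_dict$symptom_id)) {
    stop("probbase symptoms do not match the dataset", call. = FALSE)
  }
  if (!identical(as.character(pb$cause_list), causes_ds)) {
    stop("probbase causes do not match the dataset", call. = FALSE)
  }
  N <- length(causes_ds)
  if (is.null(prior)) {
    prior <- rep(1 / N, N)
  }
  stopifnot(length(prior) == N, all(prior > 0))
  prior <- prior / sum(prior)

  P <- pmin(pmax(pb$P, 1e-12), 1 - 1e-12)
  x <- dataset$symptoms
  if (config$missing_policy == "as_absent") x[is.na(x)] <- 0L
  observed <- !is.na(x)
  xy <- ifelse(observed, x, 0L)            # 1 where endorsed
  xn <- ifelse(observed, 1L - x, 0L)       # 1 where observed and not endorsed
  logP <- log(P)
  scores <- xy %*% t(logP)
  if (config$kind == "bayes_full") {
    scores <- scores + xn %*% t(log1p(-P))
  }
  scores <- sweep(scores, 2L, log(prior), "+")

  all_missing <- rowSums(observed) == 0L
  post <- softmax_rows(scores)
  pred_idx <- max.col(post, ties.method = "first")
  if (any(all_missing)) {
    # no symptom evidence: posterior is the prior, prediction its argmax
    post[all_missing, ] <- matrix(prior, sum(all_missing), N, byrow = TRUE)
    pred_idx[all_missing] <- which.max(prior)
  }
  ps <- prediction_set(dataset$records$record_id, causes_ds[pred_idx],
                       dataset$cause_list, posterior = post)
  attr(ps, "all_missing") <- sum(all_missing)
  ps
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Uniform random cause assignment (chance baseline)
#'
#' Assigns each record a cause uniformly at random. By construction its
#' expected CCC is 0 and its expected CSMF accuracy against
#' Dirichlet-distributed true fractions is about 1 - exp(-1): the levels the
#' chance-corrected metrics are anchored to.
#'
#' @param dataset a [va_dataset()].
#' @param seed integer seed.
#' @return A [prediction_set()].
#' @export
random_classifier <- function(dataset, seed = 1L) {
  predict_va(dataset, config = classifier_config("random"), seed = seed)
}
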