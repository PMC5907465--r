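#' Draw a cause composition from a symmetric Dirichlet
#'
#' One draw from Dirichlet(alpha, ..., alpha); `alpha = 1` is flat on the
#' simplex ("uninformative"). Uses the current RNG stream.
#'
#' @param n_causes number of causes N >= 2.
#' @param alpha concentration parameter > 0.
#' @return Probability vector of length N summing to 1.
#' @export
draw_dirichlet_csmf <- function(n_causes, alpha = 1) {
  stopifnot(n_causes >= 2L, alpha > 0)
  g <- stats::rgamma(n_causes, shape = alpha, rate = 1)
  while (sum(g) == 0) {  # pathological underflow at tiny alpha
    g <- stats::rgamma(n_causes, shape = alpha, rate = 1)
  }
  g / sum(g)
}

#' Generate repeated train/test split plans
#'
#' The validation design partitions the data uniformly at random into a
#' train fold (default 75%) and test fold (25%), repeated `n_splits` times
#' (500 in the standard protocol). Each split also carries a target cause
#' composition drawn from a flat Dirichlet, to which the test fold is later
#' resampled so that train and test cause compositions are uncorrelated.
#' Every split has its own RNG seed derived from `master_seed`, so any split
#' can be reproduced in isolation.
#'
#' @param dataset a [va_dataset()] with at least 8 records.
#' @param n_splits number of repetitions.
#' @param train_frac fraction of records in the train fold, in (0, 1).
#' @param master_seed integer seed for the whole plan.
#' @param alpha Dirichlet concentration for the target compositions.
#' @return List of `split_plan` objects, each with `index`, `seed`,
#'   `train_ids`, `test_ids`, `target_csmf`.
#' @export
make_splits <- function(dataset, n_splits = 500L, train_frac = 0.75,
                        master_seed = 1L, alpha = 1) {
  stopifnot(inherits(dataset, "va_dataset"),
            n_splits >= 1L, train_frac > 0, train_frac < 1)
  n <- n_records(dataset)
  if (n < 8L) stop("need at least 8 records to split", call. = FALSE)
  n_train <- round(train_frac * n)
  if (n_train == 0L || n_train == n) {
    stop("train or test fold would be empty", call. = FALSE)
  }
  ids <- dataset$records$record_id
  n_causes <- length(dataset$cause_list)
  seeds <- derive_seeds(master_seed, n_splits)
  lapply(seq_len(n_splits), function(i) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seeds[i])
    train_idx <- sample.int(n, n_train)
    target <- draw_dirichlet_csmf(n_causes, alpha)
    structure(
      list(index = i, seed = seeds[i],
           train_ids = ids[train_idx],
           test_ids = ids[-train_idx],
           target_csmf = stats::setNames(target,
                                         as.character(dataset$cause_list))),
      class = "split_plan"
    )
  })
}

# Deterministic per-split seed stream, kept within 32-bit integer range.
derive_seeds <- function(master_seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Resample records to a target cause composition
#'
#' Draws `size` records with replacement so that expected cause counts are
#' proportional to `target_csmf`, renormalised over the causes that have at
#' least one available record. Realised counts are multinomial; within a
#' cause, records are drawn uniformly with replacement. Record payloads are
#' referenced by id, never copied or mutated.
#'
#' @param dataset a [va_dataset()].
#' @param record_ids pool of record ids to resample from (e.g. a test fold).
#' @param target_csmf named or unnamed probability vector over the dataset's
#'   cause list.
#' @param size number of draws; defaults to `length(record_ids)`.
#' @return A `resampled_test_set`: list with `record_ids` (with repetition),
#'   `cause_counts` (realised counts by cause), `renormalised` flag.
#' @export
resample_to_csmf <- function(dataset, record_ids, target_csmf,
                             size = length(record_ids)) {
  stopifnot(inherits(dataset, "va_dataset"))
  if (length(record_ids) == 0L) {
    stop("record pool must be non-empty", call. = FALSE)
  }
  stopifnot(size >= 1L)
  causes <- as.character(dataset$cause_list)
  if (length(target_csmf) != length(causes)) {
    stop("target_csmf length must equal the number of causes", call. = FALSE)
  }
  pool_causes <- dataset$records$gold_cause[
    match(record_ids, dataset$records$record_id)]
  if (anyNA(pool_causes)) {
    stop("unknown record id in pool", call. = FALSE)
  }
  available <- causes %in% pool_causes
  w <- as.numeric(target_csmf) * available
  if (sum(w) == 0) {
    stop("no cause with positive target mass has available records",
         call. = FALSE)
  }
  w <- w / sum(w)
  counts <- as.vector(stats::rmultinom(1L, size, w))
  by_cause <- split(record_ids, factor(pool_causes, levels = causes))
  drawn <- unlist(lapply(seq_along(causes), function(j) {
    if (counts[j] == 0L) return(character(0))
    pool <- by_cause[[j]]
    pool[sample.int(length(pool), counts[j], replace = TRUE)]
  }), use.names = FALSE)
  structure(
    list(record_ids = drawn,
         cause_counts = stats::setNames(counts, causes),
         renormalised = any(as.numeric(target_csmf) > 0 & !available)),
    class = "resampled_test_set"
  )
}

#' Subset a VA dataset by record id
#'
#' Repeated ids are allowed (as produced by [resample_to_csmf()]); each
#' occurrence becomes one row, with a disambiguated record id suffix when an
#' id repeats.
#'
#' @param dataset a [va_dataset()].
#' @param record_ids ids to keep, in order, repetition allowed.
#' @return A [va_dataset()].
#' @export
subset_records <- function(dataset, record_ids) {
  stopifnot(inherits(dataset, "va_dataset"))
  idx <- match(record_ids, dataset$records$record_id)
  if (anyNA(idx)) stop("unknown record id", call. = FALSE)
  records <- dataset$records[idx, , drop = FALSE]
  if (anyDuplicated(records$record_id)) {
    records$record_id <- make.unique(records$record_id, sep = "#")
  }
  rownames(records) <- NULL
  va_dataset(records, dataset$symptoms[idx, , drop = FALSE],
             dataset$cause_list, dataset$symptom_dict)
}
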