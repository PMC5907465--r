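# Independent record-by-record reference implementations used to cross-check
# the vectorised metric code. Deliberately naive: one pass over records per
# cause, no shared code with the package internals.

brute_confusion <- function(true, pred, causes) {
  n <- length(true)
  tp <- fn <- fp <- tn <- stats::setNames(numeric(length(causes)), causes)
  M <- matrix(0L, length(causes), length(causes),
              dimnames = list(true = causes, predicted = causes))
  for (j in causes) {
    for (i in seq_len(n)) {
      if (true[i] == j && pred[i] == j) tp[j] <- tp[j] + 1
      else if (true[i] == j && pred[i] != j) fn[j] <- fn[j] + 1
      else if (true[i] != j && pred[i] == j) fp[j] <- fp[j] + 1
      else tn[j] <- tn[j] + 1
    }
  }
  for (i in seq_len(n)) {
    M[true[i], pred[i]] <- M[true[i], pred[i]] + 1L
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn, misclass = M, n_records = n)
}

brute_ccc <- function(conf, N) {
  sapply(seq_along(conf$tp), function(j) {
    denom <- conf$tp[j] + conf$fn[j]
    if (denom == 0) return(NA_real_)
    (conf$tp[j] / denom - 1 / N) / (1 - 1 / N)
  })
}

brute_csmf <- function(labels, causes) {
  sapply(causes, function(j) sum(labels == j)) / length(labels)
}

brute_csmf_accuracy <- function(ct, cp) {
  1 - sum(abs(ct - cp)) / (2 * (1 - min(ct)))
}

brute_sens_spec <- function(conf) {
  sens <- ifelse(conf$tp + conf$fn > 0, conf$tp / (conf$tp + conf$fn), NA)
  spec <- ifelse(conf$tn + conf$fp > 0, conf$tn / (conf$tn + conf$fp), NA)
  list(sens = sens, spec = spec)
}

# Small synthetic fixtures -------------------------------------------------

tiny_cause_list <- function(n = 3L, module = "adult") {
  cause_list(LETTERS[seq_len(n)], module)
}

tiny_dataset <- function(n_causes = 3L, n_symptoms = 6L, n_records = 60L,
                         seed = 11L, ...) {
  cfg <- generator_config(n_causes = n_causes, n_symptoms = n_symptoms,
                          n_records = n_records, signature_size = 2L,
                          seed = seed, ...)
  generate_dataset(generate_probbase(cfg), cfg)
}
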