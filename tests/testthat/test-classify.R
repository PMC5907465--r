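make_ds <- function(records, symptoms, cl, sd) {
  va_dataset(records, symptoms, cl, sd)
}

test_that("empirical probbase estimation matches counting by hand", {
  cl <- tiny_cause_list(2)
  sd <- symptom_dictionary("s1")
  # cause A: s1 endorsed 3 of 4 observed (a fifth response is missing)
  recs2 <- data.frame(record_id = paste0("r", 1:6), module = "adult",
                      site = "x", gold_cause = c(rep("A", 5), "B"))
  sym2 <- matrix(c(1L, 1L, 1L, 0L, NA, 0L), ncol = 1)
  train2 <- make_ds(recs2, sym2, cl, sd)
  expect_equal(estimate_probbase(train2, smoothing = 0)$P["A", "s1"], 0.75)
  expect_equal(estimate_probbase(train2, smoothing = 0.5)$P["A", "s1"], 0.7)

  # a cause with no training records gets a flat 0.5 row and is flagged
  cl3 <- tiny_cause_list(3)
  train3 <- make_ds(recs2, sym2, cl3, sd)
  pb3 <- estimate_probbase(train3)
  expect_equal(unname(pb3$P["C", ]), 0.5)
  expect_identical(attr(pb3, "empty_causes"), "C")
  expect_identical(pb3$provenance, "trained")
})

test_that("Bayes classification reproduces hand-computed posteriors", {
  cl <- tiny_cause_list(2)
  sd <- symptom_dictionary("s1")
  pb <- probbase(matrix(c(0.9, 0.1), ncol = 1), cl, sd)
  endorsed <- make_ds(
    data.frame(record_id = "r1", module = "adult", site = "x",
               gold_cause = "A"),
    matrix(1L, 1, 1), cl, sd)
  not_endorsed <- make_ds(
    data.frame(record_id = "r1", module = "adult", site = "x",
               gold_cause = "A"),
    matrix(0L, 1, 1), cl, sd)

  p1 <- predict_va(endorsed, pb, classifier_config("bayes_full"))
  expect_identical(p1$predicted_cause, "A")
  expect_equal(unname(p1$posterior[1, ]), c(0.9, 0.1), tolerance = 1e-9)

  p0 <- predict_va(not_endorsed, pb, classifier_config("bayes_full"))
  expect_identical(p0$predicted_cause, "B")
  expect_equal(unname(p0$posterior[1, ]), c(0.1, 0.9), tolerance = 1e-9)

  # endorsed-only scoring ignores absences: symmetric prior -> tie -> A
  pe <- predict_va(not_endorsed, pb, classifier_config("bayes_endorsed_only"))
  expect_identical(pe$predicted_cause, "A")
  expect_equal(unname(pe$posterior[1, ]), c(0.5, 0.5))

  # identical probbase rows: tie broken to the lowest cause index
  pb_tie <- probbase(matrix(c(0.7, 0.7), ncol = 1), cl, sd)
  pt <- predict_va(endorsed, pb_tie, classifier_config("bayes_full"))
  expect_identical(pt$predicted_cause, "A")
})

test_that("missing handling follows the configured policy", {
  cl <- tiny_cause_list(2)
  sd <- symptom_dictionary(c("s1", "s2"))
  pb <- probbase(matrix(c(0.9, 0.1, 0.5, 0.5), 2), cl, sd)
  ds <- make_ds(
    data.frame(record_id = "r1", module = "adult", site = "x",
               gold_cause = "A"),
    matrix(c(NA_integer_, NA_integer_), 1), cl, sd)
  # all missing + skip: posterior equals the prior, prediction its argmax
  p <- predict_va(ds, pb, classifier_config("bayes_full"),
                  prior = c(0.3, 0.7))
  expect_identical(p$predicted_cause, "B")
  expect_equal(unname(p$posterior[1, ]), c(0.3, 0.7))
  expect_equal(attr(p, "all_missing"), 1L)
  # as_absent treats missing as "no": evidence against cause A
  p2 <- predict_va(ds, pb, classifier_config(
    "bayes_full", missing_policy = "as_absent"))
  expect_identical(p2$predicted_cause, "B")
})

test_that("posteriors are simplex rows and scores stay finite", {
  ds <- tiny_dataset(n_causes = 4, n_symptoms = 8, n_records = 100, seed = 6,
                     missing_rate = 0.3)
  pb <- estimate_probbase(subset_records(ds, ds$records$record_id))
  p <- predict_va(ds, pb, classifier_config("bayes_full"))
  expect_true(all(abs(rowSums(p$posterior) - 1) < 1e-9))
  expect_true(all(is.finite(p$posterior)))
})

test_that("random baseline is seeded and roughly uniform", {
  # only labels matter for the random classifier; keep symptoms small
  cfg <- generator_config(n_causes = 34, n_symptoms = 34, n_records = 34000,
                          signature_size = 1, seed = 14)
  ds <- generate_dataset(generate_probbase(cfg), cfg)
  p1 <- random_classifier(ds, seed = 2)
  p2 <- random_classifier(ds, seed = 2)
  expect_identical(p1$predicted_cause, p2$predicted_cause)
  counts <- table(p1$predicted_cause)
  expect_true(all(abs(counts - 1000) < 100))
})

test_that("probbase estimates recover the generator's truth", {
  rmse_at <- function(per_cause) {
    cfg <- generator_config(n_causes = 4, n_symptoms = 12,
                            n_records = 4 * per_cause, signature_size = 3,
                            noise_eps = 0, missing_rate = 0,
                            hce_fraction = 0, seed = 120)
    pb <- generate_probbase(cfg)
    ds <- generate_dataset(pb, cfg)
    est <- estimate_probbase(subset_records(ds, ds$records$record_id))
    sqrt(mean((est$P - pb$P)^2))
  }
  r50 <- rmse_at(50); r200 <- rmse_at(200); r500 <- rmse_at(500)
  expect_lt(r200, 0.06)
  expect_lt(r500, r50)
})

test_that("cause-label permutation permutes probbase rows and predictions", {
  ds <- tiny_dataset(n_causes = 3, n_records = 150, seed = 44)
  pb <- estimate_probbase(subset_records(ds, ds$records$record_id))
  perm <- c(3L, 1L, 2L)
  causes <- as.character(ds$cause_list)
  cl_perm <- cause_list(causes[perm], "adult")
  recs_perm <- ds$records
  ds_perm <- va_dataset(recs_perm, ds$symptoms, cl_perm, ds$symptom_dict)
  pb_perm <- estimate_probbase(subset_records(ds_perm,
                                              ds_perm$records$record_id))
  expect_equal(pb_perm$P, pb$P[perm, ])
  p <- predict_va(ds, pb, classifier_config("bayes_full"))
  pp <- predict_va(ds_perm, pb_perm, classifier_config("bayes_full"))
  expect_identical(p$predicted_cause, pp$predicted_cause)
})

test_that("using absence information helps when absences are informative", {
  # high background endorsement makes the absence of a cause's own
  # signature symptoms the strongest discriminating signal
  cfg <- generator_config(n_causes = 5, n_symptoms = 15, n_records = 800,
                          signature_size = 3, signature_strength = 0.95,
                          background_rate = 0.45, noise_eps = 0.05,
                          missing_rate = 0, hce_fraction = 0, seed = 202)
  ds <- generate_dataset(generate_probbase(cfg), cfg)
  splits <- make_splits(ds, n_splits = 15, master_seed = 5)
  ccc <- sapply(c("bayes_full", "bayes_endorsed_only"), function(kind) {
    mean(sapply(splits, function(s) {
      train <- subset_records(ds, s$train_ids)
      test <- subset_records(ds, s$test_ids)
      pb <- estimate_probbase(train)
      p <- predict_va(test, pb, classifier_config(kind),
                      prior = train_prior(train))
      metric_report(test$records$gold_cause, p$predicted_cause,
                    ds$cause_list)$ccc_overall_mean
    }))
  })
  expect_gte(ccc["bayes_full"], ccc["bayes_endorsed_only"])
})

test_that("prediction validates its inputs", {
  ds <- tiny_dataset(n_records = 20, seed = 1)
  other_sd <- symptom_dictionary(paste0("z", 1:6))
  pb_bad <- probbase(matrix(0.5, 3, 6), ds$cause_list, other_sd)
  expect_error(predict_va(ds, pb_bad, classifier_config()), "match")
})
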