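test_that("aggregation produces medians with interpolated 95% intervals", {
  per_split <- data.frame(metric_a = as.numeric(1:500))
  s <- aggregate_metrics(per_split)
  expect_equal(s$median, 250.5)
  expect_equal(s$ui_lo, 13.475)
  expect_equal(s$ui_hi, 487.525)
  expect_equal(s$n_splits, 500L)

  const <- aggregate_metrics(data.frame(m = rep(0.4, 10)))
  expect_equal(const$median, 0.4)
  expect_equal(const$ui_lo, 0.4)
  expect_equal(const$ui_hi, 0.4)

  with_na <- aggregate_metrics(data.frame(m = c(1, 2, 3, NaN)))
  expect_equal(with_na$n_dropped, 1L)
  expect_equal(with_na$median, 2)
})

test_that("validation runs are deterministic given the master seed", {
  ds <- tiny_dataset(n_causes = 3, n_records = 120, seed = 10)
  cfg <- experiment_config("trained", n_splits = 4, seed = 33)
  s1 <- run_validation(ds, cfg)
  s2 <- run_validation(ds, cfg)
  expect_identical(s1$per_split, s2$per_split)
  expect_identical(s1$summary, s2$summary)
  s3 <- run_validation(ds, experiment_config("trained", n_splits = 4,
                                             seed = 34))
  expect_false(identical(s1$per_split, s3$per_split))
})

test_that("separable data yields a perfect pipeline score", {
  cfg <- generator_config(n_causes = 5, n_symptoms = 10, n_records = 300,
                          signature_size = 2, signature_strength = 1,
                          background_rate = 0, noise_eps = 0,
                          missing_rate = 0, hce_fraction = 0, seed = 61)
  ds <- generate_dataset(generate_probbase(cfg), cfg)
  s <- run_validation(ds, experiment_config("trained", n_splits = 10,
                                            seed = 62))
  sm <- s$summary
  expect_equal(sm$median[sm$metric == "ccc_overall_mean"], 1)
  expect_equal(sm$median[sm$metric == "csmf_accuracy"], 1)
  expect_equal(sm$median[sm$metric == "cccsmf_accuracy"], 1)
})

test_that("accuracy degrades monotonically with reporting noise", {
  median_ccc <- sapply(c(0, 0.15, 0.3), function(eps) {
    cfg <- generator_config(n_causes = 4, n_symptoms = 12, n_records = 300,
                            signature_size = 3, signature_strength = 0.9,
                            background_rate = 0.05, noise_eps = eps,
                            missing_rate = 0, hce_fraction = 0, seed = 71)
    ds <- generate_dataset(generate_probbase(cfg), cfg)
    s <- run_validation(ds, experiment_config("trained", n_splits = 8,
                                              seed = 72))
    s$summary$median[s$summary$metric == "ccc_overall_mean"]
  })
  expect_true(all(diff(median_ccc) <= 0))
  expect_lt(median_ccc[3], median_ccc[1])
})

test_that("trained classifier beats the random baseline on paired splits", {
  cfg <- generator_config(n_causes = 5, n_symptoms = 15, n_records = 400,
                          signature_size = 3, signature_strength = 0.9,
                          background_rate = 0.05, noise_eps = 0.05,
                          missing_rate = 0.05, hce_fraction = 0, seed = 81)
  ds <- generate_dataset(generate_probbase(cfg), cfg)
  trained <- run_validation(ds, experiment_config(
    "trained", n_splits = 20, seed = 82))
  rand <- run_validation(ds, experiment_config(
    "trained", classifier_config("random"), n_splits = 20, seed = 82))
  win_ccc <- mean(trained$per_split$ccc_overall_mean >
                  rand$per_split$ccc_overall_mean)
  win_cccsmf <- mean(trained$per_split$cccsmf_accuracy >
                     rand$per_split$cccsmf_accuracy)
  expect_gte(win_ccc, 0.95)
  expect_gte(win_cccsmf, 0.95)
})

test_that("a mis-specified fixed probbase can score below chance", {
  cfg <- generator_config(n_causes = 5, n_symptoms = 10, n_records = 400,
                          signature_size = 2, signature_strength = 0.9,
                          background_rate = 0.05, noise_eps = 0.05,
                          missing_rate = 0, hce_fraction = 0, seed = 91)
  pb_true <- generate_probbase(cfg)
  ds <- generate_dataset(pb_true, cfg)
  # rotate the signature blocks so every cause points at the wrong symptoms
  P_bad <- pb_true$P[c(2:5, 1), ]
  pb_bad <- probbase(P_bad, pb_true$cause_list, pb_true$symptom_dict)
  s <- run_validation(ds, experiment_config("fixed_probbase",
                                            n_splits = 20, seed = 92),
                      fixed_probbase = pb_bad)
  expect_lt(s$summary$median[s$summary$metric == "cccsmf_accuracy"], 0)
})

test_that("HCE exclusion is applied consistently inside the pipeline", {
  ds <- tiny_dataset(n_causes = 3, n_records = 150, seed = 13,
                     hce_fraction = 0.3)
  expect_true(any(ds$symptom_dict$hce_flag))
  s <- run_validation(ds, experiment_config("trained", n_splits = 3,
                                            include_hce = FALSE, seed = 14))
  expect_equal(nrow(s$per_split), 3L)
  s2 <- run_validation(ds, experiment_config("trained", n_splits = 3,
                                             include_hce = TRUE, seed = 14))
  expect_false(identical(s$per_split, s2$per_split))
})

test_that("comparisons report median differences and win counts", {
  ds <- tiny_dataset(n_causes = 3, n_records = 150, seed = 15)
  cfg <- experiment_config("trained", n_splits = 4, seed = 16)
  s <- run_validation(ds, cfg)
  self <- compare_runs(s, s)
  expect_true(all(self$metrics$diff_pp == 0))
  expect_equal(self$n_tied, 3L)

  # difference-in-medians reporting in percentage points
  a <- s; b <- s
  a$summary$median[1] <- 0.378
  b$summary$median[1] <- 0.285
  cmp <- compare_runs(a, b)
  expect_equal(cmp$metrics$diff_pp[1], 9.3, tolerance = 1e-9)

  d <- c(0.1, -0.2, 0)
  a$ccc_by_cause$median <- b$ccc_by_cause$median + d
  cmp2 <- compare_runs(a, b)
  expect_equal(cmp2$n_higher, 1L)
  expect_equal(cmp2$n_lower, 1L)
  expect_equal(cmp2$n_tied, 1L)
})

test_that("mode invariants are enforced", {
  ds <- tiny_dataset(n_records = 50, seed = 17)
  expect_error(
    run_validation(ds, experiment_config("fixed_probbase", n_splits = 2)),
    "requires a probbase")
  expect_error(experiment_config("trained", n_splits = 1), "n_splits")
})
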