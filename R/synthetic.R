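#' Configuration for the synthetic gold-standard generator
#'
#' Defines a PHMRC-like generating process: each cause has a block of
#' `signature_size` dedicated "signature" symptoms endorsed with probability
#' `signature_strength`; every other symptom is endorsed at `background_rate`.
#' Records draw a gold cause from `csmf_true`, draw each symptom Bernoulli
#' from the true probbase, then pass through symmetric reporting noise
#' (each response flipped with probability `noise_eps`) and completely-at-
#' random missingness (`missing_rate`). Sites are assigned uniformly.
#'
#' @param module age module, `"adult"`, `"child"` or `"neonate"`.
#' @param n_causes number of causes N.
#' @param n_symptoms number of symptoms S; needs `signature_size * N <= S`.
#' @param n_records number of deaths to simulate.
#' @param csmf_true true cause fractions (length N, sums to 1); default
#'   uniform.
#' @param signature_strength endorsement probability on signature symptoms,
#'   in (0.5, 1].
#' @param background_rate endorsement probability elsewhere, in \[0, 0.5\].
#' @param signature_size dedicated symptoms per cause.
#' @param noise_eps symmetric flip probability, in \[0, 0.5\].
#' @param missing_rate probability a response is set to missing, in \[0, 1).
#' @param hce_fraction fraction of symptoms flagged as health-care-experience
#'   items (the last `round(hce_fraction * S)` columns), in \[0, 1).
#' @param n_sites number of study sites (labels only; no distributional
#'   effect unless `site_effect` is nonzero).
#' @param site_effect optional per-site additive offset magnitude on
#'   endorsement probabilities (evenly spaced in `[-site_effect, site_effect]`
#'   across sites, clipped to \[0.01, 0.99\]); default 0.
#' @param seed integer seed making generation deterministic.
#' @return A `generator_config` (validated list).
#' @export
generator_config <- function(module = "adult", n_causes, n_symptoms,
                             n_records, csmf_true = NULL,
                             signature_strength = 0.85,
                             background_rate = 0.05,
                             signature_size = 3L,
                             noise_eps = 0.05, missing_rate = 0.1,
                             hce_fraction = 0.15, n_sites = 6L,
                             site_effect = 0, seed = 1L) {
  module <- match.arg(module, c("adult", "child", "neonate"))
  n_causes <- as.integer(n_causes)
  n_symptoms <- as.integer(n_symptoms)
  signature_size <- as.integer(signature_size)
  if (is.null(csmf_true)) csmf_true <- rep(1 / n_causes, n_causes)
  stopifnot(n_causes >= 2L, n_symptoms >= 1L, n_records >= 1L,
            length(csmf_true) == n_causes, all(csmf_true >= 0),
            signature_strength > 0.5, signature_strength <= 1,
            background_rate >= 0, background_rate <= 0.5,
            signature_size >= 1L,
            noise_eps >= 0, noise_eps <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            hce_fraction >= 0, hce_fraction < 1,
            n_sites >= 1L, site_effect >= 0)
  if (abs(sum(csmf_true) - 1) > 1e-9) {
    stop("csmf_true must sum to 1", call. = FALSE)
  }
  if (signature_size * n_causes > n_symptoms) {
    stop("signature blocks overlap: signature_size * n_causes > n_symptoms",
         call. = FALSE)
  }
  structure(
    list(module = module, n_causes = n_causes, n_symptoms = n_symptoms,
         n_records = as.integer(n_records), csmf_true = csmf_true,
         signature_strength = signature_strength,
         background_rate = background_rate,
         signature_size = signature_size,
         noise_eps = noise_eps, missing_rate = missing_rate,
         hce_fraction = hce_fraction, n_sites = as.integer(n_sites),
         site_effect = site_effect, seed = as.integer(seed)),
    class = "generator_config"
  )
}

config_cause_list <- function(config) {
  cause_list(sprintf("cause_%02d", seq_len(config$n_causes)), config$module)
}

config_symptom_dict <- function(config) {
  s <- config$n_symptoms
  n_hce <- min(round(config$hce_fraction * s), s - 1L)
  symptom_dictionary(
    sprintf("symptom_%03d", seq_len(s)),
    seq_len(s) > s - n_hce
  )
}

#' Generate the true probbase implied by a generator configuration
#'
#' Cause j gets `signature_size` consecutive dedicated columns at
#' `signature_strength`; all other entries are `background_rate`. The matrix
#' is deterministic given the configuration.
#'
#' @param config a [generator_config()].
#' @return A [probbase()] with provenance `"fixed"`.
#' @examples
#' cfg <- generator_config(n_causes = 3, n_symptoms = 6, n_records = 10,
#'                         signature_size = 2, hce_fraction = 0)
#' generate_probbase(cfg)$P
#' @export
generate_probbase <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  P <- matrix(config$background_rate, config$n_causes, config$n_symptoms)
  for (j in seq_len(config$n_causes)) {
    cols <- ((j - 1L) * config$signature_size + 1L):(j * config$signature_size)
    P[j, cols] <- config$signature_strength
  }
  probbase(P, config_cause_list(config), config_symptom_dict(config),
           provenance = "fixed")
}

#' Simulate a gold-standard VA dataset
#'
#' Draws each record's cause from `csmf_true`, each symptom Bernoulli from
#' the true probbase row, applies symmetric flip noise, then missingness,
#' and assigns sites uniformly. Deterministic given `config$seed`.
#'
#' @param probbase_true a [probbase()] whose shape matches `config` (usually
#'   from [generate_probbase()]).
#' @param config a [generator_config()].
#' @return A [va_dataset()].
#' @export
generate_dataset <- function(probbase_true, config) {
  stopifnot(inherits(probbase_true, "probbase"),
            inherits(config, "generator_config"))
  P <- probbase_true$P
  if (nrow(P) != config$n_causes || ncol(P) != config$n_symptoms) {
    stop("probbase shape does not match the configuration", call. = FALSE)
  }
  n <- config$n_records
  if (n < config$n_causes) {
    warning("fewer records than causes: some causes may be absent",
            call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  causes <- sample.int(config$n_causes, n, replace = TRUE,
                       prob = config$csmf_true)
  sites <- sample.int(config$n_sites, n, replace = TRUE)
  p <- P[causes, , drop = FALSE]
  if (config$site_effect > 0 && config$n_sites > 1L) {
    offsets <- seq(-config$site_effect, config$site_effect,
                   length.out = config$n_sites)
    p <- p + offsets[sites]
    p <- pmin(pmax(p, 0.01), 0.99)
  }
  x <- matrix(as.integer(stats::runif(length(p)) < p), nrow = n)
  if (config$noise_eps > 0) {
    flip <- matrix(stats::runif(length(x)) < config$noise_eps, nrow = n)
    x[flip] <- 1L - x[flip]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(x)) < config$missing_rate, nrow = n)
    x[miss] <- NA_integer_
  }
  records <- data.frame(
    record_id = sprintf("r%06d", seq_len(n)),
    module = config$module,
    site = sprintf("site_%d", sites),
    gold_cause = as.character(probbase_true$cause_list)[causes],
    stringsAsFactors = FALSE
  )
  va_dataset(records, x, probbase_true$cause_list,
             probbase_true$symptom_dict)
}

#' PHMRC-like generator presets by age module
#'
#' Mirrors the structure of the multi-site gold-standard validation
#' database: 34 adult causes with 171 symptoms, 21 child causes with 86
#' symptoms, 6 neonate causes (including stillbirth) with 110 symptoms;
#' record counts near the study's 7841 adult, 2064 child and 1620 + 1005
#' neonate/stillbirth deaths, rounded to 7800 / 2100 / 2600; six sites.
#'
#' @param module `"adult"`, `"child"` or `"neonate"`.
#' @param ... overrides passed to [generator_config()] (e.g. `n_records`,
#'   `seed`, `noise_eps`).
#' @return A [generator_config()].
#' @examples
#' phmrc_like_preset("adult")$n_causes  # 34
#' @export
phmrc_like_preset <- function(module = c("adult", "child", "neonate"), ...) {
  module <- match.arg(module)
  base <- switch(module,
    adult   = list(n_causes = 34L, n_symptoms = 171L, n_records = 7800L),
    child   = list(n_causes = 21L, n_symptoms = 86L,  n_records = 2100L),
    neonate = list(n_causes = 6L,  n_symptoms = 110L, n_records = 2600L)
  )
  args <- utils::modifyList(c(list(module = module), base), list(...))
  do.call(generator_config, args)
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
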