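# Shared fixtures, generated once per test run and cached on disk for the
# session. Cohorts are small by design: geometry and learnability are what
# the tests probe, not scale.

fixture_env <- new.env()

# a small, clearly separable imbalanced cohort (shared across test files)
small_cohort <- function() {
  if (!is.null(fixture_env$small)) return(fixture_env$small)
  dir <- file.path(tempdir(), "ebusfusion-small-cohort")
  cfg <- phantom_config(image_size_px = 208L, pixels_per_cm = 50,
                        n_cases_benign = 4L, n_cases_malignant = 8L,
                        frames_per_case = 2L, seed = 11L)
  man <- generate_cohort(cfg, dir)
  fixture_env$small <- list(config = cfg, manifest = man, dir = dir)
  fixture_env$small
}

# central-difference gradient of scalar f at x
numerical_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Mann-Whitney pair-counting AUC: the O(n^2) oracle
pair_count_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  wins <- 0
  for (a in sp) for (b in sn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}

# literal four-step weight derivation: normalize counts, reciprocate,
# renormalize (independent of the packaged implementation)
four_step_weights <- function(n_b, n_m) {
  norm <- c(n_b, n_m) / sum(c(n_b, n_m))
  rec <- 1 / norm
  rec / sum(rec)
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
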