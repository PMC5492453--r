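# Shared fixtures, memoized across test files (testthat sources helpers
# once per session, so expensive synthetic cohorts are built once).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# Small two-class cohort: 3 participants per class, 6 two-second epochs
# each, 8 channels; the class contrast sits in the 8-12 Hz sub-band.
tiny_sim <- function(effect = 4, seed = 1, noise = 0.1) {
  fixture(sprintf("sim_%g_%d_%g", effect, seed, noise),
          generate_dataset(synth_config(participants_per_class = 3,
                                        epochs_per_participant = 6,
                                        epoch_seconds = 2,
                                        effect_size = effect,
                                        noise_sd = noise, seed = seed)))
}

# Full-protocol cohort (24 participants x 54 six-second epochs, 8 channels)
# with its LOPO-CV run and a 20-cell parameter grid; the wall time of the
# evaluation (filtering cache + LOPO + grid) is recorded.
paper_scale_run <- function() {
  fixture("paper_scale", {
    sim <- generate_dataset(synth_config(seed = 101L))
    spec <- feature_spec("kefbcsp", p = 3, d = 4, sigma = 20)
    t0 <- proc.time()[["elapsed"]]
    cache <- build_feature_cache(sim$set, spec)
    lopo <- lopo_cv(sim$set, spec, classifier_config("knn"), cache = cache)
    grid <- suppressMessages(grid_search(
      sim$set, spec, list(sigma = c(5, 10, 20, 40, 80), d = c(2, 4, 8, 12)),
      classifier_config("knn"), cache = cache))
    elapsed <- proc.time()[["elapsed"]] - t0
    list(sim = sim, spec = spec, lopo = lopo, grid = grid, elapsed = elapsed)
  })
}

# Deterministic multichannel noise epochs for algebraic CSP/KPCA tests.
rand_epoch <- function(n = 4, T = 200, rate = 100, scale = rep(1, n),
                       channels = NULL) {
  eeg_epoch(diag(scale, n) %*% matrix(stats::rnorm(n * T), n), rate, channels)
}

rand_epochs <- function(k, n = 4, T = 200, rate = 100, scale = rep(1, n)) {
  lapply(seq_len(k), function(i) rand_epoch(n, T, rate, scale))
}

# Null cohort for label-permutation checks: 24 participants so the
# leave-one-out prior imbalance (11/23) stays close to chance.
null_sim24 <- function() {
  fixture("null24",
          generate_dataset(synth_config(participants_per_class = 12,
                                        epochs_per_participant = 4,
                                        epoch_seconds = 2, effect_size = 1,
                                        noise_sd = 0.1, seed = 21)))
}

# Mean LOPO accuracy per planted effect size (5 seeds each), shared by the
# monotonicity checks.
effect_monotonicity_means <- function() {
  fixture("effect_means", {
    spec <- feature_spec("fbcsp", p = 1)
    vapply(c(1, 2, 4, 8), function(eff) {
      mean(vapply(1:5, function(s)
        lopo_cv(generate_dataset(synth_config(participants_per_class = 3,
                                              epochs_per_participant = 6,
                                              epoch_seconds = 2,
                                              effect_size = eff,
                                              noise_sd = 0.1,
                                              seed = 300 + s))$set,
                spec)$R_ave, numeric(1)))
    }, numeric(1))
  })
}

# Per-participant correct ratios of the published voting worked examples
# (n_t = 15 and n_t = 1), patients first then controls.
voting_example_nt15 <- function() {
  list(ratios = c(1, 1, 1, 0, 1, 0.4, 0.73, 1, 1, 1, 0.6, 1,
                  0.73, 0.67, 0.33, 0.8, 1, 0.73, 1, 1, 0, 1, 1, 1),
       labels = rep(c(1L, 2L), each = 12L))
}

voting_example_nt1 <- function() {
  list(ratios = c(rep(1, 12),
                  1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1),
       labels = rep(c(1L, 2L), each = 12L))
}
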