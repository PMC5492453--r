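# Build a stateless-feature epoch set whose band power separates classes
# perfectly: class 1 has a strong alpha tone, class 2 only noise.
separable_set <- function(n_per_class = 2, epochs_each = 2, T = 500,
                          rate = 250, seed = 9) {
  set.seed(seed)
  t <- (seq_len(T) - 1) / rate
  mk <- function(signal) {
    s <- if (signal) 5 * sin(2 * pi * 10 * t) else rep(0, T)
    eeg_epoch(rbind(s + rnorm(T, sd = 0.3), rnorm(T, sd = 0.3)), rate,
              c("C3", "C4"))
  }
  epochs <- list(); part <- character(); lab <- integer()
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) 1L else 2L
    for (k in seq_len(epochs_each)) {
      epochs[[length(epochs) + 1L]] <- mk(cls == 1L)
      part <- c(part, sprintf("s%02d", i)); lab <- c(lab, cls)
    }
  }
  labeled_epoch_set(epochs, part, lab)
}

test_that("classifier configurations validate and all three kinds train", {
  expect_error(classifier_config("knn", k = 2), "odd")
  expect_error(classifier_config("svm", C = 0), "positive")
  expect_error(classifier_config("svm", sigma_s = -1), "positive")
  set.seed(1)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  y <- rep(c(1L, 2L), each = 10)
  Xt <- rbind(c(0, 0), c(6, 6))
  for (kind in c("knn", "lda", "svm")) {
    m <- train_classifier(classifier_config(kind, sigma_s = 3), X, y)
    expect_identical(predict(m, Xt), c(1L, 2L))
  }
  expect_error(train_classifier(classifier_config("lda"), X, rep(1L, 20)),
               "single class")
  # small-width Gaussian SVM memorizes any consistent labeling
  set.seed(2)
  Xr <- matrix(rnorm(40), 20, 2)
  yr <- rep(c(1L, 2L), 10)
  ms <- train_classifier(classifier_config("svm", sigma_s = 0.05, C = 100),
                         Xr, yr)
  expect_identical(predict(ms, Xr), yr)
})

test_that("voting aggregation applies the strict majority rule", {
  expect_equal(summarize_voting(rep(1, 4), c(1, 1, 2, 2)),
               list(vote = 4L, sensitivity = 100, specificity = 100, CA = 100))
  # a ratio of exactly 0.5 is not a correct vote
  agg <- summarize_voting(c(0.5, 1, 0.51, 0.5), c(1, 1, 2, 2))
  expect_equal(agg$vote, 2L)
  expect_equal(agg$sensitivity, 50)
  expect_equal(agg$specificity, 50)
  expect_error(summarize_voting(c(1, 1), c(1, 1)), "both classes")
  expect_error(summarize_voting(c(2, 1), c(1, 2)), "0, 1")
})

test_that("LOPO-CV fits per fold and scores perfectly separable data", {
  set <- separable_set()
  spec <- feature_spec("bp", band = "alpha")
  res <- lopo_cv(set, spec, classifier_config("knn", k = 1))
  expect_equal(res$R_ave, 1)
  expect_equal(nrow(res$per_participant), 4L)
  expect_equal(res$per_participant$n_test, rep(2L, 4))
  expect_equal(mean(res$per_participant$rate), res$R_ave)
})

test_that("reordering a participant's epochs does not change fold results", {
  sim <- tiny_sim()
  spec <- feature_spec("bp", band = "alpha")
  r1 <- lopo_cv(sim$set, spec)
  idx <- seq_along(sim$set$epochs)
  p1 <- which(sim$set$participant == "P01")
  idx[p1] <- rev(idx[p1])
  shuffled <- sim$set[idx]
  r2 <- lopo_cv(shuffled, spec)
  expect_equal(r2$per_participant[order(r2$per_participant$participant), ],
               r1$per_participant[order(r1$per_participant$participant), ],
               ignore_attr = TRUE)
})

test_that("voting LOPO matches epoch-level LOPO before aggregation", {
  set <- separable_set(n_per_class = 2, epochs_each = 4)
  spec <- feature_spec("bp", band = "alpha")
  clf <- classifier_config("knn", k = 1)
  n_t <- 3L
  v <- voting_lopo_cv(set, n_t, spec, clf)
  restricted <- set[set$epoch_order <= n_t]
  l <- lopo_cv(restricted, spec, clf)
  o <- order(v$per_participant$participant)
  o2 <- order(l$per_participant$participant)
  expect_equal(v$per_participant$correct_ratio[o],
               l$per_participant$rate[o2])
  expect_equal(v$CA, 100)
  # n_t = 1: every ratio is 0 or 1
  v1 <- voting_lopo_cv(set, 1L, spec, clf)
  expect_true(all(v1$per_participant$correct_ratio %in% c(0, 1)))
  expect_error(voting_lopo_cv(set, 5L, spec, clf), "n_t")
})

test_that("cohort summaries are invariant under participant reordering", {
  sim <- tiny_sim()
  spec <- feature_spec("bp", band = "alpha")
  v1 <- voting_lopo_cv(sim$set, 3L, spec)
  idx <- order(match(sim$set$participant, rev(unique(sim$set$participant))))
  v2 <- voting_lopo_cv(sim$set[idx], 3L, spec)
  expect_equal(v2$CA, v1$CA)
  expect_equal(v2$sensitivity, v1$sensitivity)
  expect_equal(v2$specificity, v1$specificity)
})

test_that("grid search enumerates cells and the shared-work path agrees", {
  sim <- tiny_sim()
  spec <- feature_spec("kefbcsp", p = 1, d = 2, sigma = 10)
  cache <- build_feature_cache(sim$set, spec)
  grid <- list(sigma = c(5, 20), d = c(2, 3))
  gs <- suppressMessages(grid_search(sim$set, spec, grid, cache = cache))
  expect_equal(nrow(gs$table), 4L)
  # the shared-eigendecomposition fast path must equal cell-by-cell LOPO
  for (i in seq_len(nrow(gs$table))) {
    sp <- spec; sp$d <- gs$table$d[i]; sp$sigma <- gs$table$sigma[i]
    expect_equal(gs$table$accuracy[i],
                 lopo_cv(sim$set, sp, cache = cache)$R_ave,
                 tolerance = 1e-10)
  }
  expect_equal(gs$best_accuracy, max(gs$table$accuracy))
  # single cell returns that cell
  g1 <- suppressMessages(grid_search(sim$set, spec, list(d = 2),
                                     cache = cache))
  expect_equal(nrow(g1$table), 1L)
  expect_equal(g1$best_params$d, 2)
  expect_error(suppressMessages(grid_search(sim$set, spec, list())), "empty")
  expect_error(suppressMessages(
    grid_search(sim$set, spec, list(bogus = 1), cache = cache)), "unknown")
})

test_that("an informative kernel width dominates a degenerate one", {
  set <- separable_set(n_per_class = 3, epochs_each = 3)
  spec <- feature_spec("kefbcsp", low = 8, high = 16, width = 4, p = 1,
                       d = 2, sigma = 5)
  # sigma -> 0 makes the kernel matrix the identity: training points become
  # mutually orthogonal and test points project to ~0, losing all signal
  gs <- suppressMessages(grid_search(set, spec, list(sigma = c(1e-4, 5)),
                                     classifier_config("knn", k = 1)))
  expect_equal(gs$best_params$sigma, 5)
  acc <- gs$table$accuracy
  expect_gt(acc[gs$table$sigma == 5], acc[gs$table$sigma == 1e-4])
})

test_that("label permutation drives LOPO accuracy to chance", {
  sim <- null_sim24()
  spec <- feature_spec("bp", band = "alpha")
  cache <- build_feature_cache(sim$set, spec)
  ids <- unique(sim$set$participant)
  set.seed(33)
  accs <- vapply(1:20, function(i) {
    lab_p <- sample(rep(c(1L, 2L), length.out = length(ids)))
    names(lab_p) <- ids
    shuffled <- sim$set
    shuffled$label <- unname(lab_p[shuffled$participant])
    lopo_cv(shuffled, spec, cache = cache)$R_ave
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.1 / 0.5)
})

test_that("nested grid search reports an outer-fold accuracy", {
  set <- separable_set(n_per_class = 3, epochs_each = 2)
  spec <- feature_spec("bp", band = "alpha")
  gs <- suppressMessages(grid_search(set, spec, list(k = c(1, 3)),
                                     nested = TRUE))
  expect_true(gs$best_accuracy >= 0 && gs$best_accuracy <= 1)
  expect_length(gs$per_fold_params, 6L)
})
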