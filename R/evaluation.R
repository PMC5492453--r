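# Classifiers, feature-extraction pipelines, leave-one-participant-out
# cross-validation (LOPO-CV), its majority-voting variant, and grid search.
#
# Participant-independence is enforced structurally: within each fold every
# data-dependent stage (CSP transforms, kernel PCA, classifier) is fitted
# on the training participants only. Per-epoch band scatters are cached
# across folds -- band-pass filtering is a fixed per-epoch operation, so
# caching it cannot leak test information into training.

# ---- classifier configuration and training -------------------------------

#' Classifier configuration
#'
#' @param kind `"knn"`, `"lda"` or `"svm"`.
#' @param k neighbors for k-NN (odd, default 3).
#' @param C SVM penalty weight (default 100).
#' @param sigma_s SVM Gaussian kernel width; the kernel is
#'   `exp(-||x - y||^2 / (2 sigma_s^2))`.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("knn", "lda", "svm"), k = 3L, C = 100,
                              sigma_s = 1) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("'k' must be odd and >= 1")
  if (C <= 0) stop("'C' must be positive")
  if (sigma_s <= 0) stop("'sigma_s' must be positive")
  structure(list(kind = kind, k = k, C = C, sigma_s = sigma_s),
            class = "classifier_config")
}

#' Train a classifier on feature vectors
#'
#' k-NN (Euclidean, lazy), linear discriminant analysis, or a Gaussian-
#' kernel support vector machine. Deterministic given the configuration
#' and data.
#'
#' @param config a [classifier_config()].
#' @param X numeric matrix, feature vectors in rows.
#' @param y integer labels in `{1, 2}`, one per row.
#' @return an object of class `eeg_classifier` with a `predict` method.
#' @export
train_classifier <- function(config, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("one label per row of 'X' required")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  fit <- switch(config$kind,
    knn = list(X = X, y = y),
    lda = MASS::lda(x = X, grouping = factor(y, levels = c(1L, 2L))),
    svm = e1071::svm(x = X, y = factor(y, levels = c(1L, 2L)),
                     kernel = "radial", gamma = 1 / (2 * config$sigma_s^2),
                     cost = config$C, scale = FALSE))
  structure(list(config = config, fit = fit), class = "eeg_classifier")
}

#' @export
predict.eeg_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- switch(object$config$kind,
    knn = class::knn(object$fit$X, newdata,
                     factor(object$fit$y, levels = c(1L, 2L)),
                     k = object$config$k, use.all = TRUE),
    lda = stats::predict(object$fit, newdata)$class,
    svm = stats::predict(object$fit, newdata))
  as.integer(as.character(out))
}

# ---- feature-extraction specification ------------------------------------

#' Specify a feature-extraction pipeline
#'
#' Describes one of the supported features: stateless spectral/nonlinear
#' features (`bp`, `coherence`, `gpfd`), the single-band CSP (`csp`), the
#' filter-bank CSP (`fbcsp`), and its kernel-PCA reductions
#' (`fbcsp_pca` = polynomial degree-1 kernel, i.e. ordinary PCA;
#' `kefbcsp` = Gaussian kernel).
#'
#' @param feature one of `"bp"`, `"coherence"`, `"gpfd"`, `"csp"`,
#'   `"fbcsp"`, `"fbcsp_pca"`, `"kefbcsp"`.
#' @param band band name or `c(lo, hi)` Hz; required for `bp`,
#'   `coherence` and `csp`.
#' @param low,high,width filter-bank range and sub-band width in Hz
#'   (defaults 4-44 Hz, 4-Hz bands).
#' @param order Butterworth design order.
#' @param p CSP filters kept from each end per sub-band.
#' @param d kernel-PCA components retained.
#' @param sigma Gaussian kernel width for `kefbcsp`.
#' @param tau delay (samples) for `gpfd`.
#' @param M_max,saturation_tol GPFD saturation scan settings.
#' @param segment_seconds Welch segment length for `coherence`.
#' @param literal_eq14,paper_literal_scaling kernel-PCA literal-formula
#'   flags, see [fit_kpca()].
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(feature = c("kefbcsp", "fbcsp_pca", "fbcsp", "csp",
                                     "bp", "coherence", "gpfd"),
                         band = NULL, low = 4, high = 44, width = 4,
                         order = 3L, p = 3L, d = 2L, sigma = 10,
                         tau = 100L, M_max = 30L, saturation_tol = 0.05,
                         segment_seconds = 1,
                         literal_eq14 = FALSE, paper_literal_scaling = FALSE) {
  feature <- match.arg(feature)
  if (feature %in% c("bp", "coherence", "csp") && is.null(band))
    stop(sprintf("feature '%s' requires a 'band'", feature))
  if (!feature %in% c("bp", "coherence", "csp") && !is.null(band))
    stop(sprintf("feature '%s' does not take a 'band'", feature))
  structure(list(feature = feature, band = band, low = low, high = high,
                 width = width, order = as.integer(order), p = as.integer(p),
                 d = as.integer(d), sigma = sigma, tau = as.integer(tau),
                 M_max = as.integer(M_max), saturation_tol = saturation_tol,
                 segment_seconds = segment_seconds,
                 literal_eq14 = literal_eq14,
                 paper_literal_scaling = paper_literal_scaling),
            class = "feature_spec")
}

.spec_bands <- function(spec) {
  if (spec$feature == "csp") list(.resolve_band(spec$band))
  else make_filter_bank(spec$low, spec$high, spec$width)$bands
}

.spec_kernel <- function(spec) {
  switch(spec$feature, kefbcsp = "gaussian", fbcsp_pca = "polynomial", NULL)
}

.is_csp_family <- function(spec)
  spec$feature %in% c("csp", "fbcsp", "fbcsp_pca", "kefbcsp")

# ---- per-epoch cache ------------------------------------------------------

#' Precompute per-epoch quantities for repeated cross-validation
#'
#' For CSP-family features, stores the raw scatter matrix `E E^t` of every
#' epoch in every sub-band (band-pass filtering is per-epoch and
#' fold-independent, so this is leakage-free); CSP fits and surrogate
#' energies are then quadratic forms in these matrices. For stateless
#' features, stores the full feature matrix.
#'
#' @param set an `epoch_set`.
#' @param spec a [feature_spec()].
#' @return an opaque cache object for [lopo_cv()], [voting_lopo_cv()] and
#'   [grid_search()].
#' @export
build_feature_cache <- function(set, spec) {
  if (.is_csp_family(spec)) {
    bands <- .spec_bands(spec)
    scat <- lapply(bands, function(b) {
      lapply(set$epochs, function(e)
        .epoch_scatter(bandpass_epoch(e, b, spec$order)))
    })
    structure(list(type = "scatter", bands = bands, scatters = scat,
                   n = length(set$epochs)),
              class = "feature_cache")
  } else {
    X <- t(vapply(set$epochs, function(e) .stateless_features(e, spec),
                  numeric(.stateless_dim(set, spec))))
    structure(list(type = "matrix", X = X, n = length(set$epochs)),
              class = "feature_cache")
  }
}

.stateless_features <- function(epoch, spec) {
  switch(spec$feature,
    bp = unname(band_power(epoch, spec$band)),
    coherence = unname(coherence_features(epoch, spec$band,
                                          spec$segment_seconds)),
    gpfd = unname(gpfd_features(epoch, spec$tau, M_max = spec$M_max,
                                saturation_tol = spec$saturation_tol)))
}

.stateless_dim <- function(set, spec) {
  N <- length(set$channels)
  switch(spec$feature, bp = N, gpfd = N, coherence = N * (N - 1L) / 2L)
}

.subset_cache <- function(cache, idx) {
  if (cache$type == "matrix") {
    cache$X <- cache$X[idx, , drop = FALSE]
  } else {
    cache$scatters <- lapply(cache$scatters, function(sl) sl[idx])
  }
  cache$n <- length(idx)
  cache
}

# Fit CSP models on the training epochs of a fold and return the
# filter-bank CSP matrix for the requested epochs.
.fold_csp_models <- function(cache, labels, train_idx) {
  lapply(seq_along(cache$bands), function(bi) {
    sl <- cache$scatters[[bi]]
    avg <- function(idx) {
      acc <- 0
      for (i in idx) acc <- acc + sl[[i]] / sum(diag(sl[[i]]))
      acc / length(idx)
    }
    i1 <- train_idx[labels[train_idx] == 1L]
    i2 <- train_idx[labels[train_idx] == 2L]
    if (!length(i1) || !length(i2))
      stop("a training fold lost one class entirely")
    m <- .fit_csp_cov(avg(i1), avg(i2))
    m$band <- cache$bands[[bi]]
    m
  })
}

.fbcsp_matrix <- function(cache, models, idx, p) {
  q <- 2L * p * length(models)
  out <- matrix(0, length(idx), q)
  for (bi in seq_along(models)) {
    sl <- cache$scatters[[bi]]
    cols <- ((bi - 1L) * 2L * p + 1L):(bi * 2L * p)
    for (r in seq_along(idx))
      out[r, cols] <- .csp_features_scatter(models[[bi]], sl[[idx[r]]], p)
  }
  out
}

# Train/test feature matrices for one fold under a spec.
.fold_features <- function(cache, spec, labels, train_idx, test_idx) {
  if (cache$type == "matrix") {
    return(list(train = cache$X[train_idx, , drop = FALSE],
                test = cache$X[test_idx, , drop = FALSE]))
  }
  models <- .fold_csp_models(cache, labels, train_idx)
  tr <- .fbcsp_matrix(cache, models, train_idx, spec$p)
  te <- .fbcsp_matrix(cache, models, test_idx, spec$p)
  kern <- .spec_kernel(spec)
  if (!is.null(kern)) {
    km <- fit_kpca(tr, sigma = spec$sigma, d = min(spec$d, nrow(tr)),
                   kernel = kern, poly_degree = 1,
                   paper_literal_scaling = spec$paper_literal_scaling,
                   literal_eq14 = spec$literal_eq14)
    tr <- km$projections
    te <- kpca_project(km, te)
  }
  list(train = tr, test = te)
}

# ---- LOPO-CV --------------------------------------------------------------

#' Leave-one-participant-out cross-validation
#'
#' For each participant, the whole pipeline (CSP transforms per sub-band,
#' kernel PCA, classifier) is fitted on all other participants' epochs and
#' evaluated on every epoch of the held-out participant; `R_ave` is the
#' unweighted mean of the per-participant correct rates.
#'
#' @param set an `epoch_set` with at least 2 participants per class.
#' @param spec a [feature_spec()].
#' @param clf a [classifier_config()].
#' @param cache optional cache from [build_feature_cache()] built on `set`.
#' @return an object of class `lopo_result`: `$per_participant`
#'   (data.frame with `participant`, `label`, `n_test`, `rate`) and
#'   `$R_ave`.
#' @export
lopo_cv <- function(set, spec, clf = classifier_config("knn"), cache = NULL) {
  pl <- participant_labels(set)
  if (sum(pl == 1L) < 2L || sum(pl == 2L) < 2L)
    stop("need at least 2 participants per class so every training fold ",
         "retains both classes")
  if (is.null(cache)) cache <- build_feature_cache(set, spec)
  ids <- names(pl)
  rates <- numeric(length(ids))
  for (f in seq_along(ids)) {
    test_idx <- which(set$participant == ids[f])
    if (!length(test_idx)) stop(sprintf("participant %s has no epochs", ids[f]))
    train_idx <- which(set$participant != ids[f])
    feats <- .fold_features(cache, spec, set$label, train_idx, test_idx)
    model <- train_classifier(clf, feats$train, set$label[train_idx])
    pred <- predict(model, feats$test)
    rates[f] <- mean(pred == set$label[test_idx])
  }
  structure(list(per_participant = data.frame(participant = ids,
                                              label = unname(pl),
                                              n_test = as.integer(table(set$participant)[ids]),
                                              rate = rates,
                                              stringsAsFactors = FALSE),
                 R_ave = mean(rates), spec = spec, clf = clf),
            class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("<lopo_result> %s feature, %s classifier\n",
              x$spec$feature, x$clf$kind))
  cat(sprintf("  R_ave = %.2f%% over %d participants\n",
              100 * x$R_ave, nrow(x$per_participant)))
  invisible(x)
}

# ---- voting-based LOPO-CV --------------------------------------------------

#' Majority-voting leave-one-participant-out cross-validation
#'
#' Restricts every participant to their first `n_t` epochs (by acquisition
#' order), trains on the other participants' first `n_t` epochs, classifies
#' the held-out participant's `n_t` epochs one at a time, and declares the
#' participant correctly classified iff strictly more than half of those
#' epochs are correct. Reports per-participant correct ratios, the vote
#' count, sensitivity (class 1), specificity (class 2), and the individual
#' classification accuracy `CA = vote / participants`.
#'
#' @param set an `epoch_set`.
#' @param n_t epochs per participant used, `1 <= n_t <=` epochs available.
#' @param spec a [feature_spec()].
#' @param clf a [classifier_config()].
#' @param cache optional cache built on the full `set`.
#' @return an object of class `voting_result`.
#' @export
voting_lopo_cv <- function(set, n_t, spec, clf = classifier_config("knn"),
                           cache = NULL) {
  n_t <- as.integer(n_t)
  per_part <- min(table(set$participant))
  if (n_t < 1L || n_t > per_part)
    stop(sprintf("'n_t' must be in 1..%d", per_part))
  keep <- which(set$epoch_order <= n_t)
  sub <- set[keep]
  cache <- if (is.null(cache)) build_feature_cache(sub, spec) else
    .subset_cache(cache, keep)
  pl <- participant_labels(sub)
  ids <- names(pl)
  ratios <- numeric(length(ids))
  for (f in seq_along(ids)) {
    test_idx <- which(sub$participant == ids[f])
    train_idx <- which(sub$participant != ids[f])
    feats <- .fold_features(cache, spec, sub$label, train_idx, test_idx)
    model <- train_classifier(clf, feats$train, sub$label[train_idx])
    pred <- predict(model, feats$test)
    ratios[f] <- mean(pred == sub$label[test_idx])
  }
  agg <- summarize_voting(ratios, unname(pl))
  structure(list(n_t = n_t,
                 per_participant = data.frame(participant = ids,
                                              label = unname(pl),
                                              correct_ratio = ratios,
                                              voted_correct = ratios > 0.5,
                                              stringsAsFactors = FALSE),
                 vote = agg$vote, sensitivity = agg$sensitivity,
                 specificity = agg$specificity, CA = agg$CA,
                 spec = spec, clf = clf),
            class = "voting_result")
}

#' @export
print.voting_result <- function(x, ...) {
  cat(sprintf("<voting_result> n_t = %d, %d/%d participants voted correct\n",
              x$n_t, x$vote, nrow(x$per_participant)))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$CA))
  invisible(x)
}

#' Aggregate per-participant correct ratios into cohort statistics
#'
#' A participant is voted correct iff their ratio is strictly above 0.5.
#' Sensitivity is the fraction of class-1 (patient) participants voted
#' correct, specificity the class-2 (control) fraction, and `CA` the
#' overall fraction. Values are exact fractions expressed in percent.
#'
#' @param ratios numeric per-participant correct ratios in `[0, 1]`.
#' @param labels integer participant labels in `{1, 2}`.
#' @return list with `vote`, `sensitivity`, `specificity`, `CA` (percent).
#' @export
summarize_voting <- function(ratios, labels) {
  labels <- as.integer(labels)
  if (length(ratios) != length(labels))
    stop("'ratios' and 'labels' must have equal length")
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  if (!any(labels == 1L) || !any(labels == 2L))
    stop("both classes must be present")
  correct <- ratios > 0.5
  list(vote = sum(correct),
       sensitivity = 100 * mean(correct[labels == 1L]),
       specificity = 100 * mean(correct[labels == 2L]),
       CA = 100 * mean(correct))
}

# ---- grid search -----------------------------------------------------------

#' Exhaustive grid search over pipeline and classifier parameters
#'
#' Evaluates every cell of the Cartesian product of the supplied parameter
#' values by LOPO-CV (or its voting variant at a fixed `n_t`) and returns
#' the best cell; ties go to the first cell in iteration order (parameter
#' names sorted alphabetically, values ascending, first parameter varying
#' fastest). Grid parameters may address the feature spec (`p`, `d`,
#' `sigma`, `tau`, `width`) or the classifier (`k`, `C`, `sigma_s`).
#'
#' Note: selecting parameters by the same cross-validation that reports the
#' accuracy optimistically biases the estimate; `nested = TRUE` instead
#' re-runs the search inside each training fold and reports the unbiased
#' outer-fold accuracy (slower; selected cells may differ per fold).
#'
#' @param set an `epoch_set`.
#' @param spec base [feature_spec()]; grid values override its fields.
#' @param grid named list, parameter name to candidate values.
#' @param clf base [classifier_config()].
#' @param evaluator `"lopo"` or `"voting"`.
#' @param n_t epochs per participant for the voting evaluator.
#' @param cache optional cache from [build_feature_cache()]; only reused
#'   when no grid parameter changes the filtering stage.
#' @param nested use nested cross-validation (see above).
#' @return an object of class `grid_search_result` with `$best_params`,
#'   `$best_accuracy` and the full `$table`.
#' @export
grid_search <- function(set, spec, grid, clf = classifier_config("knn"),
                        evaluator = c("lopo", "voting"), n_t = NULL,
                        cache = NULL, nested = FALSE) {
  evaluator <- match.arg(evaluator)
  if (!length(grid)) stop("empty parameter grid")
  if (evaluator == "voting" && is.null(n_t))
    stop("the voting evaluator requires 'n_t'")
  nm <- sort(names(grid))
  cells <- expand.grid(lapply(stats::setNames(nm, nm),
                              function(p) sort(unlist(grid[[p]]))),
                       KEEP.OUT.ATTRS = FALSE)
  message("grid_search: parameters are selected by the same ",
          "cross-validation that reports the accuracy; the selected ",
          "accuracy is optimistically biased (use nested = TRUE for an ",
          "unbiased estimate)")
  if (nested) return(.nested_grid(set, spec, grid, clf, evaluator, n_t, cells))
  spec_pars <- intersect(nm, c("p", "d", "sigma", "tau", "width", "low",
                               "high", "order", "segment_seconds"))
  clf_pars <- intersect(nm, c("k", "C", "sigma_s"))
  unknown <- setdiff(nm, c(spec_pars, clf_pars))
  if (length(unknown))
    stop(sprintf("unknown grid parameter(s): %s", paste(unknown, collapse = ", ")))
  filter_pars <- intersect(spec_pars, c("width", "low", "high", "order"))
  if (is.null(cache) && !length(filter_pars))
    cache <- build_feature_cache(set, spec)
  fast <- evaluator == "lopo" && .is_csp_family(spec) &&
    !is.null(.spec_kernel(spec)) && !length(filter_pars) &&
    all(spec_pars %in% c("p", "d", "sigma"))
  acc <- if (fast) {
    .grid_lopo_kpca_fast(set, spec, cells, clf, clf_pars, cache)
  } else {
    vapply(seq_len(nrow(cells)), function(ci) {
      sp <- spec; cl <- clf
      for (pp in spec_pars) sp[[pp]] <- cells[[pp]][ci]
      for (pp in clf_pars) cl[[pp]] <- cells[[pp]][ci]
      cc <- if (length(filter_pars)) NULL else cache
      if (evaluator == "lopo") lopo_cv(set, sp, cl, cache = cc)$R_ave
      else voting_lopo_cv(set, n_t, sp, cl, cache = cc)$CA / 100
    }, numeric(1))
  }
  best <- which.max(acc)
  structure(list(best_params = as.list(cells[best, , drop = FALSE]),
                 best_accuracy = acc[best],
                 table = cbind(cells, accuracy = acc),
                 evaluator = evaluator, n_t = n_t),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d cells (%s evaluator)\n",
              nrow(x$table), x$evaluator))
  cat("  best:", paste(names(x$best_params), unlist(x$best_params),
                       sep = "=", collapse = ", "),
      sprintf("-> %.2f%%\n", 100 * x$best_accuracy))
  invisible(x)
}

# Shared-work grid evaluation for kernel-PCA pipelines under LOPO: per fold,
# FBCSP vectors are computed once per p, the kernel eigenproblem once per
# (p, sigma), and each d reuses the leading components.
.grid_lopo_kpca_fast <- function(set, spec, cells, clf, clf_pars, cache) {
  pl <- participant_labels(set)
  ids <- names(pl)
  kern <- .spec_kernel(spec)
  p_vals <- if ("p" %in% names(cells)) unique(cells$p) else spec$p
  rates <- matrix(0, length(ids), nrow(cells))
  for (f in seq_along(ids)) {
    test_idx <- which(set$participant == ids[f])
    train_idx <- which(set$participant != ids[f])
    y_tr <- set$label[train_idx]; y_te <- set$label[test_idx]
    models <- .fold_csp_models(cache, set$label, train_idx)
    for (pv in p_vals) {
      tr <- .fbcsp_matrix(cache, models, train_idx, pv)
      te <- .fbcsp_matrix(cache, models, test_idx, pv)
      rows_p <- if ("p" %in% names(cells)) which(cells$p == pv) else
        seq_len(nrow(cells))
      sig_vals <- if ("sigma" %in% names(cells))
        unique(cells$sigma[rows_p]) else spec$sigma
      d2tr <- if (kern == "gaussian") .sqdist(tr, tr) else NULL
      d2te <- if (kern == "gaussian") .sqdist(te, tr) else NULL
      for (sv in sig_vals) {
        rows_s <- if ("sigma" %in% names(cells))
          rows_p[cells$sigma[rows_p] == sv] else rows_p
        d_vals <- if ("d" %in% names(cells)) cells$d[rows_s] else
          rep(spec$d, length(rows_s))
        d_max <- min(max(d_vals), nrow(tr))
        if (kern == "gaussian") {
          K <- exp(-d2tr / (2 * sv^2))
          Kt <- exp(-d2te / (2 * sv^2))
        } else {
          K <- tcrossprod(tr)
          Kt <- te %*% t(tr)
        }
        km <- .kpca_from_gram(K, d_max, spec$paper_literal_scaling)
        n <- nrow(K)
        Ktc <- if (spec$literal_eq14) Kt else
          Kt - matrix(colMeans(K), nrow(Kt), n, byrow = TRUE) -
            rowMeans(Kt) + mean(K)
        Ztr <- if (spec$literal_eq14) K %*% km$alphas else km$proj_train
        Zte <- Ktc %*% km$alphas
        for (ri in seq_along(rows_s)) {
          ci <- rows_s[ri]
          dv <- min(d_vals[ri], km$d)
          cl <- clf
          for (pp in clf_pars) cl[[pp]] <- cells[[pp]][ci]
          model <- train_classifier(cl, Ztr[, seq_len(dv), drop = FALSE], y_tr)
          pred <- predict(model, Zte[, seq_len(dv), drop = FALSE])
          rates[f, ci] <- mean(pred == y_te)
        }
      }
    }
  }
  colMeans(rates)
}

# Eigen machinery shared with fit_kpca, starting from an uncentered Gram
# matrix of the training set.
.kpca_from_gram <- function(K, d, paper_literal_scaling = FALSE) {
  Kc <- center_kernel(K)
  Kc <- (Kc + t(Kc)) / 2
  eg <- eigen(Kc, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eg$values), 1e-300)
  d <- min(d, sum(eg$values > tol))
  ev <- eg$values[seq_len(d)]
  A <- eg$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  alphas <- sweep(A, 2L, if (paper_literal_scaling) ev else sqrt(ev), "/")
  list(alphas = alphas, eigvals = ev, d = d,
       proj_train = Kc %*% alphas)
}

.nested_grid <- function(set, spec, grid, clf, evaluator, n_t, cells) {
  pl <- participant_labels(set)
  ids <- names(pl)
  rates <- numeric(length(ids))
  chosen <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    inner <- set[set$participant != ids[f]]
    gs <- suppressMessages(grid_search(inner, spec, grid, clf, evaluator,
                                       n_t = n_t, nested = FALSE))
    sp <- spec; cl <- clf
    for (pp in names(gs$best_params)) {
      v <- gs$best_params[[pp]]
      if (pp %in% c("k", "C", "sigma_s")) cl[[pp]] <- v else sp[[pp]] <- v
    }
    test_idx <- which(set$participant == ids[f])
    train_idx <- which(set$participant != ids[f])
    cache <- build_feature_cache(set, sp)
    feats <- .fold_features(cache, sp, set$label, train_idx, test_idx)
    model <- train_classifier(cl, feats$train, set$label[train_idx])
    rates[f] <- mean(predict(model, feats$test) == set$label[test_idx])
    chosen[[f]] <- gs$best_params
  }
  structure(list(best_params = NULL, best_accuracy = mean(rates),
                 per_fold_params = chosen,
                 table = data.frame(participant = ids, rate = rates),
                 evaluator = evaluator, n_t = n_t, nested = TRUE),
            class = "grid_search_result")
}
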