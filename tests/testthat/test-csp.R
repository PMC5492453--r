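# Epoch whose scatter E E^t is exactly the given diagonal (T = N columns).
diag_epoch <- function(d, rate = 100) {
  n <- length(d)
  eeg_epoch(cbind(diag(sqrt(d), n), matrix(0, n, 1))[, 1:max(n, 2)], rate)
}

test_that("average covariance is trace-normalized and matches hand cases", {
  e_id <- eeg_epoch(diag(2), 100)
  expect_equal(average_covariance(list(e_id)), 0.5 * diag(2))
  set.seed(1)
  e <- rand_epoch(3)
  expect_equal(sum(diag(average_covariance(list(e)))), 1)
  # two rank-1 epochs on orthogonal channels average to diag(0.5, 0.5)
  e1 <- eeg_epoch(rbind(c(1, 1), c(0, 0)) + 0, 100)
  e2 <- eeg_epoch(rbind(c(0, 0), c(2, -1)) + 0, 100)
  expect_equal(average_covariance(list(e1, e2)), diag(c(0.5, 0.5)))
  expect_error(average_covariance(list()), "no epochs")
})

test_that("CSP solves the 2-channel diagonal case in closed form", {
  # class covariances proportional to diag(2,1) and diag(1,2):
  # whitened class-1 eigenvalues are 2/3 and 1/3, filters axis-aligned
  m <- fit_csp(list(diag_epoch(c(2, 1))), list(diag_epoch(c(1, 2))))
  expect_equal(m$eigvals, c(2 / 3, 1 / 3), tolerance = 1e-10)
  aW <- abs(m$W / sqrt(rowSums(m$W^2)))
  expect_equal(aW, diag(2), tolerance = 1e-8)
})

test_that("CSP satisfies whitening and eigenvalue complementarity", {
  set.seed(2)
  c1 <- rand_epochs(6, n = 4, scale = c(3, 1, 1, 0.5))
  c2 <- rand_epochs(6, n = 4, scale = c(0.5, 1, 1, 3))
  m <- fit_csp(c1, c2)
  C1 <- average_covariance(c1); C2 <- average_covariance(c2)
  expect_equal(m$W %*% (C1 + C2) %*% t(m$W), diag(4), tolerance = 1e-6)
  S1 <- m$W %*% C1 %*% t(m$W)
  expect_equal(diag(S1), m$eigvals, tolerance = 1e-8)
  expect_lt(max(abs(S1 - diag(diag(S1)))), 1e-8)
  # lambda_1 + lambda_2 = I: class-2 eigenvalues are the complements
  S2 <- m$W %*% C2 %*% t(m$W)
  expect_equal(diag(S2), 1 - m$eigvals, tolerance = 1e-8)
  expect_true(all(diff(m$eigvals) <= 1e-12))
  # identical classes: all eigenvalues 1/2
  m0 <- fit_csp(c1, c1)
  expect_equal(m0$eigvals, rep(0.5, 4), tolerance = 1e-8)
})

test_that("CSP eigenvalues match a brute-force generalized eigenproblem", {
  for (seed in 1:5) {
    for (n in 2:3) {
      set.seed(seed)
      c1 <- rand_epochs(5, n = n, scale = seq(2, 1, length.out = n))
      c2 <- rand_epochs(5, n = n, scale = seq(1, 2, length.out = n))
      m <- fit_csp(c1, c2)
      C1 <- average_covariance(c1); C2 <- average_covariance(c2)
      brute <- sort(Re(eigen(solve(C1 + C2) %*% C1)$values), decreasing = TRUE)
      expect_equal(m$eigvals, brute, tolerance = 1e-8)
    }
  }
})

test_that("CSP features are invariant to invertible channel mixing", {
  set.seed(3)
  c1 <- rand_epochs(8, n = 4, scale = c(3, 1, 1, 0.5))
  c2 <- rand_epochs(8, n = 4, scale = c(0.5, 1, 1, 3))
  probe <- rand_epoch(4)
  m <- fit_csp(c1, c2)
  f0 <- csp_features(m, probe, p = 2)
  # trace-preserving mixings (scaled rotations) leave the per-epoch trace
  # normalization untouched, so the CSP solution absorbs them exactly
  A <- 1.3 * qr.Q(qr(matrix(rnorm(16), 4)))
  mix <- function(e) eeg_epoch(A %*% e$data, e$rate, e$channels)
  m2 <- fit_csp(lapply(c1, mix), lapply(c2, mix))
  f1 <- csp_features(m2, mix(probe), p = 2)
  expect_equal(f1, f0, tolerance = 1e-6)
  # a general invertible mixing reweights the per-epoch traces, so
  # invariance is approximate, degrading only mildly
  B <- diag(4) + matrix(c(0, 0.3, -0.2, 0.1,
                          0.2, 0, 0.3, -0.1,
                          0, 0.2, 0, 0.3,
                          -0.2, 0.1, 0.2, 0), 4, 4, byrow = TRUE)
  mixb <- function(e) eeg_epoch(B %*% e$data, e$rate, e$channels)
  m3 <- fit_csp(lapply(c1, mixb), lapply(c2, mixb))
  f2 <- csp_features(m3, mixb(probe), p = 2)
  expect_equal(f2, f0, tolerance = 0.1)
})

test_that("normalized log-power features satisfy their identities", {
  ident <- structure(list(W = diag(2), eigvals = c(0.6, 0.4), band = NULL,
                          channels = NULL), class = "csp_model")
  # equal surrogate powers -> both features log(1/2)
  eq <- eeg_epoch(rbind(c(1, 1, 0, 0), c(0, 0, 1, -1)) + 0, 100)
  expect_equal(csp_features(ident, eq, p = 1), rep(log(0.5), 2))
  # powers 3 and 1 -> log(3/4), log(1/4)
  e31 <- eeg_epoch(rbind(c(sqrt(3), 0), c(1, 0)) + 0, 100)
  expect_equal(csp_features(ident, e31, p = 1), log(c(0.75, 0.25)))
  # normalization identity on arbitrary data
  set.seed(4)
  m <- fit_csp(rand_epochs(4, n = 4), rand_epochs(4, n = 4))
  f <- csp_features(m, rand_epoch(4), p = 2)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-12)
  expect_error(csp_features(m, rand_epoch(4), p = 3), "'p' must be")
  z <- eeg_epoch(matrix(0, 4, 10), 100)
  expect_error(csp_features(m, z, p = 2), "degenerate")
})

test_that("filter-bank concatenation has dimension 2 p N_sb", {
  sim <- tiny_sim()
  set <- sim$set
  bank <- make_filter_bank(4, 44, 4)
  i1 <- which(set$label == 1L); i2 <- which(set$label == 2L)
  models <- lapply(bank$bands, function(b) {
    fit_csp(lapply(set$epochs[i1], bandpass_epoch, band = b),
            lapply(set$epochs[i2], bandpass_epoch, band = b), band = b)
  })
  v <- extract_fbcsp(models, set$epochs[[1]], p = 3, bank)
  expect_length(v, 60L)  # 2 * 3 * 10
  expect_true(all(is.finite(v)))
  v1 <- extract_fbcsp(models, set$epochs[[1]], p = 1, bank)
  expect_length(v1, 20L)
  # single-band bank: concatenation of one equals the per-band features
  bank1 <- make_filter_bank(8, 12, 4)
  m1 <- models[2]  # the 8-12 Hz model
  expect_equal(extract_fbcsp(m1, set$epochs[[1]], p = 1, bank1),
               csp_features(m1[[1]], bandpass_epoch(set$epochs[[1]], c(8, 12)),
                            p = 1))
  expect_error(extract_fbcsp(models[1:3], set$epochs[[1]], 1, bank), "models")
})

test_that("CSP model TSV serialization round-trips", {
  set.seed(5)
  m <- fit_csp(rand_epochs(3, n = 3), rand_epochs(3, n = 3), band = c(8, 12))
  path <- tempfile(fileext = ".tsv")
  write_csp_models(list(m, m), path)
  back <- read_csp_models(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$W, m$W, tolerance = 1e-9)
  expect_equal(back[[2]]$eigvals, m$eigvals, tolerance = 1e-9)
  expect_equal(back[[1]]$band, c(8, 12))
})
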