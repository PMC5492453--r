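# Comparison features: spectral band power, Welch magnitude-squared
# coherence between channel pairs, and the Grassberger-Procaccia
# correlation dimension (GPFD) of single-channel series.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-44 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 44),
             stringsAsFactors = FALSE)
}

.resolve_band <- function(band) {
  if (is.character(band)) {
    tab <- eeg_bands()
    i <- match(band, tab$name)
    if (is.na(i)) stop(sprintf("unknown band name '%s'", band))
    c(tab$lo[i], tab$hi[i])
  } else as.numeric(band)
}

#' Per-channel spectral band power
#'
#' Power of each channel within `[lo, hi)` Hz, from a single full-epoch
#' periodogram (rectangular window, one DFT); the concatenation over
#' channels is the N-dimensional band-power feature.
#'
#' @param epoch an `eeg_epoch`.
#' @param band a band name (`"alpha"`, ...) or numeric `c(lo, hi)` in Hz.
#' @return nonnegative numeric vector, one value per channel, named by
#'   channel.
#' @export
band_power <- function(epoch, band) {
  band <- .resolve_band(band)
  T_ <- ncol(epoch$data)
  nyq <- epoch$rate / 2
  if (band[2L] > nyq)
    stop(sprintf("band edge %g Hz exceeds the Nyquist frequency %g Hz",
                 band[2L], nyq))
  freqs <- (seq_len(T_) - 1L) * epoch$rate / T_
  half <- freqs <= nyq
  sel <- half & freqs >= band[1L] & freqs < band[2L]
  out <- apply(epoch$data, 1L, function(x) {
    px <- Mod(stats::fft(x))^2
    2 * sum(px[sel]) / T_^2   # one-sided power, amplitude^2 units
  })
  names(out) <- epoch$channels
  out
}

#' Band-averaged magnitude-squared coherence of all channel pairs
#'
#' Welch estimator: Hann-windowed segments of `segment_seconds` with 50%
#' overlap; cross- and auto-spectra averaged over segments; the
#' magnitude-squared coherence `|Sxy|^2 / (Sxx Syy)` is averaged over the
#' frequency bins inside `[lo, hi)`. Returns the `(N^2 - N)/2` upper-
#' triangle pairs in row-major order ((1,2), (1,3), ..., (2,3), ...).
#'
#' @param epoch an `eeg_epoch` with at least 2 channels.
#' @param band a band name or numeric `c(lo, hi)` in Hz.
#' @param segment_seconds Welch segment length in seconds (default 1).
#' @return numeric vector of length `N*(N-1)/2`, values in `[0, 1]`, named
#'   `"CH1-CH2"` style.
#' @export
coherence_features <- function(epoch, band, segment_seconds = 1) {
  band <- .resolve_band(band)
  N <- nrow(epoch$data)
  if (N < 2L) stop("coherence needs at least 2 channels")
  T_ <- ncol(epoch$data)
  seg <- round(epoch$rate * segment_seconds)
  if (T_ < seg)
    stop(sprintf("epoch (%d samples) shorter than one %d-sample segment",
                 T_, seg))
  step <- max(1L, floor(seg / 2))
  starts <- seq(1L, T_ - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  freqs <- (seq_len(seg) - 1L) * epoch$rate / seg
  sel <- freqs >= band[1L] & freqs < band[2L] & freqs <= epoch$rate / 2
  if (!any(sel)) stop("band contains no frequency bin at this segment length")
  # segment FFTs: [channel x bin x segment]
  F <- array(0 + 0i, c(N, sum(sel), length(starts)))
  for (s in seq_along(starts)) {
    cols <- starts[s]:(starts[s] + seg - 1L)
    for (i in seq_len(N)) {
      X <- stats::fft(epoch$data[i, cols] * w)
      F[i, , s] <- X[sel]
    }
  }
  auto <- matrix(0, N, dim(F)[2L])
  for (i in seq_len(N))
    auto[i, ] <- rowMeans(matrix(Mod(F[i, , ])^2, dim(F)[2L]))
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  out <- numeric(nrow(pairs))
  nm <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    cross <- rowMeans(matrix(F[i, , ] * Conj(F[j, , ]), dim(F)[2L]))
    msc <- Mod(cross)^2 / (auto[i, ] * auto[j, ])
    out[k] <- mean(pmin(msc, 1))
    nm[k] <- paste0(epoch$channels[i], "-", epoch$channels[j])
  }
  names(out) <- nm
  out
}

# ---- Grassberger-Procaccia correlation dimension -------------------------

#' Delay-coordinate embedding of a scalar series
#'
#' Row `i` of the result is `(x[i], x[i + tau], ..., x[i + (M-1) tau])`,
#' for `i = 1 .. T - (M-1) tau`.
#'
#' @param x numeric series of length T.
#' @param M embedding dimension, `>= 1`.
#' @param tau delay in samples, `>= 1`.
#' @return a `(T - (M-1) tau) x M` matrix.
#' @export
embed_time_series <- function(x, M, tau) {
  T_ <- length(x)
  M <- as.integer(M); tau <- as.integer(tau)
  if (M < 1L || tau < 1L) stop("'M' and 'tau' must be positive integers")
  count <- T_ - (M - 1L) * tau
  if (count < 2L)
    stop(sprintf("series too short: T - (M-1)*tau = %d < 2", count))
  vapply(0:(M - 1L), function(m) x[seq_len(count) + m * tau], numeric(count))
}

#' Correlation integral at radius r
#'
#' Fraction of unordered pairs of embedded vectors whose Euclidean distance
#' is strictly below `r` (Heaviside with `theta(0) = 0`). By default the
#' normalizer is the number of embedded-vector pairs, so the integral
#' reaches 1 for large `r`; `literal_T_normalizer = TRUE` divides by
#' `T (T - 1) / 2` with `T` the original series length instead.
#'
#' @param Y embedded matrix (rows = delay vectors), or a precomputed
#'   `dist`-like vector of pairwise distances.
#' @param r radius, `>= 0`.
#' @param literal_T_normalizer use the series-length normalizer.
#' @param series_length original series length `T` (required for the
#'   literal normalizer).
#' @return scalar in `[0, 1]` (possibly below 1 under the literal
#'   normalizer), nondecreasing in `r`.
#' @export
correlation_integral <- function(Y, r, literal_T_normalizer = FALSE,
                                 series_length = NULL) {
  if (r < 0) stop("'r' must be nonnegative")
  dd <- if (inherits(Y, "dist") || is.null(dim(Y))) as.numeric(Y) else
    as.numeric(stats::dist(Y))
  if (!length(dd)) stop("need at least 2 embedded vectors")
  cnt <- sum(dd < r)
  if (literal_T_normalizer) {
    if (is.null(series_length))
      stop("'series_length' required for the literal normalizer")
    2 * cnt / (series_length * (series_length - 1))
  } else {
    cnt / length(dd)
  }
}

# Correlation integrals over a radius grid (strict inequality per the
# Heaviside convention theta(0) = 0).
.corr_curve <- function(dd, radii) {
  counts <- vapply(radii, function(r) sum(dd < r), numeric(1))
  counts / length(dd)
}

#' Correlation dimension at a fixed embedding dimension
#'
#' Estimates the small-radius slope of `log C(r)` versus `log r`:
#' correlation integrals are evaluated on `n_radii` log-spaced radii
#' between the 1st and 99th percentiles of the pairwise distances, a
#' sliding window of `window` radii is scored by the variance of its local
#' finite-difference slopes, and a least-squares line is fitted over the
#' most slope-constant window.
#'
#' @param x numeric series.
#' @param M embedding dimension.
#' @param tau delay in samples.
#' @param n_radii number of log-spaced radii (default 30).
#' @param window width of the linear-region window in radii (default 10).
#' @param max_points cap on embedded vectors (evenly thinned above it) to
#'   bound the O(count^2) distance computation.
#' @return nonnegative slope estimate (the correlation dimension).
#' @export
correlation_dimension <- function(x, M, tau, n_radii = 30L, window = 10L,
                                  max_points = 2000L) {
  Y <- embed_time_series(x, M, tau)
  if (nrow(Y) > max_points) {
    keep <- unique(round(seq(1L, nrow(Y), length.out = max_points)))
    Y <- Y[keep, , drop = FALSE]
  }
  dd <- as.numeric(stats::dist(Y))
  dd_pos <- dd[dd > 0]
  if (length(dd_pos) < 3L)
    stop("degenerate series: fewer than 3 distinct pairwise distances")
  # discard distances at floating-point-noise scale (near-duplicate points of
  # periodic orbits) so the radius grid spans geometric scales only
  hi <- stats::quantile(dd_pos, 0.99, names = FALSE)
  dd_geo <- dd_pos[dd_pos > 1e-6 * hi]
  if (length(dd_geo) < 3L)
    stop("degenerate series: fewer than 3 distinct pairwise distances")
  q <- stats::quantile(dd_geo, c(0.01, 0.99), names = FALSE)
  radii <- exp(seq(log(q[1L]), log(q[2L]), length.out = n_radii))
  C <- .corr_curve(dd, radii)
  # usable radii: nonzero counts, and below the large-r saturation plateau
  # where C(r) is constant by construction and carries no scaling slope
  keep <- C > 0 & C < 0.975
  radii <- radii[keep]; C <- C[keep]
  if (length(radii) < 3L) stop("fewer than 3 usable radii for the slope fit")
  lr <- log(radii); lC <- log(C)
  w <- min(window, length(lr))
  if (w < 3L) w <- 3L
  slopes <- diff(lC) / diff(lr)
  best <- 1L; best_score <- Inf
  for (s in seq_len(length(lr) - w + 1L)) {
    sl <- slopes[s:(s + w - 2L)]
    score <- stats::var(sl)
    if (is.finite(score) && score < best_score) {
      best_score <- score; best <- s
    }
  }
  idx <- best:(best + w - 1L)
  fit <- stats::lsfit(lr[idx], lC[idx])
  max(unname(fit$coefficients[2L]), 0)
}

#' Grassberger-Procaccia fractal dimension of a series
#'
#' Runs [correlation_dimension()] for embedding dimensions `M = 2 ..
#' M_max` and returns the estimate at the smallest `M` whose relative
#' increase over the previous `M` falls below `saturation_tol` (the
#' saturation value). If saturation is never reached, the `M_max` estimate
#' is returned with attribute `saturated = FALSE`.
#'
#' @param x numeric series.
#' @param tau delay in samples (candidate values 50..100 are typical for
#'   6-s, 500-Hz epochs).
#' @param M_max largest embedding dimension tried (default 30).
#' @param saturation_tol relative-increase threshold (default 0.05).
#' @param ... passed to [correlation_dimension()].
#' @return scalar dimension with attributes `saturated` (logical) and `M`
#'   (embedding dimension at which it was taken).
#' @export
gpfd <- function(x, tau, M_max = 30L, saturation_tol = 0.05, ...) {
  d_prev <- NULL
  for (M in 2:M_max) {
    d_cur <- correlation_dimension(x, M, tau, ...)
    if (!is.null(d_prev)) {
      rel <- (d_cur - d_prev) / max(d_prev, .Machine$double.eps)
      if (rel < saturation_tol)
        return(structure(d_cur, saturated = TRUE, M = M))
    }
    d_prev <- d_cur
  }
  structure(d_prev, saturated = FALSE, M = M_max)
}

#' Per-channel GPFD feature vector of an epoch
#'
#' @param epoch an `eeg_epoch`.
#' @param tau delay in samples.
#' @param ... passed to [gpfd()].
#' @return numeric vector, one dimension estimate per channel.
#' @export
gpfd_features <- function(epoch, tau, ...) {
  out <- apply(epoch$data, 1L, function(x) as.numeric(gpfd(x, tau, ...)))
  names(out) <- epoch$channels
  out
}
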