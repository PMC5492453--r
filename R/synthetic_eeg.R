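# Synthetic two-class multichannel EEG with a known band-limited
# spatial-variance contrast, for validation and parameter-recovery tests.
#
# Each source is a sum of independent band-limited Gaussian processes, one
# per filter-bank sub-band (white noise spectrally masked to the band). In
# class 1 the designated source's component in the discriminative band has
# its variance multiplied by `effect_size`; channels are a fixed mixing of
# the sources plus white sensor noise, with per-participant channel gains
# drawn log-normally to make participants heterogeneous.

#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate a resting-state recording protocol: 500 Hz sampling,
#' 6-s epochs, 54 epochs per participant, 12 participants per class, and
#' an 8-channel (temporal montage) layout.
#'
#' @param n_channels number of channels (8 uses the temporal montage
#'   names, 30 the entire montage, 3 the occipital one).
#' @param rate sampling rate in Hz.
#' @param epoch_seconds epoch length in seconds.
#' @param participants_per_class participants in each of the two classes.
#' @param epochs_per_participant epochs per participant.
#' @param mixing channels x sources mixing matrix; default is a random
#'   full-rank orthonormal matrix drawn from the seed.
#' @param discriminative_band `c(lo, hi)` Hz carrying the class contrast.
#' @param effect_size class-1 / class-2 variance ratio of the
#'   discriminative source within the discriminative band (`1` = null).
#' @param noise_sd standard deviation of additive white sensor noise,
#'   relative to unit-variance band sources.
#' @param participant_gain_sd log-sd of per-participant channel gains.
#' @param low,high,width source filter bank (matching the analysis bank).
#' @param seed integer RNG seed; the dataset is a pure function of the
#'   configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8L, rate = 500, epoch_seconds = 6,
                         participants_per_class = 12L,
                         epochs_per_participant = 54L, mixing = NULL,
                         discriminative_band = c(8, 12), effect_size = 4,
                         noise_sd = 0.1, participant_gain_sd = 0.1,
                         low = 4, high = 44, width = 4, seed = 1L) {
  if (effect_size <= 0) stop("'effect_size' must be positive")
  if (n_channels < 2L) stop("need at least 2 channels")
  if (participants_per_class < 1L || epochs_per_participant < 1L)
    stop("counts must be positive")
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels) stop("mixing must have n_channels rows")
    if (qr(mixing)$rank < ncol(mixing)) stop("mixing is rank-deficient")
  }
  structure(list(n_channels = as.integer(n_channels), rate = rate,
                 epoch_seconds = epoch_seconds,
                 participants_per_class = as.integer(participants_per_class),
                 epochs_per_participant = as.integer(epochs_per_participant),
                 mixing = mixing, discriminative_band = discriminative_band,
                 effect_size = effect_size, noise_sd = noise_sd,
                 participant_gain_sd = participant_gain_sd,
                 low = low, high = high, width = width, seed = as.integer(seed)),
            class = "synth_config")
}

.synth_channel_names <- function(n) {
  if (n == 8L) .montage_table$temporal
  else if (n == 30L) .montage_table$entire
  else if (n == 3L) .montage_table$occipital
  else paste0("CH", seq_len(n))
}

# Band-limited unit-variance Gaussian noise by spectral masking.
.bandlimited_noise <- function(T_, rate, lo, hi) {
  x <- stats::rnorm(T_)
  X <- stats::fft(x)
  f <- (seq_len(T_) - 1L) * rate / T_
  f <- pmin(f, rate - f)          # fold to two-sided frequency magnitude
  X[!(f >= lo & f < hi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / T_
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for this epoch length")
  y / s
}

#' Generate a synthetic labeled EEG dataset
#'
#' @param config a [synth_config()].
#' @return an object of class `synth_eeg`: `$set` (a labeled `epoch_set`)
#'   and `$truth` (mixing matrix, index of the discriminative source, the
#'   discriminative band, per-participant gains, and the config).
#' @examples
#' sim <- generate_dataset(synth_config(participants_per_class = 2,
#'                                      epochs_per_participant = 3,
#'                                      epoch_seconds = 2, seed = 7))
#' sim$set
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  N <- config$n_channels
  T_ <- round(config$rate * config$epoch_seconds)
  bank <- make_filter_bank(config$low, config$high, config$width)
  db <- config$discriminative_band
  disc_band_idx <- which(vapply(bank$bands, function(b)
    isTRUE(all.equal(as.numeric(b), as.numeric(db))), logical(1)))
  A <- config$mixing
  if (is.null(A)) A <- qr.Q(qr(matrix(stats::rnorm(N * N), N)))
  n_src <- ncol(A)
  src_idx <- 1L                    # designated discriminative source
  chn <- .synth_channel_names(N)
  n_part <- 2L * config$participants_per_class
  ids <- sprintf("P%02d", seq_len(n_part))
  labels_p <- rep(c(1L, 2L), each = config$participants_per_class)
  gains <- matrix(exp(stats::rnorm(n_part * N, 0, config$participant_gain_sd)),
                  n_part, N)
  epochs <- list(); participant <- character(); label <- integer()
  for (pi in seq_len(n_part)) {
    Ap <- diag(gains[pi, ], N) %*% A
    for (ei in seq_len(config$epochs_per_participant)) {
      S <- matrix(0, n_src, T_)
      for (si in seq_len(n_src)) {
        for (bi in seq_along(bank$bands)) {
          b <- bank$bands[[bi]]
          comp <- .bandlimited_noise(T_, config$rate, b[1L], b[2L])
          if (si == src_idx && length(disc_band_idx) &&
              bi == disc_band_idx[1L] && labels_p[pi] == 1L)
            comp <- comp * sqrt(config$effect_size)
          S[si, ] <- S[si, ] + comp
        }
      }
      dat <- Ap %*% S + config$noise_sd * matrix(stats::rnorm(N * T_), N)
      epochs[[length(epochs) + 1L]] <- eeg_epoch(dat, config$rate, chn)
      participant <- c(participant, ids[pi])
      label <- c(label, labels_p[pi])
    }
  }
  set <- labeled_epoch_set(epochs, participant, label)
  structure(list(set = set,
                 truth = list(mixing = A, source_index = src_idx,
                              band = db, band_index = disc_band_idx,
                              gains = gains, config = config)),
            class = "synth_eeg")
}

#' @export
print.synth_eeg <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<synth_eeg> effect size %g in %g-%g Hz, noise sd %g, seed %d\n",
              cfg$effect_size, x$truth$band[1L], x$truth$band[2L],
              cfg$noise_sd, cfg$seed))
  print(x$set)
  invisible(x)
}

#' Alignment between a fitted CSP pattern and the true mixing column
#'
#' Scores parameter recovery: the absolute cosine between the spatial
#' pattern of the top CSP filter (first column of `solve(W)`) and the
#' mixing column of the discriminative source. 1 means the fitted pattern
#' points exactly along the true source topography.
#'
#' @param sim a `synth_eeg` object from [generate_dataset()].
#' @param model a `csp_model` fitted on the discriminative band of `sim`.
#' @return scalar in `[0, 1]`.
#' @export
recovery_report <- function(sim, model) {
  stopifnot(inherits(sim, "synth_eeg"), inherits(model, "csp_model"))
  if (!is.null(model$band) &&
      !isTRUE(all.equal(as.numeric(model$band), as.numeric(sim$truth$band))))
    stop(sprintf("model fitted on band %g-%g Hz, dataset's contrast is %g-%g Hz",
                 model$band[1L], model$band[2L],
                 sim$truth$band[1L], sim$truth$band[2L]))
  pat <- csp_patterns(model)[, 1L]
  truth <- sim$truth$mixing[, sim$truth$source_index]
  abs(sum(pat * truth)) / (sqrt(sum(pat^2)) * sqrt(sum(truth^2)))
}

#' Write a synthetic dataset to disk with a manifest
#'
#' One file per epoch (TSV matrix or EDF) plus a `manifest.tsv` readable by
#' [load_epochs()]. Epochs are grouped into pseudo-sessions of at most
#' `trials_per_session` for the manifest's bookkeeping columns.
#'
#' @param sim a `synth_eeg` object.
#' @param dir output directory (created if needed).
#' @param format `"text"` or `"edf"`.
#' @param trials_per_session manifest session grouping (default 27).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(sim, dir, format = c("text", "edf"),
                          trials_per_session = 27L) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "synth_eeg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set <- sim$set
  ext <- if (format == "edf") "edf" else "tsv"
  rows <- vector("list", length(set$epochs))
  for (i in seq_along(set$epochs)) {
    pid <- set$participant[i]
    ord <- set$epoch_order[i]
    fn <- sprintf("%s_e%03d.%s", pid, ord, ext)
    path <- file.path(dir, fn)
    if (format == "edf") write_edf(set$epochs[[i]], path)
    else write_epoch_tsv(set$epochs[[i]], path)
    rows[[i]] <- data.frame(participant_id = pid, label = set$label[i],
                            session = (ord - 1L) %/% trials_per_session + 1L,
                            trial = ord, path = fn, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(man_path)
}
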