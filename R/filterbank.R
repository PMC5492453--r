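# Stage 1 of the pipeline: an equal-width bank of Butterworth band-pass
# filters tiling 4-44 Hz, applied zero-phase to each channel of an epoch.

#' Construct an equal-width filter bank
#'
#' Partitions `[low, high]` Hz into contiguous sub-bands of equal `width`;
#' adjacent bands share an edge. The defaults tile the theta-to-gamma range
#' 4-44 Hz into ten 4-Hz sub-bands; a 2-Hz width gives twenty.
#'
#' @param low,high band edges in Hz; `high - low` must be divisible by
#'   `width`.
#' @param width sub-band width in Hz.
#' @return an object of class `filter_bank` with a `bands` list of
#'   `c(lo, hi)` pairs.
#' @examples
#' length(make_filter_bank(4, 44, 4)$bands)  # 10
#' length(make_filter_bank(4, 44, 2)$bands)  # 20
#' @export
make_filter_bank <- function(low = 4, high = 44, width = 4) {
  if (!(high > low)) stop("'high' must exceed 'low'")
  if (width <= 0) stop("'width' must be positive")
  k <- (high - low) / width
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("range %g-%g Hz is not divisible by width %g Hz",
                 low, high, width))
  k <- as.integer(round(k))
  edges <- low + width * 0:k
  bands <- lapply(seq_len(k), function(i) c(edges[i], edges[i + 1L]))
  structure(list(low = low, high = high, width = width, bands = bands),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d sub-bands of %g Hz over %g-%g Hz\n",
              length(x$bands), x$width, x$low, x$high))
  invisible(x)
}

# Zero-phase forward-backward IIR pass with odd (point-symmetric) reflection
# padding of 3x the effective filter order at each end.
.filtfilt_reflect <- function(b, a, x, eff_order) {
  n <- length(x)
  npad <- min(n - 1L, 3L * eff_order)
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filter(b, a, c(pre, x, post))
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(npad + 1L):(npad + n)])
}

#' Band-pass filter an epoch
#'
#' Applies a Butterworth band-pass of the given order to every channel,
#' forward and backward (zero net phase; magnitude response squared), with
#' reflection padding to suppress startup transients.
#'
#' @param epoch an `eeg_epoch`.
#' @param band numeric `c(lo, hi)` in Hz; `lo > 0`, `hi` below Nyquist.
#' @param order Butterworth design order (3 by default, i.e. 6 poles for
#'   the band-pass).
#' @return the filtered `eeg_epoch`, same shape and channel order.
#' @export
bandpass_epoch <- function(epoch, band, order = 3L) {
  lo <- band[1L]; hi <- band[2L]
  nyq <- epoch$rate / 2
  if (!(lo > 0)) stop("band low edge must be positive")
  if (!(hi > lo)) stop("band high edge must exceed the low edge")
  if (hi >= nyq)
    stop(sprintf("band edge %g Hz is at or above the Nyquist frequency %g Hz",
                 hi, nyq))
  bt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  eff <- 2L * as.integer(order)  # band-pass doubles the pole count
  out <- epoch$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- .filtfilt_reflect(bt$b, bt$a, epoch$data[i, ], eff)
  eeg_epoch(out, epoch$rate, epoch$channels)
}

#' Apply a whole filter bank to an epoch
#'
#' @param epoch an `eeg_epoch`.
#' @param bank a `filter_bank`.
#' @param order Butterworth design order.
#' @return list of filtered `eeg_epoch` objects, one per sub-band, in bank
#'   order.
#' @export
filter_bank_epoch <- function(epoch, bank, order = 3L) {
  lapply(bank$bands, function(b) bandpass_epoch(epoch, b, order))
}
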