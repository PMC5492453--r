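# The user-facing model: fit the whole spectral-spatial pipeline on a
# labeled epoch set, then project new epochs into the d-dimensional
# KEFB-CSP feature space.

#' Fit the KEFB-CSP feature extractor
#'
#' Fits the full three-stage pipeline on a labeled epoch set: (1) a bank of
#' 3rd-order Butterworth band-pass filters tiling `[low, high]` Hz in
#' `width`-Hz sub-bands; (2) a common spatial pattern transform per
#' sub-band, keeping the `p` most discriminative filters from each end and
#' concatenating the normalized log-power features into a
#' `2 p N_sb`-dimensional filter-bank CSP vector; (3) kernel PCA of those
#' vectors (Gaussian kernel of width `sigma`, or a degree-1 polynomial
#' kernel for ordinary PCA), retaining `d` components.
#'
#' @param set a labeled `epoch_set` (see [labeled_epoch_set()]).
#' @param low,high,width filter-bank range and sub-band width in Hz.
#' @param order Butterworth design order.
#' @param p CSP filters kept from each end per sub-band,
#'   `1 <= p <= floor(N/2)`.
#' @param d kernel principal components retained.
#' @param sigma Gaussian kernel width.
#' @param kernel `"gaussian"` (KEFB-CSP) or `"polynomial"` (with
#'   `poly_degree = 1`, the FBCSP+PCA special case).
#' @param poly_degree polynomial kernel degree.
#' @param ... kernel-PCA literal-formula flags passed to [fit_kpca()].
#' @return an object of class `kefbcsp` with components `bank`,
#'   `csp_models` (one per sub-band), `kpca`, `features` (training feature
#'   matrix, epochs x d), `labels`, and the call.
#' @seealso [predict.kefbcsp()], [lopo_cv()], [voting_lopo_cv()]
#' @examples
#' sim <- generate_dataset(synth_config(participants_per_class = 2,
#'                                      epochs_per_participant = 4,
#'                                      epoch_seconds = 2, seed = 1))
#' fit <- kefbcsp(sim$set, p = 1, d = 2, sigma = 10)
#' fit
#' @export
kefbcsp <- function(set, low = 4, high = 44, width = 4, order = 3L, p = 3L,
                    d = 2L, sigma = 10, kernel = c("gaussian", "polynomial"),
                    poly_degree = 1, ...) {
  kernel <- match.arg(kernel)
  if (!inherits(set, "epoch_set")) stop("'set' must be an epoch_set")
  bank <- make_filter_bank(low, high, width)
  models <- vector("list", length(bank$bands))
  n_ep <- length(set$epochs)
  # scatter matrices per band, reused for fitting and feature extraction
  scat <- lapply(bank$bands, function(b)
    lapply(set$epochs, function(e) .epoch_scatter(bandpass_epoch(e, b, order))))
  i1 <- which(set$label == 1L); i2 <- which(set$label == 2L)
  if (!length(i1) || !length(i2)) stop("both classes must be present")
  for (bi in seq_along(bank$bands)) {
    avg <- function(idx) {
      acc <- 0
      for (i in idx) acc <- acc + scat[[bi]][[i]] / sum(diag(scat[[bi]][[i]]))
      acc / length(idx)
    }
    m <- .fit_csp_cov(avg(i1), avg(i2))
    m$band <- bank$bands[[bi]]
    m$channels <- set$channels
    models[[bi]] <- m
  }
  q <- 2L * p * length(bank$bands)
  fb <- matrix(0, n_ep, q)
  for (bi in seq_along(bank$bands)) {
    cols <- ((bi - 1L) * 2L * p + 1L):(bi * 2L * p)
    for (i in seq_len(n_ep))
      fb[i, cols] <- .csp_features_scatter(models[[bi]], scat[[bi]][[i]], p)
  }
  km <- fit_kpca(fb, sigma = sigma, d = min(d, n_ep), kernel = kernel,
                 poly_degree = poly_degree, ...)
  structure(list(bank = bank, csp_models = models, kpca = km,
                 p = as.integer(p), d = km$d, sigma = sigma, kernel = kernel,
                 order = as.integer(order), q = q,
                 features = km$projections, labels = set$label,
                 participant = set$participant, channels = set$channels,
                 call = match.call()),
            class = "kefbcsp")
}

#' @export
print.kefbcsp <- function(x, ...) {
  cat("KEFB-CSP feature extractor\n")
  cat(sprintf("  filter bank : %d sub-bands of %g Hz over %g-%g Hz\n",
              length(x$bank$bands), x$bank$width, x$bank$low, x$bank$high))
  cat(sprintf("  CSP         : p = %d filters per side -> q = %d FBCSP features\n",
              x$p, x$q))
  cat(sprintf("  kernel PCA  : %s kernel%s, d = %d components\n", x$kernel,
              if (x$kernel == "gaussian") sprintf(" (sigma = %g)", x$sigma)
              else "", x$d))
  cat(sprintf("  fitted on   : %d epochs, %d participants, %d channels\n",
              length(x$labels), length(unique(x$participant)),
              length(x$channels)))
  invisible(x)
}

#' @export
summary.kefbcsp <- function(object, ...) {
  top <- vapply(object$csp_models, function(m) m$eigvals[1L], numeric(1))
  structure(list(model = object, top_eigvals = top,
                 kpca_eigvals = object$kpca$eigvals),
            class = "summary.kefbcsp")
}

#' @export
print.summary.kefbcsp <- function(x, ...) {
  print(x$model)
  bands <- vapply(x$model$bank$bands, function(b)
    sprintf("%g-%g", b[1L], b[2L]), character(1))
  cat("  top CSP eigenvalue (class-1 variance share) per sub-band:\n")
  for (i in seq_along(bands))
    cat(sprintf("    %8s Hz  %.3f\n", bands[i], x$top_eigvals[i]))
  cat("  kernel PCA eigenvalues:",
      paste(sprintf("%.4g", x$kpca_eigvals), collapse = " "), "\n")
  invisible(x)
}

#' Project epochs into the fitted KEFB-CSP feature space
#'
#' @param object a fitted `kefbcsp` model.
#' @param newdata an `epoch_set`, a list of `eeg_epoch`s, or a single
#'   `eeg_epoch`.
#' @param ... unused.
#' @return numeric matrix, one row of `d` features per epoch.
#' @export
predict.kefbcsp <- function(object, newdata, ...) {
  epochs <- if (inherits(newdata, "epoch_set")) newdata$epochs
  else if (inherits(newdata, "eeg_epoch")) list(newdata)
  else newdata
  fb <- t(vapply(epochs, function(e)
    extract_fbcsp(object$csp_models, e, object$p, object$bank, object$order),
    numeric(object$q)))
  kpca_project(object$kpca, fb)
}

#' Training-set feature coordinates
#' @param object a fitted `kefbcsp` model.
#' @param ... unused.
#' @return the training feature matrix (epochs x d).
#' @export
fitted.kefbcsp <- function(object, ...) object$features

#' CSP spatial filters of the fitted model
#'
#' @param object a fitted `kefbcsp` model.
#' @param ... unused.
#' @return list of N x N spatial-filter matrices, one per sub-band.
#' @export
coef.kefbcsp <- function(object, ...) {
  out <- lapply(object$csp_models, function(m) m$W)
  names(out) <- vapply(object$bank$bands, function(b)
    sprintf("%g-%g Hz", b[1L], b[2L]), character(1))
  out
}

#' Diagnostic plot of a fitted KEFB-CSP model
#'
#' Left: top CSP eigenvalue (class-1 variance share of the most
#' discriminative spatial filter) per sub-band -- values far from 0.5 mark
#' spectrally localized class contrasts. Right: the kernel-PCA eigenvalue
#' spectrum (scree).
#'
#' @param x a fitted `kefbcsp` model.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.kefbcsp <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  top <- vapply(x$csp_models, function(m) m$eigvals[1L], numeric(1))
  lab <- vapply(x$bank$bands, function(b) sprintf("%g", b[1L]), character(1))
  graphics::barplot(top, names.arg = lab, ylim = c(0, 1),
                    xlab = "sub-band low edge (Hz)",
                    ylab = "top CSP eigenvalue", ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::plot(x$kpca$eigvals, type = "b", xlab = "component",
                 ylab = "kernel PCA eigenvalue")
  invisible(x)
}
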