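# Stage 2: the common spatial pattern (CSP) transform per sub-band.
#
# Fitting whitens the composite class covariance and simultaneously
# diagonalizes the two class covariances; the rows of W (spatial filters)
# are ordered by descending class-1 eigenvalue, so the first rows maximize
# class-1 variance relative to class 2 and the last rows do the opposite.

#' Trace-normalized average spatial covariance
#'
#' Averages `E %*% t(E) / tr(E %*% t(E))` over epochs, so every epoch
#' contributes a unit-trace term and the average itself has unit trace.
#'
#' @param epochs list of `eeg_epoch` objects of identical shape.
#' @return symmetric N x N matrix with trace 1.
#' @export
average_covariance <- function(epochs) {
  if (!length(epochs)) stop("no epochs supplied")
  n <- nrow(epochs[[1L]]$data)
  acc <- matrix(0, n, n)
  for (e in epochs) {
    cc <- tcrossprod(e$data)
    tr <- sum(diag(cc))
    if (tr <= 0) stop("degenerate (all-zero) epoch in covariance average")
    acc <- acc + cc / tr
  }
  acc / length(epochs)
}

# Raw (unnormalized) scatter E E^t; trace-normalized on demand. Used by the
# cached evaluation path: surrogate-signal energies are quadratic forms in
# this matrix, so filtered signals never need to be kept.
.epoch_scatter <- function(epoch) tcrossprod(epoch$data)

#' Fit a common spatial pattern transform
#'
#' Computes the trace-normalized average covariances of the two classes,
#' whitens their sum and diagonalizes the whitened class-1 covariance. The
#' returned transform `W` satisfies `W (C1 + C2) t(W) = I` and
#' `W C1 t(W) = diag(eigvals)` with `eigvals` descending in `[0, 1]`; the
#' class-2 eigenvalues are their complements `1 - eigvals`.
#'
#' @param class1,class2 lists of `eeg_epoch` objects (band-filtered), one
#'   per class.
#' @param band optional `c(lo, hi)` recording which sub-band the epochs
#'   were filtered to; stored for bookkeeping.
#' @param reg relative ridge added to the composite covariance before
#'   whitening (`reg * trace/N` on the diagonal).
#' @return an object of class `csp_model` with fields `W` (N x N, rows =
#'   spatial filters), `eigvals`, `band`, `channels`.
#' @export
fit_csp <- function(class1, class2, band = NULL, reg = 1e-10) {
  if (!length(class1) || !length(class2))
    stop("both classes need at least one epoch")
  C1 <- average_covariance(class1)
  C2 <- average_covariance(class2)
  model <- .fit_csp_cov(C1, C2, reg = reg)
  model$band <- band
  model$channels <- class1[[1L]]$channels
  model
}

# Core fit from the two averaged covariances (already trace-normalized).
.fit_csp_cov <- function(C1, C2, reg = 1e-10) {
  n <- nrow(C1)
  Cc <- C1 + C2
  Cc <- Cc + diag(reg * sum(diag(Cc)) / n, n)
  ec <- eigen(Cc, symmetric = TRUE)
  lam <- ec$values
  floor_ <- 1e-12 * max(lam)
  if (any(lam < floor_)) {
    if (max(lam) <= 0)
      stop("composite covariance is not positive definite (rank-deficient data)")
    lam <- pmax(lam, floor_)
  }
  P <- diag(1 / sqrt(lam), n) %*% t(ec$vectors)      # whitening matrix
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)                  # descending eigenvalues
  W <- t(eb$vectors) %*% P
  # fix the sign ambiguity: largest-magnitude entry of each filter positive
  for (i in seq_len(n)) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  structure(list(W = W, eigvals = pmin(pmax(eb$values, 0), 1), band = NULL,
                 channels = NULL),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d spatial filters", nrow(x$W)))
  if (!is.null(x$band)) cat(sprintf(", band %g-%g Hz", x$band[1L], x$band[2L]))
  cat("\n  class-1 eigenvalues:",
      paste(sprintf("%.3f", x$eigvals), collapse = " "), "\n")
  invisible(x)
}

#' Spatial patterns of a CSP model
#'
#' The pattern associated with each spatial filter (row of `W`) is the
#' corresponding column of `solve(W)`: the scalp topography through which
#' the extracted surrogate source projects into the channels.
#'
#' @param model a `csp_model`.
#' @return N x N matrix of patterns in columns, same order as the filters.
#' @export
csp_patterns <- function(model) solve(model$W)

#' Normalized log-power CSP features of one epoch
#'
#' Projects the (band-filtered) epoch through the first `p` and last `p`
#' spatial filters and returns the log of each surrogate signal's energy,
#' normalized over the 2p retained signals; `sum(exp(features)) == 1`.
#' Energy is the plain sum of squared sample values, without mean removal.
#'
#' @param model a `csp_model`.
#' @param epoch an `eeg_epoch`, band-filtered to `model$band`.
#' @param p filters kept from each end; `1 <= p <= floor(N/2)`.
#' @return numeric vector of length `2 * p`.
#' @export
csp_features <- function(model, epoch, p) {
  .csp_features_scatter(model, .epoch_scatter(epoch), p)
}

# Same features from the epoch's raw scatter matrix E E^t: the energy of
# surrogate signal w E is the quadratic form w (E E^t) w^t.
.csp_features_scatter <- function(model, scatter, p) {
  n <- nrow(model$W)
  p <- as.integer(p)
  if (p < 1L || p > floor(n / 2))
    stop(sprintf("'p' must be in 1..%d for %d channels", floor(n / 2), n))
  sel <- c(seq_len(p), (n - p + 1L):n)
  Wsel <- model$W[sel, , drop = FALSE]
  v <- rowSums((Wsel %*% scatter) * Wsel)
  if (any(v <= 0)) stop("zero-power surrogate signal: degenerate epoch")
  log(v / sum(v))
}

#' Filter-bank CSP feature vector of one raw epoch
#'
#' Band-pass filters the raw epoch to every sub-band of the bank, extracts
#' the 2p CSP features per sub-band with the matching fitted model, and
#' concatenates them band-major (band 1 first) into a vector of length
#' `2 * p * length(bank$bands)`.
#'
#' @param models list of `csp_model` objects, one per sub-band, in bank
#'   order.
#' @param epoch an unfiltered `eeg_epoch`.
#' @param p filters kept from each end of each model.
#' @param bank the `filter_bank` the models were fitted on.
#' @param order Butterworth design order used for filtering.
#' @return numeric vector of length `2 * p * N_sb`.
#' @export
extract_fbcsp <- function(models, epoch, p, bank, order = 3L) {
  if (length(models) != length(bank$bands))
    stop(sprintf("%d models for %d sub-bands", length(models),
                 length(bank$bands)))
  out <- lapply(seq_along(models), function(i) {
    filt <- bandpass_epoch(epoch, bank$bands[[i]], order)
    csp_features(models[[i]], filt, p)
  })
  unlist(out, use.names = FALSE)
}

# ---- TSV serialization for audit ----------------------------------------

#' Serialize CSP models as TSV blocks
#'
#' One block per model: a `# band lo hi` header, the rows of `W`, then an
#' `# eigvals` line. Human-auditable; read back with [read_csp_models()].
#'
#' @param models list of `csp_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csp_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    b <- if (is.null(m$band)) c(NA, NA) else m$band
    writeLines(sprintf("# band\t%.10g\t%.10g", b[1L], b[2L]), con)
    utils::write.table(format(m$W, digits = 12, trim = TRUE), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(paste(c("# eigvals",
                       format(m$eigvals, digits = 12, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read CSP models serialized with [write_csp_models()]
#' @param path TSV file of model blocks.
#' @return list of `csp_model` objects.
#' @export
read_csp_models <- function(path) {
  lines <- readLines(path)
  heads <- grep("^# band", lines)
  lapply(seq_along(heads), function(k) {
    i <- heads[k]
    end <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    band <- as.numeric(strsplit(lines[i], "\t")[[1L]][-1L])
    ev_line <- grep("^# eigvals", lines[i:end])[1L] + i - 1L
    W <- as.matrix(utils::read.table(text = lines[(i + 1L):(ev_line - 1L)],
                                     sep = "\t"))
    dimnames(W) <- NULL
    ev <- as.numeric(strsplit(lines[ev_line], "\t")[[1L]][-1L])
    structure(list(W = W, eigvals = ev,
                   band = if (all(is.na(band))) NULL else band,
                   channels = NULL),
              class = "csp_model")
  })
}
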