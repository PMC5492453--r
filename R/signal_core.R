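#' @keywords internal
"_PACKAGE"

# ---- channel naming ------------------------------------------------------

# Older 10-20 names are kept as canonical (T3/T4/T5/T6); modern synonyms from
# EDF exports are mapped back onto them.
.channel_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Canonicalize EEG channel names
#'
#' Upper-cases channel names and maps modern 10-10 synonyms (T7/T8/P7/P8)
#' onto the older 10-20 labels (T3/T4/T5/T6) used throughout this package.
#'
#' @param channels character vector of channel names.
#' @return character vector of canonical names.
#' @export
canonical_channels <- function(channels) {
  ch <- toupper(trimws(as.character(channels)))
  hit <- ch %in% names(.channel_aliases)
  ch[hit] <- .channel_aliases[ch[hit]]
  ch
}

# ---- EEGEpoch ------------------------------------------------------------

#' Construct a multichannel EEG epoch
#'
#' An epoch is an N x T numeric matrix (channels x samples, microvolts)
#' together with its sampling rate and ordered channel names.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param rate sampling rate in Hz.
#' @param channels character vector of channel names, one per row of `data`.
#' @return an object of class `eeg_epoch`.
#' @examples
#' e <- eeg_epoch(matrix(rnorm(2 * 100), 2), rate = 100, channels = c("C3", "C4"))
#' e
#' @export
eeg_epoch <- function(data, rate, channels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("an EEG epoch needs at least 2 channels")
  if (ncol(data) < 2L) stop("an EEG epoch needs at least 2 samples")
  if (!all(is.finite(data))) stop("epoch contains non-finite values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a positive scalar (Hz)")
  if (is.null(channels)) channels <- paste0("CH", seq_len(nrow(data)))
  channels <- canonical_channels(channels)
  if (length(channels) != nrow(data))
    stop("length(channels) must equal the number of rows of 'data'")
  if (anyDuplicated(channels)) stop("duplicated channel names")
  dimnames(data) <- NULL
  structure(list(data = data, rate = as.numeric(rate), channels = channels),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_epoch <- function(x) dim(x$data)

.epoch_seconds <- function(epoch) ncol(epoch$data) / epoch$rate

# ---- LabeledEpochSet -----------------------------------------------------

#' Construct a labeled set of EEG epochs
#'
#' Groups epochs by participant with a binary class label per participant
#' (1 = patient/positive, 2 = control/negative) and an acquisition-order
#' index per epoch within participant.
#'
#' @param epochs list of [eeg_epoch] objects sharing shape, rate and
#'   channel order.
#' @param participant character/integer vector, one id per epoch.
#' @param label integer vector in `{1, 2}`, one per epoch; constant within
#'   participant.
#' @param epoch_order integer acquisition index per epoch within its
#'   participant; defaults to order of appearance.
#' @return an object of class `epoch_set`.
#' @export
labeled_epoch_set <- function(epochs, participant, label, epoch_order = NULL) {
  if (!length(epochs)) stop("empty epoch set")
  if (!all(vapply(epochs, inherits, logical(1), "eeg_epoch")))
    stop("'epochs' must be a list of eeg_epoch objects")
  participant <- as.character(participant)
  label <- as.integer(label)
  n <- length(epochs)
  if (length(participant) != n || length(label) != n)
    stop("participant and label must have one entry per epoch")
  if (!all(label %in% c(1L, 2L)))
    stop("labels must be 1 (positive/patient) or 2 (negative/control)")
  ref <- epochs[[1L]]
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    if (!identical(dim(e$data), dim(ref$data)))
      stop(sprintf("epoch %d has shape %dx%d, expected %dx%d", i,
                   nrow(e$data), ncol(e$data), nrow(ref$data), ncol(ref$data)))
    if (!isTRUE(all.equal(e$rate, ref$rate)))
      stop(sprintf("epoch %d has rate %g, expected %g", i, e$rate, ref$rate))
    if (!identical(e$channels, ref$channels))
      stop(sprintf("epoch %d has a different channel order", i))
  }
  for (p in unique(participant)) {
    if (length(unique(label[participant == p])) != 1L)
      stop(sprintf("participant '%s' has inconsistent labels", p))
  }
  if (is.null(epoch_order)) {
    epoch_order <- integer(n)
    for (p in unique(participant)) {
      idx <- which(participant == p)
      epoch_order[idx] <- seq_along(idx)
    }
  }
  epoch_order <- as.integer(epoch_order)
  for (p in unique(participant)) {
    o <- sort(epoch_order[participant == p])
    if (!identical(o, seq_along(o)))
      stop(sprintf("epoch_order of participant '%s' is not a permutation of 1..%d",
                   p, length(o)))
  }
  structure(list(epochs = epochs, participant = participant, label = label,
                 epoch_order = epoch_order, channels = ref$channels,
                 rate = ref$rate, n_samples = ncol(ref$data)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  pl <- participant_labels(x)
  cat(sprintf("<epoch_set> %d epochs, %d participants (%d class 1 / %d class 2)\n",
              length(x$epochs), length(pl), sum(pl == 1L), sum(pl == 2L)))
  cat(sprintf("  %d channels x %d samples @ %g Hz\n",
              length(x$channels), x$n_samples, x$rate))
  invisible(x)
}

#' @export
length.epoch_set <- function(x) length(x$epochs)

#' Subset an epoch set by epoch index
#' @param x an `epoch_set`.
#' @param i integer or logical index over epochs.
#' @param ... unused.
#' @return an `epoch_set` restricted to the selected epochs.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  idx <- seq_along(x$epochs)[i]
  out <- x
  out$epochs <- x$epochs[idx]
  out$participant <- x$participant[idx]
  out$label <- x$label[idx]
  out$epoch_order <- x$epoch_order[idx]
  out
}

#' Per-participant labels of an epoch set
#' @param set an `epoch_set`.
#' @return named integer vector, label per participant id.
#' @export
participant_labels <- function(set) {
  ids <- unique(set$participant)
  out <- vapply(ids, function(p) set$label[match(p, set$participant)], integer(1))
  names(out) <- ids
  out
}

# ---- montages ------------------------------------------------------------

.montage_table <- list(
  frontal   = c("FP1", "FP2", "FZ", "F3", "F4", "F7", "F8"),
  central   = c("FCZ", "FC3", "CZ", "FC4", "C3", "C4"),
  temporal  = c("FT7", "T3", "TP7", "T5", "FT8", "T4", "TP8", "T6"),
  parietal  = c("CP3", "CPZ", "CP4", "P3", "PZ", "P4"),
  occipital = c("O1", "OZ", "O2")
)
.montage_table$entire <- unname(unlist(.montage_table))

#' Named electrode montages
#'
#' The six scalp-region montages used throughout the package: frontal (7
#' channels), central (6), temporal (8), parietal (6), occipital (3) and
#' entire (all 30).
#'
#' @param name one of `"frontal"`, `"central"`, `"temporal"`, `"parietal"`,
#'   `"occipital"`, `"entire"`.
#' @return an object of class `eeg_montage` with fields `name` and
#'   `channels`.
#' @examples
#' montage("temporal")
#' @export
montage <- function(name = c("frontal", "central", "temporal", "parietal",
                             "occipital", "entire")) {
  name <- match.arg(name)
  structure(list(name = name, channels = .montage_table[[name]]),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %s (%d channels): %s\n", x$name,
              length(x$channels), paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Restrict an epoch set to a montage
#'
#' Keeps only the montage's channels, re-ordered to montage order; labels,
#' participants and epoch order are unchanged.
#'
#' @param set an `epoch_set`.
#' @param mont an `eeg_montage` or montage name.
#' @return the restricted `epoch_set`.
#' @export
select_montage <- function(set, mont) {
  if (is.character(mont)) mont <- montage(mont)
  idx <- match(mont$channels, set$channels)
  if (anyNA(idx)) {
    missing <- mont$channels[is.na(idx)]
    stop(sprintf("montage '%s' channel(s) not in set: %s", mont$name,
                 paste(missing, collapse = ", ")))
  }
  epochs <- lapply(set$epochs, function(e)
    eeg_epoch(e$data[idx, , drop = FALSE], e$rate, e$channels[idx]))
  labeled_epoch_set(epochs, set$participant, set$label, set$epoch_order)
}

# ---- epoching ------------------------------------------------------------

#' Segment a long recording into fixed-length epochs
#'
#' Cuts consecutive non-overlapping windows of `epoch_seconds` from the
#' start of the record; a trailing remainder shorter than one window is
#' discarded. Windows are half-open sample intervals, so adjacent epochs
#' share no sample.
#'
#' @param record an `eeg_epoch` holding the full trial.
#' @param epoch_seconds window length in seconds.
#' @return list of `eeg_epoch` objects.
#' @examples
#' rec <- eeg_epoch(matrix(rnorm(2 * 540), 2), rate = 10, channels = c("C3", "C4"))
#' length(segment_trial(rec, 6))  # 54 s at 10 Hz -> nine 6-s epochs
#' @export
segment_trial <- function(record, epoch_seconds) {
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0)
    stop("'epoch_seconds' must be a positive scalar")
  len <- round(record$rate * epoch_seconds)
  total <- ncol(record$data)
  if (total < len)
    stop(sprintf("record (%.3g s) shorter than one %.3g-s epoch",
                 total / record$rate, epoch_seconds))
  k <- floor(total / len)
  lapply(seq_len(k), function(i) {
    cols <- ((i - 1L) * len + 1L):(i * len)
    eeg_epoch(record$data[, cols, drop = FALSE], record$rate, record$channels)
  })
}

# ---- delimited-text epoch I/O --------------------------------------------

#' Write an epoch as a delimited-text matrix
#'
#' Format: a comment line `#rate<TAB><Hz>`, a header row of channel names,
#' then one row per channel with tab-separated sample values
#' (channels x samples orientation).
#'
#' @param epoch an `eeg_epoch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_tsv <- function(epoch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#rate\t%.10g", epoch$rate), con)
  writeLines(paste(epoch$channels, collapse = "\t"), con)
  utils::write.table(format(epoch$data, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an epoch from a delimited-text matrix
#'
#' @param path file written by [write_epoch_tsv()] (or following the same
#'   convention).
#' @param rate sampling rate in Hz; taken from the `#rate` comment line if
#'   present.
#' @return an `eeg_epoch`.
#' @export
read_epoch_tsv <- function(path, rate = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  i <- 1L
  if (startsWith(lines[1L], "#rate")) {
    rate <- as.numeric(strsplit(lines[1L], "\t")[[1L]][2L])
    i <- 2L
  }
  if (is.null(rate)) stop("no '#rate' line and no 'rate' argument given")
  channels <- strsplit(lines[i], "\t")[[1L]]
  dat <- utils::read.table(text = lines[(i + 1L):length(lines)], sep = "\t")
  dat <- as.matrix(dat)
  if (nrow(dat) != length(channels))
    stop(sprintf("%s: %d data rows but %d header channels", path,
                 nrow(dat), length(channels)))
  eeg_epoch(dat, rate, channels)
}

# ---- minimal 16-bit EDF I/O ----------------------------------------------

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write an epoch to a European Data Format (EDF) file
#'
#' Writes a single-record 16-bit EDF file: one data record holding the full
#' epoch, one EDF signal per channel, physical range set to the symmetric
#' data range. Amplitudes are quantized to 16 bits.
#'
#' @param epoch an `eeg_epoch`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(epoch, path) {
  dat <- epoch$data
  ns <- nrow(dat)
  nsamp <- ncol(dat)
  dur <- nsamp / epoch$rate
  pmax <- max(abs(dat), 1e-9)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (1L + ns), 8); wr("", 44); wr(1L, 8)
  wr(format(dur, digits = 8), 8); wr(ns, 4)
  for (ch in epoch$channels) wr(paste("EEG", ch), 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pmax, digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax, digits = 7), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(nsamp, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dmax - dmin) / (2 * pmax)
  for (i in seq_len(ns)) {
    dig <- as.integer(round((dat[i, ] + pmax) * scale) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file as one epoch
#'
#' Supports the plain (continuous) EDF layout with a uniform sampling rate
#' across signals; all data records are concatenated into a single
#' channels x samples epoch.
#'
#' @param path an EDF file.
#' @return an `eeg_epoch`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmaxv <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dminv <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmaxv <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1L)
    stop(sprintf("%s: signals have different sampling rates", path))
  out <- matrix(0, ns, nsamp[1L] * nrec)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dminv[i]) * (pmaxv[i] - pmin[i]) / (dmaxv[i] - dminv[i]) +
        pmin[i]
      out[i, ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <- phys
    }
  }
  channels <- sub("^EEG ?", "", labels)
  eeg_epoch(out, nsamp[1L] / dur, channels)
}

# ---- manifest loader -----------------------------------------------------

#' Load labeled epochs from a manifest
#'
#' The manifest is a TSV with columns `participant_id`, `label`, `session`,
#' `trial`, `path`; paths are resolved relative to the manifest's
#' directory. Each referenced file holds one recording (text matrix or
#' EDF); if `epoch_seconds` is given, recordings longer than one epoch are
#' segmented with [segment_trial()]. Acquisition order per participant
#' follows (session, trial, segment).
#'
#' @param manifest_path path to the manifest TSV.
#' @param format `"text"` or `"edf"`.
#' @param epoch_seconds optional epoch length for segmentation.
#' @return an `epoch_set`.
#' @export
load_epochs <- function(manifest_path, format = c("text", "edf"),
                        epoch_seconds = NULL) {
  format <- match.arg(format)
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path))
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("participant_id", "label", "session", "trial", "path")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  if (!nrow(man)) stop("manifest is empty")
  man <- man[order(man$participant_id, man$session, man$trial), , drop = FALSE]
  base <- dirname(normalizePath(manifest_path))
  epochs <- list(); participant <- character(); label <- integer()
  ref_channels <- NULL
  for (i in seq_len(nrow(man))) {
    f <- man$path[i]
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(base, f)
    if (!file.exists(f)) stop(sprintf("manifest row %d: file not found: %s", i, f))
    rec <- if (format == "edf") read_edf(f) else read_epoch_tsv(f)
    if (is.null(ref_channels)) ref_channels <- rec$channels
    if (!identical(rec$channels, ref_channels))
      stop(sprintf("inconsistent channel set in file: %s", f))
    segs <- if (is.null(epoch_seconds)) list(rec) else
      segment_trial(rec, epoch_seconds)
    epochs <- c(epochs, segs)
    participant <- c(participant, rep(as.character(man$participant_id[i]),
                                      length(segs)))
    label <- c(label, rep(as.integer(man$label[i]), length(segs)))
  }
  labeled_epoch_set(epochs, participant, label)
}
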