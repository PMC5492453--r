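test_that("epoch construction enforces shape, finiteness and channel naming", {
  expect_error(eeg_epoch(matrix(1:10, 1), 100), "2 channels")
  expect_error(eeg_epoch(matrix(1:2, 2, 1), 100), "2 samples")
  m <- matrix(rnorm(20), 2); m[1, 1] <- NA
  expect_error(eeg_epoch(m, 100), "non-finite")
  expect_error(eeg_epoch(matrix(rnorm(20), 2), 100, c("C3", "C3")), "duplicated")
  e <- eeg_epoch(matrix(rnorm(20), 2), 100, c("c3", "t7"))
  expect_identical(e$channels, c("C3", "T3"))
  expect_identical(dim(e), c(2L, 10L))
})

test_that("channel dialects canonicalize onto the 10-20 names", {
  expect_identical(canonical_channels(c("T7", "T8", "P7", "P8", "fp1", " Oz ")),
                   c("T3", "T4", "T5", "T6", "FP1", "OZ"))
})

test_that("segment_trial cuts half-open non-overlapping windows", {
  rec <- eeg_epoch(matrix(rnorm(2 * 540), 2), rate = 10, c("C3", "C4"))
  segs <- segment_trial(rec, 6)  # 54 s at 10 Hz
  expect_length(segs, 9L)
  expect_true(all(vapply(segs, function(s) ncol(s$data) == 60L, logical(1))))
  # concatenating the segments reproduces the first 9 x 6 s exactly
  expect_identical(do.call(cbind, lapply(segs, function(s) s$data)),
                   unname(rec$data[, 1:540]))
  one <- segment_trial(segs[[1]], 6)
  expect_length(one, 1L)
  expect_identical(one[[1]]$data, segs[[1]]$data)
  rec10 <- eeg_epoch(matrix(rnorm(2 * 100), 2), 10, c("C3", "C4"))
  segs10 <- segment_trial(rec10, 6)  # 10 s -> one 6-s epoch, 4 s discarded
  expect_length(segs10, 1L)
  expect_identical(segs10[[1]]$data, rec10$data[, 1:60])
  expect_error(segment_trial(rec, 0), "positive")
  expect_error(segment_trial(segs10[[1]], 60), "shorter")
})

test_that("montages carry the standard channel sets and selection respects order", {
  counts <- c(frontal = 7L, central = 6L, temporal = 8L, parietal = 6L,
              occipital = 3L, entire = 30L)
  for (nm in names(counts))
    expect_length(montage(nm)$channels, counts[[nm]])
  expect_identical(montage("occipital")$channels, c("O1", "OZ", "O2"))
  expect_identical(montage("temporal")$channels,
                   c("FT7", "T3", "TP7", "T5", "FT8", "T4", "TP8", "T6"))

  set.seed(42)
  chn <- montage("entire")$channels
  epochs <- lapply(1:4, function(i)
    eeg_epoch(matrix(rnorm(30 * 50), 30), 50, chn))
  set <- labeled_epoch_set(epochs, rep(c("a", "b"), each = 2), rep(c(1, 2), each = 2))

  tmp <- select_montage(set, "temporal")
  expect_length(tmp$channels, 8L)
  expect_identical(tmp$label, set$label)
  occ <- select_montage(set, "occipital")
  expect_identical(occ$channels, c("O1", "OZ", "O2"))
  # entire montage on an entire set is the identity
  ent <- select_montage(set, "entire")
  expect_equal(ent$epochs[[1]]$data, set$epochs[[1]]$data)
  # idempotence
  expect_equal(select_montage(tmp, "temporal")$epochs[[2]]$data,
               tmp$epochs[[2]]$data)
  # selection commutes with segmentation
  rec <- eeg_epoch(matrix(rnorm(30 * 200), 30), 50, chn)
  sel_then_seg <- segment_trial(
    select_montage(labeled_epoch_set(list(rec), "a", 1L), "parietal")$epochs[[1]],
    2)
  seg_then_sel <- select_montage(
    labeled_epoch_set(segment_trial(rec, 2), rep("a", 2), rep(1L, 2)),
    "parietal")$epochs
  expect_equal(sel_then_seg[[2]]$data, seg_then_sel[[2]]$data)
  expect_error(select_montage(tmp, "frontal"), "FP1")
})

test_that("text and EDF round trips preserve data to format precision", {
  set.seed(7)
  e <- eeg_epoch(matrix(rnorm(8 * 120, sd = 40), 8), 60,
                 montage("temporal")$channels)
  tsv <- tempfile(fileext = ".tsv")
  write_epoch_tsv(e, tsv)
  e2 <- read_epoch_tsv(tsv)
  expect_identical(e2$channels, e$channels)
  expect_equal(e2$rate, e$rate)
  expect_equal(e2$data, e$data, tolerance = 1e-8)

  edf <- tempfile(fileext = ".edf")
  write_edf(e, edf)
  e3 <- read_edf(edf)
  expect_identical(e3$channels, e$channels)
  expect_equal(e3$rate, e$rate)
  # 16-bit quantization: absolute error bounded by one digitization step
  step <- 2 * max(abs(e$data)) / 65535
  expect_lt(max(abs(e3$data - e$data)), step)
})

test_that("manifest loading assembles a labeled set and validates inputs", {
  sim <- tiny_sim()
  dir <- tempfile("ds")
  man <- write_dataset(sim, dir, format = "text")
  set <- load_epochs(man, format = "text")
  expect_s3_class(set, "epoch_set")
  expect_length(set$epochs, length(sim$set$epochs))
  expect_identical(sort(unique(set$participant)),
                   sort(unique(sim$set$participant)))
  i <- which(set$participant == "P01" & set$epoch_order == 1)
  j <- which(sim$set$participant == "P01" & sim$set$epoch_order == 1)
  expect_equal(set$epochs[[i]]$data, sim$set$epochs[[j]]$data,
               tolerance = 1e-8)

  # an EDF fixture written by the generator round-trips through the loader
  dir3 <- tempfile("edf")
  sim3 <- generate_dataset(synth_config(participants_per_class = 1,
                                        epochs_per_participant = 2,
                                        epoch_seconds = 1, seed = 3))
  man3 <- write_dataset(sim3, dir3, format = "edf")
  set3 <- load_epochs(man3, format = "edf")
  expect_length(set3$epochs, 4L)
  expect_equal(set3$epochs[[1]]$data, sim3$set$epochs[[1]]$data,
               tolerance = 1e-3 * max(abs(sim3$set$epochs[[1]]$data)))

  empty <- tempfile(fileext = ".tsv")
  writeLines("participant_id\tlabel\tsession\ttrial\tpath", empty)
  expect_error(load_epochs(empty), "empty")

  # inconsistent channel sets are rejected with the offending file named
  bad_dir <- tempfile("bad")
  dir.create(bad_dir)
  e1 <- eeg_epoch(matrix(rnorm(20), 2), 10, c("C3", "C4"))
  e2 <- eeg_epoch(matrix(rnorm(20), 2), 10, c("O1", "O2"))
  write_epoch_tsv(e1, file.path(bad_dir, "a.tsv"))
  write_epoch_tsv(e2, file.path(bad_dir, "b.tsv"))
  manbad <- file.path(bad_dir, "manifest.tsv")
  writeLines(c("participant_id\tlabel\tsession\ttrial\tpath",
               "p1\t1\t1\t1\ta.tsv", "p2\t2\t1\t1\tb.tsv"), manbad)
  expect_error(load_epochs(manbad), "b.tsv")
})
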