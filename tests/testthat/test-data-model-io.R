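test_that("raw float32 dialect round-trips signals bit-exactly", {
  # float32-representable values survive write -> read unchanged
  x <- as.numeric(round(sin(seq_len(640) / 7) * 2048)) / 256
  rec <- recording(x, 64, subject_id = "m01", channel = "EEG-PR")
  path <- file.path(withr::local_tempdir(), "rec.f32")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$samples, x)
  expect_identical(back$fs, 64)
  expect_identical(back$subject_id, "m01")
  expect_identical(back$channel, "EEG-PR")
  # arbitrary doubles: one write/read quantizes, after which the dialect is
  # lossless
  y <- rnorm(100)
  p2 <- file.path(withr::local_tempdir(), "r2.f32")
  write_recording(recording(y, 128), p2)
  q <- read_recording(p2)$samples
  write_recording(recording(q, 128), p2)
  expect_identical(read_recording(p2)$samples, q)
})

test_that("recording and raw reader reject invalid inputs", {
  expect_error(recording(1:10, fs = 0), "positive")
  expect_error(recording(c(1, NA), fs = 10), "finite")
  expect_error(recording(c(1, Inf), fs = 10), "finite")
  d <- withr::local_tempdir()
  writeBin(rnorm(8), file.path(d, "orphan.f32"), size = 4)
  expect_error(read_recording(file.path(d, "orphan.f32")), "sidecar")
})

test_that("EDF writer/reader preserve the non-integer native sampling rate", {
  x <- sin(2 * pi * 3 * seq(0, 10, length.out = 9921)[-9921]) * 150
  rec <- recording(x, 992.06, subject_id = "mouse7")
  path <- file.path(withr::local_tempdir(), "rec.edf")
  write_recording(rec, path, format = "edf")
  back <- read_recording(path)
  expect_equal(back$fs, 992.06)
  expect_identical(back$subject_id, "mouse7")
  # 16-bit quantization: relative error bounded by one digital step
  n <- length(x)
  expect_lt(max(abs(back$samples[1:n] - x)), 2 * max(abs(x)) / 65535 + 1e-9)
  # rates with no short integer record length are a format error
  expect_error(write_recording(recording(rnorm(100), pi * 100), path,
                               format = "edf"), "not representable")
})

test_that("EDF header encodes the rate as samples-per-record over duration", {
  rec <- recording(rnorm(9920) * 50, 992.06)
  path <- file.path(withr::local_tempdir(), "r.edf")
  write_recording(rec, path, format = "edf")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 512, useBytes = TRUE)
  dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  spr <- as.numeric(trimws(substr(hdr, 256 + 217, 256 + 224)))
  expect_identical(spr / dur, 992.06)
})

test_that("hypnogram CSV round-trips, sorts and validates", {
  h <- hypnogram(c("W", "N", "P", "R", "A"))
  expect_identical(h$labels, c("WAKE", "NREM", "PREREM", "REM", "ARTIFACT"))
  d <- withr::local_tempdir()
  p <- file.path(d, "hyp.csv")
  write_hypnogram(h, p)
  expect_identical(read_hypnogram(p, n_epochs = 5)$labels, h$labels)

  # shuffled epoch_index gives the same hypnogram as the sorted file
  df <- utils::read.csv(p)
  set.seed(1)
  utils::write.csv(df[sample(nrow(df)), ], file.path(d, "shuf.csv"),
                   row.names = FALSE)
  expect_identical(read_hypnogram(file.path(d, "shuf.csv"), 5)$labels,
                   h$labels)

  expect_error(read_hypnogram(p, n_epochs = 4), "length error")
  utils::write.csv(data.frame(epoch_index = c(0, 0, 2), label = c("W", "N", "R")),
                   file.path(d, "dup.csv"), row.names = FALSE)
  expect_error(read_hypnogram(file.path(d, "dup.csv"), 3), "epoch_index")
  utils::write.csv(data.frame(epoch_index = 0:1, label = c("W", "XX")),
                   file.path(d, "bad.csv"), row.names = FALSE)
  expect_error(read_hypnogram(file.path(d, "bad.csv"), 2), "unknown stage")
})

test_that("stage vocabulary has five canonical stages and three standard ones", {
  expect_identical(stage_levels(5),
                   c("WAKE", "NREM", "PREREM", "REM", "ARTIFACT"))
  expect_identical(stage_levels(3), c("WAKE", "NREM", "REM"))
  expect_identical(stage_code(c("WAKE", "ARTIFACT")), c(0L, 4L))
  expect_identical(normalize_stage("pre-rem"), "PREREM")
})

test_that("reduction to standard stages relabels pre-REM and drops artifacts", {
  h <- hypnogram(c("W", "N", "P", "R", "A"))
  red <- reduce_to_standard_stages(h)
  expect_identical(red$hypnogram$labels, c("WAKE", "NREM", "NREM", "REM"))
  expect_identical(red$kept_indices, 1:4)

  h2 <- hypnogram(c("W", "N", "R", "W"))
  red2 <- reduce_to_standard_stages(h2)
  expect_identical(red2$hypnogram$labels, h2$labels)
  expect_identical(red2$kept_indices, 1:4)
})

test_that("reduction arithmetic matches the training-set bookkeeping", {
  # 203,747 Wake + 18,606 REM + 136,586 NREM + 7,181 pre-REM + 600 artifact
  labels <- rep(c("WAKE", "REM", "NREM", "PREREM", "ARTIFACT"),
                c(203747, 18606, 136586, 7181, 600))
  red <- reduce_to_standard_stages(hypnogram(labels))
  counts <- table(red$hypnogram$labels)
  expect_identical(as.integer(counts[["WAKE"]]), 203747L)
  expect_identical(as.integer(counts[["REM"]]), 18606L)
  expect_identical(as.integer(counts[["NREM"]]), 136586L + 7181L)
  expect_identical(length(red$hypnogram$labels), 366120L)
})

test_that("reduction preserves class counts as an invariant", {
  set.seed(42)
  for (i in 1:20) {
    labels <- sample(stage_levels(5), 200, replace = TRUE,
                     prob = c(.5, .3, .05, .1, .05))
    h <- hypnogram(labels)
    red <- reduce_to_standard_stages(h)
    tin <- table(factor(labels, stage_levels(5)))
    tout <- table(factor(red$hypnogram$labels, stage_levels(3)))
    expect_identical(as.integer(tout[["WAKE"]]), as.integer(tin[["WAKE"]]))
    expect_identical(as.integer(tout[["REM"]]), as.integer(tin[["REM"]]))
    expect_identical(as.integer(tout[["NREM"]]),
                     as.integer(tin[["NREM"]] + tin[["PREREM"]]))
    expect_identical(length(red$hypnogram$labels),
                     200L - as.integer(tin[["ARTIFACT"]]))
  }
})
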