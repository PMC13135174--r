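# WAV round trips, manifest parsing, record invariants.

test_that("WAV round trip is bounded by one quantization step", {
  set.seed(1)
  x <- stats::runif(4000, -0.99, 0.99)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, p16, fs = 2000, bit_depth = "pcm16")
  r16 <- read_wav(p16)
  expect_equal(r16$fs, 2000)
  expect_lte(max(abs(r16$samples - x)), 1 / 32768)

  pf <- withr::local_tempfile(fileext = ".wav")
  write_wav(pcg_record(x, 2000), pf, bit_depth = "float32")
  rf <- read_wav(pf)
  expect_lte(max(abs(rf$samples - x)), 1e-7)  # float32 rounding only
})

test_that("the most negative 16-bit code maps into [-1, -0.9999]", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(c(-1, 0, 1), p, fs = 2000)
  r <- read_wav(p)
  expect_gte(r$samples[1], -1)
  expect_lte(r$samples[1], -0.9999)
})

test_that("degenerate and multi-channel WAVs are handled", {
  expect_error(write_wav(numeric(0), tempfile(), fs = 2000), "zero-length")
  expect_error(read_wav(tempfile("nope")), "not found")

  # hand-craft a zero-length-data WAV
  p0 <- withr::local_tempfile(fileext = ".wav")
  con <- file(p0, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  for (v in list(1L, 1L)) writeBin(v, con, size = 2, endian = "little")
  writeBin(2000L, con, size = 4, endian = "little")
  writeBin(4000L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_wav(p0), "no audio data")

  # hand-craft a stereo PCM WAV; channel 1 must be returned
  p2 <- withr::local_tempfile(fileext = ".wav")
  ch1 <- as.integer(round(seq(-0.5, 0.5, length.out = 100) * 32768))
  ch2 <- rep(0L, 100)
  inter <- as.integer(rbind(ch1, ch2))
  con <- file(p2, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(2L, con, size = 2, endian = "little")   # 2 channels
  writeBin(2000L, con, size = 4, endian = "little")
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  r2 <- read_wav(p2)
  expect_equal(length(r2$samples), 100)
  expect_equal(r2$samples, ch1 / 32768, tolerance = 1e-12)
})

test_that("manifest parsing validates and is order-independent", {
  man <- test_manifest()
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(man, p, row.names = FALSE)
  m <- load_manifest(p)
  expect_equal(nrow(m), 75)
  # group sizes of the emulated cohort
  cuts <- cut(m$stenosis_pct, c(-1, 10, 35, 50, 65, 80, 87, 101))
  expect_equal(as.vector(table(cuts)), c(10, 10, 10, 15, 10, 10, 10))

  shuffled <- man[sample.int(nrow(man)), ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuffled, p2, row.names = FALSE)
  m2 <- load_manifest(p2)
  expect_setequal(m2$participant_id, m$participant_id)

  # empty table parses to an empty manifest
  pe <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(man[0, ], pe, row.names = FALSE)
  expect_equal(nrow(load_manifest(pe)), 0)

  # duplicate ids, missing columns, out-of-range stenosis are rejected
  dup <- man; dup$participant_id[2] <- dup$participant_id[1]
  pd <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, pd, row.names = FALSE)
  expect_error(load_manifest(pd), "duplicate")

  pm <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(man[c("participant_id", "path")], pm, row.names = FALSE)
  expect_error(load_manifest(pm), "missing column")

  bad <- man; bad$stenosis_pct[1] <- 120
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(load_manifest(pb), "\\[0, 100\\]")
})

test_that("pcg_record enforces its invariants", {
  expect_error(pcg_record(1:10, fs = 0), "positive")
  expect_error(pcg_record(1:10, 2000, r_times = c(0.5, 0.4)), "increasing")
  expect_error(pcg_record(1:10, 2000, stenosis_pct = 30, label = "severe"),
               "inconsistent")
  r <- pcg_record(1:10, 2000, stenosis_pct = 60)
  expect_equal(r$label, "moderate")
})
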