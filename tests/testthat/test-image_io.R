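test_that("hyperstack TIFF write/read round-trips grid and metadata", {
  set.seed(42)
  arr <- array(sample(0:65535, 10 * 2 * 5 * 64 * 64, replace = TRUE),
               c(10, 2, 5, 64, 64))
  stack <- TimelapseStack(arr, pixelSizeUm = 0.21, frameIntervalMin = 10,
                          channelRoles = c(green = 1L, red = 2L))
  f <- file.path(withr::local_tempdir(), "stack.tif")
  writeHyperstack(stack, f)
  back <- readHyperstack(f)
  expect_identical(dim(frames(back)), dim(arr))
  expect_equal(frames(back), arr)
  expect_equal(pixelSize(back), 0.21)
  expect_equal(frameInterval(back), 10)
  expect_identical(channelRoles(back), c(green = 1L, red = 2L))
  expect_identical(bitDepth(back), 16L)
  # canonicalization is idempotent: re-writing the canonical stack changes nothing
  f2 <- file.path(dirname(f), "stack2.tif")
  writeHyperstack(back, f2)
  expect_equal(frames(readHyperstack(f2)), arr)
})

test_that("single-channel TIFF is rejected with a channel count error", {
  arr <- array(sample(0:255, 3 * 1 * 2 * 8 * 8, replace = TRUE),
               c(3, 1, 2, 8, 8))
  f <- file.path(withr::local_tempdir(), "one.tif")
  pages <- list()
  for (t in 1:3) for (z in 1:2) pages <- c(pages, list(arr[t, 1, z, , ] / 255))
  tiff::writeTIFF(pages, f, bits.per.sample = 8, compression = "none")
  jsonlite::write_json(list(frames = 3, channels = 1, slices = 2),
                       sub("\\.tif$", ".json", f), auto_unbox = TRUE)
  expect_error(readHyperstack(f), "channel count")
})

test_that("missing metadata requires a hint; hint plus defaults works", {
  arr <- array(sample(0:255, 2 * 2 * 2 * 8 * 8, replace = TRUE),
               c(2, 2, 2, 8, 8))
  stack <- TimelapseStack(arr, bitDepth = 8L)
  f <- file.path(withr::local_tempdir(), "bare.tif")
  writeHyperstack(stack, f)
  unlink(sub("\\.tif$", ".json", f))  # strip the sidecar
  expect_error(readHyperstack(f), "calibration required")
  expect_message(back <- readHyperstack(f, axisOrderHint = "T2C2Z2"),
                 "assay defaults")
  expect_equal(frames(back), arr)
  expect_equal(pixelSize(back), 32 / 150, tolerance = 1e-12)
  expect_equal(frameInterval(back), 10)
})

test_that("ImageJ hyperstack description strings parse", {
  meta <- parseImageJDescription(
    "ImageJ=1.54f\nimages=100\nchannels=2\nslices=5\nframes=10\nhyperstack=true\nfinterval=600")
  expect_equal(meta$channels, 2L)
  expect_equal(meta$slices, 5L)
  expect_equal(meta$frames, 10L)
  expect_equal(meta$frameIntervalMin, 10)  # finterval is seconds
  expect_null(parseImageJDescription("not imagej at all"))
})

test_that("simulator output carries 10 timepoints and 2 channels at defaults", {
  cfg <- smallSimConfig(shotNoise = FALSE, readNoiseSd = 0)
  rend <- renderFrames(simulateKinetics(cfg), cfg)
  d <- dim(frames(rend$stack))
  expect_identical(d[1:2], c(10L, 2L))
})

test_that("trace CSV round-trips coordinates to 6 decimals", {
  set.seed(7)
  traces <- lapply(1:3, function(t)
    TracePath(cbind(cumsum(runif(50, 0.5, 2)), cumsum(runif(50, 0.5, 2))),
              timepointIndex = t))
  f <- file.path(withr::local_tempdir(), "traces.csv")
  writeTrace(traces, f)
  back <- readTrace(f)
  expect_length(back, 3L)
  for (t in 1:3)
    expect_equal(tracePoints(back[[t]]), tracePoints(traces[[t]]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CSV of collinear points loads as one ordered trace", {
  f <- file.path(withr::local_tempdir(), "line.csv")
  write.csv(data.frame(timepoint = 1L, y = 5, x = seq(0, 199)), f,
            row.names = FALSE)
  tr <- readTrace(f)
  expect_length(tr, 1L)
  expect_equal(nrow(tracePoints(tr[[1]])), 200L)
  expect_equal(tracePoints(tr[[1]])[1, ], c(y = 5, x = 0))
})

test_that("SWC parent links define order and branches are rejected", {
  dir <- withr::local_tempdir()
  lin <- file.path(dir, "lin.swc")
  # root (tip) at id 1; children chain 1 <- 2 <- 3 <- 4
  writeLines(c("# linear", "1 2 10 20 0 1 -1", "2 2 11 20 0 1 1",
               "3 2 12 21 0 1 2", "4 2 13 22 0 1 3"), lin)
  tr <- readTrace(lin)
  expect_equal(tracePoints(tr)[, "x"], c(10, 11, 12, 13), ignore_attr = TRUE)
  expect_equal(tracePoints(tr)[1, "y"], 20, ignore_attr = TRUE)
  br <- file.path(dir, "branch.swc")
  writeLines(c("1 2 0 0 0 1 -1", "2 2 1 0 0 1 1", "3 2 1 1 0 1 1"), br)
  expect_error(readTrace(br), "non-linear trace")
  short <- file.path(dir, "short.swc")
  writeLines("1 2 0 0 0 1 -1", short)
  expect_error(readTrace(short), "degenerate trace")
})

test_that("FASTA reading handles records, duplicates and round-trips", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "one.fa")
  writeLines(c(">a", "GGACT"), f1)
  rec <- readFastaRecords(f1)
  expect_identical(names(rec), "a")
  expect_identical(nchar(rec[["a"]]), 5L)
  f2 <- file.path(dir, "two.fa")
  writeLines(c(">a desc", "ACGT", ">b", "TTTT"), f2)
  expect_identical(names(readFastaRecords(f2)), c("a", "b"))
  fd <- file.path(dir, "dup.fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), fd)
  expect_warning(recs <- readFastaRecords(fd), "duplicate")
  expect_length(recs, 2L)
  # 1000 random records round-trip byte-identically
  set.seed(11)
  seqs <- setNames(vapply(1:1000, function(i)
    randomDnaSeq(sample(20:80, 1)), ""), sprintf("s%04d", 1:1000))
  fr <- file.path(dir, "rand.fa")
  writeFastaRecords(seqs, fr)
  expect_identical(readFastaRecords(fr), seqs)
})
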