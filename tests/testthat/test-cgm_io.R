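test_that("CSV parsing handles the documented column layout, headers and dialects", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("0,2023-01-01T00:00:00,4.6", path)
  s <- read_cgm_csv(path)
  expect_s3_class(s, "cgm_series")
  expect_length(s, 1L)
  expect_equal(s$values, 4.6)
  expect_equal(s$timestamps, t0_utc)

  # header auto-detection
  writeLines(c("index,timestamp,glucose_mmol_l",
               "0,2023-01-01T00:00:00,4.6",
               "1,2023-01-01T00:05:00,4.3"), path)
  expect_equal(read_cgm_csv(path)$values, c(4.6, 4.3))

  # second timestamp dialect behind the config switch
  writeLines(c("0,01/01/2023 00:00:00,5.0", "1,01/01/2023 00:05:00,5.2"), path)
  s2 <- read_cgm_csv(path, timestamp_dialect = "dmy")
  expect_equal(as.numeric(diff(s2$timestamps), units = "secs"), 300)
})

test_that("malformed CGM files raise distinct named errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  file.create(path)
  expect_error(read_cgm_csv(path), class = "evocgm_empty_input")

  writeLines(c("0,2023-01-01T00:05:00,4.6", "1,2023-01-01T00:00:00,4.3"), path)
  expect_error(read_cgm_csv(path), class = "evocgm_monotonicity_error")

  writeLines("0,not-a-time,4.6", path)
  expect_error(read_cgm_csv(path), class = "evocgm_parse_error")

  writeLines("0,2023-01-01T00:00:00,banana", path)
  expect_error(read_cgm_csv(path), class = "evocgm_parse_error")

  writeLines("0,2023-01-01T00:00:00,99.9", path)
  expect_error(read_cgm_csv(path), class = "evocgm_bounds_error")

  expect_error(read_cgm_csv(tempfile()), class = "evocgm_io_error")
})

test_that("write then read round-trips timestamps and 1-dp values exactly", {
  set.seed(31)
  s <- make_series(round(runif(200, 3, 12), 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cgm_csv(s, path)
  s2 <- read_cgm_csv(path)
  expect_identical(s2$values, s$values)
  expect_equal(as.numeric(s2$timestamps), as.numeric(s$timestamps))
})

test_that("gap interpolation is time-linear, rounded to 1 dp, and capped", {
  # one missing 5-min slot between 4.0 and 5.0 -> midpoint 4.5
  s <- cgm_series(t0_utc + c(0, 300, 900, 1200), c(4.2, 4.0, 5.0, 5.1))
  f <- interpolate_gaps(s)
  expect_length(f, 5L)
  expect_equal(f$values[3], 4.5)
  expect_true(f$filled[3])

  # gapless input is returned unchanged
  g <- make_series(c(4, 5, 6))
  expect_identical(interpolate_gaps(g)$values, g$values)
  expect_length(interpolate_gaps(g), 3L)

  # 3-hour gap with max_gap = 60 min stays open
  long <- cgm_series(t0_utc + c(0, 300, 300 + 3 * 3600), c(4, 5, 6))
  out <- interpolate_gaps(long, max_gap = 3600)
  expect_length(out, 3L)

  # linear-function recovery: filled points equal the true line exactly
  # (line chosen so every grid value is exactly one decimal place)
  line_v <- function(t) 4 + 0.1 * t / 300
  tt <- c(0:4, 10:14) * 300
  s_lin <- cgm_series(t0_utc + tt, line_v(tt))
  f_lin <- interpolate_gaps(s_lin, max_gap = 2000)
  expect_length(f_lin, 15L)
  expect_equal(f_lin$values, round(line_v((0:14) * 300), 1))
})

test_that("segmentation partitions the series at irregular steps", {
  # one unfilled 2-hour gap -> exactly 2 segments
  s <- cgm_series(t0_utc + c(0, 300, 600, 600 + 7200, 600 + 7500), rep(5, 5))
  segs <- segment_contiguous(s)
  expect_equal(nrow(segs), 2L)

  # fully regular -> one segment covering everything
  r <- make_series(rep(5, 50))
  segs_r <- segment_contiguous(r)
  expect_equal(nrow(segs_r), 1L)
  expect_equal(c(segs_r$start, segs_r$end), c(1L, 51L))

  # long gaps everywhere -> all singleton segments
  iso <- cgm_series(t0_utc + (0:4) * 7200, rep(5, 5))
  expect_equal(nrow(segment_contiguous(iso)), 5L)

  # property: indices disjoint, sorted, covering all readings (jittered series)
  set.seed(7)
  sj <- inject_artifacts(make_series(round(runif(500, 4, 9), 1)),
                         missing_rate = 0.05, jitter_fraction = 0.41, seed = 5)
  segs_j <- segment_contiguous(sj)
  covered <- unlist(Map(function(a, b) a:(b - 1L), segs_j$start, segs_j$end))
  expect_identical(covered, seq_len(length(sj)))
  # jittered steps (299-301 s) must not split segments
  dt <- diff(as.numeric(sj$timestamps))
  expect_equal(nrow(segs_j), sum(abs(dt - 300) > 2) + 1L)
})
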