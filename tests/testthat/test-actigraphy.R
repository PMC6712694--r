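t0 <- as.POSIXct("2015-03-02 06:00:00", tz = "UTC")

make_series <- function(counts, start = t0) {
  epoch_series("p1", start + seq_along(counts) - 1, counts)
}

test_that("non-wear needs at least 60 min of consecutive zeros", {
  s60 <- make_series(c(1, rep(0, 3600), 1))
  wear <- detect_nonwear(s60)
  expect_identical(wear, c(TRUE, rep(FALSE, 3600), TRUE))

  s59 <- make_series(c(1, rep(0, 3599), 1))
  expect_true(all(detect_nonwear(s59)))

  expect_true(all(detect_nonwear(make_series(rep(5, 1000)))))
  expect_identical(detect_nonwear(make_series(numeric(0))), logical(0))
})

test_that("a recording gap breaks a zero run", {
  # 50 min of zeros before midnight, 50 min after the restricted window
  # reopens: two short runs, not one 100-min run
  late <- as.POSIXct("2015-03-02 23:10:00", tz = "UTC") + 0:2999
  early <- as.POSIXct("2015-03-03 06:00:00", tz = "UTC") + 0:2999
  s <- epoch_series("p1", c(late, early), rep(0, 6000))
  expect_true(all(detect_nonwear(s)))
})

test_that("hour restriction keeps exactly 06:00:00 through 23:59:59", {
  ts <- as.POSIXct("2015-03-02 05:59:58", tz = "UTC") + 0:3
  s <- epoch_series("p1", ts, rep(1, 4))
  kept <- restrict_hours(s)
  expect_identical(format(kept$timestamp, "%H:%M:%S"),
                   c("06:00:00", "06:00:01"))
  late <- epoch_series("p1",
                       as.POSIXct("2015-03-02 23:59:29", tz = "UTC") + 0:1,
                       c(2, 2))
  expect_equal(nrow(restrict_hours(late)), 2)
})

test_that("day and measurement validity thresholds are sharp", {
  day <- function(minutes) {
    one <- data.frame(start = c(0, 8, 8 + minutes / 60),
                      end = c(8, 8 + minutes / 60, 24),
                      level = c(0, 30, 0), wear = c(FALSE, TRUE, FALSE))
    one
  }
  s480 <- generate_epoch_series(4, day(480))
  vd <- valid_days(s480)
  expect_true(all(vd$days$valid))
  expect_true(vd$valid)

  s479 <- generate_epoch_series(1, day(479))
  expect_false(valid_days(s479)$days$valid)

  s3 <- generate_epoch_series(3, day(480))
  expect_false(valid_days(s3)$valid)
  expect_error(bin_profile(s3, bin_scheme("traditional")),
               class = "invalid_wear_error")
})

test_that("epoch counts are classified against cpm edges after scaling by 60", {
  # 40 counts/s = 2400 cpm: inside the 2296-4011 moderate interval
  s <- restrict_hours(generate_epoch_series(4, one_block_day(level = 40)))
  prof <- bin_profile(s, bin_scheme("traditional"))
  expect_equal(unname(prof$bin_minutes),
               c(0, 0, 600, 0))
  expect_equal(prof$wear_minutes, 600)
  expect_equal(prof$n_valid_days, 4)
})

test_that("short zero runs inside wear land in the sedentary bin", {
  wp <- data.frame(start = c(0, 8, 10, 10.5, 18),
                   end = c(8, 10, 10.5, 18, 24),
                   level = c(0, 40, 0, 40, 0),
                   wear = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  s <- restrict_hours(generate_epoch_series(4, wp))
  prof <- bin_profile(s, bin_scheme("traditional"))
  expect_equal(unname(prof$bin_minutes[["SED"]]), 30)
  expect_equal(unname(prof$bin_minutes[["MPA"]]), 570)
  # conservation: bins sum exactly to wear
  expect_equal(sum(prof$bin_minutes), prof$wear_minutes, tolerance = 1e-9)
})

test_that("the spectrum scheme yields 23 bins summing to the same wear time", {
  s <- restrict_hours(generate_epoch_series(4, one_block_day(level = 40)))
  trad <- bin_profile(s, bin_scheme("traditional"))
  spec <- bin_profile(s, bin_scheme("spectrum"))
  expect_length(spec$bin_minutes, 23)
  expect_equal(sum(spec$bin_minutes), sum(trad$bin_minutes),
               tolerance = 1e-9)
  expect_equal(sum(spec$bin_minutes), spec$wear_minutes, tolerance = 1e-9)
})

test_that("traditional summaries: MVPA, guideline flag, overall cpm", {
  prof <- structure(list(
    participant_id = "p1",
    bin_minutes = c(SED = 597, LPA = 122, MPA = 37, VPA = 39),
    wear_minutes = 795, n_valid_days = 5,
    scheme = bin_scheme("traditional"), valid = TRUE
  ), class = "intensity_profile")
  sm <- derive_summary(prof)
  expect_equal(sm$mvpa_minutes, 76)
  expect_true(sm$meets_guideline)

  prof$bin_minutes <- c(SED = 700, LPA = 35, MPA = 30, VPA = 29.99)
  sm2 <- derive_summary(prof)
  expect_equal(sm2$mvpa_minutes, 59.99)
  expect_false(sm2$meets_guideline)

  prof$bin_minutes <- c(SED = 795, LPA = 0, MPA = 0, VPA = 0)
  expect_equal(derive_summary(prof)$mvpa_minutes, 0)

  # cpm from the underlying stream: constant 50 counts/s = 3000 cpm
  s <- restrict_hours(generate_epoch_series(4, one_block_day(level = 50)))
  p <- bin_profile(s, bin_scheme("traditional"))
  expect_equal(derive_summary(p, series = s)$overall_cpm, 3000)
})
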