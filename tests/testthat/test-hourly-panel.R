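test_that("construction, accessors and validity", {
  p <- tinyPanel(2, 6)
  expect_s4_class(p, "HourlyPanel")
  expect_identical(cities(p), c("A", "B"))
  expect_identical(panelVariables(p), c("PM25", "SO2"))
  expect_equal(length(hourlyTimes(p)), 6)
  expect_equal(dim(panelMatrix(p, "PM25")), c(2, 6))
  arr <- panelArray(p)
  expect_equal(dim(arr), c(2, 6, 2))
  expect_equal(arr[, , "PM25"], panelMatrix(p, "PM25"),
               ignore_attr = TRUE)
  # non-hourly spacing rejected
  expect_error(
    HourlyPanel(list(PM25 = matrix(1, 1, 3)),
                as.POSIXct("2023-01-01", tz = "UTC") + c(0, 3600, 10800),
                "A"),
    "1-hour")
  # negative concentrations rejected
  expect_error(HourlyPanel(list(PM25 = matrix(-1, 1, 3)),
                           hoursFrom("2023-01-01", 3), "A"),
               ">= 0")
  # PM25 mandatory
  expect_error(HourlyPanel(list(SO2 = matrix(1, 1, 3)),
                           hoursFrom("2023-01-01", 3), "A"),
               "PM25")
})

test_that("long CSV round-trips through read and write", {
  p <- tinyPanel(2, 5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeHourlyPanel(p, f)
  p2 <- readHourlyPanel(f)
  expect_equal(panelMatrix(p2, "PM25"), panelMatrix(p, "PM25"))
  expect_equal(hourlyTimes(p2), hourlyTimes(p))
  expect_identical(cities(p2), cities(p))
})

test_that("wide CSV ingestion and unknown columns", {
  tm <- format(hoursFrom("2023-01-01", 3), "%Y-%m-%d %H:%M:%S")
  df <- data.frame(datetime = rep(tm, 2), city = rep(c("A", "B"), each = 3),
                   PM25 = 1:6, SO2 = 11:16, bogus = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_warning(p <- readHourlyPanel(f), "bogus")
  expect_setequal(panelVariables(p), c("PM25", "SO2"))
  expect_equal(panelMatrix(p, "PM25")["A", ], c(1, 2, 3),
               ignore_attr = TRUE)
})

test_that("gaps in the hourly grid become missing cells", {
  tm <- hoursFrom("2023-01-01", 3)
  df <- data.frame(datetime = format(tm, "%Y-%m-%d %H:%M:%S"),
                   city = "A", variable = "PM25", value = c(5, 6, 7))
  df <- df[-2, ]                      # drop hour 01:00
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  p <- readHourlyPanel(f)
  expect_equal(ncol(p), 3)            # grid completed, not dropped
  expect_true(is.na(panelMatrix(p)["A", 2]))
})

test_that("duplicate records raise an error naming the offender", {
  tm <- format(hoursFrom("2023-01-01", 2), "%Y-%m-%d %H:%M:%S")
  df <- data.frame(datetime = c(tm, tm[1]), city = "A",
                   variable = "PM25", value = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(readHourlyPanel(f), "duplicate record.*A.*PM25")
})
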