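test_that("table constructors enforce their invariants", {
  x <- id_tbl(data.frame(id = 1:2, sex = c("Male", "Female")),
              id_vars = "id")
  expect_s3_class(x, "id_tbl")
  expect_identical(id_vars(x), "id")
  expect_identical(data_vars(x), "sex")

  expect_error(id_tbl(data.frame(id = c(1, NA)), id_vars = "id"),
               "missing values")
  expect_error(id_tbl(data.frame(a = 1), id_vars = "id"), "not present")

  y <- ts_tbl(data.frame(id = 1, t = c(-120L, 0L, 60L), v = 1:3),
              id_vars = "id", index_var = "t", interval = 60)
  expect_s3_class(y, "ts_tbl")
  expect_identical(interval(y), 60L)

  expect_error(ts_tbl(data.frame(id = 1, t = 30L, v = 1), id_vars = "id",
                      index_var = "t", interval = 60),
               "multiples")
  expect_error(ts_tbl(data.frame(id = 1, t = 0L, v = 1), id_vars = "id",
                      index_var = "t", interval = 0), "positive")

  w <- win_tbl(data.frame(id = 1, t = 0L, dur = 159, v = "invasive"),
               id_vars = "id", index_var = "t", dur_var = "dur")
  expect_s3_class(w, "win_tbl")
  expect_error(win_tbl(data.frame(id = 1, t = 0L, dur = -5, v = "x"),
                       id_vars = "id", index_var = "t", dur_var = "dur"),
               "non-negative")
})

test_that("duplicate keys are rejected only when asked", {
  x <- ts_tbl(data.frame(id = c(1, 1), t = c(0L, 0L), v = 1:2),
              id_vars = "id", index_var = "t", interval = 60)
  expect_silent(validate_tbl(x))
  expect_error(validate_tbl(x, dups = TRUE), "duplicate")
})

test_that("CSV + sidecar serialization round-trips tables", {
  y <- ts_tbl(data.frame(id = c(1L, 1L), t = c(0L, 60L),
                         lact = c(1.7, 2.2)),
              id_vars = "id", index_var = "t", interval = 60,
              units = c(lact = "mmol/L"))
  p <- file.path(tempdir(), "roundtrip.csv")
  write_tbl(y, p)
  z <- read_tbl(p)
  expect_s3_class(z, "ts_tbl")
  expect_identical(tbl_meta <- id_vars(z), "id")
  expect_identical(interval(z), 60L)
  expect_identical(units_of(z), c(lact = "mmol/L"))
  expect_equal(as.data.frame(z), as.data.frame(y))
})

test_that("printing shows the table kind and metadata", {
  y <- ts_tbl(data.frame(id = 1L, t = 0L, lact = 1.7),
              id_vars = "id", index_var = "t", interval = 60,
              units = c(lact = "mmol/L"))
  out <- capture.output(print(y))
  expect_match(out[1], "ts_tbl.*1 x 3")
  expect_match(paste(out, collapse = "\n"), "Index var")
  expect_match(paste(out, collapse = "\n"), "mmol/L")
})
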