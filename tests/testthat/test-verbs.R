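mk_ts <- function(id, t, v, interval = 1L, var = "v") {
  d <- data.frame(id = id, t = as.integer(t), v = v)
  names(d)[3] <- var
  ts_tbl(d, id_vars = "id", index_var = "t", interval = interval)
}

test_that("bin_index floors toward negative infinity", {
  x <- mk_ts(1, c(61, -61, 0, 59, -1), 1:5)
  b <- bin_index(x, 60)
  expect_identical(b$t, c(60L, -120L, 0L, 0L, -60L))
  expect_identical(interval(b), 60L)
  expect_error(bin_index(x, 0), "positive")

  ## property: equals the elementwise floor-division oracle
  set.seed(42)
  raw <- as.integer(sample(-5000:5000, 400))
  for (step in c(15L, 60L, 1440L)) {
    got <- bin_index(mk_ts(1, raw, seq_along(raw)), step)$t
    oracle <- as.integer(floor(raw / step) * step)
    expect_identical(got, oracle)
  }
})

test_that("aggregate_by collapses duplicate keys with the right function", {
  x <- mk_ts(1, c(0, 0), c(80, 90), interval = 60, var = "hr")
  expect_equal(aggregate_by(x, "median")$hr, 85)

  y <- mk_ts(1, c(0, 0), c(3, 9), interval = 60, var = "ins")
  expect_equal(aggregate_by(y, "sum")$ins, 12)

  z <- ts_tbl(data.frame(id = 1, t = c(0L, 0L, 60L),
                         death = c(FALSE, TRUE, FALSE)),
              id_vars = "id", index_var = "t", interval = 60)
  a <- aggregate_by(z, "any")
  expect_identical(a$death, c(TRUE, FALSE))

  na <- mk_ts(1, c(0, 0), c(NA_real_, NA_real_), interval = 60)
  expect_true(is.na(aggregate_by(na, "median")$v))
  expect_error(aggregate_by(x, "frobnicate"), "unknown aggregation")
})

test_that("change_interval equals bin-then-aggregate composition", {
  set.seed(7)
  x <- mk_ts(rep(1:3, each = 40), rep(seq(0, 39 * 60, 60), 3),
             rnorm(120), interval = 60)
  expect_equal(as.data.frame(change_interval(x, 60)),
               as.data.frame(aggregate_by(x)))
  y <- change_interval(x, 120)
  expect_lte(length(unique(y$t)), length(unique(x$t)))
  oracle <- aggregate_by(bin_index(x, 120), "median")
  expect_equal(as.data.frame(y), as.data.frame(oracle))
})

test_that("fill_gaps densifies, is idempotent, and matches the closed form", {
  x <- mk_ts(1, c(0, 180), c(1.5, 2.0), interval = 60, var = "lact")
  f <- fill_gaps(x)
  expect_identical(f$t, c(0L, 60L, 120L, 180L))
  expect_identical(f$lact, c(1.5, NA, NA, 2.0))
  expect_equal(as.data.frame(fill_gaps(f)), as.data.frame(f))

  set.seed(11)
  ids <- rep(1:5, times = sample(3:8, 5, replace = TRUE))
  tt <- unlist(lapply(table(ids), function(k) {
    sort(sample(seq(0, 50) * 60L, k))
  }))
  y <- fill_gaps(mk_ts(ids, tt, seq_along(ids), interval = 60))
  spans <- tapply(tt, ids, function(t) (max(t) - min(t)) / 60 + 1)
  expect_identical(nrow(y), as.integer(sum(spans)))
})

test_that("replace_na handles locf and const schemes", {
  x <- mk_ts(1, (0:3) * 60, c(1.7, NA, NA, 2.2), interval = 60,
             var = "lact")
  r <- replace_na(x, NA, type = "locf", vars = "lact")
  expect_equal(r$lact, c(1.7, 1.7, 1.7, 2.2))
  ## locf is idempotent
  expect_equal(as.data.frame(replace_na(r, NA, type = "locf",
                                        vars = "lact")),
               as.data.frame(r))
  ## leading missing values stay missing
  y <- mk_ts(1, c(0, 60), c(NA, 5), interval = 60)
  expect_equal(replace_na(y, NA, type = "locf", vars = "v")$v, c(NA, 5))
  ## missing death flags become FALSE
  z <- ts_tbl(data.frame(id = 1, t = (0:2) * 60L,
                         death = c(NA, NA, TRUE)),
              id_vars = "id", index_var = "t", interval = 60)
  expect_identical(replace_na(z, FALSE, type = "const",
                              vars = "death")$death,
                   c(FALSE, FALSE, TRUE))
  expect_error(replace_na(z, NA, type = "const", vars = "death"),
               "fill value")
  expect_error(replace_na(z, NA, type = "mean", vars = "death"), "locf")
})

test_that("expand unrolls windows and conserves values", {
  w <- win_tbl(data.frame(id = 1L, t = 0L, dur = 159, v = "invasive"),
               id_vars = "id", index_var = "t", dur_var = "dur",
               interval = 60)
  e <- expand(w)
  expect_identical(e$t, c(0L, 60L, 120L))
  expect_identical(e$v, rep("invasive", 3))

  w0 <- win_tbl(data.frame(id = 1L, t = 60L, dur = 0, v = "x"),
                id_vars = "id", index_var = "t", dur_var = "dur",
                interval = 60)
  expect_identical(nrow(expand(w0)), 1L)

  set.seed(3)
  n <- 40
  durs <- sample(0:500, n)
  w2 <- win_tbl(data.frame(id = seq_len(n), t = 0L, dur = durs,
                           v = seq_len(n)),
                id_vars = "id", index_var = "t", dur_var = "dur",
                interval = 60)
  e2 <- expand(w2)
  expect_identical(nrow(e2), as.integer(sum(floor(durs / 60) + 1)))
  ## each value repeated floor(dur/60)+1 times
  reps <- table(e2$v)
  expect_identical(as.integer(reps[as.character(seq_len(n))]),
                   as.integer(floor(durs / 60) + 1))
})

test_that("slide matches a brute-force window scan", {
  x <- mk_ts(1, (0:5) * 60, c(5, 3, 8, 1, 9, 2), interval = 60)
  ident <- slide(x, before = 0, after = 0, fun = "max")
  expect_equal(ident$v, x$v)

  set.seed(5)
  ids <- sample(1:4, 300, replace = TRUE)
  tt <- sample(seq(0, 100) * 60L, 300, replace = TRUE)
  dd <- data.table::data.table(id = ids, t = tt, v = rnorm(300))
  dd <- dd[!duplicated(paste(id, t))]
  y <- ts_tbl(dd, id_vars = "id", index_var = "t", interval = 60)
  got <- slide(y, before = 24 * 60, after = 0, fun = "max")
  ## O(n^2) oracle
  gg <- merge(as.data.frame(got), as.data.frame(dd),
              by = c("id", "t"), suffixes = c(".got", ".raw"))
  oo <- vapply(seq_len(nrow(gg)), function(i) {
    max(dd$v[dd$id == gg$id[i] & dd$t >= gg$t[i] - 24 * 60 &
               dd$t <= gg$t[i]])
  }, numeric(1))
  expect_equal(gg$v.got, oo)
})

test_that("truncate_at_first keeps rows through the first raised flag", {
  mk <- function(flags) {
    ts_tbl(data.frame(id = 1, t = seq_along(flags) * 60L, death = flags),
           id_vars = "id", index_var = "t", interval = 60)
  }
  expect_identical(nrow(truncate_at_first(mk(c(FALSE, FALSE, TRUE, FALSE)),
                                          "death")), 3L)
  expect_identical(nrow(truncate_at_first(mk(c(FALSE, FALSE, FALSE)),
                                          "death")), 3L)
  expect_identical(nrow(truncate_at_first(mk(c(TRUE, FALSE)), "death")), 1L)
  expect_error(truncate_at_first(mk(TRUE), "nope"), "not present")
})

test_that("merge_concepts joins by id and index, broadcasting static data", {
  lact <- mk_ts(c(1, 1, 2), c(0, 60, 0), c(1.7, 1.8, 2.2), interval = 60,
                var = "lact")
  death <- ts_tbl(data.frame(id = 2, t = 60L, death = TRUE),
                  id_vars = "id", index_var = "t", interval = 60)
  m <- merge_concepts(list(lact, death))
  expect_s3_class(m, "ts_tbl")
  expect_setequal(data_vars(m), c("lact", "death"))
  expect_identical(nrow(m), 4L)

  expect_identical(merge_concepts(list(lact)), lact)

  sex <- id_tbl(data.frame(id = c(1, 2), sex = c("Male", "Female")),
                id_vars = "id")
  b <- merge_concepts(list(lact, sex))
  expect_identical(nrow(b), nrow(lact))
  expect_identical(b$sex, c("Male", "Male", "Female"))

  slow <- change_interval(lact, 120)
  expect_error(merge_concepts(list(lact, slow)), "change_interval")
})
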