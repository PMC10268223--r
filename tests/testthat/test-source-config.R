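min_cfg <- function() {
  list(
    name = "tiny", time_mode = "relative",
    id_systems = list(
      list(name = "icustay", id_column = "stay_id",
           origin_table = "stays", start_column = "admit",
           end_column = "disch", rank = 1L)),
    tables = list(
      list(name = "stays", file = "stays.csv",
           columns = list(list(name = "stay_id", type = "id"),
                          list(name = "admit", type = "timestamp"),
                          list(name = "disch", type = "timestamp")),
           defaults = list(id_column = "stay_id"))))
}

test_that("a minimal source configuration parses and validates", {
  cfg <- parse_source_config(jsonlite::toJSON(min_cfg(),
                                              auto_unbox = TRUE))
  expect_s3_class(cfg, "src_cfg")
  expect_identical(id_hierarchy(cfg), "icustay")
  expect_identical(cfg$id_systems[[1]]$rank, 1L)
})

test_that("nested identifier systems keep their coarse-to-fine ranks", {
  h <- make_two_stay_source()
  expect_identical(id_hierarchy(h$cfg), c("patient", "hadm", "icustay"))
  expect_identical(vapply(h$cfg$id_systems, `[[`, integer(1), "rank"),
                   1:3)
})

test_that("invalid configurations fail with the offending path", {
  bad <- min_cfg()
  bad$tables[[1]]$defaults$value_column <- "nonexistent"
  expect_error(parse_source_config(bad), "defaults.value_column")

  dup <- min_cfg()
  dup$tables <- c(dup$tables, dup$tables)
  expect_error(parse_source_config(dup), "duplicate table")

  badrank <- min_cfg()
  badrank$id_systems[[1]]$rank <- 2L
  expect_error(parse_source_config(badrank), "rank")

  orphan <- min_cfg()
  orphan$id_systems[[1]]$origin_table <- "ghost"
  expect_error(parse_source_config(orphan), "not a declared table")
})

test_that("parse -> serialize -> parse round-trips the configuration", {
  cfg <- parse_source_config(min_cfg())
  again <- parse_source_config(serialize_source_config(cfg))
  expect_equal(again, cfg)
})

test_that("register_source verifies files and headers", {
  dir <- file.path(tempdir(), "srcreg")
  dir.create(dir, showWarnings = FALSE)
  cfg <- parse_source_config(min_cfg())
  expect_error(register_source(cfg, dir), "missing table file.*stays")

  writeLines(c("stay_id,admit", "1,0"), file.path(dir, "stays.csv"))
  expect_error(register_source(cfg, dir), "disch")

  ## undeclared extra columns are tolerated with a warning
  writeLines(c("stay_id,admit,disch,extra_col", "1,0,1440,x"),
             file.path(dir, "stays.csv"))
  expect_warning(h <- register_source(cfg, dir), "extra_col")
  tb <- src_table(h, "stays")
  expect_identical(names(tb), c("stay_id", "admit", "disch"))
  expect_identical(tb$disch, 1440L)
})
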