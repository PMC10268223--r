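test_that("the heart-rate concept document parses to a bounded numeric concept", {
  dict <- parse_dictionary(list(hr_concept_json))
  hr <- find_concept(dict, "hr")
  expect_identical(hr$kind, "num_cncpt")
  expect_identical(hr$unit, c("bpm", "/min"))
  expect_identical(hr$min, 0L)
  expect_identical(hr$max, 300L)
  expect_identical(hr$omopid, 4239408L)
  it <- hr$sources$mimic_demo[[1]]
  expect_identical(it$kind, "sel_itm")
  expect_identical(it$sub_var, "itemid")
  expect_identical(as.integer(it$ids), c(211L, 220045L))
})

test_that("later documents override earlier ones, with provenance", {
  override <- '{"hr": {"unit": ["bpm"], "min": 10, "max": 200,
    "description": "heart rate (narrow)", "category": "vitals",
    "sources": {"mimic_demo": [
      {"ids": [211], "table": "chartevents", "sub_var": "itemid"}]}}}'
  dict <- parse_dictionary(list(hr_concept_json, override))
  hr <- find_concept(dict, "hr")
  expect_identical(hr$min, 10L)
  expect_identical(hr$max, 200L)
  expect_match(dict$provenance[["hr"]], "overrides")
})

test_that("dependency cycles among recursive concepts are rejected", {
  cyc <- '{
    "a": {"class": "rec_cncpt", "concepts": ["b"], "callback": "gcs_cb"},
    "b": {"class": "rec_cncpt", "concepts": ["a"], "callback": "gcs_cb"}}'
  expect_error(parse_dictionary(list(cyc)), "cycle.*a -> b -> a|cycle.*b -> a -> b")
  self <- '{"a": {"class": "rec_cncpt", "concepts": ["a"],
                  "callback": "gcs_cb"}}'
  expect_error(parse_dictionary(list(self)), "cycle")
})

test_that("concepts are found by name or OMOP id", {
  dict <- load_dictionary(include_user = FALSE)
  lact <- find_concept(dict, "lact")
  expect_identical(lact$name, "lact")
  expect_identical(find_concept(dict, 4191725)$name, "lact")
  expect_error(find_concept(dict, "nonexistent"), "unknown concept")
  expect_error(find_concept(dict, 999999999), "omopid")
})

test_that("dict_stats reports composition and per-source availability", {
  empty <- parse_dictionary(list("{}"))
  s0 <- dict_stats(empty)
  expect_identical(s0$total, 0L)
  expect_identical(s0$atomic, 0L)
  expect_identical(s0$recursive, 0L)

  dict <- load_dictionary(include_user = FALSE)
  s <- dict_stats(dict)
  expect_identical(s$atomic + s$recursive, s$total)
  expect_identical(sum(s$by_category), s$total)
})

test_that("callback reference grammar resolves factories and bare names", {
  f <- resolve_callback("transform_fun(grep_diab)")
  rows <- data.table::data.table(value = c("25012", "250.01", "2501",
                                           "4019", "250123"))
  out <- f(rows)
  expect_identical(out$value, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  ident <- resolve_callback("transform_fun(identity)")
  expect_identical(ident(data.table::data.table(value = 1:3))$value, 1:3)

  expect_error(resolve_callback("no_such_cb"), "unknown callback")
  expect_error(resolve_callback("transform_fun(nope)"), "unknown function")
  expect_error(resolve_callback("system('x')"), "malformed|unknown")
})

test_that("make_transform_callback registers and refuses collisions", {
  nm <- paste0("tmp_", as.integer(runif(1, 1, 1e6)))
  ref <- make_transform_callback(nm, function(x) x > 0)
  expect_identical(ref, paste0("transform_fun(", nm, ")"))
  cb <- resolve_callback(ref)
  expect_identical(cb(data.table::data.table(value = c(-1, 2)))$value,
                   c(FALSE, TRUE))
  expect_error(make_transform_callback(nm, identity), "already registered")
})

test_that("dictionary serialization round-trips", {
  dict <- parse_dictionary(list(hr_concept_json))
  again <- parse_dictionary(list(serialize_dictionary(dict)))
  expect_equal(again$concepts, dict$concepts)
})

test_that("every shipped callback reference resolves", {
  dict <- load_dictionary(include_user = FALSE)
  for (cn in dict$concepts) {
    if (!is.null(cn$callback)) expect_true(callback_exists(cn$callback))
    for (src in names(cn$sources)) {
      for (it in cn$sources[[src]]) {
        if (!is.null(it$callback)) expect_true(callback_exists(it$callback))
      }
    }
  }
})

test_that("user dictionaries are discovered through the environment variable", {
  withr::local_envvar(ICUHARM_CONFIG_PATH = "")
  expect_identical(discover_user_dictionaries(), character())

  dir <- file.path(tempdir(), "userdict")
  dir.create(dir, showWarnings = FALSE)
  writeLines('{"hr": {"unit": ["bpm"], "min": 5, "max": 250,
    "description": "hr override", "category": "vitals",
    "sources": {"eav_absolute": [
      {"ids": [211, 220045], "table": "chartevents",
       "sub_var": "itemid"}]}}}',
    file.path(dir, "custom.json"))
  withr::local_envvar(ICUHARM_CONFIG_PATH = dir)
  found <- discover_user_dictionaries()
  expect_length(found, 1L)
  dict <- load_dictionary()
  hr <- find_concept(dict, "hr")
  expect_identical(hr$min, 5L)
  expect_identical(hr$max, 250L)
  ## shipped concepts are still present alongside the override
  expect_identical(dict_stats(dict)$total, 119L)
})
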