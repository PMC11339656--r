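# Hazard registry: code validation, table loading, penalty sums.

test_that("hazard codes are normalized and malformed codes rejected", {
  expect_equal(hazard_codes(c("h225", "H360FD")), c("H225", "H360FD"))
  expect_error(hazard_codes("X999"), class = "mipgreen_format_error")
  expect_error(hazard_codes("H22"), class = "mipgreen_format_error")
  expect_equal(hazard_codes(character()), character())
})

test_that("packaged default table loads, is labelled, and validates", {
  tbl <- load_penalty_table()
  expect_s3_class(tbl, "penalty_table")
  expect_gt(nrow(tbl), 0)
  expect_true(all(tbl$points >= 0))
  expect_true(all(tbl$points == floor(tbl$points)))
  expect_false(any(duplicated(tbl$code)))
  expect_match(attr(tbl, "source_label"), "synthetic")
})

test_that("a user table round-trips through CSV exactly", {
  tbl <- penalty_table(c("H225", "H301"), c(6, 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_penalty_table(tbl, f)
  back <- load_penalty_table(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$code, tbl$code)
  expect_equal(back$points, tbl$points)
})

test_that("YAML penalty tables are accepted", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("H225: 6", "H301: 8"), f)
  tbl <- load_penalty_table(f)
  expect_equal(sort(tbl$code), c("H225", "H301"))
})

test_that("malformed tables fail with named offenders", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,points", "X999,3"), f)
  expect_error(load_penalty_table(f), "X999", class = "mipgreen_format_error")
  writeLines(c("code,points", "H225,-1"), f)
  expect_error(load_penalty_table(f), class = "mipgreen_validation_error")
  writeLines(c("code,points", "H225,3", "H225,4"), f)
  expect_error(load_penalty_table(f), "H225", class = "mipgreen_validation_error")
  expect_error(load_penalty_table("/no/such/file.csv"), class = "mipgreen_io_error")
})

test_that("penalty_sum follows set semantics", {
  tbl <- tiny_table()
  expect_identical(penalty_sum(character(), tbl), 0L)
  expect_identical(penalty_sum(c("H225", "H301"), tbl), 14L)
  # duplicates counted once: list-based oracle deduplicates first
  oracle <- function(codes) sum(tbl$points[match(unique(toupper(codes)), tbl$code)])
  dup <- c("H225", "H225", "h225")
  expect_identical(penalty_sum(dup, tbl), as.integer(oracle(dup)))
})

test_that("penalty_sum is monotone, permutation- and duplicate-invariant", {
  tbl <- load_penalty_table()
  set.seed(101)
  for (i in 1:50) {
    codes <- sample(tbl$code, sample(1:8, 1))
    s <- penalty_sum(codes, tbl)
    expect_identical(penalty_sum(sample(codes), tbl), s)
    expect_identical(penalty_sum(rep(codes, 2), tbl), s)
    extra <- sample(setdiff(tbl$code, codes), 1)
    expect_gte(penalty_sum(c(codes, extra), tbl), s)
  }
})

test_that("unknown codes error in strict mode, warn and contribute 0 in lenient", {
  tbl <- tiny_table()
  expect_error(penalty_sum("H999", tbl, strict = TRUE), "H999",
               class = "mipgreen_lookup_error")
  expect_warning(s <- penalty_sum(c("H999", "H225"), tbl, strict = FALSE), "H999")
  expect_identical(s, 6L)
})

test_that("lenient mode falls back to the 4-character stem", {
  tbl <- penalty_table(c("H360", "H225"), c(10, 6))
  # exact lookup first: a table holding the suffixed code wins
  tbl2 <- penalty_table(c("H360", "H360FD"), c(10, 9))
  expect_identical(penalty_sum("H360FD", tbl2, strict = TRUE), 9L)
  # stem fallback only in lenient mode
  expect_error(penalty_sum("H360FD", tbl, strict = TRUE),
               class = "mipgreen_lookup_error")
  expect_identical(suppressWarnings(penalty_sum("H360FD", tbl, strict = FALSE)), 10L)
})
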