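test_that("age-at-harvest data round-trips through CSV unchanged", {
  d <- aah_data(2001:2006, c(10, 12, 9, 14, 11, 8), c(30, 28, 33, 25, 27, 31),
                c(1.2, 1.1, 1.3, 1.25, 1.15, 1.2))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_age_at_harvest(d, path)
  d2 <- read_age_at_harvest(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))
})

test_that("malformed age-at-harvest input is rejected with row and field", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("year,juvenile_harvest,adult_harvest,effort",
               "2001,10,30,1.2", "2002,12,-1,1.1", "2003,9,33,1.3"), path)
  expect_error(read_age_at_harvest(path), "negative count.*adult_harvest")
  writeLines(c("year,juvenile_harvest,adult_harvest,effort",
               "2001,10,30,1.2", "2003,9,33,1.3", "2004,7,21,1.0"), path)
  expect_error(read_age_at_harvest(path), "contiguous")
  writeLines(c("year,juvenile_harvest,effort",
               "2001,10,1.2"), path)
  expect_error(read_age_at_harvest(path), "missing column.*adult_harvest")
  writeLines(c("year,juvenile_harvest,adult_harvest,effort",
               "2001,10,30,1.2", "2002,12,28,0", "2003,9,33,1.3"), path)
  expect_error(read_age_at_harvest(path), "effort must be positive")
})

test_that("telemetry data validates and an empty file is a valid empty set", {
  expect_error(telemetry_data(2001, "adult", 12, 13), "exceeds n_at_risk")
  expect_error(telemetry_data(2001, "yearling", 12, 3), "age_class")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines("year,age_class,n_at_risk,n_harvested", path)
  tel <- read_telemetry(path)
  expect_s3_class(tel, "telemetry_data")
  expect_identical(nrow(tel), 0L)
  # an empty telemetry set contributes nothing to the likelihood
  expect_identical(telemetry_loglik(tel, data.frame(year = integer(),
                                                    age_class = character(),
                                                    prob = numeric())), 0)
})

test_that("removal data round-trips and rejects partially missing rows", {
  tk <- turkey_data()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(as.data.frame(tk$removals), path, row.names = FALSE)
  r2 <- read_removals(path)
  expect_equal(as.data.frame(r2), as.data.frame(tk$removals))
  expect_error(
    removal_data(2001, 5, NA, 3, 2),
    "all present or all missing"
  )
  expect_error(removal_data(2001:2002, c(5, -2), c(1, 1), c(3, 3), c(2, 2)),
               "negative removal")
})

test_that("the packaged turkey dataset matches the published table", {
  tk <- turkey_data()
  expect_identical(length(tk$aah$years), 15L)
  expect_identical(tk$aah$years, 1996:2010)
  expect_identical(tk$aah$juvenile_harvest[1L], 626L)
  expect_identical(tk$aah$adult_harvest[1L], 2703L)
  expect_equal(tk$aah$effort[1L], 6.9298)
  rt96 <- tk$telemetry[tk$telemetry$year == 1996, ]
  expect_identical(nrow(rt96), 2L)
  expect_identical(rt96$n_at_risk[rt96$age_class == "juvenile"], 23L)
  expect_identical(rt96$n_harvested[rt96$age_class == "juvenile"], 0L)
  expect_identical(rt96$n_at_risk[rt96$age_class == "adult"], 32L)
  expect_identical(rt96$n_harvested[rt96$age_class == "adult"], 7L)
  # 1995 index-only row carries the lagged productivity index
  expect_equal(tk$removals$poult_hen_ratio[tk$removals$year == 1995], 1.4)
  expect_true(all(is.na(
    tk$removals$spring_npr_juvenile[tk$removals$year == 1995])))
})

test_that("model specification enforces the AA_FE catch-effort requirement", {
  expect_error(model_spec("AA", "FE", catch_effort = FALSE), "catch-effort")
  expect_s3_class(model_spec("AA", "FE", catch_effort = TRUE),
                  "spr_model_spec")
  expect_identical(model_code(model_spec("HT", "RE")), "HT_RE")
  fe <- model_spec("HT", "FE")
  expect_false(fe$re_survival || fe$re_vulnerability)
})
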