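test_that("a minimal well-formed cohort file reads into a one-record table", {
  cf <- tempfile(fileext = ".csv")
  ff <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,treatment,egg_d,larva_d,pupa_d,sex,death_stage,adult_longevity_d",
    "a,0,3,7,6,female,adult,14"), cf)
  writeLines("id,adult_day,eggs", ff)
  co <- read_cohort(cf, ff)
  expect_s3_class(co, "cohort")
  expect_equal(co$n, 1)
  expect_equal(nrow(co$fecundity), 0)
  expect_equal(co$records$egg_d, 3)
  expect_equal(unname(lifespan(co)), 30)
})

test_that("structural invariants are enforced with informative errors", {
  base <- adult_rec("a", "female")
  # preadult death must be unsexed
  bad <- base
  bad$death_stage <- "larva"; bad$pupa_d <- NA; bad$adult_longevity_d <- 0
  expect_error(cohort(bad), "sex must be undetermined for preadult deaths")
  # duplicate ids
  expect_error(cohort(rbind(base, base)), "duplicate id")
  # fecundity for a male
  expect_error(
    cohort(adult_rec("m", "male"),
           data.frame(id = "m", adult_day = 2, eggs = 5)),
    "male or a non-emerger")
  # laying day beyond adult lifespan
  expect_error(
    cohort(base, data.frame(id = "a", adult_day = 15, eggs = 5)),
    "beyond adult longevity")
  # fractional and negative durations
  bad <- base; bad$larva_d <- 6.5
  expect_error(cohort(bad), "whole days")
  # duration recorded for a stage never entered
  bad <- death_rec("d", "egg", egg = 2); bad$larva_d <- 3
  expect_error(cohort(bad), "died before")
  # mixed treatments in one analysis group
  b2 <- adult_rec("b", "male"); b2$treatment <- "30"
  expect_error(cohort(rbind(base, b2)), "one treatment label")
})

test_that("readers reject missing columns, negative values and NA tokens", {
  cf <- tempfile(fileext = ".csv"); ff <- tempfile(fileext = ".csv")
  writeLines(c("id,treatment,egg_d", "a,0,3"), cf)
  writeLines("id,adult_day,eggs", ff)
  expect_error(read_cohort(cf, ff), "missing required column")
  writeLines(c(
    "id,treatment,egg_d,larva_d,pupa_d,sex,death_stage,adult_longevity_d",
    "a,0,3,NA,,undetermined,larva,0"), cf)
  expect_error(read_cohort(cf, ff), "'NA' tokens")
  writeLines(c(
    "id,treatment,egg_d,larva_d,pupa_d,sex,death_stage,adult_longevity_d",
    "a,0,-3,7,6,female,adult,14"), cf)
  expect_error(read_cohort(cf, ff), "negative")
})

test_that("write/read round-trips generated cohorts bit-exactly", {
  for (trt in c("0", "300")) {
    for (seed in c(11, 23)) {
      co <- simulate_cohort(default_params(trt), seed = seed)
      cf <- tempfile(fileext = ".csv"); ff <- tempfile(fileext = ".csv")
      write_cohort(co, cf, ff)
      back <- read_cohort(cf, ff)
      expect_equal(back$records, co$records)
      rownames(back$fecundity) <- rownames(co$fecundity) <- NULL
      expect_equal(back$fecundity, co$fecundity)
      expect_equal(back$n, co$n)
    }
  }
  # a male-only cohort writes a header-only fecundity file
  co <- cohort(rbind(adult_rec("m1", "male"), adult_rec("m2", "male")))
  cf <- tempfile(fileext = ".csv"); ff <- tempfile(fileext = ".csv")
  write_cohort(co, cf, ff)
  expect_equal(readLines(ff), "id,adult_day,eggs")
  # the control fixture keeps its 20 rows and 9 females through a round trip
  co <- control_fixture()
  write_cohort(co, cf, ff)
  back <- read_cohort(cf, ff)
  expect_equal(back$n, 20)
  expect_equal(sum(back$records$sex == "female"), 9)
})

test_that("lifespan follows the daily-census day-counting convention", {
  co <- cohort(adult_rec("a", "female", egg = 3, larva = 7, pupa = 6,
                         longevity = 14))
  expect_equal(unname(lifespan(co)), 30)
  co <- cohort(death_rec("d", "egg", egg = 2))
  expect_equal(unname(lifespan(co)), 2)
  # adult emergence bookkeeping: adults = females + males
  co <- control_fixture()
  rec <- co$records
  expect_equal(sum(rec$death_stage == "adult"),
               sum(rec$sex == "female") + sum(rec$sex == "male"))
})
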