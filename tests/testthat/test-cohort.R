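test_that("read_cohort handles empty, well-formed and unordered input", {
  header <- "patient_id,time_h,hr,rr,spo2,sysbp,temp,outcome,event_time_h"
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(header, f)
  expect_equal(n_patients(read_cohort(f)), 0)

  writeLines(c(header,
               "A,0,80,16,97,120,36.5,normal,",
               "A,6,82,15,96,118,36.4,normal,",
               "A,12,79,17,98,121,36.6,normal,"), f)
  co <- read_cohort(f)
  expect_equal(n_patients(co), 1)
  expect_equal(nrow(co$observations), 3)
  expect_equal(co$observations$time_h, c(0, 6, 12))

  # rows deliberately out of time order: result must match independent sort
  set.seed(11)
  times <- sample(seq(0, 95, by = 5))
  rows <- sprintf("B,%g,%g,16,97,120,36.5,normal,", times, 70 + times)
  writeLines(c(header, rows), f)
  co <- read_cohort(f)
  expect_equal(co$observations$time_h, sort(times))
  expect_equal(co$observations$hr, 70 + sort(times))
})

test_that("read_cohort reports schema errors, bad cells and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,time_h,hr,rr,spo2,temp",
               "A,0,80,16,97,36.5"), f)
  expect_error(read_cohort(f), "sysbp")

  header <- "patient_id,time_h,hr,rr,spo2,sysbp,temp,outcome,event_time_h"
  writeLines(c(header,
               "A,0,oops,16,97,120,36.5,normal,",
               "A,6,81,16,97,120,36.5,normal,"), f)
  co <- read_cohort(f)
  expect_equal(co$filter_report$n_parse_failures, 1)
  expect_equal(nrow(co$observations), 2)  # bad cell kept as NA, not dropped
  expect_true(is.na(co$observations$hr[1]))

  writeLines(c(header,
               "A,6,80,16,97,120,36.5,normal,",
               "A,6,85,17,96,119,36.6,normal,"), f)
  expect_warning(co <- read_cohort(f), "duplicate")
  expect_equal(nrow(co$observations), 2)

  # schema mapping renames non-standard headers
  writeLines(c("id,hours,hr,rr,spo2,sysbp,temp",
               "A,0,80,16,97,120,36.5"), f)
  co <- read_cohort(f, schema = c(patient_id = "id", time_h = "hours"))
  expect_equal(n_patients(co), 1)
})

test_that("write_cohort / read_cohort round-trips the data model", {
  set.seed(21)
  co <- simulate_cohort(small_params(), seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$observations$time_h, co$observations$time_h)
  for (v in vitals) {
    expect_equal(back$observations[[v]], co$observations[[v]],
                 tolerance = 1e-12)
  }
  expect_equal(back$patients$outcome, co$patients$outcome)
  expect_equal(back$patients$length_of_stay_days,
               co$patients$length_of_stay_days)
})

test_that("drop_incomplete removes exactly the observations with gaps", {
  co <- toy_cohort(c(A = 5, B = 6))
  expect_equal(nrow(drop_incomplete(co)$observations),
               nrow(co$observations))
  expect_equal(drop_incomplete(co)$filter_report$n_observations_dropped, 0)

  # 10 observations, 3 lacking HR
  obs <- obs_series("A", days = 3, every = 6)[1:10, ]
  obs$hr[c(2, 5, 9)] <- NA
  co <- new_cohort(obs)
  expect_equal(nrow(drop_incomplete(co)$observations), 7)

  # random missingness mask: survivors = complement of the mask
  set.seed(31)
  co <- simulate_cohort(small_params(missing_rate = 0.15), seed = 4)
  mask <- !stats::complete.cases(co$observations[, vitals])
  kept <- drop_incomplete(co)
  expect_equal(nrow(kept$observations), nrow(co$observations) - sum(mask))
  expect_equal(kept$filter_report$n_observations_dropped, sum(mask))

  # a patient losing every observation disappears from the cohort
  obs <- rbind(obs_row("A", 0, hr = NA), obs_series("B", 4))
  expect_equal(drop_incomplete(new_cohort(obs))$patients$patient_id, "B")
})

test_that("filter_by_stay applies inclusive day bounds", {
  co <- toy_cohort(c(A = 2, B = 4, C = 9, D = 29, E = 30))
  kept <- filter_by_stay(co)
  expect_setequal(kept$patients$patient_id, c("B", "C", "D"))
  expect_equal(kept$filter_report$n_after_stay_filter, 3)
  expect_equal(n_patients(filter_by_stay(toy_cohort(c(A = 3)))), 0)
  expect_equal(n_patients(filter_by_stay(toy_cohort(c(A = 4)))), 1)
})

test_that("split_by_outcome partitions the cohort by label", {
  co <- toy_cohort(c(A = 5, B = 6, C = 7))
  sp <- split_by_outcome(co)
  expect_equal(n_patients(sp$normal), 3)
  expect_equal(n_patients(sp$abnormal), 0)

  set.seed(41)
  stays <- setNames(sample(4:12, 50, TRUE), sprintf("P%02d", 1:50))
  abn <- sample(names(stays), 18)
  sp <- split_by_outcome(toy_cohort(stays, abnormal = abn))
  expect_equal(n_patients(sp$normal), 32)
  expect_equal(n_patients(sp$abnormal), 18)
  expect_setequal(c(sp$normal$patients$patient_id,
                    sp$abnormal$patients$patient_id), names(stays))

  un <- toy_cohort(c(A = 5))
  un$patients$outcome <- NA_character_
  expect_error(split_by_outcome(un), "unlabelled")
})

test_that("completeness and stay filters commute and counts are monotone", {
  set.seed(51)
  for (s in 1:3) {
    co <- simulate_cohort(small_params(missing_rate = 0.2), seed = s)
    a <- filter_by_stay(drop_incomplete(co))
    b <- drop_incomplete(filter_by_stay(co))
    expect_equal(a$patients$patient_id, b$patients$patient_id)
    expect_equal(a$observations, b$observations)
    fr <- a$filter_report
    expect_true(fr$n_after_completeness <= fr$n_input_patients)
    expect_true(fr$n_after_stay_filter <= fr$n_after_completeness)
    expect_equal(fr$n_normal + fr$n_abnormal, n_patients(a))
  }
})

test_that("abnormal stay length is the time to first event", {
  co <- toy_cohort(c(A = 10), abnormal = "A")
  co2 <- new_cohort(co$observations,
                    data.frame(patient_id = "A", outcome = "abnormal",
                               event_time_h = 5 * 24 + 3))
  expect_equal(co2$patients$length_of_stay_days, 6L)
  expect_error(new_cohort(co$observations,
                          data.frame(patient_id = "A", outcome = "abnormal",
                                     event_time_h = NA_real_)),
               "event_time_h")
})
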