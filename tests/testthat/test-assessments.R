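write_resp_csv <- function(rows, path) {
  header <- "facility_id,round,subtool,criterion_id,respondent,value"
  writeLines(c(header, rows), path)
}

test_that("responses are read, decoded and grouped into sessions", {
  inst <- demo_instrument()
  reg <- test_register()
  path <- withr::local_tempfile(fileext = ".csv")

  write_resp_csv(c("F1,2011,1,1.1a,1,1",
                   "F1,2011,1,1.1b,1,0",
                   "F1,2011,1,1.1c,1,99"), path)
  sessions <- read_responses(path, inst, reg)
  expect_length(sessions, 1L)
  s <- sessions[[1]]
  expect_equal(nrow(s$records), 3L)
  expect_equal(sort(s$records$value), c("na", "no", "yes"))

  # two rounds for one facility -> two sessions
  write_resp_csv(c("F1,2011,1,1.1a,1,1",
                   "F1,2012,1,1.1a,1,0"), path)
  expect_length(read_responses(path, inst, reg), 2L)

  # illegal value code names the row
  write_resp_csv(c("F1,2011,1,1.1a,1,1",
                   "F1,2011,1,1.1b,1,2"), path)
  expect_error(read_responses(path, inst, reg), "row 2",
               class = "etiqh_error_value")

  # unknown ids are named
  write_resp_csv("F9,2011,1,1.1a,1,1", path)
  expect_error(read_responses(path, inst, reg), "F9",
               class = "etiqh_error_unknown_id")
  write_resp_csv("F1,2011,1,9.9z,1,1", path)
  expect_error(read_responses(path, inst, reg), "9.9z",
               class = "etiqh_error_unknown_id")

  # empty file
  write_resp_csv(character(), path)
  expect_error(read_responses(path, inst, reg),
               class = "etiqh_error_empty_input")
})

test_that("write/read round-trip preserves the record multiset", {
  inst <- demo_instrument()
  reg <- test_register()
  s1 <- make_session(list("1.1a" = c("yes", "no"),
                          "1.1b" = c("na", "yes"),
                          "1.1c" = c("no", "no")),
                     facility_id = "F1", inst = inst)
  s2 <- complete_session(inst, "health_center", facility_id = "F3")
  path <- withr::local_tempfile(fileext = ".csv")
  sc_path <- withr::local_tempfile(fileext = ".csv")
  back <- read_responses(write_responses(list(s1, s2), path,
                                         scenarios_path = sc_path),
                         inst, reg, scenarios_path = sc_path)
  expect_length(back, 2L)
  key <- function(s) sort(paste(s$records$criterion_id, s$records$respondent,
                                s$records$value))
  orig <- list(s1, s2)
  for (i in 1:2) {
    j <- which(vapply(back, function(b) b$facility_id, "") ==
                 orig[[i]]$facility_id)
    expect_equal(key(back[[j]]), key(orig[[i]]))
  }
  expect_equal(back[[which(names(back) == "F3|2011")]]$scenario_observed,
               sort(etiqh_scenario_tags()))
})

test_that("duplicate answers for one criterion/respondent are rejected", {
  rec <- tibble::tibble(subtool = 1L, criterion_id = c("1.1a", "1.1a"),
                        respondent = 1L, value = c("yes", "no"))
  expect_error(new_session("F1", "2011", rec),
               class = "etiqh_error_duplicate")
})

test_that("validation reproduces the front-end completeness checks", {
  inst <- demo_instrument()

  clean <- complete_session(inst, "dispensary")
  expect_equal(nrow(validate_session(inst, clean, "dispensary")), 0L)

  # drop every sub-tool 5 record: below the dispensary minimum
  no5 <- clean
  no5$records <- no5$records[no5$records$subtool != 5L, ]
  no5 <- new_session("F1", "2011", no5$records, clean$scenario_observed)
  iss <- validate_session(inst, no5, "dispensary")
  expect_true(any(iss$code == "RESPONDENT_COUNT" & iss$subtool == 5L))

  # a respondent skipping one of standard 3.1's seven criteria
  gap <- clean
  gap$records <- gap$records[gap$records$criterion_id != "3.1g", ]
  gap <- new_session("F1", "2011", gap$records, clean$scenario_observed)
  iss <- validate_session(inst, gap, "dispensary")
  miss <- iss[iss$code == "MISSING_ANSWER", ]
  expect_equal(miss$criterion_id, "3.1g")

  # scenario answered but not recorded as observed
  sg <- new_session("F1", "2011", clean$records,
                    setdiff(etiqh_scenario_tags(), "pregnant"))
  iss <- validate_session(inst, sg, "dispensary")
  expect_true(any(iss$code == "SCENARIO_GAP" &
                    grepl("pregnant", iss$message)))
  # the unobserved scenario's criterion is also not expected: no
  # MISSING_ANSWER for it once its records are removed
  rec <- clean$records[clean$records$criterion_id != "3.2b", ]
  ok <- new_session("F1", "2011", rec,
                    setdiff(etiqh_scenario_tags(), "pregnant"))
  expect_equal(nrow(validate_session(inst, ok, "dispensary")), 0L)
})

test_that("validation is idempotent and order-independent", {
  inst <- demo_instrument()
  s <- complete_session(inst, "dispensary")
  s$records <- s$records[s$records$criterion_id != "3.1g", ]
  set.seed(4)
  shuffled <- new_session("F1", "2011",
                          s$records[sample(nrow(s$records)), ],
                          s$scenario_observed)
  original <- new_session("F1", "2011", s$records, s$scenario_observed)
  i1 <- validate_session(inst, original, "dispensary")
  i2 <- validate_session(inst, shuffled, "dispensary")
  expect_equal(i1, i2)
  expect_equal(validate_session(inst, original, "dispensary"), i1)
})
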