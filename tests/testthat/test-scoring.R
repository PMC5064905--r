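test_that("criterion proportion averages non-NA answers", {
  expect_equal(criterion_proportion(c("yes", "yes", "no"))$proportion_met,
               2 / 3)
  expect_equal(criterion_proportion(c("yes", "yes", "no"))$n_responses, 3L)
  expect_false(criterion_proportion(c("na", "na"))$defined)
  p <- criterion_proportion(c("yes", "na", "no", "yes"))
  expect_equal(p$proportion_met, 2 / 3)
  expect_equal(p$n_responses, 3L)
  expect_false(criterion_proportion(character())$defined)
  expect_error(criterion_proportion("maybe"), class = "etiqh_error_value")
})

test_that("worked example on standard 3.1 matches the brute-force oracle", {
  inst <- demo_instrument()
  crit <- criteria_table(inst)
  s31 <- crit[crit$standard_id == "3.1", ]

  # one respondent: yes on 3.1a, 3.1b, 3.1d; no on the rest
  ans <- setNames(as.list(rep("no", 7)), s31$criterion_id)
  ans[c("3.1a", "3.1b", "3.1d")] <- "yes"
  session <- make_session(ans, inst = inst)
  got <- subtool_score(inst, session, 3)
  expect_equal(got$percent,
               oracle_subtool_percent(s31, session$records))
  expect_equal(round(got$percent, 2), 38.46)
  expect_equal(got$points_achievable, 26)
  expect_equal(got$points_achieved, 10)

  # same but 3.1g answered NA: denominator contracts to 22
  ans$`3.1g` <- "na"
  session <- make_session(ans, inst = inst)
  got <- subtool_score(inst, session, 3)
  expect_equal(got$percent,
               oracle_subtool_percent(s31, session$records))
  expect_equal(round(got$percent, 2), 45.45)
  expect_equal(got$points_achievable, 22)
})

test_that("a fully met sub-tool scores 100 and an unanswered one is un-scorable", {
  inst <- demo_instrument()
  s <- complete_session(inst, "dispensary", value = "yes")
  for (i in 1:6)
    expect_equal(subtool_score(inst, s, i)$percent, 100)

  s0 <- complete_session(inst, "dispensary", value = "no")
  for (i in 1:6)
    expect_equal(subtool_score(inst, s0, i)$percent, 0)

  all_na <- make_session(list("1.1a" = "na", "1.1b" = "na"), inst = inst)
  expect_error(subtool_score(inst, all_na, 1),
               class = "etiqh_error_no_defined_criteria")
  expect_error(subtool_score(inst, all_na, 9), "unknown sub-tool")
})

test_that("facility overall score averages exactly the defined dimensions", {
  inst <- demo_instrument()
  s <- complete_session(inst, "dispensary", value = "yes")
  fs <- facility_score(inst, s)
  expect_equal(fs$overall_percent, 100)
  expect_equal(fs$n_dimensions_defined, 6L)

  # five defined dimensions at 60 %, one undefined -> overall 60
  crit <- criteria_table(inst)
  rows <- lapply(inst$subtools[1:5], function(st) {
    ids <- crit$criterion_id[crit$subtool == st$index &
                               is.na(crit$scenario)]
    # each criterion answered by 5 respondents, 3 yes / 2 no -> p = 0.6
    tibble::tibble(subtool = st$index,
                   criterion_id = rep(ids, each = 5),
                   respondent = rep(1:5, times = length(ids)),
                   value = rep(c("yes", "yes", "yes", "no", "no"),
                               times = length(ids)))
  })
  s5 <- new_session("F1", "2011", dplyr::bind_rows(rows))
  fs <- facility_score(inst, s5)
  expect_equal(fs$overall_percent, 60)
  expect_equal(fs$n_dimensions_defined, 5L)
  expect_true(is.na(fs$dimensions$percent[6]))

  # overall is always the mean of the defined dimension percents
  set.seed(21)
  for (rep in 1:10) {
    ans <- random_answers(3, 2)
    names(ans) <- c("1.1a", "1.1b", "1.1c")
    ans2 <- random_answers(2, 3, p_na = 0.3)
    names(ans2) <- c("2.1a", "2.1b")
    fs <- facility_score(inst, make_session(c(ans, ans2), inst = inst))
    def <- fs$dimensions$percent[!is.na(fs$dimensions$percent)]
    if (length(def))
      expect_equal(fs$overall_percent, mean(def))
    expect_equal(fs$n_dimensions_defined, length(def))
  }
})

test_that("scenario scores restrict the formula to the tagged criteria", {
  inst <- demo_instrument()
  s <- complete_session(inst, "dispensary", value = "yes")
  expect_equal(scenario_score(inst, s, "under5_imci")$percent, 100)

  expect_error(scenario_score(inst, s, "cholera"),
               class = "etiqh_error_value")
  s_no_tb <- new_session("F1", "2011",
                         s$records[s$records$criterion_id != "3.2d", ],
                         setdiff(etiqh_scenario_tags(), "tb_hiv"))
  expect_error(scenario_score(inst, s_no_tb, "tb_hiv"),
               class = "etiqh_error_scenario_not_observed")

  # mixed answers equal the oracle on the tagged subset
  crit <- criteria_table(inst)
  tagged <- crit[!is.na(crit$scenario), ]
  set.seed(9)
  for (rep in 1:20) {
    vals <- sample(c("yes", "no", "na"), nrow(tagged), replace = TRUE)
    ans <- setNames(as.list(vals), tagged$criterion_id)
    sess <- make_session(ans, scenario_observed = etiqh_scenario_tags(),
                         inst = inst)
    for (sc in etiqh_scenario_tags()) {
      sub <- tagged[tagged$scenario == sc, ]
      want <- oracle_subtool_percent(sub, sess$records)
      if (is.na(want)) {
        expect_error(scenario_score(inst, sess, sc),
                     class = "etiqh_error_no_defined_criteria")
      } else {
        expect_equal(scenario_score(inst, sess, sc)$percent, want)
      }
    }
  }
})

test_that("unobserved scenarios are excluded from the achievable points", {
  inst <- demo_instrument()
  # all of 3.1 answered yes; scenarios not observed at all
  crit <- criteria_table(inst)
  s31 <- crit$criterion_id[crit$standard_id == "3.1"]
  sess <- make_session(setNames(as.list(rep("yes", 7)), s31), inst = inst)
  got <- subtool_score(inst, sess, 3)
  expect_equal(got$points_achievable, 26)
  expect_equal(got$percent, 100)
})

test_that("the 75 % threshold is a strict lower bound", {
  expect_equal(classify_score(74.9), "unsatisfactory")
  expect_equal(classify_score(75.0), "satisfactory")
  expect_equal(classify_score(93.7), "satisfactory")
  expect_equal(classify_score(c(10, 80), threshold = 50),
               c("unsatisfactory", "satisfactory"))
})

test_that("score_sessions emits one tidy row per dimension plus overall", {
  inst <- demo_instrument()
  sessions <- list(complete_session(inst, "dispensary", facility_id = "F1"),
                   complete_session(inst, "dispensary", value = "no",
                                    facility_id = "F2"))
  tab <- score_sessions(inst, sessions)
  expect_equal(nrow(tab), 2L * 7L)
  expect_equal(sum(tab$level == "overall"), 2L)
  expect_equal(tab$percent[tab$facility_id == "F1" & tab$level == "overall"],
               100)
  expect_equal(tab$percent[tab$facility_id == "F2" & tab$level == "overall"],
               0)
})
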