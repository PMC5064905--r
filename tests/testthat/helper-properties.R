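# Randomised property checks over the scoring engine. Each returns the
# number of failing cases (0 = property holds on every generated case), so
# the same code can run at different case counts in the unit and
# acceptance suites.

random_case <- function(max_crit = 5, max_resp = 3, weights = 1:5) {
  n_crit <- sample(2:max_crit, 1)
  n_resp <- sample(1:max_resp, 1)
  w <- sample(weights, n_crit, replace = TRUE)
  inst <- mini_instrument(w)
  ans <- random_answers(n_crit, n_resp)
  list(inst = inst, w = w, session = make_session(ans, inst = inst),
       n_resp = n_resp)
}

case_percent <- function(case) {
  tryCatch(subtool_score(case$inst, case$session, 1)$percent,
           etiqh_error_no_defined_criteria = function(e) NA_real_)
}

prop_check_monotonicity <- function(n_cases, seed) {
  set.seed(seed)
  fails <- 0L
  for (i in seq_len(n_cases)) {
    case <- random_case()
    before <- case_percent(case)
    rec <- case$session$records
    no_rows <- which(rec$value == "no")
    if (length(no_rows)) {
      rec2 <- rec
      rec2$value[sample(no_rows, 1)] <- "yes"
      case2 <- case
      case2$session <- new_session("F1", "2011", rec2)
      after <- case_percent(case2)
      if (!is.na(before) && after < before - 1e-9) fails <- fails + 1L
    }
    yes_rows <- which(rec$value == "yes")
    if (length(yes_rows)) {
      rec3 <- rec
      rec3$value[sample(yes_rows, 1)] <- "no"
      case3 <- case
      case3$session <- new_session("F1", "2011", rec3)
      after <- case_percent(case3)
      if (!is.na(before) && after > before + 1e-9) fails <- fails + 1L
    }
  }
  fails
}

prop_check_weight_scale <- function(n_cases, seed) {
  set.seed(seed)
  fails <- 0L
  for (i in seq_len(n_cases)) {
    # weights in {1, 2} so the doubled instrument stays within 1..5
    case <- random_case(weights = 1:2)
    scaled <- mini_instrument(2L * case$w)
    p1 <- case_percent(case)
    p2 <- tryCatch(subtool_score(scaled, case$session, 1)$percent,
                   etiqh_error_no_defined_criteria = function(e) NA_real_)
    same <- (is.na(p1) && is.na(p2)) ||
      (!is.na(p1) && !is.na(p2) && abs(p1 - p2) < 1e-9)
    if (!same) fails <- fails + 1L
  }
  fails
}

prop_check_permutation <- function(n_cases, seed) {
  set.seed(seed)
  fails <- 0L
  for (i in seq_len(n_cases)) {
    case <- random_case()
    p1 <- case_percent(case)
    rec <- case$session$records
    perm <- sample(case$n_resp)
    rec$respondent <- perm[rec$respondent]
    rec <- rec[sample(nrow(rec)), ]
    p2 <- tryCatch(
      subtool_score(case$inst, new_session("F1", "2011", rec), 1)$percent,
      etiqh_error_no_defined_criteria = function(e) NA_real_)
    same <- (is.na(p1) && is.na(p2)) ||
      (!is.na(p1) && !is.na(p2) && abs(p1 - p2) < 1e-9)
    if (!same) fails <- fails + 1L
  }
  fails
}

prop_check_na_contraction <- function(n_cases, seed) {
  set.seed(seed)
  fails <- 0L
  for (i in seq_len(n_cases)) {
    case <- random_case()
    sc <- tryCatch(subtool_score(case$inst, case$session, 1),
                   etiqh_error_no_defined_criteria = function(e) NULL)
    if (is.null(sc)) next
    cs <- criterion_scores(case$inst, case$session, 1)
    def <- cs[cs$defined, ]
    pick <- def[sample(nrow(def), 1), ]
    rec <- case$session$records
    rec$value[rec$criterion_id == pick$criterion_id] <- "na"
    sc2 <- tryCatch(
      subtool_score(case$inst, new_session("F1", "2011", rec), 1),
      etiqh_error_no_defined_criteria = function(e) NULL)
    if (is.null(sc2)) {
      # the picked criterion was the only defined one
      if (nrow(def) != 1L) fails <- fails + 1L
      next
    }
    ok <- abs(sc2$points_achievable - (sc$points_achievable - pick$weight)) <
      1e-9
    crit <- criteria_table(case$inst)
    crit <- crit[crit$subtool == 1, ]
    ok <- ok && abs(sc2$percent - oracle_subtool_percent(crit, rec)) < 1e-9
    if (!ok) fails <- fails + 1L
  }
  fails
}

prop_check_oracle_equivalence <- function(n_cases, seed) {
  set.seed(seed)
  fails <- 0L
  for (i in seq_len(n_cases)) {
    case <- random_case(max_crit = 4, max_resp = 3)
    crit <- criteria_table(case$inst)
    crit <- crit[crit$subtool == 1, ]
    want <- oracle_subtool_percent(crit, case$session$records)
    got <- case_percent(case)
    same <- (is.na(want) && is.na(got)) ||
      (!is.na(want) && !is.na(got) && abs(want - got) < 1e-9)
    if (!same) fails <- fails + 1L
  }
  fails
}

# Exhaustive oracle comparison: every yes/no/na assignment for a fixed
# criterion/respondent grid.
exhaustive_oracle_check <- function(weights, n_resp) {
  inst <- mini_instrument(weights)
  crit <- criteria_table(inst)
  crit <- crit[crit$subtool == 1, ]
  n_cells <- length(weights) * n_resp
  vals <- c("yes", "no", "na")
  fails <- 0L
  for (code in seq_len(3^n_cells) - 1L) {
    digits <- (code %/% 3^(seq_len(n_cells) - 1L)) %% 3L
    v <- vals[digits + 1L]
    rec <- tibble::tibble(
      subtool = 1L,
      criterion_id = rep(paste0("c", seq_along(weights)), each = n_resp),
      respondent = rep(seq_len(n_resp), times = length(weights)),
      value = v)
    want <- oracle_subtool_percent(crit, rec)
    got <- tryCatch(
      subtool_score(inst, new_session("F1", "2011", rec), 1)$percent,
      etiqh_error_no_defined_criteria = function(e) NA_real_)
    same <- (is.na(want) && is.na(got)) ||
      (!is.na(want) && !is.na(got) && abs(want - got) < 1e-9)
    if (!same) fails <- fails + 1L
  }
  fails
}
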