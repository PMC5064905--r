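# Builders for sessions and small instruments used across test files.

# Session from a named list: criterion id -> vector of answers, one per
# respondent.
make_session <- function(answers, facility_id = "F1", round = "2011",
                         scenario_observed = character(),
                         inst = demo_instrument()) {
  crit <- criteria_table(inst)
  rows <- lapply(names(answers), function(cid) {
    vals <- answers[[cid]]
    tibble::tibble(subtool = crit$subtool[crit$criterion_id == cid],
                   criterion_id = cid, respondent = seq_along(vals),
                   value = vals)
  })
  new_session(facility_id, round, dplyr::bind_rows(rows), scenario_observed)
}

# A session answering every applicable criterion with `value`, using the
# minimum respondent count per sub-tool for the facility type.
complete_session <- function(inst, facility_type = "dispensary",
                             value = "yes", facility_id = "F1",
                             round = "2011",
                             scenario_observed = etiqh_scenario_tags()) {
  crit <- criteria_table(inst)
  rows <- lapply(inst$subtools, function(st) {
    n_resp <- st$respondent_rule[[facility_type]][1]
    sc <- crit[crit$subtool == st$index, ]
    sc <- sc[is.na(sc$scenario) | sc$scenario %in% scenario_observed, ]
    if (nrow(sc) == 0) return(NULL)
    tibble::tibble(subtool = st$index,
                   criterion_id = rep(sc$criterion_id, times = n_resp),
                   respondent = rep(seq_len(n_resp), each = nrow(sc)),
                   value = value)
  })
  new_session(facility_id, round, dplyr::bind_rows(rows), scenario_observed)
}

etiqh_scenario_tags <- function() {
  c("under5_imci", "pregnant", "fever_over5", "tb_hiv")
}

# Six-sub-tool instrument whose sub-tool 1 carries the given weights
# (criteria c1, c2, ...); the other sub-tools are minimal placeholders.
mini_instrument <- function(weights) {
  filler <- function(i) {
    new_subtool(i, sprintf("dim%d", i), "checklist",
                list(new_standard(sprintf("%d.1", i), "q",
                                  data.frame(id = sprintf("f%d", i),
                                             text = "x", weight = 1L))))
  }
  st1 <- new_subtool(1L, "dim1", "checklist",
                     list(new_standard("1.1", "q",
                       data.frame(id = paste0("c", seq_along(weights)),
                                  text = "x",
                                  weight = as.integer(weights)))))
  new_instrument("mini", "1", c(list(st1), lapply(2:6, filler)))
}

# Random answers for the criteria of mini_instrument sub-tool 1.
random_answers <- function(n_crit, n_resp, p_na = 0.15, p_yes = 0.55) {
  ans <- lapply(seq_len(n_crit), function(i) {
    r <- runif(n_resp)
    ifelse(r < p_na, "na", ifelse(r < p_na + (1 - p_na) * p_yes,
                                  "yes", "no"))
  })
  names(ans) <- paste0("c", seq_len(n_crit))
  ans
}

# A small register for aggregation tests.
test_register <- function() {
  tibble::tibble(
    id = c("F1", "F2", "F3", "F4"),
    name = paste("Facility", 1:4),
    type = c("dispensary", "dispensary", "health_center", "hospital_opd"),
    ownership = c("public", "public", "faith_based", "faith_based"),
    council = c("A", "A", "A", "B"),
    region = c("R1", "R1", "R1", "R1"))
}

# A scores table (as from score_sessions) with given overall and dimension
# percents; dims is a list facility_id -> numeric(6).
scores_table <- function(dims, round = "2011") {
  rows <- lapply(names(dims), function(fid) {
    d <- dims[[fid]]
    dplyr::bind_rows(
      tibble::tibble(facility_id = fid, round = round, level = "dimension",
                     subtool = 1:6, percent = d,
                     points_achieved = NA_real_,
                     points_achievable = NA_real_,
                     n_criteria_defined = NA_integer_,
                     n_dimensions_defined = sum(!is.na(d))),
      tibble::tibble(facility_id = fid, round = round, level = "overall",
                     subtool = NA_integer_,
                     percent = mean(d, na.rm = TRUE),
                     points_achieved = NA_real_,
                     points_achievable = NA_real_,
                     n_criteria_defined = NA_integer_,
                     n_dimensions_defined = sum(!is.na(d))))
  })
  dplyr::bind_rows(rows)
}
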