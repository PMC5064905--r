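# The two-step weighted score calculation. Step 1: for each verification
# criterion, the proportion of non-NA answers that were "yes" (averaged over
# respondents/observations). Step 2: the weighted mean of those proportions,
# weights being the criterion importances 1-5, expressed as a percentage of
# the achievable points. NA answers are excluded from both the achieved and
# the achievable points, so a criterion answered NA by everyone shrinks the
# denominator rather than dragging the score down.

#' Proportion of respondents meeting one criterion
#'
#' @param values Character vector of answers (`"yes"`, `"no"`, `"na"`).
#' @return A one-row tibble: `n_responses` (non-NA answers),
#'   `proportion_met` (`NA` when undefined) and `defined` (`FALSE` when all
#'   answers were NA or there were none).
#' @examples
#' criterion_proportion(c("yes", "yes", "no"))   # 2/3
#' criterion_proportion(c("na", "na"))           # undefined
#' @export
criterion_proportion <- function(values) {
  bad <- setdiff(values, c("yes", "no", "na"))
  if (length(bad))
    etiqh_abort(sprintf("illegal response value '%s'", bad[1]),
                "etiqh_error_value")
  n_yes <- sum(values == "yes")
  n <- n_yes + sum(values == "no")
  tibble(n_responses = n,
         proportion_met = if (n > 0L) n_yes / n else NA_real_,
         defined = n > 0L)
}

# Internal workhorse: criterion-level scores for a set of records joined to
# the instrument's criteria table. Criteria of scenarios not observed are
# excluded before this point.
criterion_scores_impl <- function(records, crit) {
  counts <- dplyr::summarise(
    dplyr::group_by(records, .data$criterion_id),
    n_yes = sum(.data$value == "yes"),
    n_responses = sum(.data$value != "na"),
    .groups = "drop")
  out <- dplyr::left_join(crit[, c("subtool", "criterion_id", "weight",
                                   "scenario")],
                          counts, by = "criterion_id")
  out$n_yes[is.na(out$n_yes)] <- 0L
  out$n_responses[is.na(out$n_responses)] <- 0L
  out$defined <- out$n_responses > 0L
  out$proportion_met <- ifelse(out$defined, out$n_yes / out$n_responses,
                               NA_real_)
  out
}

# Criteria applicable in a session: everything untagged plus the criteria of
# observed scenarios.
applicable_criteria <- function(inst, session, subtool_index = NULL,
                                crit = criteria_table(inst)) {
  if (!is.null(subtool_index)) crit <- crit[crit$subtool == subtool_index, ]
  crit[is.na(crit$scenario) |
         crit$scenario %in% session$scenario_observed, ]
}

#' Criterion-level scores for one session
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param subtool_index Optional sub-tool restriction.
#' @param crit Precomputed [criteria_table()] (an optimisation for batch
#'   callers; defaults to computing it).
#' @return Tibble with one row per applicable criterion: `subtool`,
#'   `criterion_id`, `weight`, `scenario`, `n_yes`, `n_responses`,
#'   `defined`, `proportion_met`.
#' @export
criterion_scores <- function(inst, session, subtool_index = NULL,
                             crit = criteria_table(inst)) {
  crit <- applicable_criteria(inst, session, subtool_index, crit = crit)
  rec <- session$records[session$records$criterion_id %in%
                           crit$criterion_id, ]
  criterion_scores_impl(rec, crit)
}

weighted_percent <- function(cs) {
  def <- cs[cs$defined, ]
  if (nrow(def) == 0L) return(NULL)
  achievable <- sum(def$weight)
  achieved <- sum(def$weight * def$proportion_met)
  list(points_achieved = achieved, points_achievable = achievable,
       percent = 100 * achieved / achievable,
       n_criteria_defined = nrow(def))
}

#' Weighted percentage score of one sub-tool
#'
#' Computes `100 * sum(w_c * p_c) / sum(w_c)` over the sub-tool's defined
#' criteria, where `p_c` is the proportion of non-NA answers that were yes
#' and `w_c` the criterion weight. Criteria that are all-NA, never answered,
#' or tied to an unobserved clinical scenario are excluded from both the
#' numerator and the denominator.
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param subtool_index Integer 1-6.
#' @param crit Precomputed [criteria_table()] (optimisation for batch
#'   callers).
#' @return A one-row tibble: `subtool`, `points_achieved`,
#'   `points_achievable`, `percent`, `n_criteria_defined`.
#' @section Errors: signals a condition of class
#'   `etiqh_error_no_defined_criteria` when no criterion of the sub-tool has
#'   a defined proportion (the sub-tool is un-scorable).
#' @export
subtool_score <- function(inst, session, subtool_index,
                          crit = criteria_table(inst)) {
  if (!subtool_index %in% 1:6)
    etiqh_abort(sprintf("unknown sub-tool index %s", subtool_index),
                "etiqh_error_structure")
  cs <- criterion_scores(inst, session, subtool_index, crit = crit)
  wp <- weighted_percent(cs)
  if (is.null(wp))
    etiqh_abort(sprintf(
      "facility %s round %s: sub-tool %d has no defined criteria",
      session$facility_id, session$round, subtool_index),
      "etiqh_error_no_defined_criteria")
  tibble(subtool = as.integer(subtool_index),
         points_achieved = wp$points_achieved,
         points_achievable = wp$points_achievable,
         percent = wp$percent,
         n_criteria_defined = wp$n_criteria_defined)
}

#' Facility score across the six quality dimensions
#'
#' The overall quality of a facility in one round is the unweighted
#' arithmetic mean of its defined sub-tool percentages. A sub-tool with no
#' defined criteria is reported as an undefined dimension (`NA` percent)
#' and excluded from the mean; `n_dimensions_defined` records how many
#' dimensions entered it.
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param crit Precomputed [criteria_table()] (optimisation for batch
#'   callers).
#' @return An object of class `etiqh_facility_score`: a list with
#'   `facility_id`, `round`, `dimensions` (six-row tibble as in
#'   [subtool_score()], `NA` rows for undefined dimensions),
#'   `overall_percent` and `n_dimensions_defined`.
#' @export
facility_score <- function(inst, session, crit = criteria_table(inst)) {
  dims <- lapply(1:6, function(i) {
    tryCatch(subtool_score(inst, session, i, crit = crit),
             etiqh_error_no_defined_criteria = function(e)
               tibble(subtool = i, points_achieved = NA_real_,
                      points_achievable = NA_real_, percent = NA_real_,
                      n_criteria_defined = 0L))
  })
  dims <- dplyr::bind_rows(dims)
  defined <- !is.na(dims$percent)
  structure(
    list(facility_id = session$facility_id, round = session$round,
         dimensions = dims,
         overall_percent = if (any(defined)) mean(dims$percent[defined])
                           else NA_real_,
         n_dimensions_defined = sum(defined)),
    class = "etiqh_facility_score")
}

#' @export
print.etiqh_facility_score <- function(x, decimals = 1, ...) {
  cat(sprintf("<etiqh_facility_score> facility %s, round %s\n",
              x$facility_id, x$round))
  d <- x$dimensions
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  sub-tool %d: %s\n", d$subtool[i],
                if (is.na(d$percent[i])) "undefined"
                else sprintf("%.*f %%", decimals, d$percent[i])))
  }
  cat(sprintf("  overall: %.*f %% over %d defined dimension(s)\n", decimals,
              x$overall_percent, x$n_dimensions_defined))
  invisible(x)
}

#' Disease-specific scenario score
#'
#' The same weighted formula restricted to the criteria carrying one of the
#' four clinical-observation scenario tags of sub-tool 3 (under-5 IMCI,
#' pregnant women, fever over 5, TB/HIV).
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param scenario One of `"under5_imci"`, `"pregnant"`, `"fever_over5"`,
#'   `"tb_hiv"`; must be among the session's observed scenarios.
#' @return One-row tibble: `scenario`, `points_achieved`,
#'   `points_achievable`, `percent`, `n_criteria_defined`.
#' @export
scenario_score <- function(inst, session, scenario) {
  if (!scenario %in% etiqh_scenarios)
    etiqh_abort(sprintf("unknown scenario '%s'", scenario),
                "etiqh_error_value")
  if (!scenario %in% session$scenario_observed)
    etiqh_abort(sprintf(
      "facility %s round %s: scenario '%s' was not observed",
      session$facility_id, session$round, scenario),
      "etiqh_error_scenario_not_observed")
  cs <- criterion_scores(inst, session)
  cs <- cs[!is.na(cs$scenario) & cs$scenario == scenario, ]
  wp <- weighted_percent(cs)
  if (is.null(wp))
    etiqh_abort(sprintf("scenario '%s' has no defined criteria", scenario),
                "etiqh_error_no_defined_criteria")
  tibble(scenario = scenario, points_achieved = wp$points_achieved,
         points_achievable = wp$points_achievable, percent = wp$percent,
         n_criteria_defined = wp$n_criteria_defined)
}

#' Classify a score against the satisfactory threshold
#'
#' A score strictly below the threshold (default 75 %) is unsatisfactory;
#' at or above it, satisfactory.
#'
#' @param percent Numeric vector of percentages in `[0, 100]`.
#' @param threshold Threshold percentage, default 75.
#' @return Character vector, `"satisfactory"` or `"unsatisfactory"`.
#' @examples
#' classify_score(c(74.9, 75, 93.7))
#' @export
classify_score <- function(percent, threshold = 75) {
  stopifnot(all(percent >= 0 & percent <= 100, na.rm = TRUE))
  ifelse(percent < threshold, "unsatisfactory", "satisfactory")
}

#' Score a batch of sessions
#'
#' Applies [facility_score()] to every session and returns one tidy table,
#' with a row per facility, round and dimension plus an `overall` row per
#' facility and round (subtool `NA`, `level = "overall"`). Percentages are
#' kept at full precision; round only for presentation.
#'
#' @param inst Instrument.
#' @param sessions List of `etiqh_session` objects.
#' @return Tibble: `facility_id`, `round`, `level` (`"dimension"` or
#'   `"overall"`), `subtool`, `percent`, `points_achieved`,
#'   `points_achievable`, `n_criteria_defined`, `n_dimensions_defined`.
#' @export
score_sessions <- function(inst, sessions) {
  crit <- criteria_table(inst)
  rows <- lapply(sessions, function(s) {
    fs <- facility_score(inst, s, crit = crit)
    d <- fs$dimensions
    dplyr::bind_rows(
      tibble(facility_id = fs$facility_id, round = fs$round,
             level = "dimension", subtool = d$subtool, percent = d$percent,
             points_achieved = d$points_achieved,
             points_achievable = d$points_achievable,
             n_criteria_defined = d$n_criteria_defined,
             n_dimensions_defined = fs$n_dimensions_defined),
      tibble(facility_id = fs$facility_id, round = fs$round,
             level = "overall", subtool = NA_integer_,
             percent = fs$overall_percent, points_achieved = NA_real_,
             points_achievable = NA_real_, n_criteria_defined = NA_integer_,
             n_dimensions_defined = fs$n_dimensions_defined))
  })
  dplyr::bind_rows(rows)
}

#' Write a score table
#'
#' @param scores Tibble from [score_sessions()] or [aggregate_scores()].
#' @param path Output CSV path.
#' @param decimals Decimals for the percent columns (default 1, matching
#'   the reporting convention; pass `NA` to keep full precision).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, decimals = 1) {
  out <- scores
  if (!is.na(decimals)) {
    num <- intersect(c("percent", "points_achieved", "points_achievable",
                       "mean_percent"), names(out))
    for (cn in num) out[[cn]] <- round(out[[cn]], decimals)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
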