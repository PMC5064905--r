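# Standardized aggregation: mean scores by facility, council, region or
# ownership category, per-criterion met/not-met disaggregation, historical
# trend tables, and the per-facility summary sheet of strengths and
# weaknesses compiled after each visit.

join_register <- function(scores, register) {
  miss <- setdiff(unique(scores$facility_id), register$id)
  if (length(miss))
    etiqh_abort(sprintf("facility %s not in register", miss[1]),
                "etiqh_error_unknown_id")
  dplyr::left_join(scores,
                   register[, c("id", "type", "ownership", "council",
                                "region")],
                   by = c(facility_id = "id"))
}

#' Aggregate facility scores
#'
#' Unweighted arithmetic means of facility scores within a stratum: by
#' facility (identity), council or region, optionally stratified by
#' ownership category. Each dimension's mean is taken over the facilities
#' for which that dimension is defined; a facility with an undefined
#' dimension is excluded from that dimension's mean only.
#'
#' @param scores Score table from [score_sessions()].
#' @param register Facility register.
#' @param level `"facility"`, `"council"` or `"region"`.
#' @param stratifier `"none"` or `"ownership"`.
#' @param rounds Optional subset of rounds to keep.
#' @return Tibble: `stratum`, (optional `ownership`), `round`, `level`,
#'   `subtool` (`NA` for overall rows), `mean_percent`, `n_facilities`.
#' @export
aggregate_scores <- function(scores, register,
                             level = c("council", "region", "facility"),
                             stratifier = c("none", "ownership"),
                             rounds = NULL) {
  level <- match.arg(level)
  stratifier <- match.arg(stratifier)
  if (!is.null(rounds)) scores <- scores[scores$round %in% rounds, ]
  if (nrow(scores) == 0L)
    etiqh_abort("no scores in the requested stratum",
                "etiqh_error_empty_stratum")
  j <- join_register(scores, register)
  j$stratum <- switch(level, facility = j$facility_id, council = j$council,
                      region = j$region)
  keys <- c("stratum", if (stratifier == "ownership") "ownership",
            "round", "level", "subtool")
  out <- dplyr::summarise(
    dplyr::group_by(j, dplyr::across(dplyr::all_of(keys))),
    mean_percent = mean(.data$percent, na.rm = TRUE),
    n_facilities = sum(!is.na(.data$percent)),
    .groups = "drop")
  out$mean_percent[is.nan(out$mean_percent)] <- NA_real_
  out[order(out$stratum, out$round, out$level, out$subtool), ]
}

#' Historical trend table
#'
#' Mean scores by round for a facility, council or region, one row per
#' round and dimension (plus overall rows), rounds in the supplied order.
#'
#' @param scores Score table from [score_sessions()].
#' @param register Facility register.
#' @param level Aggregation level as in [aggregate_scores()].
#' @param round_order Optional character vector fixing the round ordering;
#'   defaults to sorted unique rounds.
#' @return Tibble as from [aggregate_scores()], ordered by round.
#' @export
historical_trend_table <- function(scores, register, level = "council",
                                   round_order = NULL) {
  agg <- aggregate_scores(scores, register, level = level)
  round_order <- round_order %||% sort(unique(agg$round))
  agg$round <- factor(agg$round, levels = round_order)
  out <- agg[order(agg$stratum, agg$round, agg$subtool), ]
  out$round <- as.character(out$round)
  out
}

#' Per-criterion met/not-met report
#'
#' Disaggregates scores down to single verification criteria across a set
#' of sessions: for each criterion, the proportion of facilities that fully
#' met it (all non-NA answers "yes"), flagged `met` (green) or `not_met`
#' (red) depending on whether that proportion reaches the cutoff.
#' Facilities where the criterion is undefined are excluded from its
#' denominator.
#'
#' @param inst Instrument.
#' @param sessions List of sessions (typically one round).
#' @param cutoff Proportion of facilities above which the criterion is
#'   flagged `met`; default 0.75, mirroring the satisfactory threshold.
#' @return Tibble: `subtool`, `criterion_id`, `n_facilities`,
#'   `prop_facilities_met`, `flag`.
#' @export
criterion_report <- function(inst, sessions, cutoff = 0.75) {
  per <- lapply(sessions, function(s) {
    cs <- criterion_scores(inst, s)
    cs <- cs[cs$defined, ]
    tibble(subtool = cs$subtool, criterion_id = cs$criterion_id,
           met = cs$proportion_met == 1)
  })
  all <- dplyr::bind_rows(per)
  if (nrow(all) == 0L)
    etiqh_abort("no defined criteria across sessions",
                "etiqh_error_empty_stratum")
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$subtool, .data$criterion_id),
    n_facilities = dplyr::n(),
    prop_facilities_met = mean(.data$met),
    .groups = "drop")
  out$flag <- ifelse(out$prop_facilities_met >= cutoff, "met", "not_met")
  out[order(out$subtool, out$criterion_id), ]
}

#' Post-assessment summary sheet
#'
#' The sheet compiled at the end of a visit: the six dimension scores plus
#' the facility's main strengths and weaknesses. Criteria are ranked by
#' weighted shortfall `w_c * (1 - p_c)` (weaknesses, largest first) and by
#' weighted attainment `w_c * p_c` (strengths); ties break by criterion id.
#' Fully met criteria never appear as weaknesses, fully missed ones never
#' as strengths.
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param k Number of strengths and weaknesses to list (default 5).
#' @return Object of class `etiqh_summary_sheet` with fields `facility_id`,
#'   `round`, `dimensions`, `overall_percent`, `strengths`, `weaknesses`.
#' @export
summary_sheet <- function(inst, session, k = 5) {
  fs <- facility_score(inst, session)
  cs <- criterion_scores(inst, session)
  cs <- cs[cs$defined, ]
  cs$attainment <- cs$weight * cs$proportion_met
  cs$shortfall <- cs$weight * (1 - cs$proportion_met)
  strengths <- cs[cs$attainment > 0, ]
  strengths <- strengths[order(-strengths$attainment,
                               strengths$criterion_id), ]
  weaknesses <- cs[cs$shortfall > 0, ]
  weaknesses <- weaknesses[order(-weaknesses$shortfall,
                                 weaknesses$criterion_id), ]
  cols <- c("subtool", "criterion_id", "weight", "proportion_met",
            "attainment", "shortfall")
  structure(
    list(facility_id = fs$facility_id, round = fs$round,
         dimensions = fs$dimensions, overall_percent = fs$overall_percent,
         strengths = head(strengths[, cols], k),
         weaknesses = head(weaknesses[, cols], k)),
    class = "etiqh_summary_sheet")
}

#' @export
print.etiqh_summary_sheet <- function(x, decimals = 1, ...) {
  cat(sprintf("Summary sheet — facility %s, round %s\n", x$facility_id,
              x$round))
  d <- x$dimensions
  for (i in seq_len(nrow(d)))
    cat(sprintf("  sub-tool %d: %s\n", d$subtool[i],
                if (is.na(d$percent[i])) "not assessed"
                else sprintf("%.*f %%", decimals, d$percent[i])))
  cat(sprintf("  overall: %.*f %%\n", decimals, x$overall_percent))
  cat("Strengths:\n")
  if (nrow(x$strengths) == 0L) cat("  (none)\n")
  for (i in seq_len(nrow(x$strengths)))
    cat(sprintf("  %s (weight %d, met %.0f %%)\n",
                x$strengths$criterion_id[i], x$strengths$weight[i],
                100 * x$strengths$proportion_met[i]))
  cat("Weaknesses:\n")
  if (nrow(x$weaknesses) == 0L) cat("  (none)\n")
  for (i in seq_len(nrow(x$weaknesses)))
    cat(sprintf("  %s (weight %d, met %.0f %%)\n",
                x$weaknesses$criterion_id[i], x$weaknesses$weight[i],
                100 * x$weaknesses$proportion_met[i]))
  invisible(x)
}
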