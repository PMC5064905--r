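# Assessment sessions: the raw yes/no/NA responses of one facility visit,
# their file format, and the completeness/consistency checks the original
# hand-held front end enforced at data entry.

#' Construct an assessment session
#'
#' One session is one facility visited in one assessment round: all its
#' response records plus the set of clinical scenarios actually observed
#' (relevant to sub-tool 3 only; criteria of unobserved scenarios do not
#' count towards the achievable points).
#'
#' @param facility_id Facility id.
#' @param round Round label (opaque, e.g. a calendar year).
#' @param records Tibble with columns `subtool`, `criterion_id`,
#'   `respondent`, `value` (`"yes"`, `"no"` or `"na"`).
#' @param scenario_observed Character vector of observed scenario tags.
#' @return An object of class `etiqh_session`.
#' @export
new_session <- function(facility_id, round, records,
                        scenario_observed = character()) {
  records <- as_tibble(records)
  records$subtool <- as.integer(records$subtool)
  records$respondent <- as.integer(records$respondent)
  bad <- !records$value %in% c("yes", "no", "na")
  if (any(bad))
    etiqh_abort(sprintf("illegal response value '%s' (criterion %s)",
                        records$value[bad][1],
                        records$criterion_id[bad][1]),
                "etiqh_error_value")
  key <- paste(records$criterion_id, records$respondent)
  dup <- key[duplicated(key)]
  if (length(dup))
    etiqh_abort(sprintf(
      "facility %s round %s: duplicate answer for criterion/respondent %s",
      facility_id, round, dup[1]), "etiqh_error_duplicate")
  bad_sc <- setdiff(scenario_observed, etiqh_scenarios)
  if (length(bad_sc))
    etiqh_abort(sprintf("unknown scenario tag '%s'", bad_sc[1]),
                "etiqh_error_value")
  structure(list(facility_id = facility_id, round = as.character(round),
                 records = records,
                 scenario_observed = sort(unique(scenario_observed))),
            class = "etiqh_session")
}

#' @export
print.etiqh_session <- function(x, ...) {
  cat(sprintf("<etiqh_session> facility %s, round %s: %d records, %d respondents max\n",
              x$facility_id, x$round, nrow(x$records),
              if (nrow(x$records)) max(x$records$respondent) else 0L))
  if (length(x$scenario_observed))
    cat("  scenarios observed:", paste(x$scenario_observed, collapse = ", "),
        "\n")
  invisible(x)
}

# Combine a long response table (internal values) into a list of sessions.
split_into_sessions <- function(records, scenarios = NULL) {
  key <- paste(records$facility_id, records$round, sep = "|")
  groups <- split(seq_len(nrow(records)), key)
  lapply(groups, function(idx) {
    sub <- records[idx, ]
    fid <- sub$facility_id[1]
    rnd <- sub$round[1]
    sc <- if (!is.null(scenarios)) {
      scenarios$scenario[scenarios$facility_id == fid &
                           scenarios$round == rnd]
    } else NULL
    new_session(fid, rnd,
                sub[, c("subtool", "criterion_id", "respondent", "value")],
                scenario_observed = sc %||% character())
  })
}

#' Read assessment responses
#'
#' Reads a long-format CSV with one row per answer — columns `facility_id`,
#' `round`, `subtool`, `criterion_id`, `respondent`, `value` — where value
#' uses the wire codes 1 (yes), 0 (no) and 99 (not applicable). Rows are
#' grouped into one [new_session()] per facility and round. Unknown
#' facility ids, unknown criterion ids and illegal value codes are errors
#' naming the offending row.
#'
#' When no scenario file is given, the scenarios observed in a session are
#' inferred as those with at least one response on a scenario-tagged
#' criterion; an explicit file (columns `facility_id`, `round`, `scenario`)
#' overrides the inference and allows detecting scenario gaps.
#'
#' @param path Responses CSV path.
#' @param inst Instrument the responses refer to.
#' @param register Facility register tibble.
#' @param scenarios_path Optional CSV of observed scenarios.
#' @return Named list of `etiqh_session` objects (`"<facility>|<round>"`).
#' @export
read_responses <- function(path, inst, register, scenarios_path = NULL) {
  if (!file.exists(path))
    etiqh_abort(sprintf("responses file not found: %s", path),
                "etiqh_error_io")
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
  needed <- c("facility_id", "round", "subtool", "criterion_id",
              "respondent", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    etiqh_abort(sprintf("responses file is missing columns: %s",
                        paste(missing_cols, collapse = ", ")),
                "etiqh_error_parse")
  if (nrow(raw) == 0L)
    etiqh_abort(sprintf("responses file %s is empty", path),
                "etiqh_error_empty_input")
  code <- suppressWarnings(as.integer(raw$value))
  bad <- which(is.na(code) | !code %in% c(0L, 1L, 99L))
  if (length(bad))
    etiqh_abort(sprintf("row %d: illegal value code '%s' (expected 1, 0 or 99)",
                        bad[1], raw$value[bad[1]]), "etiqh_error_value")
  unknown_f <- which(!raw$facility_id %in% register$id)
  if (length(unknown_f))
    etiqh_abort(sprintf("row %d: unknown facility id '%s'", unknown_f[1],
                        raw$facility_id[unknown_f[1]]),
                "etiqh_error_unknown_id")
  crit <- criteria_table(inst)
  unknown_c <- which(!raw$criterion_id %in% crit$criterion_id)
  if (length(unknown_c))
    etiqh_abort(sprintf("row %d: unknown criterion id '%s'", unknown_c[1],
                        raw$criterion_id[unknown_c[1]]),
                "etiqh_error_unknown_id")
  records <- tibble(
    facility_id = raw$facility_id, round = raw$round,
    subtool = as.integer(raw$subtool),
    criterion_id = raw$criterion_id,
    respondent = as.integer(raw$respondent),
    value = decode_value(code))
  # subtool column must agree with the instrument's placement
  placed <- crit$subtool[match(records$criterion_id, crit$criterion_id)]
  mismatch <- which(records$subtool != placed)
  if (length(mismatch))
    etiqh_abort(sprintf(
      "row %d: criterion %s belongs to sub-tool %d, not %d", mismatch[1],
      records$criterion_id[mismatch[1]], placed[mismatch[1]],
      records$subtool[mismatch[1]]), "etiqh_error_parse")
  scenarios <- NULL
  if (!is.null(scenarios_path)) {
    scenarios <- as_tibble(read.csv(scenarios_path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
  } else {
    tagged <- crit[!is.na(crit$scenario), c("criterion_id", "scenario")]
    hit <- dplyr::inner_join(records, tagged, by = "criterion_id")
    scenarios <- dplyr::distinct(hit[, c("facility_id", "round", "scenario")])
  }
  split_into_sessions(records, scenarios)
}

#' Write assessment responses
#'
#' Inverse of [read_responses()]: emits the long CSV with wire codes
#' 1/0/99. Writing then re-reading preserves the multiset of records.
#'
#' @param sessions List of `etiqh_session` objects.
#' @param path Output CSV path.
#' @param scenarios_path Optional path for the observed-scenarios CSV.
#' @return `path`, invisibly.
#' @export
write_responses <- function(sessions, path, scenarios_path = NULL) {
  rows <- lapply(sessions, function(s) {
    if (nrow(s$records) == 0L) return(NULL)
    tibble(facility_id = s$facility_id, round = s$round,
           subtool = s$records$subtool,
           criterion_id = s$records$criterion_id,
           respondent = s$records$respondent,
           value = encode_value(s$records$value))
  })
  out <- dplyr::bind_rows(rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(scenarios_path)) {
    sc <- lapply(sessions, function(s) {
      if (!length(s$scenario_observed)) return(NULL)
      tibble(facility_id = s$facility_id, round = s$round,
             scenario = s$scenario_observed)
    })
    write.csv(dplyr::bind_rows(sc), scenarios_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}

#' Validate one session against the instrument rules
#'
#' Reproduces the front end's data-entry safeguards as data-quality issues
#' rather than errors:
#' \describe{
#'   \item{MISSING_ANSWER}{a respondent answered some criteria of a
#'     sub-tool but skipped others that apply (the "bounce-back" condition);
#'     one issue per skipped criterion and respondent.}
#'   \item{RESPONDENT_COUNT}{fewer distinct respondents on a sub-tool than
#'     the respondent rule requires for the facility type, or a respondent
#'     index beyond the rule's maximum.}
#'   \item{SCENARIO_GAP}{responses present for a scenario-tagged criterion
#'     whose scenario is not recorded as observed.}
#' }
#' An empty issue table means the session is clean. The check is
#' deterministic, idempotent and independent of record order.
#'
#' @param inst Instrument.
#' @param session An `etiqh_session`.
#' @param facility_type Facility type (determines respondent rules).
#' @return Tibble with columns `code`, `subtool`, `criterion_id`,
#'   `respondent`, `message`; zero rows when clean.
#' @export
validate_session <- function(inst, session, facility_type) {
  if (!facility_type %in% etiqh_facility_types)
    etiqh_abort(sprintf("unknown facility type '%s'", facility_type),
                "etiqh_error_parse")
  crit <- criteria_table(inst)
  rec <- session$records
  issues <- list()
  add <- function(code, subtool, criterion_id, respondent, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      code = code, subtool = as.integer(subtool),
      criterion_id = criterion_id, respondent = as.integer(respondent),
      message = message)
  }
  for (st in inst$subtools) {
    st_rec <- rec[rec$subtool == st$index, ]
    respondents <- sort(unique(st_rec$respondent))
    rule <- st$respondent_rule[[facility_type]]
    if (length(respondents) < rule[1])
      add("RESPONDENT_COUNT", st$index, NA_character_, NA_integer_,
          sprintf("sub-tool %d: %d respondent(s), rule requires at least %d for a %s",
                  st$index, length(respondents), rule[1], facility_type))
    over <- respondents[respondents > rule[2]]
    for (r in over)
      add("RESPONDENT_COUNT", st$index, NA_character_, r,
          sprintf("sub-tool %d: respondent index %d exceeds rule maximum %d",
                  st$index, r, rule[2]))
    st_crit <- crit[crit$subtool == st$index, ]
    applicable <- st_crit$criterion_id[is.na(st_crit$scenario) |
                                         st_crit$scenario %in%
                                           session$scenario_observed]
    for (r in respondents) {
      answered <- st_rec$criterion_id[st_rec$respondent == r]
      for (m in setdiff(applicable, answered))
        add("MISSING_ANSWER", st$index, m, r,
            sprintf("criterion %s not answered by respondent %d", m, r))
    }
    tagged <- st_crit[!is.na(st_crit$scenario), ]
    if (nrow(tagged)) {
      seen <- merge(st_rec, tagged[, c("criterion_id", "scenario")],
                    by = "criterion_id")
      gap <- sort(unique(seen$scenario[!seen$scenario %in%
                                         session$scenario_observed]))
      for (g in gap)
        add("SCENARIO_GAP", st$index, NA_character_, NA_integer_,
            sprintf("responses recorded for scenario '%s' not marked as observed",
                    g))
    }
  }
  if (!length(issues))
    return(tibble(code = character(), subtool = integer(),
                  criterion_id = character(), respondent = integer(),
                  message = character()))
  out <- dplyr::bind_rows(issues)
  out[order(out$code, out$subtool, out$criterion_id, out$respondent), ]
}

#' Validate many sessions
#'
#' @param inst Instrument.
#' @param sessions List of sessions.
#' @param register Facility register (provides facility types).
#' @return Issue tibble with `facility_id` and `round` columns prepended.
#' @export
validate_sessions <- function(inst, sessions, register) {
  rows <- lapply(sessions, function(s) {
    type <- register$type[register$id == s$facility_id]
    if (!length(type))
      etiqh_abort(sprintf("facility %s not in register", s$facility_id),
                  "etiqh_error_unknown_id")
    iss <- validate_session(inst, s, type[1])
    if (nrow(iss) == 0L) return(NULL)
    dplyr::bind_cols(tibble(facility_id = s$facility_id, round = s$round),
                     iss)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble(facility_id = character(), round = character(),
                  code = character(), subtool = integer(),
                  criterion_id = character(), respondent = integer(),
                  message = character())
  out
}
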