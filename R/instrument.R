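# Instrument model: six sub-tools -> quality standards -> weighted
# verification criteria. The instrument is the unit that gets versioned,
# shared between assessment rounds, and loaded by every other module.

#' Construct an assessment instrument
#'
#' An instrument holds exactly six sub-tools, one per quality dimension
#' (infrastructure & equipment; job expectations; professional knowledge,
#' skills & ethics; management & administration; staff motivation; client
#' satisfaction). Each sub-tool contains one or more quality standards, and
#' each standard a non-empty set of verification criteria answerable
#' yes/no/NA and weighted 1 (least important) to 5 (essential).
#'
#' @param name Instrument name.
#' @param version Free-form version label.
#' @param subtools List of six sub-tool objects as produced by [new_subtool()].
#' @param schema_version Integer schema version of the on-disk format.
#' @return An object of class `etiqh_instrument`.
#' @seealso [read_instrument()], [demo_instrument()], [reference_instrument()]
#' @export
new_instrument <- function(name, version, subtools, schema_version = 1L) {
  inst <- structure(
    list(name = name, version = version,
         schema_version = as.integer(schema_version), subtools = subtools),
    class = "etiqh_instrument")
  validate_instrument(inst)
  inst
}

#' Construct a sub-tool
#'
#' @param index Sub-tool index, 1 through 6.
#' @param dimension_name Name of the quality dimension.
#' @param method Assessment method, one of `"checklist"`,
#'   `"structured_interview"`, `"interview_plus_checklist"`,
#'   `"direct_observation"`, `"exit_interview"`.
#' @param standards List of standards from [new_standard()].
#' @param respondent_rule Named list mapping each facility type to
#'   `c(min, max)` respondent counts; defaults per sub-tool via
#'   [default_respondent_rule()].
#' @return A list of class `etiqh_subtool`.
#' @export
new_subtool <- function(index, dimension_name, method, standards,
                        respondent_rule = default_respondent_rule(index)) {
  structure(
    list(index = as.integer(index), dimension_name = dimension_name,
         method = method, respondent_rule = respondent_rule,
         standards = standards),
    class = "etiqh_subtool")
}

#' Construct a quality standard
#'
#' @param id Standard identifier (e.g. `"3.1"`).
#' @param question The qualitative quality statement the criteria verify.
#' @param criteria Data frame with columns `id`, `text`, `weight` and
#'   optionally `scenario` (sub-tool 3 clinical scenarios) and
#'   `applicability_note`.
#' @return A list of class `etiqh_standard`.
#' @export
new_standard <- function(id, question, criteria) {
  criteria <- as_tibble(criteria)
  if (!"scenario" %in% names(criteria)) criteria$scenario <- NA_character_
  if (!"applicability_note" %in% names(criteria))
    criteria$applicability_note <- NA_character_
  criteria$weight <- as.integer(criteria$weight)
  structure(list(id = id, question = question,
                 criteria = criteria[, c("id", "text", "weight", "scenario",
                                         "applicability_note")]),
            class = "etiqh_standard")
}

#' Default respondent-count rules
#'
#' Package defaults for how many respondents (providers, patients, or direct
#' observations) each sub-tool requires per facility type. Facility-level
#' checklists (sub-tools 1 and 4) take a single observation. Provider
#' interviews and clinical observations (sub-tools 2 and 3) range from 1-3
#' in a dispensary up to 10 in a hospital out-patient department. Staff
#' motivation (5) mirrors the provider interviews; client exit interviews
#' (6) target 5-10 patients at any facility type.
#'
#' @param index Sub-tool index 1-6.
#' @return Named list of `c(min, max)` per facility type.
#' @export
default_respondent_rule <- function(index) {
  rules <- list(
    `1` = list(dispensary = c(1L, 1L), health_center = c(1L, 1L),
               hospital_opd = c(1L, 1L)),
    `2` = list(dispensary = c(1L, 3L), health_center = c(3L, 6L),
               hospital_opd = c(10L, 10L)),
    `3` = list(dispensary = c(1L, 3L), health_center = c(3L, 6L),
               hospital_opd = c(10L, 10L)),
    `4` = list(dispensary = c(1L, 1L), health_center = c(1L, 1L),
               hospital_opd = c(1L, 1L)),
    `5` = list(dispensary = c(1L, 3L), health_center = c(5L, 10L),
               hospital_opd = c(10L, 10L)),
    `6` = list(dispensary = c(5L, 10L), health_center = c(5L, 10L),
               hospital_opd = c(5L, 10L)))
  rules[[as.character(index)]]
}

#' Validate an instrument
#'
#' Checks every structural invariant: exactly six sub-tools with unique
#' indices 1-6, non-empty criteria per standard, integer weights in 1-5,
#' globally unique criterion ids, scenario tags restricted to the four
#' clinical scenarios (and only on sub-tool 3), respondent rules with
#' `1 <= min <= max`. Errors name the offending element.
#'
#' @param inst An `etiqh_instrument`.
#' @return `inst`, invisibly, if valid.
#' @export
validate_instrument <- function(inst) {
  if (!inherits(inst, "etiqh_instrument"))
    etiqh_abort("not an etiqh_instrument", "etiqh_error_parse")
  if (length(inst$subtools) != 6L)
    etiqh_abort(sprintf("instrument must have exactly 6 sub-tools, found %d",
                        length(inst$subtools)), "etiqh_error_structure")
  idx <- vapply(inst$subtools, function(s) s$index, integer(1))
  if (!identical(sort(idx), 1:6))
    etiqh_abort("sub-tool indices must be exactly 1..6",
                "etiqh_error_structure")
  for (st in inst$subtools) {
    if (!st$method %in% etiqh_methods)
      etiqh_abort(sprintf("sub-tool %d: unknown method '%s'", st$index,
                          st$method), "etiqh_error_structure")
    if (length(st$standards) == 0L)
      etiqh_abort(sprintf("sub-tool %d has no standards", st$index),
                  "etiqh_error_structure")
    for (type in names(st$respondent_rule)) {
      r <- st$respondent_rule[[type]]
      if (!type %in% etiqh_facility_types)
        etiqh_abort(sprintf("sub-tool %d: unknown facility type '%s'",
                            st$index, type), "etiqh_error_structure")
      if (r[1] < 1L || r[1] > r[2])
        etiqh_abort(sprintf(
          "sub-tool %d, %s: respondent rule needs 1 <= min <= max",
          st$index, type), "etiqh_error_structure")
    }
    for (std in st$standards) {
      if (nrow(std$criteria) == 0L)
        etiqh_abort(sprintf("standard %s has no criteria", std$id),
                    "etiqh_error_structure")
      bad_w <- std$criteria$id[!std$criteria$weight %in% 1:5]
      if (length(bad_w))
        etiqh_abort(sprintf(
          "criterion %s (standard %s): weight must be an integer in 1..5",
          bad_w[1], std$id), "etiqh_error_weight")
      tagged <- std$criteria$scenario[!is.na(std$criteria$scenario)]
      if (length(tagged) && st$index != 3L)
        etiqh_abort(sprintf(
          "standard %s: scenario tags are only allowed on sub-tool 3",
          std$id), "etiqh_error_structure")
      bad_s <- setdiff(tagged, etiqh_scenarios)
      if (length(bad_s))
        etiqh_abort(sprintf("standard %s: unknown scenario tag '%s'",
                            std$id, bad_s[1]), "etiqh_error_structure")
    }
  }
  ids <- criteria_table(inst)$criterion_id
  dup <- ids[duplicated(ids)]
  if (length(dup))
    etiqh_abort(sprintf("duplicate criterion id '%s'", dup[1]),
                "etiqh_error_duplicate_id")
  invisible(inst)
}

#' Flat table of all verification criteria
#'
#' @param inst An `etiqh_instrument`.
#' @return A tibble with one row per criterion: `subtool`, `standard_id`,
#'   `criterion_id`, `text`, `weight`, `scenario`, `applicability_note`.
#' @export
criteria_table <- function(inst) {
  rows <- lapply(inst$subtools, function(st) {
    per_std <- lapply(st$standards, function(std) {
      cbind(data.frame(subtool = st$index, standard_id = std$id,
                       stringsAsFactors = FALSE),
            as.data.frame(std$criteria))
    })
    do.call(rbind, per_std)
  })
  out <- as_tibble(do.call(rbind, rows))
  names(out)[names(out) == "id"] <- "criterion_id"
  out
}

#' Maximum achievable points of a sub-tool
#'
#' The sum of the weights of all verification criteria of one sub-tool, on a
#' single-respondent, all-scenarios-observed basis. This is the denominator
#' of the sub-tool percentage when nothing is excluded, and the per-sub-tool
#' accounting figure quoted for the canonical instrument
#' (117, 34, 477, 217, 66 and 24 points; 935 in total).
#'
#' @param inst An `etiqh_instrument`.
#' @param subtool_index Integer in 1..6.
#' @return Integer number of points.
#' @export
max_achievable_points <- function(inst, subtool_index) {
  if (!subtool_index %in% 1:6)
    etiqh_abort(sprintf("unknown sub-tool index %s", subtool_index),
                "etiqh_error_structure")
  tab <- criteria_table(inst)
  sum(tab$weight[tab$subtool == subtool_index])
}

# YAML serialisation --------------------------------------------------------

#' Read an instrument definition file
#'
#' The on-disk format is a YAML document with top-level `name`, `version`,
#' `schema_version` and a `subtools` list; each sub-tool carries `index`,
#' `dimension_name`, `method`, an optional `respondent_rule` block (per
#' facility type `min`/`max`) and a `standards` list whose entries hold
#' `id`, `question` and `criteria` rows (`id`, `text`, `weight`, optional
#' `scenario` and `applicability_note`). All invariants are validated on
#' load and violations raise errors naming the offending element.
#'
#' @param path Path to the YAML instrument file.
#' @return A validated `etiqh_instrument`.
#' @export
read_instrument <- function(path) {
  if (!file.exists(path))
    etiqh_abort(sprintf("instrument file not found: %s", path),
                "etiqh_error_io")
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    etiqh_abort(sprintf("cannot parse instrument file %s: %s", path,
                        conditionMessage(e)), "etiqh_error_parse"))
  if (is.null(doc$subtools))
    etiqh_abort(sprintf("instrument file %s has no 'subtools' key", path),
                "etiqh_error_parse")
  subtools <- lapply(doc$subtools, function(st) {
    rule <- if (is.null(st$respondent_rule)) {
      default_respondent_rule(st$index)
    } else {
      lapply(st$respondent_rule, function(r)
        c(as.integer(r$min), as.integer(r$max)))
    }
    standards <- lapply(st$standards, function(std) {
      crit <- do.call(rbind, lapply(std$criteria, function(cr) {
        data.frame(id = cr$id, text = cr$text %||% "",
                   weight = as.integer(cr$weight),
                   scenario = cr$scenario %||% NA_character_,
                   applicability_note = cr$applicability_note %||%
                     NA_character_,
                   stringsAsFactors = FALSE)
      }))
      new_standard(std$id, std$question %||% "", crit)
    })
    new_subtool(st$index, st$dimension_name %||% "", st$method %||%
                  "checklist", standards, rule)
  })
  new_instrument(doc$name %||% basename(path), doc$version %||% "0",
                 subtools, doc$schema_version %||% 1L)
}

#' Write an instrument definition file
#'
#' Inverse of [read_instrument()]; `read_instrument(write_instrument(x))`
#' is structurally identical to `x`.
#'
#' @param inst An `etiqh_instrument`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(inst, path) {
  doc <- list(
    name = inst$name, version = inst$version,
    schema_version = inst$schema_version,
    subtools = lapply(inst$subtools, function(st) {
      list(index = st$index, dimension_name = st$dimension_name,
           method = st$method,
           respondent_rule = lapply(st$respondent_rule, function(r)
             list(min = r[1], max = r[2])),
           standards = lapply(st$standards, function(std) {
             list(id = std$id, question = std$question,
                  criteria = lapply(seq_len(nrow(std$criteria)), function(i) {
                    row <- std$criteria[i, ]
                    cr <- list(id = row$id, text = row$text,
                               weight = row$weight)
                    if (!is.na(row$scenario)) cr$scenario <- row$scenario
                    if (!is.na(row$applicability_note))
                      cr$applicability_note <- row$applicability_note
                    cr
                  }))
           }))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.etiqh_instrument <- function(x, ...) {
  tab <- criteria_table(x)
  cat(sprintf("<etiqh_instrument> %s (version %s)\n", x$name, x$version))
  for (st in x$subtools) {
    n <- sum(tab$subtool == st$index)
    pts <- sum(tab$weight[tab$subtool == st$index])
    cat(sprintf("  %d. %-45s %3d criteria, %3d points\n",
                st$index, st$dimension_name, n, pts))
  }
  cat(sprintf("  total: %d criteria, %d points\n", nrow(tab),
              sum(tab$weight)))
  invisible(x)
}
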