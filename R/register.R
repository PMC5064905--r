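# Facility register: the master list of facilities with type, ownership and
# administrative location, plus the coverage arithmetic reported per round.

#' Read a facility register
#'
#' A CSV with columns `id`, `name`, `type`, `ownership`, `council`,
#' `region`. Types and ownerships are closed vocabularies; unknown values
#' and duplicated ids are errors naming the offending row.
#'
#' @param path Path to the register CSV.
#' @return A tibble with one row per facility.
#' @export
read_register <- function(path) {
  if (!file.exists(path))
    etiqh_abort(sprintf("register file not found: %s", path),
                "etiqh_error_io")
  reg <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
  needed <- c("id", "name", "type", "ownership", "council", "region")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols))
    etiqh_abort(sprintf("register is missing columns: %s",
                        paste(missing_cols, collapse = ", ")),
                "etiqh_error_parse")
  validate_register(reg[, needed])
}

#' Validate a facility register
#'
#' @param reg Data frame with register columns.
#' @return The register as a tibble, if valid.
#' @export
validate_register <- function(reg) {
  reg <- as_tibble(reg)
  dup <- reg$id[duplicated(reg$id)]
  if (length(dup))
    etiqh_abort(sprintf("duplicate facility id '%s' in register", dup[1]),
                "etiqh_error_duplicate_id")
  bad_t <- reg$id[!reg$type %in% etiqh_facility_types]
  if (length(bad_t))
    etiqh_abort(sprintf("facility %s: unknown type '%s'", bad_t[1],
                        reg$type[reg$id == bad_t[1]][1]),
                "etiqh_error_parse")
  bad_o <- reg$id[!reg$ownership %in% etiqh_ownerships]
  if (length(bad_o))
    etiqh_abort(sprintf("facility %s: unknown ownership '%s'", bad_o[1],
                        reg$ownership[reg$id == bad_o[1]][1]),
                "etiqh_error_parse")
  reg
}

#' Write a facility register
#'
#' @param reg Register tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_register <- function(reg, path) {
  write.csv(reg, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Summarise assessment coverage
#'
#' Given the register and the set of facilities actually assessed in a
#' round, computes the coverage figures a round report quotes: number of
#' facilities, number and percentage assessed, and the assessed counts per
#' facility type (dispensaries being the remainder once hospitals and
#' health centers are counted).
#'
#' @param reg Facility register tibble.
#' @param assessed_ids Character vector of facility ids assessed.
#' @param by `"total"` for one summary row, `"council"` for one per council
#'   plus a total row.
#' @return A tibble with columns `council` (when `by = "council"`),
#'   `n_facilities`, `n_assessed`, `pct_assessed` (one decimal),
#'   `dispensaries`, `health_centers`, `hospitals` (assessed counts).
#' @export
coverage_summary <- function(reg, assessed_ids, by = c("total", "council")) {
  by <- match.arg(by)
  unknown <- setdiff(assessed_ids, reg$id)
  if (length(unknown))
    etiqh_abort(sprintf("assessed facility '%s' not in register", unknown[1]),
                "etiqh_error_unknown_id")
  summarise_one <- function(sub) {
    ass <- sub[sub$id %in% assessed_ids, ]
    tibble(
      n_facilities = nrow(sub),
      n_assessed = nrow(ass),
      pct_assessed = round(100 * nrow(ass) / nrow(sub), 1),
      dispensaries = sum(ass$type == "dispensary"),
      health_centers = sum(ass$type == "health_center"),
      hospitals = sum(ass$type == "hospital_opd"))
  }
  if (by == "total") return(summarise_one(reg))
  per <- lapply(split(reg, reg$council), summarise_one)
  out <- dplyr::bind_rows(per, .id = "council")
  total <- summarise_one(reg)
  total$council <- "TOTAL"
  dplyr::bind_rows(out, total)
}
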