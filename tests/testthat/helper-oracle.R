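# Independent brute-force scoring oracle. Enumerates the records with plain
# loops and the textbook definition of the two-step weighted score; shares
# no code with the package's scoring path.

oracle_subtool_percent <- function(criteria, records,
                                   scenario_observed = NULL) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(criteria))) {
    cid <- criteria$criterion_id[i]
    sc <- if ("scenario" %in% names(criteria)) criteria$scenario[i]
          else NA_character_
    if (!is.na(sc) && !is.null(scenario_observed) &&
        !(sc %in% scenario_observed)) next
    vals <- records$value[records$criterion_id == cid]
    n_yes <- sum(vals == "yes")
    n_no <- sum(vals == "no")
    if (n_yes + n_no == 0) next
    num <- num + criteria$weight[i] * n_yes / (n_yes + n_no)
    den <- den + criteria$weight[i]
  }
  if (den == 0) return(NA_real_)
  100 * num / den
}

oracle_achievable <- function(criteria, records, scenario_observed = NULL) {
  den <- 0
  for (i in seq_len(nrow(criteria))) {
    cid <- criteria$criterion_id[i]
    sc <- if ("scenario" %in% names(criteria)) criteria$scenario[i]
          else NA_character_
    if (!is.na(sc) && !is.null(scenario_observed) &&
        !(sc %in% scenario_observed)) next
    vals <- records$value[records$criterion_id == cid]
    if (sum(vals %in% c("yes", "no")) == 0) next
    den <- den + criteria$weight[i]
  }
  den
}
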