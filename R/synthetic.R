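# Synthetic data generation: instrument-conformant registers and
# multi-round response datasets with controllable quality levels, so the
# whole assess -> score -> aggregate -> trend pipeline can be exercised and
# validated without field data.

#' Simulation configuration
#'
#' Bundles every knob of the generator with validation. Quality is driven
#' by a per-dimension baseline yes-probability `q` and a per-round
#' improvement increment `delta`: in round `r` each answer is yes with
#' probability `q_d + (r - 1) * delta_d` (independently per criterion and
#' respondent), overridden to NA with probability `na_prob`. Respondent
#' counts are drawn uniformly within the instrument's respondent rule for
#' the facility type; each clinical scenario is observed with probability
#' `scenario_prob`.
#'
#' The default `q` profile mirrors the typical baseline pattern of such
#' assessments — client satisfaction highest, staff motivation lowest —
#' without targeting any particular real council.
#'
#' An optional facility-level random effect (`facility_sd > 0`) draws each
#' facility's dimension probability from a beta distribution with mean
#' `q_d` and standard deviation `facility_sd`, emulating between-facility
#' heterogeneity; the default model keeps criteria independent.
#'
#' @param n_councils Number of councils.
#' @param facilities_per_council Named integer vector of facility counts by
#'   type for each council.
#' @param ownership_mix Named proportions over the four ownership
#'   categories (summing to 1).
#' @param q Length-6 vector of baseline yes-probabilities per dimension.
#' @param delta Length-6 vector (or scalar) of per-round improvements.
#' @param na_prob Probability an answer is recorded NA.
#' @param scenario_prob Probability each clinical scenario is observed.
#' @param rounds Character vector of round labels, in chronological order.
#' @param facility_sd Between-facility SD of the yes-probability (0 = off).
#' @param councils_per_region Councils grouped into one region.
#' @return Validated list of class `etiqh_sim_config`.
#' @export
sim_config <- function(n_councils = 2,
                       facilities_per_council = c(dispensary = 10,
                                                  health_center = 2,
                                                  hospital_opd = 1),
                       ownership_mix = c(public = 0.7, faith_based = 0.2,
                                         private = 0.1, institutional = 0),
                       q = c(0.70, 0.55, 0.70, 0.70, 0.40, 0.80),
                       delta = 0.03,
                       na_prob = 0.05,
                       scenario_prob = 0.8,
                       rounds = c("2011", "2012"),
                       facility_sd = 0,
                       councils_per_region = 2) {
  if (length(delta) == 1L) delta <- rep(delta, 6L)
  if (length(q) != 6L || length(delta) != 6L)
    etiqh_abort("q and delta must have length 6", "etiqh_error_config")
  if (any(q < 0 | q > 1) || na_prob < 0 || na_prob > 1 ||
      scenario_prob < 0 || scenario_prob > 1)
    etiqh_abort("probabilities must lie in [0, 1]", "etiqh_error_config")
  if (any(q + (length(rounds) - 1) * delta > 1 + 1e-12))
    etiqh_abort("q + (n_rounds - 1) * delta must not exceed 1",
                "etiqh_error_config")
  if (!setequal(names(ownership_mix), etiqh_ownerships) ||
      abs(sum(ownership_mix) - 1) > 1e-8)
    etiqh_abort("ownership_mix must cover the four categories and sum to 1",
                "etiqh_error_config")
  stopifnot(all(names(facilities_per_council) %in% etiqh_facility_types),
            all(facilities_per_council >= 0), n_councils >= 1,
            facility_sd >= 0, length(rounds) >= 1)
  structure(list(n_councils = as.integer(n_councils),
                 facilities_per_council = facilities_per_council,
                 ownership_mix = ownership_mix[etiqh_ownerships],
                 q = q, delta = delta, na_prob = na_prob,
                 scenario_prob = scenario_prob,
                 rounds = as.character(rounds),
                 facility_sd = facility_sd,
                 councils_per_region = as.integer(councils_per_region)),
            class = "etiqh_sim_config")
}

#' Largest-remainder allocation of ownership categories
#'
#' Allocates `n` facilities over the ownership categories proportionally to
#' `mix`, using the largest-remainder method: each category gets the floor
#' of its exact quota, and the remaining units go to the categories with
#' the largest fractional parts, ties broken by the canonical category
#' order (public, faith_based, private, institutional).
#'
#' @param n Number of facilities.
#' @param mix Named proportions (the four ownership categories).
#' @return Named integer vector of counts summing to `n`.
#' @export
allocate_ownership <- function(n, mix) {
  mix <- mix[etiqh_ownerships]
  quota <- n * mix
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order by fractional part descending, ties by category order
    pick <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[pick] <- base[pick] + 1
  }
  setNames(as.integer(base), etiqh_ownerships)
}

#' Generate a synthetic facility register
#'
#' Deterministic given the configuration and seed: facility counts per type
#' and council match the configuration exactly, ownership categories are
#' allocated within each council by [allocate_ownership()] and then
#' assigned to facilities in a seeded random order, and councils are
#' grouped into regions.
#'
#' @param config An `etiqh_sim_config`.
#' @param seed Integer random seed.
#' @return Register tibble (columns as in [read_register()]).
#' @export
generate_register <- function(config, seed = 1L) {
  stopifnot(inherits(config, "etiqh_sim_config"))
  set.seed(seed)
  rows <- list()
  fid <- 0L
  for (ci in seq_len(config$n_councils)) {
    council <- sprintf("council_%02d", ci)
    region <- sprintf("region_%02d",
                      ceiling(ci / config$councils_per_region))
    types <- rep(names(config$facilities_per_council),
                 times = config$facilities_per_council)
    n <- length(types)
    own_counts <- allocate_ownership(n, config$ownership_mix)
    ownerships <- sample(rep(names(own_counts), times = own_counts))
    ids <- sprintf("HF%04d", fid + seq_len(n))
    fid <- fid + n
    rows[[ci]] <- tibble(id = ids, name = paste("Facility", ids),
                         type = types, ownership = ownerships,
                         council = council, region = region)
  }
  dplyr::bind_rows(rows)
}

# Beta parameters for a given mean/sd, guarded against infeasible sd.
beta_params <- function(mean, sd) {
  mean <- min(max(mean, 1e-6), 1 - 1e-6)
  v <- min(sd^2, mean * (1 - mean) * 0.999)
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Generate one round of synthetic assessment sessions
#'
#' For every facility in the register, draws respondent counts within the
#' instrument's respondent rule for the facility type, decides which
#' clinical scenarios are observed, and answers every applicable criterion
#' independently per respondent: NA with probability `na_prob`, otherwise
#' yes with probability `q_d + (round - 1) * delta_d` for the criterion's
#' dimension `d` (clipped to `[0, 1]`).
#'
#' @param inst Instrument.
#' @param register Register tibble.
#' @param config An `etiqh_sim_config`.
#' @param round Integer round index (1 = baseline).
#' @param seed Integer random seed; use a different seed per round.
#' @return Named list of `etiqh_session` objects.
#' @export
generate_round <- function(inst, register, config, round, seed = 1L) {
  stopifnot(inherits(config, "etiqh_sim_config"))
  if (round < 1L || round > length(config$rounds))
    etiqh_abort(sprintf("round index %d outside configured rounds", round),
                "etiqh_error_config")
  set.seed(seed)
  label <- config$rounds[round]
  p_dim <- pmin(pmax(config$q + (round - 1) * config$delta, 0), 1)
  crit <- criteria_table(inst)
  sessions <- vector("list", nrow(register))
  for (fi in seq_len(nrow(register))) {
    type <- register$type[fi]
    observed <- etiqh_scenarios[runif(4) < config$scenario_prob]
    per_st <- lapply(inst$subtools, function(st) {
      rule <- st$respondent_rule[[type]]
      n_resp <- if (rule[1] == rule[2]) rule[1]
                else sample(rule[1]:rule[2], 1L)
      sc <- crit[crit$subtool == st$index, ]
      sc <- sc[is.na(sc$scenario) | sc$scenario %in% observed, ]
      if (nrow(sc) == 0L) return(NULL)
      grid <- tibble(
        subtool = st$index,
        criterion_id = rep(sc$criterion_id, times = n_resp),
        respondent = rep(seq_len(n_resp), each = nrow(sc)))
      p <- p_dim[st$index]
      if (config$facility_sd > 0) {
        bp <- beta_params(p, config$facility_sd)
        p <- stats::rbeta(1, bp[1], bp[2])
      }
      n <- nrow(grid)
      is_na <- runif(n) < config$na_prob
      yes <- runif(n) < p
      grid$value <- ifelse(is_na, "na", ifelse(yes, "yes", "no"))
      grid
    })
    rec <- dplyr::bind_rows(per_st)
    sessions[[fi]] <- new_session(register$id[fi], label, rec,
                                  scenario_observed = observed)
  }
  names(sessions) <- paste(register$id, label, sep = "|")
  sessions
}

#' Generate a complete multi-round synthetic dataset
#'
#' Register plus one set of sessions per configured round. Rounds use
#' seeds derived deterministically from `seed`, so identical seeds give
#' identical datasets (and byte-identical files once written).
#'
#' @param inst Instrument.
#' @param config An `etiqh_sim_config`.
#' @param seed Integer random seed.
#' @return List with `register`, `sessions` (flat named list across
#'   rounds) and `config`.
#' @export
generate_dataset <- function(inst, config, seed = 1L) {
  register <- generate_register(config, seed)
  sessions <- list()
  for (r in seq_along(config$rounds)) {
    sessions <- c(sessions,
                  generate_round(inst, register, config, r,
                                 seed = seed + 7919L * r))
  }
  list(register = register, sessions = sessions, config = config)
}
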