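# Longitudinal trend testing: paired t-tests of facility scores between a
# baseline round and later rounds, computed over complete facility pairs
# (facilities assessed in both rounds, matched by stable id so that e.g. a
# dispensary upgraded to a health center between rounds stays paired).

#' Significance stars
#'
#' The reporting convention for paired-test p-values:
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise blank.
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Decreasing significance thresholds for `*`, `**`,
#'   `***`.
#' @return Character vector of star strings.
#' @examples
#' p_stars(c(0.2, 0.04, 0.004, 0.0004))
#' @export
p_stars <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < thresholds[3]) "***"
    else if (pi < thresholds[2]) "**"
    else if (pi < thresholds[1]) "*"
    else ""
  }, character(1))
}

as_named_scores <- function(x, value_col = "percent") {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("facility_id", value_col) %in% names(x)))
    return(setNames(x[[value_col]], x$facility_id))
  }
  etiqh_abort("scores must be a named numeric vector or a data frame with facility_id and percent",
              "etiqh_error_parse")
}

#' Match facilities across two rounds
#'
#' Pairs facilities present in both rounds by id; facilities present in
#' only one round are listed as excluded, not an error. Matching ignores
#' facility attributes, so type changes between rounds (such as an upgrade
#' from dispensary to health center) do not break a pair.
#'
#' @param baseline,post Named numeric vectors of scores (names are facility
#'   ids), or data frames with columns `facility_id` and `percent`.
#' @return List with `pairs` (tibble `facility_id`, `baseline`, `post`) and
#'   `excluded` (tibble `facility_id`, `present_in`).
#' @export
match_pairs <- function(baseline, post) {
  b <- as_named_scores(baseline)
  p <- as_named_scores(post)
  b <- b[!is.na(b)]
  p <- p[!is.na(p)]
  common <- intersect(names(b), names(p))
  excluded <- dplyr::bind_rows(
    tibble(facility_id = setdiff(names(b), common),
           present_in = "baseline"),
    tibble(facility_id = setdiff(names(p), common), present_in = "post"))
  list(pairs = tibble(facility_id = common,
                      baseline = unname(b[common]),
                      post = unname(p[common])),
       excluded = excluded)
}

#' Paired t-test of baseline vs post-baseline scores
#'
#' Classic two-sided paired t-test on the within-facility score differences
#' over complete pairs, with the star convention of [p_stars()]. Degenerate
#' cases are handled explicitly: if all differences are zero the test is a
#' null result (t = 0, p = 1); if all differences are identical but nonzero
#' the t statistic is infinite and the p-value is reported at the machine
#' floor, with `zero_variance = TRUE` either way.
#'
#' @param baseline,post Scores as accepted by [match_pairs()].
#' @param label Optional label (e.g. council and dimension) carried into
#'   the result.
#' @return Object of class `etiqh_trend`: `label`, `n_pairs`,
#'   `mean_baseline`, `mean_post`, `mean_difference`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `stars`, `zero_variance`,
#'   `excluded`.
#' @section Errors: `etiqh_error_too_few_pairs` with fewer than two
#'   complete pairs.
#' @examples
#' paired_trend_test(c(a = 50, b = 60, c = 70), c(a = 60, b = 72, c = 81))
#' @export
paired_trend_test <- function(baseline, post, label = NULL) {
  m <- match_pairs(baseline, post)
  n <- nrow(m$pairs)
  if (n < 2L)
    etiqh_abort(sprintf("paired test needs at least 2 complete pairs, got %d",
                        n), "etiqh_error_too_few_pairs")
  d <- m$pairs$post - m$pairs$baseline
  zero_var <- stats::sd(d) == 0
  if (zero_var) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf
      p <- .Machine$double.xmin
    }
  } else {
    tt <- t.test(m$pairs$post, m$pairs$baseline, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(label = label, n_pairs = n,
         mean_baseline = mean(m$pairs$baseline),
         mean_post = mean(m$pairs$post),
         mean_difference = mean(d),
         t_statistic = t_stat, degrees_of_freedom = n - 1L,
         p_value = p, stars = p_stars(p), zero_variance = zero_var,
         excluded = m$excluded),
    class = "etiqh_trend")
}

#' @export
print.etiqh_trend <- function(x, ...) {
  cat(sprintf("<etiqh_trend>%s %d complete pairs\n",
              if (!is.null(x$label)) paste0(" ", x$label, ":") else "",
              x$n_pairs))
  cat(sprintf("  baseline %.2f, post %.2f, difference %+.2f\n",
              x$mean_baseline, x$mean_post, x$mean_difference))
  cat(sprintf("  t = %.3f on %d df, p = %.4g %s\n", x$t_statistic,
              x$degrees_of_freedom, x$p_value, x$stars))
  invisible(x)
}

first_round <- function(rounds, round_order = NULL) {
  ord <- round_order %||% sort(unique(rounds))
  ord[ord %in% rounds][1]
}

#' Round-by-round trend table with significance stars
#'
#' Mirrors the standard results presentation: one row per stratum (council
#' or region) and round with the six dimension mean scores and the overall
#' mean, and on every post-baseline row the paired t-test of the facility
#' overall means against the stratum's baseline round, over complete pairs.
#' Because the test uses complete pairs only, its mean difference is not in
#' general the difference of the printed round means.
#'
#' @param scores Score table from [score_sessions()].
#' @param register Facility register.
#' @param level `"council"` or `"region"`.
#' @param round_order Optional ordering of round labels (default sorted).
#' @return Tibble: `stratum`, `round`, `n_facilities`, `tool1`..`tool6`,
#'   `mean`, `n_pairs`, `t_statistic`, `p_value`, `stars` (test columns
#'   `NA` on baseline rows).
#' @export
trend_table <- function(scores, register, level = c("council", "region"),
                        round_order = NULL) {
  level <- match.arg(level)
  j <- join_register(scores, register)
  j$stratum <- if (level == "council") j$council else j$region
  ord <- round_order %||% sort(unique(j$round))
  rows <- list()
  for (s in sort(unique(j$stratum))) {
    sub <- j[j$stratum == s, ]
    rounds <- ord[ord %in% unique(sub$round)]
    base_overall <- sub[sub$level == "overall" & sub$round == rounds[1], ]
    for (r in rounds) {
      rr <- sub[sub$round == r, ]
      dims <- vapply(1:6, function(i)
        mean(rr$percent[rr$level == "dimension" & rr$subtool == i],
             na.rm = TRUE), numeric(1))
      dims[is.nan(dims)] <- NA_real_
      overall <- rr[rr$level == "overall", ]
      row <- tibble(stratum = s, round = r,
                    n_facilities = length(unique(rr$facility_id)))
      for (i in 1:6) row[[paste0("tool", i)]] <- dims[i]
      row$mean <- mean(overall$percent, na.rm = TRUE)
      if (r == rounds[1]) {
        row$n_pairs <- NA_integer_; row$t_statistic <- NA_real_
        row$p_value <- NA_real_; row$stars <- ""
      } else {
        tr <- tryCatch(
          paired_trend_test(base_overall, overall,
                            label = sprintf("%s %s vs %s", s, r, rounds[1])),
          etiqh_error_too_few_pairs = function(e) NULL)
        if (is.null(tr)) {
          row$n_pairs <- NA_integer_; row$t_statistic <- NA_real_
          row$p_value <- NA_real_; row$stars <- ""
        } else {
          row$n_pairs <- tr$n_pairs; row$t_statistic <- tr$t_statistic
          row$p_value <- tr$p_value; row$stars <- tr$stars
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Dimension-level trend tests
#'
#' Runs [paired_trend_test()] separately for each quality dimension and for
#' the overall score, between a stratum's baseline round and a comparison
#' round (default: its latest). Optionally applies a Bonferroni correction
#' across the six dimensions.
#'
#' @param scores Score table from [score_sessions()].
#' @param register Facility register.
#' @param level `"council"` or `"region"`.
#' @param round_order Optional round ordering.
#' @param post_round Comparison round; default the latest round per
#'   stratum.
#' @param bonferroni If `TRUE`, multiply dimension p-values by 6 (capped at
#'   1) before starring. Default `FALSE`, matching the conventional
#'   uncorrected presentation.
#' @return Tibble: `stratum`, `dimension` (`"1"`..`"6"` or `"overall"`),
#'   `baseline_round`, `post_round`, `n_pairs`, `mean_baseline`,
#'   `mean_post`, `mean_difference`, `t_statistic`, `p_value`, `stars`.
#' @export
trend_tests <- function(scores, register, level = c("council", "region"),
                        round_order = NULL, post_round = NULL,
                        bonferroni = FALSE) {
  level <- match.arg(level)
  j <- join_register(scores, register)
  j$stratum <- if (level == "council") j$council else j$region
  ord <- round_order %||% sort(unique(j$round))
  rows <- list()
  for (s in sort(unique(j$stratum))) {
    sub <- j[j$stratum == s, ]
    rounds <- ord[ord %in% unique(sub$round)]
    if (length(rounds) < 2L) next
    r0 <- rounds[1]
    r1 <- post_round %||% rounds[length(rounds)]
    for (dim in c(as.character(1:6), "overall")) {
      pick <- function(r) {
        if (dim == "overall") sub[sub$level == "overall" & sub$round == r, ]
        else sub[sub$level == "dimension" & sub$round == r &
                   !is.na(sub$subtool) & sub$subtool == as.integer(dim), ]
      }
      tr <- tryCatch(paired_trend_test(pick(r0), pick(r1)),
                     etiqh_error_too_few_pairs = function(e) NULL,
                     etiqh_error_parse = function(e) NULL)
      if (is.null(tr)) next
      p <- tr$p_value
      if (bonferroni && dim != "overall") p <- min(1, p * 6)
      rows[[length(rows) + 1L]] <- tibble(
        stratum = s, dimension = dim, baseline_round = r0, post_round = r1,
        n_pairs = tr$n_pairs, mean_baseline = tr$mean_baseline,
        mean_post = tr$mean_post, mean_difference = tr$mean_difference,
        t_statistic = tr$t_statistic, p_value = p, stars = p_stars(p))
    }
  }
  dplyr::bind_rows(rows)
}
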