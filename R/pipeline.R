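#' Evaluate candidate options across a suite of trials
#'
#' The computational skeleton of the sensitivity/specificity contrast: each
#' option is scored on every trial; binary options yield per-trial 2x2
#' responder tables (patients with no determinate domain at all are
#' excluded from that option's table, with counts reported) and a C-index
#' of responder status against arm; continuous options yield per-arm means
#' and SDs of the point sum. Trials classified positive or "in between" —
#' where a treatment effect is expected — are pooled separately from
#' negative trials, where none is: a discriminating option should sit far
#' from the null in the first meta-analysis and close to it in the second.
#'
#' @param trials List of `star_trial` objects.
#' @param options An [enumerate_options()] tibble, a list of
#'   [option_spec()] objects, or a single spec.
#' @param level Confidence level for the meta-analyses.
#' @return Tibble with one row per option: `option_id`, `design`, `type`,
#'   list-columns `per_trial`, `meta_positive`, `meta_negative`, and scalar
#'   summaries `pos_est`, `pos_lo`, `pos_hi`, `neg_est`, `neg_lo`,
#'   `neg_hi` on the analysis scale (log-OR or SMD).
#' @export
evaluate_options <- function(trials, options, level = 0.95) {
  specs <- normalise_options(options)
  classes <- purrr::map_chr(trials, expert_class)
  purrr::map_dfr(specs, function(spec) {
    binary <- spec$design != "design_3b_continuous"
    per_trial <- purrr::map_dfr(trials, option_trial_summary, spec = spec)
    pos <- per_trial[classes %in% c("positive", "in_between"), ]
    neg <- per_trial[classes == "negative", ]
    pool <- function(rows) {
      rows <- rows[rows$estimable, ]
      if (nrow(rows) == 0) return(NULL)
      if (binary) pool_binary(rows, level = level)
      else pool_continuous(rows, level = level)
    }
    mp <- pool(pos); mn <- pool(neg)
    tibble(option_id = spec$option_id, design = spec$design,
           type = if (binary) "binary" else "continuous",
           per_trial = list(per_trial),
           meta_positive = list(mp), meta_negative = list(mn),
           pos_est = mp$pooled %||% NA_real_, pos_lo = mp$ci_low %||% NA_real_,
           pos_hi = mp$ci_high %||% NA_real_,
           neg_est = mn$pooled %||% NA_real_, neg_lo = mn$ci_low %||% NA_real_,
           neg_hi = mn$ci_high %||% NA_real_)
  })
}

normalise_options <- function(options) {
  if (inherits(options, "star_option")) return(list(options))
  if (is.data.frame(options)) return(options$spec)
  options
}

option_trial_summary <- function(trial, spec) {
  scored <- score_option(trial, spec)
  base <- tibble(study = trial_id(trial), expert_class = expert_class(trial),
                 n = nrow(scored))
  if (spec$design == "design_3b_continuous") {
    by_arm <- scored |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(m = mean(.data$score), s = sd(.data$score),
                       nn = dplyr::n(), .groups = "drop")
    t_ <- by_arm[by_arm$arm == "treatment", ]; p_ <- by_arm[by_arm$arm == "placebo", ]
    cidx <- c_index(scored$score[scored$arm == "treatment"],
                    scored$score[scored$arm == "placebo"])$c
    dplyr::bind_cols(base, tibble(
      mean_t = t_$m, sd_t = t_$s, n_t = t_$nn,
      mean_p = p_$m, sd_p = p_$s, n_p = p_$nn,
      c_index = cidx,
      estimable = t_$nn >= 2 && p_$nn >= 2 && (t_$s > 0 || p_$s > 0)))
  } else {
    det <- scored[scored$n_undetermined < 5, ]
    n_t <- sum(det$arm == "treatment"); n_p <- sum(det$arm == "placebo")
    events_t <- sum(det$responder[det$arm == "treatment"])
    events_p <- sum(det$responder[det$arm == "placebo"])
    cidx <- if (n_t > 0 && n_p > 0) {
      c_index(as.integer(det$responder[det$arm == "treatment"]),
              as.integer(det$responder[det$arm == "placebo"]))$c
    } else NA_real_
    dplyr::bind_cols(base, tibble(
      n_excluded = nrow(scored) - nrow(det),
      events_t = events_t, n_t = n_t, events_p = events_p, n_p = n_p,
      rate_t = events_t / n_t, rate_p = events_p / n_p, c_index = cidx,
      estimable = n_t > 0 && n_p > 0))
  }
}

#' Rank evaluated options by sensitivity and specificity to change
#'
#' Default criterion: distance from the null on the positive side minus a
#' penalty for distance from the null on the negative side,
#' `|effect_pos| - lambda * |effect_neg|` on the analysis scale (log-OR or
#' SMD, whose null is 0). `lambda = 0` ranks on sensitivity alone. Ties are
#' broken by `option_id`; options with no estimable positive-side pooling
#' rank last. The final choice among well-ranked options was, in practice,
#' a clinical-consensus decision; this ranking is only the quantitative
#' half.
#'
#' @param evaluations An [evaluate_options()] tibble.
#' @param lambda Penalty weight for the negative-side distance from null.
#' @return `evaluations` with a `rank_score` column, ordered best first.
#' @export
rank_options <- function(evaluations, lambda = 1) {
  if (nrow(evaluations) == 0) abort("no evaluations", class = "sjstar_validation_error")
  ev <- evaluations
  ev$rank_score <- abs(ev$pos_est) - lambda * abs(dplyr::coalesce(ev$neg_est, 0))
  ev$rank_score[is.na(ev$pos_est)] <- -Inf
  dplyr::arrange(ev, dplyr::desc(.data$rank_score), .data$option_id)
}
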