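#' Per-domain response rules of the candidate STAR
#'
#' Vectorised tri-state rules (`"yes"`, `"no"`, `"undetermined"`) for each
#' STAR domain. A rule is `"undetermined"` when either visit's value is
#' missing; it never silently treats a missing value as zero. All thresholds
#' are inclusive. Relative-change thresholds are evaluated in product form
#' (`followup >= baseline * (1 + threshold)` and the decrease analogue),
#' which is exact where the ratio form suffers double-precision rounding at
#' the boundary.
#'
#' * Systemic activity: decrease of >= 3 clinESSDAI points.
#' * Patient-reported outcome: ESSPRI decrease of >= 1 point, or >= 15%
#'   when baseline > 0.
#' * Schirmer's test (lachrymal): baseline abnormal (< 5 mm) — increase of
#'   >= 5 mm; baseline normal — response iff it stays normal (>= 5 mm).
#' * Ocular staining score (lachrymal): baseline abnormal (>= 3) — decrease
#'   of >= 2 points; baseline normal — response iff it stays < 3.
#' * Unstimulated whole salivary flow (salivary): baseline > 0 — increase of
#'   >= 25%; baseline 0 — any increase.
#' * Salivary gland ultrasound (salivary): decrease of >= 25% in the total
#'   Hocevar score; a zero baseline cannot decrease 25% and scores "no".
#' * Biological: serum IgG decrease of >= 10%, or rheumatoid factor decrease
#'   of >= 25% (RF baseline 0 cannot respond via RF); "undetermined" only
#'   when neither instrument has both visits.
#'
#' @param baseline,followup Numeric vectors of instrument values.
#' @return A factor with levels yes/no/undetermined.
#' @export
systemic_response <- function(baseline, followup) {
  check_instrument_range(baseline, "clin_essdai", "clin_essdai baseline")
  check_instrument_range(followup, "clin_essdai", "clin_essdai followup")
  rule_tri(baseline, followup, function(b, f) b - f >= 3)
}

#' @rdname systemic_response
#' @export
pro_response <- function(baseline, followup) {
  check_instrument_range(baseline, "esspri", "esspri baseline")
  check_instrument_range(followup, "esspri", "esspri followup")
  rule_tri(baseline, followup, function(b, f) {
    (b - f >= 1) | (b > 0 & f <= b * (1 - 0.15))
  })
}

#' @rdname systemic_response
#' @export
schirmer_response <- function(baseline, followup) {
  check_instrument_range(baseline, "schirmer", "schirmer baseline")
  check_instrument_range(followup, "schirmer", "schirmer followup")
  rule_tri(baseline, followup, function(b, f) {
    ifelse(schirmer_abnormal(b), f - b >= 5, !schirmer_abnormal(f))
  })
}

#' @rdname systemic_response
#' @export
oss_response <- function(baseline, followup) {
  check_instrument_range(baseline, "oss", "oss baseline")
  check_instrument_range(followup, "oss", "oss followup")
  rule_tri(baseline, followup, function(b, f) {
    ifelse(oss_abnormal(b), b - f >= 2, !oss_abnormal(f))
  })
}

#' @rdname systemic_response
#' @export
uwsf_response <- function(baseline, followup) {
  check_instrument_range(baseline, "uwsf", "uwsf baseline")
  check_instrument_range(followup, "uwsf", "uwsf followup")
  rule_tri(baseline, followup, function(b, f) {
    ifelse(b > 0, f >= b * (1 + 0.25), f > 0)
  })
}

#' @rdname systemic_response
#' @export
ultrasound_response <- function(baseline, followup) {
  check_instrument_range(baseline, "hocevar", "hocevar baseline")
  check_instrument_range(followup, "hocevar", "hocevar followup")
  rule_tri(baseline, followup, function(b, f) b > 0 & f <= b * (1 - 0.25))
}

#' @param igg_base,igg_fu Serum IgG (g/L) at the two visits.
#' @param rf_base,rf_fu Rheumatoid factor (IU/mL) at the two visits.
#' @rdname systemic_response
#' @export
biological_response <- function(igg_base, igg_fu, rf_base, rf_fu) {
  check_instrument_range(igg_base, "igg", "igg baseline")
  check_instrument_range(igg_fu, "igg", "igg followup")
  check_instrument_range(rf_base, "rf", "rf baseline")
  check_instrument_range(rf_fu, "rf", "rf followup")
  igg_ok <- !is.na(igg_base) & !is.na(igg_fu)
  rf_ok <- !is.na(rf_base) & !is.na(rf_fu)
  igg_yes <- igg_ok & igg_fu <= igg_base * (1 - 0.10)
  rf_yes <- rf_ok & rf_base > 0 & rf_fu <= rf_base * (1 - 0.25)
  out <- rep("undetermined", max(length(igg_base), length(rf_base)))
  out[igg_ok | rf_ok] <- "no"
  out[igg_yes | rf_yes] <- "yes"
  tri_state(out)
}

#' Baseline abnormality classifiers for the ocular tests
#'
#' Schirmer's test (without anaesthesia) is abnormal below 5 mm of wetting;
#' the ocular staining score is abnormal at 3 points or more. Both take the
#' mean of the two eyes.
#'
#' @param x Numeric vector of baseline values.
#' @return Logical vector: `TRUE` when abnormal.
#' @export
schirmer_abnormal <- function(x) x < 5

#' @rdname schirmer_abnormal
#' @export
oss_abnormal <- function(x) x >= 3

rule_tri <- function(baseline, followup, yes_fun) {
  ok <- !is.na(baseline) & !is.na(followup)
  out <- rep("undetermined", length(ok))
  out[ok] <- ifelse(yes_fun(baseline[ok], followup[ok]), "yes", "no")
  tri_state(out)
}

#' Domain-level tri-state responses for every patient
#'
#' Applies the candidate STAR per-instrument rules to a trial table and
#' combines instruments within a domain by "or": a domain responds if any
#' instrument with both visits available meets its criterion, is "no" if at
#' least one instrument pair is available and none meets it, and
#' "undetermined" if no instrument pair is available.
#'
#' @param data A `star_trial` or compatible data frame.
#' @return Tibble: `patient_id`, `arm`, and one tri-state factor column per
#'   domain (`systemic`, `pro`, `lachrymal`, `salivary`, `biological`).
#' @export
domain_responses <- function(data) {
  tibble(
    patient_id = data$patient_id,
    arm = data$arm,
    systemic = systemic_response(data$clin_essdai_base, data$clin_essdai_fu),
    pro = pro_response(data$esspri_base, data$esspri_fu),
    lachrymal = combine_instruments(
      schirmer_response(data$schirmer_base, data$schirmer_fu),
      oss_response(data$oss_base, data$oss_fu)),
    salivary = combine_instruments(
      uwsf_response(data$uwsf_base, data$uwsf_fu),
      ultrasound_response(data$hocevar_base, data$hocevar_fu)),
    biological = biological_response(data$igg_base, data$igg_fu,
                                     data$rf_base, data$rf_fu)
  )
}

combine_instruments <- function(...) {
  parts <- list(...)
  yes <- Reduce(`|`, lapply(parts, function(p) !is.na(p) & p == "yes"))
  any_det <- Reduce(`|`, lapply(parts, function(p) !is.na(p) & p != "undetermined"))
  out <- rep("undetermined", length(yes))
  out[any_det] <- "no"
  out[yes] <- "yes"
  tri_state(out)
}

#' Score the candidate STAR for every patient
#'
#' Sums domain points (systemic 3, patient-reported outcome 3, lachrymal /
#' salivary / biological 1 each) over responding domains and classifies
#' patients as STAR responders at a total of 5 points or more. Undetermined
#' domains earn 0 points — a conservative choice that biases against
#' response — and their count is surfaced in `n_undetermined` so callers can
#' apply their own completeness filters.
#'
#' @param data A `star_trial` or compatible data frame.
#' @return Tibble with one row per patient: the five tri-state domain
#'   columns, `total_points` (0-9), `responder`, `n_undetermined`.
#' @export
score_star <- function(data) {
  dom <- domain_responses(data)
  w <- star_domain_weights()
  pts <- sapply(star_domains(), function(d) ifelse(tri_yes(dom[[d]]), w[[d]], 0L))
  pts <- matrix(as.integer(pts), nrow = nrow(dom))
  dom$total_points <- as.integer(rowSums(pts))
  dom$responder <- dom$total_points >= 5L
  und <- sapply(star_domains(), function(d) dom[[d]] == "undetermined")
  dom$n_undetermined <- as.integer(rowSums(matrix(und, nrow = nrow(dom))))
  dom
}

#' Per-arm responder counts and rates for one trial
#'
#' @param trial A `star_trial`.
#' @param scorer Function mapping the trial table to a per-patient tibble
#'   with a logical `responder` column (default [score_star()]; any
#'   [score_option()] closure works).
#' @return Tibble, one row per arm: `n`, `n_scored` (patients with a
#'   determinate responder status), `responders`, `rate` (responders /
#'   n_scored).
#' @export
score_trial <- function(trial, scorer = score_star) {
  res <- scorer(trial)
  if (!"responder" %in% names(res)) {
    abort("scorer must return a `responder` column", class = "sjstar_validation_error")
  }
  res |>
    dplyr::group_by(arm = .data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_scored = sum(!is.na(.data$responder)),
      responders = sum(.data$responder, na.rm = TRUE),
      rate = .data$responders / .data$n_scored,
      .groups = "drop")
}
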