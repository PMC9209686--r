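#' Cohen's d with a noncentral-t confidence interval
#'
#' Standardised mean difference between two arms using the pooled SD,
#' `s_p^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)`. The confidence interval
#' comes from the noncentrality-parameter approach: the observed two-sample
#' t statistic `t = d / sqrt(1/n1 + 1/n2)` is held fixed and the
#' noncentrality parameters of the noncentral t distribution giving the
#' desired tail probabilities are found by root-finding, then rescaled back
#' to the d scale by `sqrt(1/n1 + 1/n2)`.
#'
#' @param values_t,values_p Numeric outcome vectors for the treatment and
#'   comparator arms (at least 2 values each, nonzero pooled variance).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `d`, `ci_low`, `ci_high`, `n1`, `n2`,
#'   `pooled_sd`, `category` (see [classify_effect_size()]).
#' @export
cohens_d <- function(values_t, values_p, level = 0.95) {
  values_t <- values_t[!is.na(values_t)]
  values_p <- values_p[!is.na(values_p)]
  n1 <- length(values_t); n2 <- length(values_p)
  if (n1 < 2 || n2 < 2) {
    abort("each arm needs at least 2 non-missing values", class = "sjstar_validation_error")
  }
  sp2 <- ((n1 - 1) * var(values_t) + (n2 - 1) * var(values_p)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("pooled variance is zero", class = "sjstar_validation_error")
  d <- (mean(values_t) - mean(values_p)) / sqrt(sp2)
  scale <- sqrt(1 / n1 + 1 / n2)
  ncp <- ncp_interval(d / scale, df = n1 + n2 - 2, level = level)
  tibble(d = d, ci_low = ncp[1] * scale, ci_high = ncp[2] * scale,
         n1 = n1, n2 = n2, pooled_sd = sqrt(sp2),
         category = classify_effect_size(d))
}

# Solve pt(t, df, ncp) = 1 - alpha/2 (lower) and alpha/2 (upper) for the
# noncentrality parameter; pt is decreasing in ncp, so each root is unique.
# Bracket half-width |t| + 10 around t covers any attainable CI at usual
# levels; tolerance 1e-8.
ncp_interval <- function(t, df, level) {
  alpha <- 1 - level
  half <- abs(t) + 10
  solve_ncp <- function(p) {
    uniroot(function(nc) suppressWarnings(pt(t, df, ncp = nc)) - p,
            lower = t - half, upper = t + half,
            extendInt = "downX", tol = 1e-8)$root
  }
  c(solve_ncp(1 - alpha / 2), solve_ncp(alpha / 2))
}

#' Hedges' g: small-sample corrected standardised mean difference
#'
#' `g = J * d` with `J = 1 - 3 / (4 * (n1 + n2 - 2) - 1)`.
#'
#' @inheritParams cohens_d
#' @return The bias-corrected standardised mean difference (numeric).
#' @export
hedges_g <- function(values_t, values_p) {
  es <- cohens_d(values_t, values_p)
  hedges_j(es$n1 + es$n2 - 2) * es$d
}

hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Concordance (C) index between two arms
#'
#' The probability that a randomly chosen treated patient has a better
#' outcome than a randomly chosen comparator patient, ties credited 0.5 —
#' the Mann-Whitney form. For a binary responder indicator this equals the
#' AUC of responder status against arm. 1 is perfectly discriminant,
#' 0.5-1 more discriminant than random, below 0.5 worse than random.
#' Computed by the midrank formula, identical to exhaustive pair counting.
#'
#' @param outcomes_t,outcomes_p Outcomes oriented so that higher = better
#'   response; non-empty.
#' @return One-row tibble: `c`, `n1`, `n2`.
#' @export
c_index <- function(outcomes_t, outcomes_p) {
  outcomes_t <- outcomes_t[!is.na(outcomes_t)]
  outcomes_p <- outcomes_p[!is.na(outcomes_p)]
  n1 <- length(outcomes_t); n2 <- length(outcomes_p)
  if (n1 == 0 || n2 == 0) {
    abort("both arms must be non-empty", class = "sjstar_validation_error")
  }
  r <- rank(c(as.double(outcomes_t), as.double(outcomes_p)))
  cval <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  tibble(c = cval, n1 = n1, n2 = n2)
}

#' Classify an effect size as small, moderate or large
#'
#' Magnitude-based: `|d| > 0.8` large, `0.5 <= |d| <= 0.8` moderate,
#' `|d| < 0.5` small. The printed cutpoints leave the value 0.8 itself
#' ambiguous; it is classified moderate (closed upper bound).
#'
#' @param d Finite standardised mean difference(s).
#' @return Factor with levels small/moderate/large.
#' @export
classify_effect_size <- function(d) {
  if (any(!is.finite(d))) {
    abort("`d` must be finite", class = "sjstar_validation_error")
  }
  a <- abs(d)
  factor(ifelse(a > 0.8, "large", ifelse(a >= 0.5, "moderate", "small")),
         levels = c("small", "moderate", "large"))
}

#' Change scores for an instrument
#'
#' Convenience for the dual analyses of change from baseline versus the
#' follow-up value itself.
#'
#' @param data A `star_trial` or compatible data frame.
#' @param instrument One of the eight instrument names (see
#'   `clin_essdai`, `esspri`, `schirmer`, `oss`, `uwsf`, `hocevar`, `igg`,
#'   `rf`).
#' @param type `"change"` (follow-up minus baseline) or `"final"`.
#' @return Tibble: `patient_id`, `arm`, `value`.
#' @export
instrument_outcome <- function(data, instrument, type = c("change", "final")) {
  type <- match.arg(type)
  instrument <- match.arg(instrument, star_instruments()$instrument)
  fu <- data[[paste0(instrument, "_fu")]]
  value <- if (type == "change") fu - data[[paste0(instrument, "_base")]] else fu
  tibble(patient_id = data$patient_id, arm = data$arm, value = value)
}
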