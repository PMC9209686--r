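#' Random-effects meta-analysis of per-trial 2x2 tables
#'
#' Pools per-trial odds ratios. Any study with a zero cell has 0.5 added to
#' all four of its cells before the log-OR and its variance are computed
#' (studies without zero cells are untouched). The fixed-effect estimate is
#' Mantel-Haenszel, computed on the uncorrected cells (the MH estimator
#' tolerates zeros) with the Robins-Breslow-Greenland variance; the
#' random-effects estimate uses inverse-variance weights `1/(v_i + tau^2)`
#' with the Paule-Mandel `tau^2` and a Q-profile interval for `tau^2` and
#' `tau`. The null reference for an odds ratio is 1.
#'
#' @param studies Data frame with columns `events_t`, `n_t`, `events_p`,
#'   `n_p`, optionally `study` labels.
#' @param level Confidence level.
#' @param correction Continuity correction added to every cell of a
#'   zero-cell study (default 0.5). Set `correct_mh = TRUE` to apply it to
#'   the Mantel-Haenszel cells as well.
#' @param correct_mh Apply `correction` to the MH computation too.
#' @return A `star_meta` object; see [tidy.star_meta()] and
#'   [glance.star_meta()].
#' @export
pool_binary <- function(studies, level = 0.95, correction = 0.5,
                        correct_mh = FALSE) {
  studies <- as_tibble(studies)
  k <- nrow(studies)
  if (k == 0) abort("no studies", class = "sjstar_validation_error")
  with(studies, {
    if (any(n_t <= 0 | n_p <= 0)) {
      abort("arm sizes must be positive", class = "sjstar_validation_error")
    }
    if (any(events_t < 0 | events_t > n_t | events_p < 0 | events_p > n_p)) {
      abort("event counts must lie in [0, n]", class = "sjstar_validation_error")
    }
  })
  a <- studies$events_t; b <- studies$n_t - studies$events_t
  c_ <- studies$events_p; d <- studies$n_p - studies$events_p
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  cc <- ifelse(zero, correction, 0)
  ac <- a + cc; bc <- b + cc; cc_ <- c_ + cc; dc <- d + cc
  yi <- log(ac * dc / (bc * cc_))
  vi <- 1 / ac + 1 / bc + 1 / cc_ + 1 / dc
  mh <- mantel_haenszel_or(a, b, c_, d, level = level,
                           correction = if (correct_mh) correction else 0)
  new_star_meta(yi, vi, k = k, level = level, measure = "OR",
                labels = if ("study" %in% names(studies)) studies$study else paste0("study_", seq_len(k)),
                fixed = mh)
}

# Mantel-Haenszel pooled OR with Robins-Breslow-Greenland variance.
mantel_haenszel_or <- function(a, b, c_, d, level, correction = 0) {
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  cc <- ifelse(zero, correction, 0)
  a <- a + cc; b <- b + cc; c_ <- c_ + cc; d <- d + cc
  n <- a + b + c_ + d
  R <- a * d / n; S <- b * c_ / n
  est <- log(sum(R) / sum(S))
  P <- (a + d) / n; Q <- (b + c_) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  z <- qnorm(1 - (1 - level) / 2)
  list(estimate = est, ci_low = est - z * sqrt(v), ci_high = est + z * sqrt(v),
       se = sqrt(v), method = "MH")
}

#' Random-effects meta-analysis of continuous two-arm summaries
#'
#' Computes each study's Hedges' g from means, SDs and sizes, with the
#' large-sample variance `1/n1 + 1/n2 + g^2 / (2 (n1 + n2))`, then pools by
#' inverse variance with the Paule-Mandel `tau^2` (random effects) and the
#' plain fixed-effect inverse-variance estimate. The null reference for a
#' standardised mean difference is 0.
#'
#' @param studies Data frame with columns `mean_t`, `sd_t`, `n_t`,
#'   `mean_p`, `sd_p`, `n_p`, optionally `study`.
#' @param level Confidence level.
#' @return A `star_meta` object.
#' @export
pool_continuous <- function(studies, level = 0.95) {
  studies <- as_tibble(studies)
  k <- nrow(studies)
  if (k == 0) abort("no studies", class = "sjstar_validation_error")
  with(studies, {
    if (any(n_t < 2 | n_p < 2)) {
      abort("each arm needs n >= 2", class = "sjstar_validation_error")
    }
    if (any(sd_t < 0 | sd_p < 0) || any(sd_t == 0 & sd_p == 0)) {
      abort("SDs must be non-negative and not both zero", class = "sjstar_validation_error")
    }
  })
  n1 <- studies$n_t; n2 <- studies$n_p
  sp <- sqrt(((n1 - 1) * studies$sd_t^2 + (n2 - 1) * studies$sd_p^2) / (n1 + n2 - 2))
  g <- hedges_j(n1 + n2 - 2) * (studies$mean_t - studies$mean_p) / sp
  vi <- 1 / n1 + 1 / n2 + g^2 / (2 * (n1 + n2))
  fe_w <- 1 / vi
  fe <- sum(fe_w * g) / sum(fe_w)
  z <- qnorm(1 - (1 - level) / 2)
  fe_se <- 1 / sqrt(sum(fe_w))
  new_star_meta(g, vi, k = k, level = level, measure = "SMD",
                labels = if ("study" %in% names(studies)) studies$study else paste0("study_", seq_len(k)),
                fixed = list(estimate = fe, ci_low = fe - z * fe_se,
                             ci_high = fe + z * fe_se, se = fe_se, method = "IV"))
}

new_star_meta <- function(yi, vi, k, level, measure, labels, fixed) {
  tau2 <- if (k >= 2) paule_mandel_tau2(yi, vi)$tau2 else 0
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- qnorm(1 - (1 - level) / 2)
  wfix <- 1 / vi
  mu_fix <- sum(wfix * yi) / sum(wfix)
  q <- sum(wfix * (yi - mu_fix)^2)
  tci <- if (k >= 2) q_profile_ci(yi, vi, level = level) else
    tibble(parameter = c("tau2", "tau"), ci_low = NA_real_, ci_high = NA_real_)
  structure(list(
    measure = measure, k = k, level = level,
    pooled = mu, se = se, ci_low = mu - z * se, ci_high = mu + z * se,
    tau2 = tau2,
    tau2_ci = unlist(tci[tci$parameter == "tau2", c("ci_low", "ci_high")]),
    tau_ci = unlist(tci[tci$parameter == "tau", c("ci_low", "ci_high")]),
    q = q, q_df = k - 1,
    q_p = if (k >= 2) pchisq(q, k - 1, lower.tail = FALSE) else NA_real_,
    fixed = fixed,
    studies = tibble(study = labels, yi = yi, vi = vi, weight = w / sum(w))
  ), class = "star_meta")
}

#' @export
print.star_meta <- function(x, ...) {
  lab <- if (x$measure == "OR") "log OR" else "SMD"
  cat(sprintf("<star_meta> %d studies, %s\n", x$k, x$measure))
  cat(sprintf("  random effects %s = %.4f [%.4f, %.4f]", lab,
              x$pooled, x$ci_low, x$ci_high))
  if (x$measure == "OR") cat(sprintf("  (OR = %.4f)", exp(x$pooled)))
  cat(sprintf("\n  fixed effect (%s) = %.4f [%.4f, %.4f]\n", x$fixed$method,
              x$fixed$estimate, x$fixed$ci_low, x$fixed$ci_high))
  cat(sprintf("  tau^2 = %.4f [%.4f, %.4f]  Q = %.3f (df %d, p = %.3f)\n",
              x$tau2, x$tau2_ci[1], x$tau2_ci[2], x$q, x$q_df, x$q_p))
  invisible(x)
}

#' Paule-Mandel estimator of between-study variance
#'
#' Solves `sum_i w_i(tau^2) (y_i - mu(tau^2))^2 = k - 1` with
#' `w_i = 1/(v_i + tau^2)` by root-finding to tolerance 1e-10, truncated at
#' 0 when the generalised Q statistic at `tau^2 = 0` already falls below
#' `k - 1`. A single study returns `tau^2 = 0` by convention, flagged.
#'
#' @param effects,variances Per-study effects and sampling variances.
#' @return List: `tau2`, `converged`, `estimable` (`FALSE` when k < 2).
#' @export
paule_mandel_tau2 <- function(effects, variances) {
  if (any(variances <= 0)) {
    abort("variances must be positive", class = "sjstar_validation_error")
  }
  k <- length(effects)
  if (k < 2) return(list(tau2 = 0, converged = TRUE, estimable = FALSE))
  f <- function(t2) generalised_q(effects, variances, t2) - (k - 1)
  if (f(0) <= 0) return(list(tau2 = 0, converged = TRUE, estimable = TRUE))
  upper <- max(variances)
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 10
  r <- uniroot(f, c(0, upper), tol = 1e-10)
  list(tau2 = r$root, converged = abs(r$f.root) < 1e-6, estimable = TRUE)
}

# Generalised Cochran Q at a candidate tau^2 (weights 1/(v + tau^2)).
generalised_q <- function(effects, variances, tau2) {
  w <- 1 / (variances + tau2)
  mu <- sum(w * effects) / sum(w)
  sum(w * (effects - mu)^2)
}

#' Q-profile confidence interval for tau^2 and tau
#'
#' Profiles the generalised Q statistic: the bounds are the `tau^2` values
#' at which Q equals the upper and lower `chi^2_{k-1}` quantiles, truncated
#' at 0 when Q at 0 already falls below a quantile.
#'
#' @inheritParams paule_mandel_tau2
#' @param level Confidence level.
#' @return Tibble with rows `tau2` and `tau`: `ci_low`, `ci_high`.
#' @export
q_profile_ci <- function(effects, variances, level = 0.95) {
  if (any(variances <= 0)) {
    abort("variances must be positive", class = "sjstar_validation_error")
  }
  k <- length(effects)
  if (k < 2) abort("Q-profile CI needs k >= 2", class = "sjstar_validation_error")
  alpha <- 1 - level
  solve_bound <- function(target) {
    if (generalised_q(effects, variances, 0) <= target) return(0)
    upper <- max(variances)
    while (generalised_q(effects, variances, upper) > target && upper < 1e12) {
      upper <- upper * 10
    }
    uniroot(function(t2) generalised_q(effects, variances, t2) - target,
            c(0, upper), tol = 1e-10)$root
  }
  lo <- solve_bound(qchisq(1 - alpha / 2, k - 1))
  hi <- solve_bound(qchisq(alpha / 2, k - 1))
  tibble(parameter = c("tau2", "tau"),
         ci_low = c(lo, sqrt(lo)), ci_high = c(hi, sqrt(hi)))
}
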