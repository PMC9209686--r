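# Instrument-level generation table: marginal baseline distribution,
# change model (additive on the instrument scale vs multiplicative relative
# change), follow-up noise SD (instrument scale), rounding granularity and
# default missingness rate. Distributions are range-respecting defaults for
# a moderately active pSS trial population, not calibrated to any real
# trial's covariance.
sim_instrument_table <- function() {
  tibble::tribble(
    ~instrument,   ~change,          ~noise_sd, ~digits, ~miss,
    "clin_essdai", "additive",        3.0,       0,      0.02,
    "esspri",      "additive",        1.2,       1,      0.02,
    "schirmer",    "additive",        3.0,       0,      0.05,
    "oss",         "additive",        1.5,       0,      0.05,
    "uwsf",        "multiplicative",  0.06,      3,      0.05,
    "hocevar",     "multiplicative",  5.0,       0,      0.20,
    "igg",         "multiplicative",  1.5,       1,      0.05,
    "rf",          "multiplicative", 10.0,       1,      0.10
  )
}

#' Per-domain treatment-effect profiles
#'
#' Mean changes applied between the two visits, per arm. Additive entries
#' (`clin_essdai`, `esspri`, `schirmer`, `oss`) are signed changes on the
#' instrument scale (negative = decrease); the remaining entries are
#' relative changes (`-0.25` = 25% decrease). The three presets emulate the
#' expert classes trials were sorted into:
#'
#' * `positive` — clear improvement on treatment across all five domains,
#'   modest placebo drift.
#' * `in_between` — trials that missed their primary endpoint but improved
#'   objective/biological measures: biological and salivary effects are
#'   near-positive, symptomatic effects modest.
#' * `negative` — treatment and placebo changes identical (enforced).
#'
#' @param label `"positive"`, `"in_between"` or `"negative"`.
#' @param treatment,placebo Optional named-list overrides of individual
#'   entries.
#' @return An `effect_profile` list: `label`, `treatment`, `placebo`.
#' @export
effect_profile <- function(label = c("positive", "in_between", "negative"),
                           treatment = list(), placebo = list()) {
  label <- match.arg(label)
  pbo <- list(clin_essdai = -1, esspri = -0.5, schirmer = 0.5, oss = -0.3,
              uwsf = 0.05, hocevar = -0.03, igg = -0.01, rf = -0.02)
  trt <- switch(label,
    positive = list(clin_essdai = -4, esspri = -1.5, schirmer = 3, oss = -1.5,
                    uwsf = 0.35, hocevar = -0.25, igg = -0.12, rf = -0.30),
    in_between = list(clin_essdai = -2, esspri = -0.8, schirmer = 1, oss = -0.8,
                      uwsf = 0.20, hocevar = -0.12, igg = -0.10, rf = -0.25),
    negative = pbo)
  pbo <- modifyList(pbo, placebo)
  trt <- if (label == "negative") pbo else modifyList(trt, treatment)
  structure(list(label = label, treatment = trt, placebo = pbo),
            class = "effect_profile")
}

#' Simulation configuration for one two-visit trial
#'
#' @param n Total patients (>= 4; both arms get at least 2).
#' @param profile An [effect_profile()].
#' @param treat_frac Fraction randomised to treatment.
#' @param correlation Latent severity loading in `[0, 1)`: baselines are
#'   drawn through a Gaussian copula with a single latent severity factor,
#'   so instruments are positively associated in severity.
#' @param missingness Named per-instrument missingness rates (probabilities
#'   applied independently to each visit's measurement); defaults in
#'   `sim_instrument_table()`.
#' @param subgroup Optional planted subgroup:
#'   `list(covariate = "biomarker", threshold = 0, extra = list(...))` —
#'   treated patients with covariate above the threshold receive the extra
#'   per-instrument changes on top of the arm profile.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 100, profile = effect_profile("positive"),
                       treat_frac = 0.5, correlation = 0.5,
                       missingness = NULL, subgroup = NULL, seed = 1) {
  check_scalar_number(n, "n", 4, 1e6)
  check_scalar_number(treat_frac, "treat_frac", 0.05, 0.95)
  check_scalar_number(correlation, "correlation", 0, 0.99)
  check_scalar_number(seed, "seed", -.Machine$integer.max, .Machine$integer.max)
  stopifnot(inherits(profile, "effect_profile"))
  miss <- setNames(sim_instrument_table()$miss, sim_instrument_table()$instrument)
  if (!is.null(missingness)) {
    if (any(unlist(missingness) < 0 | unlist(missingness) > 1)) {
      abort("missingness rates must be probabilities", class = "sjstar_validation_error")
    }
    miss[names(missingness)] <- unlist(missingness)
  }
  if (!is.null(subgroup)) {
    if (!all(c("covariate", "threshold", "extra") %in% names(subgroup))) {
      abort("subgroup needs covariate, threshold and extra",
            class = "sjstar_validation_error")
    }
  }
  structure(list(n = as.integer(n), profile = profile, treat_frac = treat_frac,
                 correlation = correlation, missingness = miss,
                 subgroup = subgroup, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one two-visit pSS trial
#'
#' Baselines are drawn from range-respecting marginals (truncated negative
#' binomial clinESSDAI, truncated normal ESSPRI and Hocevar, zero-inflated
#' gamma Schirmer and salivary flow, binomial-type OSS, lognormal IgG,
#' zero-inflated lognormal RF) coupled through a single latent severity
#' factor. Follow-up is baseline plus an arm- and subgroup-dependent mean
#' change plus Gaussian noise, truncated to the instrument range and
#' rounded to its granularity. Missing measurements are injected
#' independently per instrument and visit.
#'
#' @param config A [sim_config()].
#' @param trial_id,evaluation_week Trial metadata.
#' @param expert_class Defaults to the profile label.
#' @return A `star_trial` with baseline covariates `age`,
#'   `disease_duration` and (if a subgroup is planted) the subgroup
#'   covariate.
#' @export
simulate_trial <- function(config, trial_id = "sim",
                           expert_class = config$profile$label,
                           evaluation_week = 24L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  n_t <- max(2L, min(n - 2L, round(n * config$treat_frac)))
  arm <- sample(rep(c("treatment", "placebo"), c(n_t, n - n_t)))
  rho <- config$correlation
  severity <- rnorm(n)
  u_for <- function() pnorm(rho * severity + sqrt(1 - rho^2) * rnorm(n))

  base <- list(
    clin_essdai = pmin(qnbinom(u_for(), size = 4, mu = 10), 40),
    esspri = round(qnorm_trunc(u_for(), 6, 2, 0, 10), 1),
    schirmer = round(q_zigamma(1 - u_for(), p0 = 0.15, shape = 1.2, scale = 5)),
    oss = qbinom(u_for(), 12, 0.35),
    uwsf = round(q_zigamma(1 - u_for(), p0 = 0.20, shape = 1.5, scale = 0.15), 3),
    hocevar = round(qnorm_trunc(u_for(), 22, 8, 0, 48)),
    igg = round(qlnorm(u_for(), log(14), 0.35), 1),
    rf = round(q_zilnorm(u_for(), p0 = 0.35, meanlog = log(50), sdlog = 1), 1))

  sub_in <- rep(FALSE, n)
  covs <- tibble(age = round(qnorm_trunc(runif(n), 55, 12, 18, 85)),
                 disease_duration = round(rgamma(n, shape = 2, scale = 4), 1))
  if (!is.null(config$subgroup)) {
    covs[[config$subgroup$covariate]] <- rnorm(n)
    sub_in <- covs[[config$subgroup$covariate]] > config$subgroup$threshold
  }

  tab <- sim_instrument_table()
  meta <- star_instruments()
  fu <- purrr::imap(base, function(b, inst) {
    row <- tab[tab$instrument == inst, ]
    eff <- ifelse(arm == "treatment",
                  config$profile$treatment[[inst]], config$profile$placebo[[inst]])
    if (!is.null(config$subgroup)) {
      extra <- config$subgroup$extra[[inst]] %||% 0
      eff <- eff + ifelse(sub_in & arm == "treatment", extra, 0)
    }
    val <- if (row$change == "additive") {
      b + eff + rnorm(n, sd = row$noise_sd)
    } else {
      b * (1 + eff) + rnorm(n, sd = row$noise_sd * pmax(b / max(mean(b), 1e-8), 0.1))
    }
    m <- meta[meta$instrument == inst, ]
    lo <- if (m$lo_open) m$lo + 10^(-row$digits) else m$lo
    val <- pmax(val, lo)
    if (!is.na(m$hi)) val <- pmin(val, m$hi)
    round(val, row$digits)
  })
  dat <- tibble(patient_id = sprintf("%s_%03d", trial_id, seq_len(n)), arm = arm)
  for (inst in names(base)) {
    bcol <- base[[inst]]; fcol <- fu[[inst]]
    miss <- config$missingness[[inst]]
    if (miss > 0) {
      bcol[runif(n) < miss] <- NA
      fcol[runif(n) < miss] <- NA
    }
    dat[[paste0(inst, "_base")]] <- as.double(bcol)
    dat[[paste0(inst, "_fu")]] <- as.double(fcol)
  }
  dat <- dplyr::bind_cols(dat, covs)
  trial_dataset(dat, trial_id = trial_id, expert_class = expert_class,
                evaluation_week = evaluation_week)
}

qnorm_trunc <- function(p, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

q_zigamma <- function(p, p0, shape, scale) {
  ifelse(p < p0, 0, qgamma(pmax((p - p0) / (1 - p0), 0), shape = shape, scale = scale))
}

q_zilnorm <- function(p, p0, meanlog, sdlog) {
  ifelse(p < p0, 0, qlnorm(pmax((p - p0) / (1 - p0), 0), meanlog, sdlog))
}

#' The default nine-trial suite
#'
#' Trial sizes and expert classes mirroring the nine randomised controlled
#' trials the index was developed on: n = 80, 52, 120, 29, 27, 32, 133,
#' 120, 110, of which three are positive, three "in between" and three
#' negative, evaluated at week 24 except two week-12 and one week-48 trial.
#'
#' @return Tibble: `trial_id`, `n`, `expert_class`, `evaluation_week`.
#' @export
default_suite <- function() {
  tibble::tribble(
    ~trial_id, ~n,  ~expert_class, ~evaluation_week,
    "sim_01",  80L,  "in_between", 24L,
    "sim_02",  52L,  "negative",   24L,
    "sim_03", 120L,  "negative",   24L,
    "sim_04",  29L,  "positive",   24L,
    "sim_05",  27L,  "positive",   24L,
    "sim_06",  32L,  "positive",   12L,
    "sim_07", 133L,  "in_between", 48L,
    "sim_08", 120L,  "in_between", 24L,
    "sim_09", 110L,  "negative",   12L
  )
}

#' Simulate a suite of trials
#'
#' One trial per row of `suite`; each trial's effect profile follows its
#' expert class ("in between" trials get the `in_between` profile, negative
#' trials the null profile) and its seed is derived reproducibly from the
#' master seed.
#'
#' @param suite A tibble like [default_suite()].
#' @param seed Master seed.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `correlation`, `missingness`).
#' @return Named list of `star_trial` objects.
#' @export
simulate_suite <- function(suite = default_suite(), seed = 1, ...) {
  suite <- as_tibble(suite)
  if (nrow(suite) == 0) abort("empty suite", class = "sjstar_validation_error")
  out <- purrr::map(seq_len(nrow(suite)), function(i) {
    row <- suite[i, ]
    child_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    cfg <- sim_config(n = row$n, profile = effect_profile(row$expert_class),
                      seed = child_seed, ...)
    simulate_trial(cfg, trial_id = row$trial_id,
                   expert_class = row$expert_class,
                   evaluation_week = row$evaluation_week)
  })
  setNames(out, suite$trial_id)
}
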