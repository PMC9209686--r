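option_designs <- c("sri_two_major", "sri_one_major", "design_3a",
                    "design_3b_binary", "design_3b_continuous",
                    "acr_like", "cress_like")

#' Define a candidate composite-endpoint option
#'
#' A parameterised composite-endpoint definition from the design families
#' explored during STAR development:
#'
#' * `sri_two_major` — improvement in at least one of the two major domains
#'   (systemic activity, PROs) and no worsening of the remaining domains.
#' * `sri_one_major` — improvement in a single designated major domain and
#'   no worsening of the other four.
#' * `design_3a` — improvement in >= 3 of 5 domains including >= 1 major.
#' * `design_3b_binary` — point sum (3/3/1/1/1) at or above a threshold
#'   tested from 4 to 9; threshold 5 is the candidate STAR.
#' * `design_3b_continuous` — the 0-9 point sum itself, compared between
#'   arms as a continuous endpoint.
#' * `acr_like` — uniform percent improvement (10% to 70%) on each domain's
#'   instruments, >= 3 of 5 domains including >= 1 major.
#' * `cress_like` — improvement in >= 3 of 5 domains, no major-domain
#'   requirement.
#'
#' Domain improvements use the candidate STAR per-instrument rules except
#' for `acr_like`, which replaces every threshold by the uniform percent.
#' Worsening (used only by the SRI-like designs) defaults to the mirror
#' image of each improvement rule.
#'
#' @param design One of the design families above.
#' @param threshold Integer 4-9, `design_3b_binary` only.
#' @param acr_percent Integer 10-70, `acr_like` only.
#' @param major_domains Majors; `c("systemic", "pro")` except for
#'   `sri_one_major`, which takes exactly one of them.
#' @param option_id Identifier; a readable default is derived.
#' @return A `star_option` object.
#' @export
option_spec <- function(design, threshold = NULL, acr_percent = NULL,
                        major_domains = c("systemic", "pro"),
                        option_id = NULL) {
  design <- match.arg(design, option_designs)
  if (design == "design_3b_binary") {
    check_scalar_number(threshold, "threshold", 4, 9)
  } else if (!is.null(threshold)) {
    abort(sprintf("`threshold` only applies to design_3b_binary, not %s", design),
          class = "sjstar_config_error")
  }
  if (design == "acr_like") {
    check_scalar_number(acr_percent, "acr_percent", 10, 70)
  } else if (!is.null(acr_percent)) {
    abort(sprintf("`acr_percent` only applies to acr_like, not %s", design),
          class = "sjstar_config_error")
  }
  if (design == "sri_one_major") {
    if (length(major_domains) != 1 || !major_domains %in% c("systemic", "pro")) {
      abort("sri_one_major needs exactly one major domain (systemic or pro)",
            class = "sjstar_config_error")
    }
  } else {
    major_domains <- c("systemic", "pro")
  }
  if (is.null(option_id)) {
    option_id <- switch(design,
      design_3b_binary = sprintf("3b_th%d", as.integer(threshold)),
      design_3b_continuous = "3b_cont",
      acr_like = sprintf("acr%d", as.integer(acr_percent)),
      sri_one_major = sprintf("sri1_%s", major_domains),
      sri_two_major = "sri2",
      design_3a = "3a",
      cress_like = "cress")
  }
  structure(list(option_id = option_id, design = design,
                 threshold = if (!is.null(threshold)) as.integer(threshold),
                 acr_percent = if (!is.null(acr_percent)) as.integer(acr_percent),
                 major_domains = major_domains),
            class = "star_option")
}

#' @export
print.star_option <- function(x, ...) {
  cat(sprintf("<star_option %s> design = %s", x$option_id, x$design))
  if (!is.null(x$threshold)) cat(", threshold =", x$threshold)
  if (!is.null(x$acr_percent)) cat(", percent =", x$acr_percent)
  cat("\n")
  invisible(x)
}

#' The candidate STAR expressed as an option
#'
#' Point-sum design with responder threshold 5 and no worsening clause;
#' classifies every record identically to [score_star()].
#'
#' @return A `star_option`.
#' @export
candidate_star_spec <- function() {
  option_spec("design_3b_binary", threshold = 5, option_id = "candidate_star")
}

#' Score a composite-endpoint option on a trial table
#'
#' @param data A `star_trial` or compatible data frame.
#' @param spec A [option_spec()].
#' @return Tibble with one row per patient: `responder` (binary designs) or
#'   `score` (continuous point sum), plus `n_undetermined` (domains with no
#'   usable instrument pair).
#' @export
score_option <- function(data, spec) {
  stopifnot(inherits(spec, "star_option"))
  imp <- if (spec$design == "acr_like") {
    percent_domain_responses(data, spec$acr_percent / 100)
  } else {
    domain_responses(data)
  }
  wors <- if (spec$design %in% c("sri_two_major", "sri_one_major")) {
    domain_worsening(data)
  }
  out <- imp[c("patient_id", "arm")]
  und <- sapply(star_domains(), function(d) imp[[d]] == "undetermined")
  out$n_undetermined <- as.integer(rowSums(matrix(und, nrow = nrow(imp))))
  pattern <- sapply(star_domains(), function(d) tri_yes(imp[[d]]))
  pattern <- matrix(pattern, nrow = nrow(imp), dimnames = list(NULL, star_domains()))
  cls <- classify_pattern(pattern, spec, worsened = if (!is.null(wors)) {
    w <- sapply(star_domains(), function(d) tri_yes(wors[[d]]))
    matrix(w, nrow = nrow(imp), dimnames = list(NULL, star_domains()))
  })
  if (spec$design == "design_3b_continuous") out$score <- cls else out$responder <- cls
  out
}

# Classify a logical domain-improvement matrix under a design. `worsened`
# is required by the SRI-like families only; missing domains count as not
# worsened there (absence of evidence of worsening).
classify_pattern <- function(pattern, spec, worsened = NULL) {
  majors <- spec$major_domains
  w <- star_domain_weights()
  points <- as.vector(pattern %*% w[colnames(pattern)])
  n_improved <- rowSums(pattern)
  major_improved <- rowSums(pattern[, majors, drop = FALSE]) > 0
  switch(spec$design,
    design_3b_continuous = as.integer(points),
    design_3b_binary = points >= spec$threshold,
    design_3a = n_improved >= 3 & major_improved,
    acr_like = n_improved >= 3 & major_improved,
    cress_like = n_improved >= 3,
    sri_two_major = ,
    sri_one_major = {
      if (is.null(worsened)) {
        worsened <- matrix(FALSE, nrow(pattern), ncol(pattern),
                           dimnames = dimnames(pattern))
      }
      # no worsening among domains other than the improved major(s)
      other_wors <- vapply(seq_len(nrow(pattern)), function(i) {
        imp_major <- majors[pattern[i, majors]]
        any(worsened[i, setdiff(star_domains(), imp_major)])
      }, logical(1))
      major_improved & !other_wors
    })
}

#' All 32 domain-level response patterns
#'
#' The full yes/no grid over the five STAR domains, used to probe composite
#' definitions exhaustively.
#'
#' @return 32-row tibble of logical domain columns.
#' @export
response_patterns <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 5), KEEP.OUT.ATTRS = FALSE)
  names(g) <- star_domains()
  as_tibble(g)
}

#' Classify explicit domain-response patterns under an option
#'
#' Bypasses the instrument rules: the caller states which domains improved.
#' Worsening is taken as absent, so SRI-like designs reduce to their
#' major-domain clause.
#'
#' @param patterns Data frame with logical columns `systemic`, `pro`,
#'   `lachrymal`, `salivary`, `biological` (e.g. [response_patterns()]).
#' @param spec A [option_spec()].
#' @return `patterns` with `n_improved`, `total_points` and `responder`
#'   (or `score`) columns added.
#' @export
score_patterns <- function(patterns, spec) {
  patterns <- as_tibble(patterns)
  m <- as.matrix(patterns[star_domains()])
  out <- patterns
  out$n_improved <- as.integer(rowSums(m))
  out$total_points <- as.integer(m %*% star_domain_weights()[star_domains()])
  cls <- classify_pattern(m, spec)
  if (spec$design == "design_3b_continuous") out$score <- cls else out$responder <- cls
  out
}

# ACR-like: uniform relative-improvement rules per instrument, combined
# within domain by "or" exactly like the candidate rules.
percent_domain_responses <- function(data, p) {
  rel <- function(base, fu, direction) {
    rule_tri(base, fu, function(b, f) {
      if (direction == "increase") ifelse(b > 0, f >= b * (1 + p), f > 0)
      else b > 0 & f <= b * (1 - p)
    })
  }
  tibble(
    patient_id = data$patient_id,
    arm = data$arm,
    systemic = rel(data$clin_essdai_base, data$clin_essdai_fu, "decrease"),
    pro = rel(data$esspri_base, data$esspri_fu, "decrease"),
    lachrymal = combine_instruments(
      rel(data$schirmer_base, data$schirmer_fu, "increase"),
      rel(data$oss_base, data$oss_fu, "decrease")),
    salivary = combine_instruments(
      rel(data$uwsf_base, data$uwsf_fu, "increase"),
      rel(data$hocevar_base, data$hocevar_fu, "decrease")),
    biological = combine_instruments(
      rel(data$igg_base, data$igg_fu, "decrease"),
      rel(data$rf_base, data$rf_fu, "decrease"))
  )
}

# Mirror-image worsening rules; there is no consensual published definition
# of worsening for these outcomes, so symmetry is the default.
domain_worsening <- function(data) {
  tibble(
    patient_id = data$patient_id,
    arm = data$arm,
    systemic = rule_tri(data$clin_essdai_base, data$clin_essdai_fu,
                        function(b, f) f - b >= 3),
    pro = rule_tri(data$esspri_base, data$esspri_fu,
                   function(b, f) (f - b >= 1) | (b > 0 & f >= b * (1 + 0.15))),
    lachrymal = combine_instruments(
      rule_tri(data$schirmer_base, data$schirmer_fu,
               function(b, f) ifelse(schirmer_abnormal(b), b - f >= 5,
                                     schirmer_abnormal(f))),
      rule_tri(data$oss_base, data$oss_fu,
               function(b, f) ifelse(oss_abnormal(b), f - b >= 2, oss_abnormal(f)))),
    salivary = combine_instruments(
      rule_tri(data$uwsf_base, data$uwsf_fu,
               function(b, f) b > 0 & f <= b * (1 - 0.25)),
      rule_tri(data$hocevar_base, data$hocevar_fu,
               function(b, f) ifelse(b > 0, f >= b * (1 + 0.25), f > 0))),
    biological = combine_instruments(
      rule_tri(data$igg_base, data$igg_fu, function(b, f) f >= b * (1 + 0.10)),
      rule_tri(data$rf_base, data$rf_fu,
               function(b, f) ifelse(b > 0, f >= b * (1 + 0.25), f > 0)))
  )
}

#' Enumerate a grid of candidate options
#'
#' Expands a grid configuration into one [option_spec()] per variant: the
#' point-sum family contributes one option per threshold (4 to 9), the
#' ACR-like family one per percent step.
#'
#' @param grid Named list keyed by design (values: `list()` for designs
#'   without parameters, `list(thresholds = 4:9)` for `design_3b_binary`,
#'   `list(percents = seq(10, 70, 10))` for `acr_like`,
#'   `list(major = "systemic")` for `sri_one_major`), or the path to a YAML
#'   file holding the same structure.
#' @return Tibble: `option_id`, `design`, `threshold`, `acr_percent`, and a
#'   `spec` list-column of `star_option` objects.
#' @export
enumerate_options <- function(grid) {
  if (is.character(grid) && length(grid) == 1) grid <- yaml::read_yaml(grid)
  if (!is.list(grid) || length(grid) == 0 || is.null(names(grid))) {
    abort("`grid` must be a non-empty named list of designs",
          class = "sjstar_config_error")
  }
  specs <- purrr::list_flatten(purrr::imap(grid, function(params, design) {
    switch(design,
      design_3b_binary = purrr::map(params$thresholds %||% 4:9,
                                    ~option_spec(design, threshold = .x)),
      acr_like = purrr::map(params$percents %||% seq(10, 70, by = 10),
                            ~option_spec(design, acr_percent = .x)),
      sri_one_major = purrr::map(params$major %||% c("systemic", "pro"),
                                 ~option_spec(design, major_domains = .x)),
      list(option_spec(design)))
  }))
  specs <- unname(specs)
  ids <- purrr::map_chr(specs, "option_id")
  if (anyDuplicated(ids)) {
    abort("option ids are not unique", class = "sjstar_config_error")
  }
  tibble(
    option_id = ids,
    design = purrr::map_chr(specs, "design"),
    threshold = purrr::map_int(specs, ~.x$threshold %||% NA_integer_),
    acr_percent = purrr::map_int(specs, ~.x$acr_percent %||% NA_integer_),
    spec = specs
  )
}
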