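#' Tidy a meta-analysis: one row per study
#'
#' @param x A `star_meta` from [pool_binary()] or [pool_continuous()].
#' @param ... Unused.
#' @return Tibble: `study`, `estimate` (analysis scale), `std.error`,
#'   `conf.low`, `conf.high`, `weight` (random-effects, sums to 1).
#' @method tidy star_meta
#' @export
tidy.star_meta <- function(x, ...) {
  z <- qnorm(1 - (1 - x$level) / 2)
  se <- sqrt(x$studies$vi)
  tibble(study = x$studies$study, estimate = x$studies$yi, std.error = se,
         conf.low = x$studies$yi - z * se, conf.high = x$studies$yi + z * se,
         weight = x$studies$weight)
}

#' One-row summary of a meta-analysis
#'
#' @inheritParams tidy.star_meta
#' @return Tibble: `measure`, `k`, pooled random-effects `estimate` with CI
#'   (plus `or`/`or.low`/`or.high` back-transforms for binary pooling),
#'   `fixed.estimate`, `tau2` and its CI, `q`, `q.df`, `q.p`.
#' @method glance star_meta
#' @export
glance.star_meta <- function(x, ...) {
  out <- tibble(measure = x$measure, k = x$k, estimate = x$pooled,
                conf.low = x$ci_low, conf.high = x$ci_high,
                fixed.estimate = x$fixed$estimate,
                tau2 = x$tau2, tau2.low = x$tau2_ci[[1]], tau2.high = x$tau2_ci[[2]],
                q = x$q, q.df = x$q_df, q.p = x$q_p)
  if (x$measure == "OR") {
    out$or <- exp(x$pooled); out$or.low <- exp(x$ci_low); out$or.high <- exp(x$ci_high)
  }
  out
}

#' Tidy a virtual-twins tree: one row per candidate subgroup
#'
#' @param x A `star_vt_tree` from [grow_tree()].
#' @param ... Unused.
#' @return The `subgroups` tibble.
#' @method tidy star_vt_tree
#' @export
tidy.star_vt_tree <- function(x, ...) x$subgroups

#' One-row summary of a virtual-twins tree
#'
#' @inheritParams tidy.star_vt_tree
#' @return Tibble: subgroup count, overall relative risk, mean estimated
#'   individual treatment effect, first splitting variable (`NA` for a
#'   root-only tree).
#' @method glance star_vt_tree
#' @export
glance.star_vt_tree <- function(x, ...) {
  fr <- x$tree$frame
  tibble(n_subgroups = nrow(x$subgroups),
         rr_overall = observed_rr(x$twins),
         mean_z = mean(x$twins$z),
         first_split = if (nrow(fr) > 1) as.character(fr$var[1]) else NA_character_)
}
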