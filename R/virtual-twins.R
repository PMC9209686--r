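#' Virtual twins: per-patient treatment-effect estimates
#'
#' Stage one of virtual-twins subgroup discovery. A probabilistic
#' classifier (bagged trees via \pkg{randomForest} with `mtry` equal to the
#' number of predictors) is fit to the binary response with the arm
#' indicator as a feature, and each patient's response probability is
#' predicted with the arm toggled to treatment (`p1`) and placebo (`p0`);
#' `z = p1 - p0` is the estimated individual treatment effect. Predictions
#' are out-of-fold (K-fold cross-fitting) to limit the optimism of the
#' data-driven search.
#'
#' @param data A `star_trial` or data frame with `arm` plus the covariate
#'   columns.
#' @param response The binary response: a `star_option`, a scorer function
#'   returning a `responder` column, the name of a logical/0-1 column of
#'   `data`, or a logical vector.
#' @param covariates Character vector of >= 2 baseline covariate columns.
#' @param k_folds Cross-fitting folds (default 10).
#' @param n_trees Bagged trees per fold (default 500).
#' @param min_node Minimum terminal node size in the bagged trees.
#' @param seed Integer seed making the fit reproducible.
#' @return A `star_twins` tibble: `patient_id`, `arm`, `y`, `p1`, `p0`,
#'   `z`, plus the covariate columns; patients whose response is
#'   undeterminable are dropped and counted in `attr(, "n_dropped")`.
#' @export
fit_twins <- function(data, response, covariates, k_folds = 10,
                      n_trees = 500, min_node = 5, seed = NULL) {
  if (length(covariates) < 2) {
    abort("need at least 2 covariates", class = "sjstar_validation_error")
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    abort(sprintf("covariates not in data: %s", paste(missing_cov, collapse = ", ")),
          class = "sjstar_validation_error")
  }
  y <- resolve_response(data, response)
  keep <- !is.na(y) & complete.cases(data[covariates])
  n_dropped <- sum(!keep)
  df <- tibble(
    patient_id = if ("patient_id" %in% names(data)) data$patient_id[keep]
                 else as.character(seq_len(sum(keep))),
    arm = factor(data$arm[keep], levels = c("placebo", "treatment")),
    y = factor(as.integer(y[keep]), levels = c(0, 1)))
  df <- dplyr::bind_cols(df, as_tibble(data[keep, covariates]))
  if (dplyr::n_distinct(df$y) < 2) {
    abort("response is constant; cannot fit twins", class = "sjstar_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(df)
  k_folds <- min(k_folds, n)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  p1 <- p0 <- rep(NA_real_, n)
  feats <- c("arm", covariates)
  for (kk in seq_len(k_folds)) {
    tr <- fold != kk
    fit <- randomForest::randomForest(
      x = as.data.frame(df[tr, feats]), y = df$y[tr],
      ntree = n_trees, mtry = length(feats), nodesize = min_node)
    test <- as.data.frame(df[!tr, feats])
    test$arm <- factor("treatment", levels = levels(df$arm))
    p1[!tr] <- predict(fit, test, type = "prob")[, "1"]
    test$arm <- factor("placebo", levels = levels(df$arm))
    p0[!tr] <- predict(fit, test, type = "prob")[, "1"]
  }
  df$y <- as.integer(as.character(df$y))
  df$arm <- as.character(df$arm)
  out <- dplyr::bind_cols(df[c("patient_id", "arm", "y")],
                          tibble(p1 = p1, p0 = p0, z = p1 - p0),
                          df[covariates])
  structure(out, class = c("star_twins", class(out)),
            covariates = covariates, n_dropped = n_dropped)
}

resolve_response <- function(data, response) {
  if (inherits(response, "star_option")) {
    res <- score_option(data, response)
    y <- res$responder
    y[res$n_undetermined == 5] <- NA
    y
  } else if (is.function(response)) {
    response(data)$responder
  } else if (is.character(response) && length(response) == 1) {
    as.logical(data[[response]])
  } else {
    as.logical(response)
  }
}

#' Partition estimated treatment effects with a regression tree
#'
#' Stage two: a regression tree on `z` over the baseline covariates. Every
#' node other than the root is a candidate responder subset ("a branch");
#' for each, the observed relative risk of response (treatment vs placebo)
#' inside the subgroup is reported next to the optimism-corrected estimate
#' `mean(p1)/mean(p0)` built from the cross-fitted probabilities.
#'
#' @param twins A [fit_twins()] result.
#' @param covariates Covariates to split on (default: those used in the fit).
#' @param min_leaf Minimum patients per leaf (default 60, the sample-size
#'   criterion used for subset selection).
#' @param cp Complexity parameter passed to \pkg{rpart}.
#' @return A `star_vt_tree`: the fitted tree plus a `subgroups` tibble
#'   (`node`, `rule`, `n`, `rr_subgroup`, `optimism_corrected_rr`,
#'   `rr_overall`).
#' @export
grow_tree <- function(twins, covariates = attr(twins, "covariates"),
                      min_leaf = 60, cp = 0.01) {
  if (min_leaf < 1) abort("min_leaf must be >= 1", class = "sjstar_validation_error")
  df <- as.data.frame(twins[c("z", covariates)])
  fit <- rpart::rpart(z ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        minbucket = min_leaf, minsplit = 2 * min_leaf,
                        cp = cp, xval = 0, maxcompete = 0, maxsurrogate = 0))
  # with zero root deviance rpart accepts zero-improvement splits; a
  # constant surface has no subgroups
  if (var(df$z) < 1e-12) fit <- rpart::prune(fit, cp = Inf)
  nodes <- as.integer(rownames(fit$frame))
  leaf_of_row <- nodes[fit$where]
  rr_overall <- observed_rr(twins)
  subgroup_rows <- setdiff(nodes, 1L)
  subgroups <- purrr::map_dfr(subgroup_rows, function(nd) {
    inside <- vapply(leaf_of_row, node_is_descendant, logical(1), ancestor = nd)
    tibble(
      node = nd,
      rule = node_rule(fit, nd),
      n = sum(inside),
      rr_subgroup = observed_rr(twins[inside, ]),
      optimism_corrected_rr = mean(twins$p1[inside]) / mean(twins$p0[inside]),
      rr_overall = rr_overall)
  })
  if (nrow(subgroups) == 0) {
    subgroups <- tibble(node = integer(), rule = character(), n = integer(),
                        rr_subgroup = double(), optimism_corrected_rr = double(),
                        rr_overall = double())
  }
  structure(list(tree = fit, subgroups = subgroups, twins = twins,
                 min_leaf = min_leaf),
            class = "star_vt_tree")
}

node_is_descendant <- function(node, ancestor) {
  while (node >= ancestor) {
    if (node == ancestor) return(TRUE)
    node <- node %/% 2L
  }
  FALSE
}

node_rule <- function(fit, node) {
  pth <- rpart::path.rpart(fit, nodes = node, print.it = FALSE)[[1]]
  paste(pth[-1], collapse = " & ")
}

observed_rr <- function(twins) {
  t_ <- twins$arm == "treatment"
  if (!any(t_) || all(t_)) return(NA_real_)
  pt_ <- mean(twins$y[t_]); pp <- mean(twins$y[!t_])
  if (pp == 0) return(NA_real_)  # undefined: zero placebo responders
  pt_ / pp
}

#' @export
print.star_vt_tree <- function(x, ...) {
  cat(sprintf("<star_vt_tree> %d candidate subgroup(s), min_leaf = %d\n",
              nrow(x$subgroups), x$min_leaf))
  if (nrow(x$subgroups)) print(x$subgroups)
  invisible(x)
}

#' Select enhanced-response subsets
#'
#' A subset is selected when its optimism-corrected relative risk is at
#' least `rr_ratio_min` times the whole-population relative risk ("notably
#' higher") and it contains at least `n_min` patients (default 60, for
#' statistical power). The multiplier quantifying "notably higher" is a
#' package choice; no published value exists.
#'
#' @param vt_tree A [grow_tree()] result.
#' @param rr_ratio_min Multiplier over the overall relative risk.
#' @param n_min Minimum subgroup size.
#' @return The `subgroups` tibble with a logical `selected` column and
#'   `ratio_criterion_applied` (`FALSE` when the overall RR is undefined —
#'   zero placebo responders — in which case no subset is selected on the
#'   ratio ground).
#' @export
select_subsets <- function(vt_tree, rr_ratio_min = 1.5, n_min = 60) {
  sg <- vt_tree$subgroups
  ratio_ok <- is.finite(sg$rr_overall) & sg$rr_overall > 0
  sg$ratio_criterion_applied <- ratio_ok
  sg$selected <- ratio_ok &
    !is.na(sg$optimism_corrected_rr) &
    sg$optimism_corrected_rr >= rr_ratio_min * sg$rr_overall &
    sg$n >= n_min
  sg
}
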