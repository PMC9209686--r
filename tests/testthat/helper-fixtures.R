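# Minimal hand-built trial table: values chosen so that responder status is
# known by inspection of the domain rules.
tiny_trial <- function() {
  trial_dataset(tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    arm = c("treatment", "treatment", "placebo", "placebo"),
    clin_essdai_base = c(8, 8, 10, NA), clin_essdai_fu = c(5, 6, 10, 4),
    esspri_base = c(8, 8, 6, 5),        esspri_fu = c(7, 7.2, 6, 5),
    schirmer_base = c(3, 10, 10, 2),    schirmer_fu = c(8, 3, 6, 2),
    oss_base = c(6, NA, 6, NA),         oss_fu = c(4, NA, 5, NA),
    uwsf_base = c(0.2, 0, 0.1, 0),      uwsf_fu = c(0.25, 0, 0.1, 0),
    hocevar_base = c(20, 20, 0, NA),    hocevar_fu = c(15, 16, 0, NA),
    igg_base = c(15, NA, 14, NA),       igg_fu = c(13.5, NA, 14, NA),
    rf_base = c(NA, 40, 0, NA),         rf_fu = c(NA, 30, 0, NA),
    age = c(50, 61, 47, 55)
  ), trial_id = "tiny", expert_class = "positive")
}

# A two-arm dataset with a planted treatment-effect subgroup on x1 > 0:
# response probability 0.3 everywhere except treated patients with x1 > 0,
# where it is 0.3 + delta.
planted_vt_data <- function(n = 400, delta = 0.4, seed = 1) {
  set.seed(seed)
  dat <- tibble::tibble(
    patient_id = as.character(seq_len(n)),
    arm = sample(rep(c("treatment", "placebo"), length.out = n)),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  p <- ifelse(dat$arm == "treatment" & dat$x1 > 0, 0.3 + delta, 0.3)
  dat$y <- runif(n) < p
  dat
}

# Fake twins object (bypasses the learner) for tree-contract tests.
fake_twins <- function(z, covs, arm = NULL, y = NULL, p1 = NULL, p0 = NULL) {
  n <- length(z)
  out <- tibble::tibble(
    patient_id = as.character(seq_len(n)),
    arm = arm %||% rep(c("treatment", "placebo"), length.out = n),
    y = y %||% rep(c(1L, 0L), length.out = n),
    p1 = p1 %||% rep(0.5, n), p0 = p0 %||% rep(0.4, n), z = z)
  out <- dplyr::bind_cols(out, covs)
  structure(out, class = c("star_twins", class(out)),
            covariates = names(covs), n_dropped = 0L)
}

`%||%` <- rlang::`%||%`
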