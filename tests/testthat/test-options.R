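majors_and_minors <- function(...) {
  pat <- tibble::tibble(systemic = FALSE, pro = FALSE, lachrymal = FALSE,
                        salivary = FALSE, biological = FALSE)
  for (d in c(...)) pat[[d]] <- TRUE
  pat
}

test_that("domain-count designs honour their major-domain clauses", {
  p_major <- majors_and_minors("pro", "lachrymal", "salivary")
  p_minor <- majors_and_minors("lachrymal", "salivary", "biological")
  expect_true(score_patterns(p_major, option_spec("design_3a"))$responder)
  expect_false(score_patterns(p_minor, option_spec("design_3a"))$responder)
  expect_true(score_patterns(p_minor, option_spec("cress_like"))$responder)
  # point-sum thresholds: systemic + pro = 6 points
  p_majors <- majors_and_minors("systemic", "pro")
  expect_true(score_patterns(p_majors, option_spec("design_3b_binary", 6))$responder)
  expect_false(score_patterns(p_majors, option_spec("design_3b_binary", 7))$responder)
  expect_equal(score_patterns(p_majors, option_spec("design_3b_continuous"))$score, 6L)
})

test_that("the candidate STAR option and score_star agree record for record", {
  trials <- simulate_suite(default_suite()[c(1, 3, 5), ], seed = 42)
  for (tr in trials) {
    a <- score_star(tr)
    b <- score_option(tr, candidate_star_spec())
    expect_identical(a$responder, b$responder)
    expect_identical(a$n_undetermined, b$n_undetermined)
  }
  expect_equal(candidate_star_spec()$threshold, 5L)
})

test_that("point-sum responder sets shrink as the threshold rises", {
  tr <- simulate_trial(sim_config(n = 150, seed = 9), trial_id = "mono")
  prev <- rep(TRUE, 150)
  for (th in 4:9) {
    cur <- score_option(tr, option_spec("design_3b_binary", th))$responder
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("design 3A responders are always CRESS-like responders, never the reverse", {
  pat <- response_patterns()
  r3a <- score_patterns(pat, option_spec("design_3a"))$responder
  rcress <- score_patterns(pat, option_spec("cress_like"))$responder
  expect_true(all(!r3a | rcress))
  expect_true(any(rcress & !r3a))
})

test_that("SRI-like designs apply the no-worsening clause", {
  base <- tibble::tibble(
    patient_id = c("w", "ok"), arm = c("treatment", "placebo"),
    clin_essdai_base = c(8, 8), clin_essdai_fu = c(4, 4),   # major improves
    esspri_base = c(5, 5), esspri_fu = c(6.5, 5.4),          # w: worsens >= 1 pt
    schirmer_base = NA_real_, schirmer_fu = NA_real_,
    oss_base = NA_real_, oss_fu = NA_real_,
    uwsf_base = NA_real_, uwsf_fu = NA_real_,
    hocevar_base = NA_real_, hocevar_fu = NA_real_,
    igg_base = NA_real_, igg_fu = NA_real_,
    rf_base = NA_real_, rf_fu = NA_real_)
  res <- score_option(base, option_spec("sri_two_major"))
  expect_false(res$responder[1])  # PRO worsened
  expect_true(res$responder[2])   # undetermined/stable domains do not block
  res1 <- score_option(base, option_spec("sri_one_major", major_domains = "systemic"))
  expect_false(res1$responder[1])
  expect_true(res1$responder[2])
})

test_that("ACR-like uniform percent rules respond at the configured depth", {
  rec <- tibble::tibble(
    patient_id = "a", arm = "treatment",
    clin_essdai_base = 10, clin_essdai_fu = 7,    # -30%
    esspri_base = 8, esspri_fu = 5.6,             # -30%
    uwsf_base = 0.2, uwsf_fu = 0.27,              # +35%
    schirmer_base = NA_real_, schirmer_fu = NA_real_,
    oss_base = NA_real_, oss_fu = NA_real_,
    hocevar_base = NA_real_, hocevar_fu = NA_real_,
    igg_base = NA_real_, igg_fu = NA_real_,
    rf_base = NA_real_, rf_fu = NA_real_)
  expect_true(score_option(rec, option_spec("acr_like", acr_percent = 30))$responder)
  expect_false(score_option(rec, option_spec("acr_like", acr_percent = 40))$responder)
})

test_that("option enumeration expands grids with unique ids", {
  grid <- enumerate_options(list(design_3b_binary = list(thresholds = 4:9)))
  expect_equal(nrow(grid), 6L)
  grid2 <- enumerate_options(list(acr_like = list(percents = seq(10, 70, 10))))
  expect_equal(nrow(grid2), 7L)
  expect_false(anyDuplicated(grid2$option_id) > 0)
  expect_error(enumerate_options(list()), class = "sjstar_config_error")
})

test_that("mismatched design parameters are configuration errors", {
  expect_error(option_spec("design_3a", acr_percent = 30), class = "sjstar_config_error")
  expect_error(option_spec("cress_like", threshold = 5), class = "sjstar_config_error")
  expect_error(option_spec("design_3b_binary", threshold = 3), class = "sjstar_validation_error")
  expect_error(option_spec("sri_one_major", major_domains = c("systemic", "pro")),
               class = "sjstar_config_error")
})
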