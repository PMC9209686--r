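tri <- function(x) as.character(x)

test_that("systemic rule: decrease of >= 3 clinESSDAI points, inclusive", {
  expect_equal(tri(systemic_response(c(8, 8, NA), c(5, 6, 5))),
               c("yes", "no", "undetermined"))
  expect_equal(tri(systemic_response(3, 0)), "yes")
  expect_error(systemic_response(-1, 0), class = "sjstar_validation_error")
})

test_that("PRO rule: >= 1 point or >= 15% ESSPRI decrease", {
  expect_equal(tri(pro_response(c(8, 2, 8), c(7, 1.6, 7.2))), c("yes", "yes", "no"))
  # baseline 0 cannot improve and the percent branch must not divide by zero
  expect_equal(tri(pro_response(0, 0)), "no")
  expect_error(pro_response(11, 5), class = "sjstar_validation_error")
})

test_that("Schirmer rule: abnormal < 5 mm; +5 mm if abnormal, stay normal otherwise", {
  expect_equal(tri(schirmer_response(c(3, 10, 10, 3), c(8, 6, 3, 7))),
               c("yes", "yes", "no", "no"))
  expect_equal(schirmer_abnormal(c(4.9, 5)), c(TRUE, FALSE))
})

test_that("OSS rule: abnormal >= 3; -2 points if abnormal, stay normal otherwise", {
  expect_equal(tri(oss_response(c(6, 2, 6, 2), c(4, 2, 5, 3))),
               c("yes", "yes", "no", "no"))
  expect_equal(oss_abnormal(c(2, 3)), c(FALSE, TRUE))
})

test_that("salivary flow rule: +25% if baseline positive, any increase from zero", {
  expect_equal(tri(uwsf_response(c(0.20, 0, 0, 0.20), c(0.25, 0.01, 0, 0.24))),
               c("yes", "yes", "no", "no"))
})

test_that("ultrasound rule: -25% Hocevar; zero baseline cannot respond", {
  expect_equal(tri(ultrasound_response(c(20, 20, 0), c(15, 16, 0))),
               c("yes", "no", "no"))
})

test_that("biological rule: IgG -10% or RF -25%, undetermined only without any pair", {
  expect_equal(tri(biological_response(15, 13.5, NA, NA)), "yes")
  expect_equal(tri(biological_response(NA, NA, 40, 30)), "yes")
  expect_equal(tri(biological_response(NA, NA, NA, NA)), "undetermined")
  # an available non-responding pair makes the domain "no", not undetermined
  expect_equal(tri(biological_response(15, 14.9, NA, NA)), "no")
  # RF baseline 0 cannot decrease 25%
  expect_equal(tri(biological_response(NA, NA, 0, 0)), "no")
  expect_error(biological_response(0, 10, NA, NA), class = "sjstar_validation_error")
})

test_that("domain 'or' is symmetric in which instrument triggers it", {
  a <- tibble::tibble(patient_id = "a", arm = "treatment",
                      schirmer_base = 3, schirmer_fu = 9, oss_base = 6, oss_fu = 6)
  b <- tibble::tibble(patient_id = "b", arm = "treatment",
                      schirmer_base = 10, schirmer_fu = 3, oss_base = 6, oss_fu = 3)
  pad <- function(d) {
    for (col in setdiff(measure_cols <- sjstar:::measurement_columns(), names(d)))
      d[[col]] <- NA_real_
    d
  }
  da <- domain_responses(pad(a)); db <- domain_responses(pad(b))
  expect_equal(as.character(da$lachrymal), "yes")
  expect_equal(as.character(db$lachrymal), "yes")
})

test_that("score_star totals, responder threshold and undetermined accounting", {
  res <- score_star(tiny_trial())
  # p1: systemic yes (8->5), pro yes (8->7), lachrymal yes (3->8),
  #     salivary yes (0.2->0.25 = +25%), biological yes (15->13.5 = -10%)
  expect_equal(res$total_points[1], 9L)
  expect_true(res$responder[1])
  # p2: systemic no (dec 2), pro no (0.8 pt, 10%), lachrymal no (10->3),
  #     salivary no (uwsf 0->0, hocevar -20%), biological yes (RF -25%)
  expect_equal(res$total_points[2], 1L)
  expect_false(res$responder[2])
  # p4: clinESSDAI baseline missing -> systemic undetermined
  expect_equal(as.character(res$systemic[4]), "undetermined")
  expect_equal(res$n_undetermined[4], 2L)
  expect_equal(res$total_points[4], 0L)
})

test_that("exhaustive 32-pattern enumeration: responders need >= 5 points and a major domain", {
  pat <- score_patterns(response_patterns(), candidate_star_spec())
  expect_equal(nrow(pat), 32L)
  expect_equal(min(pat$total_points[pat$responder]), 5L)
  expect_true(all(pat$systemic[pat$responder] | pat$pro[pat$responder]))
  # monotonicity: flipping any domain to TRUE never loses responder status
  for (i in which(pat$responder)) {
    for (d in c("systemic", "pro", "lachrymal", "salivary", "biological")) {
      up <- pat[i, ]
      up[[d]] <- TRUE
      expect_true(score_patterns(up[1:5], candidate_star_spec())$responder)
    }
  }
})

test_that("score_trial conserves counts and bounds rates", {
  tr <- simulate_trial(sim_config(n = 60, seed = 2), trial_id = "s")
  tab <- score_trial(tr)
  expect_equal(sum(tab$n), 60L)
  expect_true(all(tab$rate >= 0 & tab$rate <= 1))
  expect_true(all(tab$responders <= tab$n_scored))

  all_resp <- trial_dataset(tibble::tibble(
    patient_id = c("a", "b"), arm = c("treatment", "placebo"),
    clin_essdai_base = 8, clin_essdai_fu = 2,
    esspri_base = 8, esspri_fu = 5), "all")
  expect_equal(score_trial(all_resp)$rate, c(1, 1))
})
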