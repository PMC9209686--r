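test_that("single-study odds ratios, with and without the zero-cell correction", {
  m <- pool_binary(tibble::tibble(events_t = 10, n_t = 20, events_p = 5, n_p = 20))
  expect_equal(exp(m$pooled), 3)
  expect_equal(m$tau2, 0)
  expect_equal(m$k, 1L)

  mz <- pool_binary(tibble::tibble(events_t = 0, n_t = 10, events_p = 5, n_p = 10))
  expect_equal(exp(mz$pooled), (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("Paule-Mandel tau2 solves its moment equation and matches a grid-search oracle", {
  eff <- c(0, 2); v <- c(1, 1)
  pm <- paule_mandel_tau2(eff, v)
  # oracle: brute-force grid search over tau2
  grid <- seq(0, 10, by = 1e-4)
  qv <- vapply(grid, function(t2) sjstar:::generalised_q(eff, v, t2), numeric(1))
  oracle <- grid[which.min(abs(qv - 1))]
  expect_equal(pm$tau2, oracle, tolerance = 1e-3)
  expect_equal(sjstar:::generalised_q(eff, v, pm$tau2), 1, tolerance = 1e-6)
  expect_true(pm$converged)

  expect_equal(paule_mandel_tau2(c(1, 1, 1), c(0.5, 0.5, 0.5))$tau2, 0)
  expect_error(paule_mandel_tau2(c(0, 1), c(1, 0)), class = "sjstar_validation_error")

  set.seed(3)
  for (i in 1:10) {
    y <- rnorm(6, sd = 1.5); vv <- runif(6, 0.1, 0.6)
    expect_gte(paule_mandel_tau2(y, vv)$tau2, 0)
  }
})

test_that("PM and the random-effects pooling agree with metafor", {
  skip_if_not_installed("metafor")
  at <- c(10, 8, 12, 3); nt <- c(20, 25, 30, 15)
  ap <- c(5, 6, 4, 6); np <- c(20, 25, 30, 15)
  m <- pool_binary(tibble::tibble(events_t = at, n_t = nt, events_p = ap, n_p = np))
  r <- metafor::rma(measure = "OR", ai = at, n1i = nt, ci = ap,
                    n2i = np, method = "PM")
  # two independent iterative PM solvers: agree to their joint tolerance
  expect_equal(m$tau2, r$tau2, tolerance = 1e-4)
  expect_equal(m$pooled, as.numeric(r$beta), tolerance = 1e-4)
  expect_equal(m$ci_low, r$ci.lb, tolerance = 1e-4)
  rmh <- metafor::rma.mh(measure = "OR", ai = at, n1i = nt, ci = ap, n2i = np,
                         add = 0, to = "none")
  expect_equal(m$fixed$estimate, as.numeric(rmh$beta), tolerance = 1e-8)
  ci <- confint(r)
  expect_equal(unname(m$tau2_ci[1]), ci$random["tau^2", "ci.lb"], tolerance = 1e-6)
  expect_equal(unname(m$tau2_ci[2]), ci$random["tau^2", "ci.ub"], tolerance = 1e-6)
})

test_that("Q-profile bounds satisfy their defining chi-square equations", {
  set.seed(5)
  y <- rnorm(7, sd = 1.2); v <- runif(7, 0.1, 0.5)
  ci <- q_profile_ci(y, v)
  t2 <- unlist(ci[ci$parameter == "tau2", c("ci_low", "ci_high")])
  if (t2[1] > 0) {
    expect_equal(sjstar:::generalised_q(y, v, t2[1]), qchisq(0.975, 6), tolerance = 1e-6)
  }
  expect_equal(sjstar:::generalised_q(y, v, t2[2]), qchisq(0.025, 6), tolerance = 1e-6)
  tau <- unlist(ci[ci$parameter == "tau", c("ci_low", "ci_high")])
  expect_equal(tau, sqrt(t2), ignore_attr = TRUE)

  # homogeneous data: lower bound truncated at zero
  hom <- q_profile_ci(rep(1, 10) + rnorm(10, sd = 0.01), rep(1, 10))
  expect_equal(hom$ci_low[hom$parameter == "tau2"], 0)
})

test_that("continuous pooling uses Hedges' g and matches metafor SMD", {
  st <- tibble::tibble(mean_t = c(1, 0.8), sd_t = c(1, 1.1), n_t = c(50, 40),
                       mean_p = c(0, 0.1), sd_p = c(1, 0.9), n_p = c(50, 40))
  m <- pool_continuous(st)
  expect_equal(m$studies$yi[1], (1 - 3 / (4 * 98 - 1)) * 1, tolerance = 1e-6)
  skip_if_not_installed("metafor")
  es <- metafor::escalc(measure = "SMD", m1i = st$mean_t, sd1i = st$sd_t,
                        n1i = st$n_t, m2i = st$mean_p, sd2i = st$sd_p, n2i = st$n_p)
  # metafor uses the exact gamma-function J; ours is the 1 - 3/(4 df - 1)
  # approximation, so agreement is to ~1e-5
  expect_equal(m$studies$yi, as.numeric(es$yi), tolerance = 1e-4)
  expect_equal(m$studies$vi, as.numeric(es$vi), tolerance = 1e-4)
  r <- metafor::rma(yi, vi, data = es, method = "PM")
  expect_equal(m$pooled, as.numeric(r$beta), tolerance = 1e-4)
})

test_that("identical studies pool to the single-study effect with tau2 = 0", {
  one <- tibble::tibble(events_t = 10, n_t = 20, events_p = 5, n_p = 20)
  many <- one[rep(1, 5), ]
  m1 <- pool_binary(one); m5 <- pool_binary(many)
  expect_equal(m5$pooled, m1$pooled)
  expect_equal(m5$tau2, 0)
  # duplicating studies narrows the CI around the same estimate
  expect_lt(m5$ci_high - m5$ci_low, m1$ci_high - m1$ci_low)
})

test_that("the random-effects pooled estimate stays inside the study hull", {
  set.seed(6)
  for (i in 1:10) {
    y <- rnorm(5); v <- runif(5, 0.05, 0.5)
    st <- tibble::tibble(mean_t = y, sd_t = 1, n_t = 40, mean_p = 0, sd_p = 1, n_p = 40)
    m <- pool_continuous(st)
    expect_gte(m$pooled, min(m$studies$yi) - 1e-12)
    expect_lte(m$pooled, max(m$studies$yi) + 1e-12)
    expect_equal(sum(m$studies$weight), 1)
  }
})

test_that("meta input validation", {
  expect_error(pool_binary(tibble::tibble()), class = "sjstar_validation_error")
  expect_error(pool_binary(tibble::tibble(events_t = 1, n_t = 0, events_p = 0, n_p = 5)),
               class = "sjstar_validation_error")
  expect_error(pool_continuous(tibble::tibble(mean_t = 1, sd_t = 0, n_t = 10,
                                              mean_p = 0, sd_p = 0, n_p = 10)),
               class = "sjstar_validation_error")
  expect_error(q_profile_ci(1, 1), class = "sjstar_validation_error")
})

test_that("tidy/glance/autoplot expose the meta-analysis", {
  m <- pool_binary(tibble::tibble(events_t = c(10, 8), n_t = c(20, 25),
                                  events_p = c(5, 6), n_p = c(20, 25),
                                  study = c("a", "b")))
  td <- tidy(m)
  expect_equal(td$study, c("a", "b"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(m)
  expect_equal(gl$or, exp(gl$estimate))
  expect_s3_class(autoplot(m), "ggplot")
})
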