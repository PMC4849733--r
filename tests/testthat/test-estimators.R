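test_that("ratio estimates divide, sort and weight as an element-wise loop", {
  d <- mr_data(c("a", "b"), beta_exposure = c(0.1, 0.1), se_exposure = 0.01,
               beta_outcome = c(0.2, 0.4), se_outcome = c(0.05, 0.05))
  expect_equal(ratio_estimates(d)$beta, c(2, 4))

  # proportional outcome associations give a constant ratio
  dp <- random_dataset(12, seed = 1, slope = 0.1)
  dp$beta_outcome <- 0.1 * dp$beta_exposure
  expect_equal(ratio_estimates(dp)$beta, rep(0.1, 12))

  # independent element-wise oracle for all three weight schemes
  dr <- random_dataset(10, seed = 2)
  for (scheme in c("inverse_variance", "inverse_se", "equal")) {
    r <- ratio_estimates(dr, scheme)
    exp_beta <- exp_w <- numeric(10)
    for (i in 1:10) {
      exp_beta[i] <- dr$beta_outcome[i] / dr$beta_exposure[i]
      exp_w[i] <- switch(scheme,
        inverse_variance = dr$beta_exposure[i]^2 / dr$se_outcome[i]^2,
        inverse_se = abs(dr$beta_exposure[i]) / dr$se_outcome[i],
        equal = 1)
    }
    o <- order(exp_beta)
    expect_equal(r$beta, exp_beta[o])
    expect_equal(r$weight, exp_w[o])
    expect_identical(r$variant_id, dr$variant_id[o])
  }

  dz <- dr
  dz$beta_exposure[4] <- 0
  expect_error(ratio_estimates(dz), dr$variant_id[4])
})

test_that("percentile anchors reproduce the worked weighting examples", {
  expect_equal(percentiles_of(table1_weights$equal),
               c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95))
  expect_equal(round(percentiles_of(table1_weights$weighting1), 2),
               c(1.67, 6.67, 15.00, 26.67, 41.67, 58.33, 73.33, 85.00,
                 93.33, 98.33))
  expect_equal(round(percentiles_of(table1_weights$weighting2), 2),
               c(2.78, 9.72, 27.78, 52.78, 70.83, 81.94, 88.89, 93.06,
                 95.83, 98.61))
})

test_that("weighted empirical CDF invariants hold on random weight sets", {
  for (seed in 1:25) {
    set.seed(seed)
    J <- sample(1:30, 1)
    cdf <- build_weighted_cdf(make_ratios(stats::rnorm(J),
                                          stats::runif(J, 0.1, 3)))
    expect_equal(sum(cdf$w), 1, tolerance = 1e-12)
    expect_equal(cdf$s[J], 1, tolerance = 1e-12)
    expect_true(all(diff(cdf$p) > 0))
    expect_gt(cdf$p[1], 0)
    expect_lt(cdf$p[J], 100)
    expect_equal(cdf$p, 100 * (cdf$s - cdf$w / 2), tolerance = 1e-12)
  }
  expect_error(build_weighted_cdf(make_ratios(1:2, c(1, -1))), "positive")
})

test_that("weighted median interpolates the 50th percentile as displayed", {
  beta <- c(0.4, 0.9, 1.3, 1.8, 2.3, 3.1, 3.8, 4.4, 5.2, 6.0)
  # symmetric weighting collapses to the simple median
  expect_equal(weighted_median(build_weighted_cdf(
    make_ratios(beta, table1_weights$weighting1))),
    simple_median(make_ratios(beta, rep(1, 10))))
  # the second weighting interpolates between the 3rd and 4th estimates,
  # landing nearer the 4th whose anchor is closest to 50
  p <- percentiles_of(table1_weights$weighting2, beta)
  wm <- weighted_median(build_weighted_cdf(
    make_ratios(beta, table1_weights$weighting2)))
  expect_equal(wm, beta[3] + (beta[4] - beta[3]) * (50 - p[3]) / (p[4] - p[3]))
  expect_gt(wm, mean(beta[3:4]))
  expect_lt(wm, beta[4])
  # equal weights, odd J: the middle estimate, exactly
  expect_identical(weighted_median(build_weighted_cdf(
    make_ratios(beta[1:9], rep(1, 9)))), beta[5])
  # a single variant is its own median; dominant weight warns
  expect_identical(
    suppressWarnings(weighted_median(build_weighted_cdf(make_ratios(2.5, 3)))),
    2.5)
  expect_warning(weighted_median(build_weighted_cdf(
    make_ratios(c(1, 2, 3), c(8, 1, 1)))), "50%")
})

test_that("simple median equals the sort-and-pick oracle for odd and even J", {
  expect_equal(simple_median(make_ratios(c(1, 2, 10), rep(1, 3))), 2)
  expect_equal(simple_median(make_ratios(c(1, 3), rep(1, 2))), 2)
  for (seed in 1:50) {
    set.seed(seed)
    J <- sample(1:40, 1)
    b <- stats::rnorm(J)
    r <- make_ratios(b, stats::runif(J, 0.5, 2))
    s <- sort(b)
    oracle <- if (J %% 2 == 1) s[(J + 1) / 2]
              else (s[J / 2] + s[J / 2 + 1]) / 2
    expect_equal(simple_median(r), oracle, tolerance = 1e-14)
    # equal-weight weighted median is the same number, exactly
    expect_identical(
      suppressWarnings(weighted_median(build_weighted_cdf(
        make_ratios(b, rep(1, J))))),
      simple_median(r))
  }
})

test_that("weighted median agrees with the pseudopopulation within its step", {
  # the copies-median is a step function over the ordered estimates: it must
  # be (one of) the estimates bracketing the interpolated weighted median,
  # never further than their gap, and exact under equal weights
  for (seed in 1:100) {
    set.seed(seed)
    J <- sample(3:25, 1)
    b <- sort(stats::rnorm(J))
    w <- stats::runif(J, 0.2, 2)
    cdf <- build_weighted_cdf(make_ratios(b, w))
    wm <- suppressWarnings(weighted_median(cdf))
    ps <- pseudo_median(cdf$beta, cdf$w, copies = 1e5)
    k <- findInterval(50, cdf$p)
    lo <- cdf$beta[max(k, 1)]
    hi <- cdf$beta[min(k + 1, J)]
    expect_gte(ps, lo - 1e-12)
    expect_lte(ps, hi + 1e-12)
    expect_lte(abs(wm - ps), hi - lo + 1e-12)
  }
  set.seed(99)
  b <- stats::rnorm(15)
  expect_equal(pseudo_median(sort(b), rep(1 / 15, 15), copies = 1e5),
               simple_median(make_ratios(b, rep(1, 15))))
})

test_that("IVW is the weighted mean with fixed-effect meta-analysis SE", {
  one <- mr_data("a", beta_exposure = 0.08, se_exposure = 0.01,
                 beta_outcome = 0.02, se_outcome = 0.01)
  expect_equal(mr_ivw(one)$estimate, 0.25)
  expect_equal(mr_ivw(one)$se, 0.01 / 0.08)

  dp <- random_dataset(7, seed = 3)
  dp$beta_outcome <- 0.3 * dp$beta_exposure
  expect_equal(mr_ivw(dp)$estimate, 0.3, tolerance = 1e-12)

  d <- random_dataset(5, seed = 4)
  num <- den <- 0
  for (i in 1:5) {
    w <- d$beta_exposure[i]^2 / d$se_outcome[i]^2
    num <- num + w * d$beta_outcome[i] / d$beta_exposure[i]
    den <- den + w
  }
  e <- mr_ivw(d)
  expect_equal(e$estimate, num / den, tolerance = 1e-12)
  expect_equal(e$se, sqrt(1 / den), tolerance = 1e-12)
  expect_equal(e$ci_upper - e$estimate, 1.959964 * e$se)
  expect_equal(e$p_value, 2 * stats::pnorm(-abs(e$estimate / e$se)))

  # multiplicative random effects only ever inflates the SE
  dh <- random_dataset(10, seed = 5, pleio_sd = 3)
  expect_gt(mr_ivw(dh, random_effects = TRUE)$se, mr_ivw(dh)$se)
  q <- cochran_q(dh)
  expect_equal(mr_ivw(dh, random_effects = TRUE)$se,
               mr_ivw(dh)$se * sqrt(q$Q / q$df), tolerance = 1e-12)
})

test_that("MR-Egger matches weighted least squares and collapses to IVW", {
  d <- random_dataset(10, seed = 6, slope = 0.2, pleio_sd = 0.5)

  # independent oracle: stats::lm with inverse-variance weights on the
  # reoriented associations
  flip <- d$beta_exposure < 0
  gx <- abs(d$beta_exposure)
  gy <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  ml <- stats::lm(gy ~ gx, weights = 1 / d$se_outcome^2)
  sm <- summary(ml)
  e <- mr_egger(d)
  expect_equal(e$estimate, unname(stats::coef(ml))[2], tolerance = 1e-10)
  expect_equal(e$se, sm$coefficients["gx", "Std. Error"], tolerance = 1e-10)
  expect_equal(e$extras$egger_intercept, unname(stats::coef(ml))[1],
               tolerance = 1e-10)
  expect_equal(e$extras$egger_intercept_se,
               sm$coefficients["(Intercept)", "Std. Error"],
               tolerance = 1e-10)

  # no intercept -> the IVW estimate
  expect_equal(mr_egger(d, intercept = FALSE)$estimate, mr_ivw(d)$estimate,
               tolerance = 1e-10)

  # reorientation invariance: flipping any subset of variants changes nothing
  d2 <- d
  sel <- c(2, 5, 7)
  d2$beta_exposure[sel] <- -d2$beta_exposure[sel]
  d2$beta_outcome[sel] <- -d2$beta_outcome[sel]
  e2 <- mr_egger(d2)
  expect_equal(e2$estimate, e$estimate, tolerance = 1e-12)
  expect_equal(e2$extras$egger_intercept, e$extras$egger_intercept,
               tolerance = 1e-12)

  # exact linear data recover intercept and slope
  dl <- random_dataset(8, seed = 7, signed = FALSE)
  dl$beta_outcome <- 0.03 + 0.4 * dl$beta_exposure
  el <- mr_egger(dl)
  expect_equal(el$estimate, 0.4, tolerance = 1e-10)
  expect_equal(el$extras$egger_intercept, 0.03, tolerance = 1e-10)

  # identifiability and minimum-size errors
  deq <- mr_data(c("a", "b", "c"), beta_exposure = c(0.1, -0.1, 0.1),
                 se_exposure = 0.01, beta_outcome = c(0.01, 0.02, 0.015),
                 se_outcome = 0.005)
  expect_error(mr_egger(deq), "not identified")
  expect_error(mr_egger(d[1:2, ]), "at least 3")

  # flags: t intervals are wider than normal; unit dispersion rescales SE
  et <- mr_egger(d, ci_dist = "t")
  expect_gt(et$ci_upper - et$ci_lower, e$ci_upper - e$ci_lower)
  eu <- mr_egger(d, dispersion = "unit")
  expect_false(isTRUE(all.equal(eu$se, e$se)))
})

test_that("estimator family is bounded, scale-equivariant and
           weight-scale invariant", {
  for (seed in 1:40) {
    d <- random_dataset(sample(3:20, 1), seed = 100 + seed, pleio_sd = 1)
    r <- ratio_estimates(d)
    ests <- c(mr_ivw(d)$estimate,
              simple_median(r),
              suppressWarnings(weighted_median(d)),
              suppressWarnings(penalized_weighted_median(d)))
    expect_true(all(ests >= min(r$beta) - 1e-12))
    expect_true(all(ests <= max(r$beta) + 1e-12))
  }

  d <- random_dataset(12, seed = 8, pleio_sd = 0.5)
  cc <- 2.5
  ds <- d
  ds$beta_outcome <- cc * ds$beta_outcome
  ds$se_outcome <- cc * ds$se_outcome
  expect_equal(mr_ivw(ds)$estimate, cc * mr_ivw(d)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_ivw(ds)$se, cc * mr_ivw(d)$se, tolerance = 1e-12)
  expect_equal(mr_egger(ds)$estimate, cc * mr_egger(d)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(ds)$se, cc * mr_egger(d)$se, tolerance = 1e-12)
  expect_equal(suppressWarnings(weighted_median(ds)),
               cc * suppressWarnings(weighted_median(d)), tolerance = 1e-12)
  expect_equal(simple_median(ratio_estimates(ds, "equal")),
               cc * simple_median(ratio_estimates(d, "equal")),
               tolerance = 1e-12)

  r <- ratio_estimates(d)
  r10 <- r
  r10$weight <- 10 * r10$weight
  expect_equal(suppressWarnings(weighted_median(build_weighted_cdf(r10))),
               suppressWarnings(weighted_median(build_weighted_cdf(r))),
               tolerance = 1e-14)
  expect_equal(mr_ivw(r10)$estimate, mr_ivw(r)$estimate, tolerance = 1e-14)
})
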