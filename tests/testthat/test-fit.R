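test_that("QAICc follows the small-sample quasi-likelihood formula", {
  expect_equal(qaicc(100, 1, 5, 100), 200 + 10 + 60 / 94, tolerance = 1e-12)
  expect_equal(qaicc(100, 2, 5, 100), 100 + 10 + 60 / 94, tolerance = 1e-12)
  expect_equal(qaicc(87.3, 1.7, 0, 50), 2 * 87.3 / 1.7, tolerance = 1e-12)
  expect_error(qaicc(100, 1, 10, 11), "ess must exceed")
  # large-sample limit is (Q)AIC
  for (k in c(1, 5, 20))
    expect_equal(qaicc(500, 1, k, 1e9), 2 * 500 + 2 * k, tolerance = 1e-4)
})

test_that("Wald table reports |beta/SE| and 95% limits on the printed scale", {
  fake <- structure(list(
    beta = setNames(c(-0.011, 1.690, 0), c("distance", "hf_em", "null")),
    se = setNames(c(0.001, 0.256, 0.5), c("distance", "hf_em", "null"))),
    class = "ms_fit")
  w <- wald(fake)
  expect_equal(round(w$z, 3), c(11.000, 6.602, 0))
  expect_equal(round(w$lower[2], 3), 1.188)
  expect_equal(round(w$upper[2], 3), 2.192)
  expect_equal(w$lower[3], -w$upper[3])
})

test_that("a model with every parameter fixed is rejected", {
  h <- encounter_histories(rbind(c(1L, 1L), c(2L, 2L)), "adult",
                           strata = c("A", "B"), years = 2008:2009)
  fx <- expand.grid(class = c("phi", "p", "psi"), stratum = c("A", "B"),
                    stringsAsFactors = FALSE)
  fx$dest <- "*"; fx$year <- NA; fx$age <- "*"; fx$value <- 0.5
  expect_error(ms_fit(ms_spec(fixes = fx), h), "no free coefficients")
})

test_that("fitting the generating model recovers the truth at moderate scale", {
  sc <- study_scenario()
  dat <- simulate_histories(sc, cohort_sizes(total = 2600, scenario = sc),
                            seed = 314)
  f <- ms_fit(sc$generating_spec, dat$histories, dat$covariates,
              sc$distances)
  expect_true(f$converged)
  expect_true(all(is.finite(f$se)))
  b <- coef(f); s <- f$se
  truth <- c("psi:distance" = -0.011, "psi:hf_emigration" = 1.690,
             "psi:hf_immigration" = -2.279, "psi:posthf_immigration" = 1.010,
             "phi:hatch" = -0.031)
  for (nm in names(truth))
    expect_lt(abs(b[[nm]] - truth[[nm]]), 3 * s[[nm]])
  # back-transformed resight rates near their generating values
  pr <- predict(f, "p")
  adult <- pr$age == "adult"
  expect_equal(as.numeric(tapply(pr$estimate[adult], pr$sub[adult], mean)),
               c(0.64, 0.92, 0.88), tolerance = 0.06)
})

test_that("overdispersion scales variances but not point estimates", {
  sc <- study_scenario()
  dat <- simulate_histories(sc, cohort_sizes(total = 500, scenario = sc),
                            seed = 9)
  sp <- ms_spec(phi = "age", p = "sub", psi = "distance",
                fixes = standard_fixes())
  f1 <- ms_fit(sp, dat$histories, dat$covariates, sc$distances, chat = 1)
  f2 <- ms_fit(sp, dat$histories, dat$covariates, sc$distances, chat = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(f2$se, sqrt(2) * f1$se, tolerance = 1e-3)
  expect_lt(f2$qaicc, f1$qaicc)
})

test_that("simulated data from a fit keeps the release structure", {
  sc <- study_scenario()
  dat <- simulate_histories(sc, cohort_sizes(total = 400, scenario = sc),
                            seed = 21)
  f <- ms_fit(ms_spec(phi = "age", psi = "1"), dat$histories,
              dat$covariates, sc$distances)
  sim <- simulate(f, nsim = 2, seed = 5)
  expect_length(sim, 2)
  h0 <- dat$histories
  expect_equal(nrow(sim[[1]]$codes), sum(h0$frequency))
  first0 <- max.col(h0$codes > 0, ties.method = "first")
  first1 <- max.col(sim[[1]]$codes > 0, ties.method = "first")
  expect_identical(first1, first0)
  rel0 <- h0$codes[cbind(seq_along(first0), first0)]
  rel1 <- sim[[1]]$codes[cbind(seq_along(first1), first1)]
  expect_identical(rel1, rel0)
})
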