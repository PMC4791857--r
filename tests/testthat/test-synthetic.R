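test_that("the frozen scenario matches the study design", {
  sc <- study_scenario()
  expect_equal(sc$distances["HC", "M1F"], 182)
  expect_equal(sc$distances["HC", "M2"], 241)
  expect_equal(sc$distances["M1F", "M2"], 30)
  cov <- sc$covariates
  expect_equal(cov$success[cov$stratum == "M1F" & cov$year %in% 2010:2011],
               c(0, 0))
  # flow flags sit on the prescribed intervals only
  expect_equal(sort(unique(cov$year[cov$hf_emig == 1])), 2010)
  expect_equal(sort(unique(cov$year[cov$posthf_immig == 1])), 2011)
  # generating transition kernel rows (including stay) sum to one
  arr <- plovermeta:::truth_arrays(sc)
  expect_equal(max(abs(apply(arr$psi, c(1, 3, 4), sum) - 1)), 0,
               tolerance = 1e-12)
})

test_that("release cohorts reproduce the banding totals", {
  co <- cohort_sizes()
  tot <- aggregate(n ~ stratum + age_class, co, sum)
  expect_equal(tot$n[tot$stratum == "HC"], c(93, 245))
  expect_equal(tot$n[tot$stratum == "M1F"], c(470, 1117))
  expect_equal(tot$n[tot$stratum == "M2"], c(212, 503))
  expect_false(any(co$stratum == "M1F" & co$age_class == "juvenile" &
                     co$year %in% 2010:2011))
  half <- cohort_sizes(total = 1320)
  expect_equal(sum(half$n), 1320, tolerance = 3)
})

test_that("simulation is reproducible from the seed", {
  sc <- study_scenario()
  co <- cohort_sizes(total = 300, scenario = sc)
  a <- simulate_histories(sc, co, seed = 123)
  b <- simulate_histories(sc, co, seed = 123)
  expect_identical(a$histories$codes, b$histories$codes)
  expect_identical(a$histories$hatch_day, b$histories$hatch_day)
})

test_that("resighting fractions follow the generating survival rate", {
  sc <- study_scenario()
  # perfect detection, no movement, flat survival 0.7
  truth <- list(phi_adult = c(HC = 0.7, M1F = 0.7, M2 = 0.7),
                p_adult = c(HC = 1, M1F = 1, M2 = 1),
                psi_intercept = -30, hf_emigration = 0,
                hf_immigration = 0, posthf_immigration = 0,
                distance_slope = 0, phi_high_flow = 0,
                phi_post_high_flow = 0)
  n <- 10000
  co <- data.frame(stratum = "HC", age_class = "adult", year = 2008, n = n)
  dat <- simulate_histories(sc, co, seed = 2024, truth = truth)
  seen2 <- mean(dat$histories$codes[, 2] > 0)
  expect_equal(seen2, 0.7, tolerance = 3 * sqrt(0.7 * 0.3 / n))
  expect_true(all(dat$histories$codes[, 2] %in% c(0L, 1L)))
})

test_that("large-sample transition frequencies match the kernel", {
  sc <- study_scenario()
  truth <- list(p_adult = c(HC = 1, M1F = 1, M2 = 1),
                phi_adult = c(HC = 1, M1F = 1, M2 = 1))
  n <- 20000
  co <- data.frame(stratum = "M1F", age_class = "adult", year = 2008, n = n)
  dat <- simulate_histories(sc, co, seed = 31, truth = truth)
  dest <- dat$histories$codes[, 2]
  frac <- tabulate(dest, 3) / n
  kern <- plovermeta:::truth_arrays(sc)$psi[2, , 1, 1]  # origin M1F, adults
  for (j in 1:3)
    expect_lt(abs(frac[j] - kern[j]),
              3 * sqrt(kern[j] * (1 - kern[j]) / n))
})

test_that("the canonical PVA fixture carries the study disturbance regime", {
  cfg <- pva_fixture()
  fp <- vapply(cfg$subpops, function(s) s$flood_probability, numeric(1))
  expect_equal(unname(fp), c(0, 0.05, 0))
  expect_equal(cfg$replicates, 1000L)
  expect_equal(cfg$horizon, 100L)
  dyn <- cfg$subpops$M1F
  expect_true(dyn$dynamic)
  expect_equal(dyn$K_decay_range, c(0.10, 0.60))
  expect_equal(dyn$fecundity$flood, 0)
  ev <- vapply(cfg$subpops, function(s) s$ev_sd_fraction, numeric(1))
  expect_equal(unname(ev), rep(0.20, 3))

  small <- pva_fixture(replicates = 10L)
  expect_equal(small$replicates, 10L)
  expect_equal(small$horizon, 100L)
  noev <- pva_fixture(ev_sd_fraction = 0)
  expect_true(all(vapply(noev$subpops, function(s) s$ev_sd_fraction,
                         numeric(1)) == 0))
  expect_error(pva_fixture(bogus_key = 1), "unknown override")
})
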