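make_hist <- function(S = 3, T = 6) {
  # one adult per stratum, seen at every occasion in its natal stratum
  codes <- matrix(rep(seq_len(S), each = T), S, T, byrow = TRUE)
  encounter_histories(codes, "adult", strata = LETTERS[seq_len(S)],
                      years = 2008:(2008 + T - 1))
}

test_that("coefficient counts follow the model structure", {
  h <- make_hist()
  expect_equal(compile_design(ms_spec(), h)$k, 3)          # 3 intercepts
  expect_equal(compile_design(ms_spec(phi = "sub"), h)$k, 5)
  d <- compile_design(ms_spec(psi = c("age", "distance")), h,
                      dist = distance_matrix(
                        c("A-B" = 1, "A-C" = 2, "B-C" = 3),
                        strata = c("A", "B", "C")))
  expect_equal(length(d$blocks$psi), 3)  # intercept + age + distance
  # flow dummies add three more transition coefficients
  oc <- occasion_covariates(rep(2008:2012, each = 3),
                            rep(c("A", "B", "C"), 5), 1,
                            hf_emig = as.integer(
                              rep(2008:2012, each = 3) == 2010 &
                                rep(c("A", "B", "C"), 5) == "B"),
                            hf_immig = 0,
                            posthf_immig = as.integer(
                              rep(2008:2012, each = 3) == 2011 &
                                rep(c("A", "B", "C"), 5) != "B"))
  d2 <- compile_design(
    ms_spec(psi = c("age", "distance", "hf_emigration", "hf_immigration",
                    "posthf_immigration")), h, occ_cov = oc,
    dist = distance_matrix(c("A-B" = 1, "A-C" = 2, "B-C" = 3),
                           strata = c("A", "B", "C")))
  expect_equal(length(d2$blocks$psi), 6)
})

test_that("unknown terms and missing covariates are rejected", {
  h <- make_hist()
  expect_error(ms_spec(phi = "weather"), "unknown phi term")
  expect_error(compile_design(ms_spec(phi = "success"), h),
               "occ_cov is NULL")
  expect_error(compile_design(ms_spec(psi = "distance"), h),
               "dist is NULL")
  fx <- data.frame(class = "phi", stratum = "Z", dest = NA, year = NA,
                   age = "*", value = 0)
  expect_error(compile_design(ms_spec(phi = "sub", fixes = fx), h),
               "matches no real parameter")
})

test_that("fixing real parameters removes exactly their coefficients", {
  h <- make_hist()
  # saturated year-structured survival: fixed juvenile cells own their
  # coefficients, which must drop from k
  sp_free <- ms_spec(phi = "age:sub:year")
  sp_fix <- ms_spec(phi = "age:sub:year",
                    fixes = standard_fixes("B", c(2010L, 2011L)))
  k_free <- compile_design(sp_free, h)$k
  k_fix <- compile_design(sp_fix, h)$k
  expect_equal(k_free - k_fix, 2)  # two juvenile phi cells at B
  # the forced probability appears in the parameter arrays
  d <- compile_design(sp_fix, h)
  pa <- plovermeta:::param_arrays(d, rep(0.3, d$k))
  iv <- match(c(2010, 2011), d$intervals)
  expect_equal(pa$phi[2, iv, 2], c(0, 0))
  expect_true(all(pa$phi[, -iv, 2] > 0))
})

test_that("transition rows sum to one under arbitrary coefficients", {
  h <- make_hist()
  sp <- ms_spec(psi = c("age", "sub"),
                fixes = standard_fixes("B", c(2010L, 2011L)))
  d <- compile_design(sp, h)
  set.seed(42)
  for (i in 1:20) {
    pa <- plovermeta:::param_arrays(d, rnorm(d$k, 0, 2))
    sums <- apply(pa$psi, c(1, 3, 4), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  }
})

test_that("age is a time-varying state: juvenile rates in the first interval only", {
  # two strata so transitions exist; all detection certain, no movement
  h <- encounter_histories(rbind(c(1L, 1L, 1L)), "juvenile",
                           hatch_day = 0, band_age = 0,
                           strata = c("A", "B"), years = 1:3)
  sp <- ms_spec(phi = "age")
  d <- compile_design(sp, h)
  # beta: phi intercept (adult), phi age (juvenile offset), p, psi
  b <- c(qlogis(0.8), qlogis(0.3) - qlogis(0.8), qlogis(0.99), -20)
  names(b) <- d$beta_names
  stay <- 1 / (1 + exp(-20))
  expect_equal(
    history_logprob(d, b)[1],
    log(0.3 * stay * 0.99 * 0.8 * stay * 0.99),
    tolerance = 1e-10)
})
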