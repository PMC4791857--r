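fake_fit <- function(label, qaicc, k = 5, deviance = 0, converged = TRUE) {
  structure(list(label = label, qaicc = qaicc, k = k, deviance = deviance,
                 converged = converged), class = "ms_fit")
}

test_that("Akaike weights follow the closed form and normalise", {
  ms <- rank_and_weight(list(fake_fit("a", 100), fake_fit("b", 100)))
  expect_equal(ms$table$weight, c(0.5, 0.5))
  ms2 <- rank_and_weight(list(fake_fit("a", 102), fake_fit("b", 100)))
  expect_equal(ms2$table$delta, c(0, 2))
  expect_equal(ms2$table$weight,
               c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(ms2$table$weight, 3), c(0.731, 0.269))
  set.seed(3)
  ms3 <- rank_and_weight(lapply(1:7, function(i)
    fake_fit(paste0("m", i), runif(1, 100, 120), sample(3:9, 1))))
  expect_equal(sum(ms3$table$weight), 1, tolerance = 1e-12)
  expect_equal(ms3$table$delta[1], 0)
  expect_true(!is.unsorted(ms3$table$qaicc))
})

test_that("ranking ties break by smaller k, then label", {
  ms <- rank_and_weight(list(fake_fit("zeta", 100, k = 3),
                             fake_fit("alpha", 100, k = 7),
                             fake_fit("beta", 100, k = 3)))
  expect_equal(ms$table$model, c("beta", "zeta", "alpha"))
})

test_that("model averaging weights real-scale estimates and their spread", {
  sc <- study_scenario()
  dat <- simulate_histories(sc, cohort_sizes(total = 600, scenario = sc),
                            seed = 77)
  f1 <- ms_fit(ms_spec(phi = "age", psi = "distance",
                       fixes = standard_fixes()),
               dat$histories, dat$covariates, sc$distances)
  f2 <- ms_fit(ms_spec(phi = "age", psi = "1", fixes = standard_fixes()),
               dat$histories, dat$covariates, sc$distances)
  single <- model_average(rank_and_weight(list(f1)), "phi")
  expect_equal(single$estimate, predict(f1, "phi")$estimate)

  ms <- rank_and_weight(list(f1, f2))
  w <- ms$table$weight
  p1 <- predict(ms$fits[[1]], "psi"); p2 <- predict(ms$fits[[2]], "psi")
  avg <- model_average(ms, "psi")
  expect_equal(avg$estimate, w[1] * p1$estimate + w[2] * p2$estimate)
  # unconditional SE >= weighted mean of conditional SEs
  expect_true(all(avg$se >= w[1] * p1$se + w[2] * p2$se - 1e-10))
})

test_that("stage-4 substitution grammar expands sub and year correctly", {
  v <- expand_psi_structure(c("sub", "year"))
  expect_length(v, 3)
  flow <- c("hf_emigration", "hf_immigration", "posthf_immigration")
  expect_true(any(vapply(v, setequal, TRUE, c("distance", flow))))
  expect_true(any(vapply(v, setequal, TRUE, c("distance", "success"))))
  expect_true(any(vapply(v, setequal, TRUE, c("distance", flow, "success"))))
  # age triggers the success-by-age interaction and survives substitution
  v2 <- expand_psi_structure(c("age", "sub:year"))
  expect_true(all(vapply(v2, function(x) "age" %in% x, TRUE)))
  expect_true(any(vapply(v2, function(x)
    all(c("success", "age:success") %in% x), TRUE)))
  # no year: a single distance-substituted variant
  expect_equal(expand_psi_structure(c("age", "sub")),
               list(c("age", "distance")))
})

test_that("one candidate per stage composes into the final model", {
  sc <- study_scenario()
  dat <- simulate_histories(sc, cohort_sizes(total = 400, scenario = sc),
                            seed = 55)
  catalogue <- list(p = list("sub"),
                    phi = list(c("age", "hatch", "band_age")),
                    psi = list("age"),
                    phi_stage4_extras = list(character(0)),
                    delta_max = 4, maximal = "age")
  sel <- sequential_selection(dat$histories, dat$covariates, sc$distances,
                              catalogue = catalogue,
                              fixes = standard_fixes())
  expect_equal(nrow(sel$final$table), 1)
  spec <- sel$final$fits[[1]]$design$spec
  expect_setequal(spec$p, "sub")
  expect_setequal(spec$phi, c("age", "hatch", "band_age"))
  expect_setequal(spec$psi, "age")  # no sub/year, so substitution is identity
})

test_that("a generated distance effect outranks a constant transition model", {
  sc <- study_scenario()
  wins <- 0L
  n_rep <- 6L
  for (i in seq_len(n_rep)) {
    dat <- simulate_histories(sc, cohort_sizes(total = 700, scenario = sc),
                              seed = 1000 + i)
    f_dist <- ms_fit(ms_spec(phi = "age", psi = c("age", "distance"),
                             fixes = standard_fixes()),
                     dat$histories, dat$covariates, sc$distances)
    f_const <- ms_fit(ms_spec(phi = "age", psi = "age",
                              fixes = standard_fixes()),
                      dat$histories, dat$covariates, sc$distances)
    wins <- wins + (f_dist$qaicc < f_const$qaicc)
  }
  expect_gte(wins, n_rep - 1L)
})
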