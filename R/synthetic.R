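#' The canonical three-subpopulation study scenario
#'
#' Returns the frozen design of the 2008-2013 three-subpopulation study and
#' the generating ("truth") parameters used by [simulate_histories()]: three
#' strata (HC, the human-created lower Platte sites; M1F, the flow-affected
#' Missouri River reach; M2, the reservoir sites), six annual occasions,
#' pairwise distances 182 / 241 / 30 km, the yearly chicks-fledged-per-pair
#' table (zero at M1F in the two flood years), the flow indicator variables
#' on the 2010->2011 and 2011->2012 intervals, and age-by-subpopulation
#' survival/resight means with logit-scale covariate effects (distance slope
#' per km, three flow dummies on transitions, flow effects on survival,
#' hatch-date and banding-age slopes for juveniles).
#'
#' @return An object of class `"study_scenario"`: a list with `strata`,
#'   `years`, `distances`, `covariates`, `truth`, `hatch_dist`, `band_dist`,
#'   `generating_spec`.
#' @export
study_scenario <- function() {
  strata <- c("HC", "M1F", "M2")
  years <- 2008:2013
  distances <- distance_matrix(
    c("HC-M1F" = 182, "HC-M2" = 241, "M1F-M2" = 30), strata = strata)

  succ <- rbind(  # chicks fledged / pair, 2008..2012
    HC  = c(1.20, 0.61, 0.74, 1.31, 1.44),
    M1F = c(1.14, 0.53, 0.00, 0.00, 1.80),
    M2  = c(1.56, 2.61, 1.87, 0.49, 1.27))
  colnames(succ) <- 2008:2012
  covariates <- occasion_covariates(
    year = rep(2008:2012, each = 3),
    stratum = rep(strata, 5),
    success = as.vector(succ[, as.character(2008:2012)]),
    hf_emig = as.integer(rep(2008:2012, each = 3) == 2010 &
                           rep(strata, 5) == "M1F"),
    hf_immig = as.integer(rep(2008:2012, each = 3) == 2010 &
                            rep(strata, 5) != "M1F"),
    posthf_immig = as.integer(rep(2008:2012, each = 3) == 2011 &
                                rep(strata, 5) != "M1F"))

  truth <- list(
    phi_adult = c(HC = 0.70, M1F = 0.67, M2 = 0.73),
    phi_juv = c(HC = 0.34, M1F = 0.09, M2 = 0.26),
    p_adult = c(HC = 0.64, M1F = 0.92, M2 = 0.88),
    p_juv = c(HC = 0.32, M1F = 0.74, M2 = 0.66),
    # logit-scale effects
    phi_high_flow = -0.276, phi_post_high_flow = 0.785,
    hatch_slope = -0.031, band_slope = 0.032,
    psi_intercept = -1.6, psi_age_juv = 0.8, distance_slope = -0.011,
    hf_emigration = 1.690, hf_immigration = -2.279,
    posthf_immigration = 1.010)

  # hatch day (day of season, day 1 = 1 May) and banding age distributions
  hatch_dist <- data.frame(
    stratum = strata,
    mean = c(45, 61, 64), sd = c(14, 15, 12),
    lo = c(15, 26, 37), hi = c(87, 95, 95))
  band_dist <- data.frame(
    stratum = strata,
    mean = c(5, 1, 2), sd = c(6, 2, 3),
    lo = c(0, 0, 0), hi = c(24, 16, 24))

  generating_spec <- ms_spec(
    phi = c("age:sub", "hatch", "band_age", "high_flow", "post_high_flow"),
    p = "age:sub",
    psi = c("age", "distance", "hf_emigration", "hf_immigration",
            "posthf_immigration"),
    fixes = standard_fixes("M1F", c(2010L, 2011L)))

  structure(list(strata = strata, years = years, distances = distances,
                 covariates = covariates, success = succ, truth = truth,
                 hatch_dist = hatch_dist, band_dist = band_dist,
                 generating_spec = generating_spec),
            class = "study_scenario")
}

#' @export
print.study_scenario <- function(x, ...) {
  cat("Study scenario:", length(x$strata), "strata (",
      paste(x$strata, collapse = ", "), "),",
      length(x$years), "occasions", min(x$years), "-", max(x$years), "\n")
  cat("  distances (km):",
      paste(x$distances[upper.tri(x$distances)], collapse = ", "), "\n")
  invisible(x)
}

#' Release cohort sizes
#'
#' The banding totals by stratum and age class (93/245 adults/juveniles at
#' HC, 470/1117 at M1F, 212/503 at M2) split evenly across release years.
#' No juveniles are released at M1F in the two flood years (no chicks
#' fledged), so its juvenile total is split across the remaining four years.
#'
#' @param total optional total number of birds; cohort sizes are rescaled
#'   proportionally (useful for small simulations).
#' @param scenario a [study_scenario()].
#' @return A data frame with columns `stratum`, `age_class`, `year`, `n`.
#' @export
cohort_sizes <- function(total = NULL, scenario = study_scenario()) {
  totals <- data.frame(
    stratum = rep(scenario$strata, 2),
    age_class = rep(c("adult", "juvenile"), each = 3),
    n = c(93, 470, 212, 245, 1117, 503))
  if (!is.null(total)) totals$n <- round(totals$n * total / sum(totals$n))
  split_even <- function(n, yrs) {
    base <- n %/% length(yrs)
    extra <- n %% length(yrs)
    data.frame(year = yrs, n = base + (seq_along(yrs) <= extra))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(totals)), function(i) {
    yrs <- scenario$years
    if (totals$age_class[i] == "juvenile" && totals$stratum[i] == "M1F")
      yrs <- setdiff(yrs, c(2010L, 2011L))
    cbind(totals[i, c("stratum", "age_class")],
          split_even(totals$n[i], yrs), row.names = NULL)
  }))
  out[out$n > 0, ]
}

# Truth parameters -> probability arrays in the same layout as param_arrays()
truth_arrays <- function(scenario) {
  tr <- scenario$truth
  S <- length(scenario$strata)
  NI <- length(scenario$years) - 1L
  iv <- scenario$years[-length(scenario$years)]
  flow <- match("M1F", scenario$strata)

  phi_eta <- array(NA_real_, c(S, NI, 2L))
  phi_eta[, , 1L] <- qlogis(tr$phi_adult[scenario$strata])
  phi_eta[, , 2L] <- qlogis(tr$phi_juv[scenario$strata])
  hf_t <- match(2010L, iv); post_t <- match(2011L, iv)
  phi_eta[flow, hf_t, ] <- phi_eta[flow, hf_t, ] + tr$phi_high_flow
  phi_eta[flow, post_t, ] <- phi_eta[flow, post_t, ] + tr$phi_post_high_flow
  phi_fixed <- array(NA_real_, c(S, NI, 2L))
  phi_fixed[flow, match(c(2010L, 2011L), iv), 2L] <- 0
  phi <- plogis(phi_eta)
  phi[!is.na(phi_fixed)] <- phi_fixed[!is.na(phi_fixed)]

  p <- array(NA_real_, c(S, NI, 2L))
  p[, , 1L] <- tr$p_adult[scenario$strata]
  p[, , 2L] <- tr$p_juv[scenario$strata]

  psi <- array(0, c(S, S, NI, 2L))
  for (a in 1:2) for (t in seq_len(NI)) for (r in seq_len(S)) {
    dests <- setdiff(seq_len(S), r)
    eta <- tr$psi_intercept + (a == 2L) * tr$psi_age_juv +
      tr$distance_slope * scenario$distances[r, dests] +
      tr$hf_emigration * (r == flow & iv[t] == 2010L) +
      tr$hf_immigration * (dests == flow & iv[t] == 2010L) +
      tr$posthf_immigration * (dests == flow & iv[t] == 2011L)
    if (a == 2L && r == flow && iv[t] %in% c(2010L, 2011L)) {
      psi[r, r, t, a] <- 1  # fixed: no juvenile emigration in flood years
    } else {
      e <- exp(eta)
      psi[r, dests, t, a] <- e / (1 + sum(e))
      psi[r, r, t, a] <- 1 / (1 + sum(e))
    }
  }

  list(phi = phi, p = p, psi = psi, phi_eta = phi_eta[, , 2L],
       phi_fixed = phi_fixed[, , 2L],
       b_hatch = tr$hatch_slope, b_band = tr$band_slope)
}

round_trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- round(rnorm(n, mean, sd))
  pmin(pmax(x, lo), hi)
}

# Vectorised path simulator shared by simulate_histories() and
# simulate.ms_fit(). `arr` mirrors param_arrays(): phi [S,NI,2] probabilities
# (fixes applied), juvenile logits in phi_eta [S,NI] with phi_fixed [S,NI]
# overrides, p [S,NI,2], psi [S,S,NI,2]. `hatch`/`band` enter the juvenile
# survival logit as b_hatch / b_band slopes (already centred as the caller
# intends).
simulate_paths <- function(arr, first, state0, juv, hatch, band, S, T) {
  n <- length(first)
  codes <- matrix(0L, n, T)
  codes[cbind(seq_len(n), first)] <- state0
  state <- state0
  alive <- rep(TRUE, n)
  for (t in seq_len(T - 1L)) {
    act <- alive & first <= t
    if (!any(act)) next
    is_juv <- act & juv & first == t
    a_idx <- 1L + as.integer(is_juv)
    phi_i <- arr$phi[cbind(state, t, a_idx)]
    jj <- which(is_juv & (arr$b_hatch != 0 | arr$b_band != 0))
    if (length(jj)) {
      fx <- arr$phi_fixed[cbind(state[jj], t)]
      eta <- arr$phi_eta[cbind(state[jj], t)] +
        arr$b_hatch * hatch[jj] + arr$b_band * band[jj]
      phi_i[jj] <- ifelse(is.na(fx), plogis(eta), fx)
    }
    dead <- act & runif(n) >= phi_i
    alive[dead] <- FALSE
    act <- alive & first <= t
    newstate <- state
    for (a in 1:2) for (r in seq_len(S)) {
      grp <- which(act & state == r & (a_idx == a))
      if (!length(grp)) next
      pr <- arr$psi[r, , t, a]
      newstate[grp] <- sample.int(S, length(grp), replace = TRUE, prob = pr)
    }
    state <- newstate
    seen <- act & runif(n) < arr$p[cbind(state, t, a_idx)]
    codes[cbind(which(seen), t + 1L)] <- state[seen]
  }
  codes
}

#' Simulate encounter histories under the canonical scenario
#'
#' Generates one synthetic data set with the statistical structure the
#' estimation stage assumes: every released bird survives each interval with
#' its (age, stratum, interval, covariate-adjusted) survival probability,
#' moves according to the multinomial transition kernel, and is resighted
#' with the age- and stratum-specific resight probability. Juveniles receive
#' hatch-day and banding-age covariates drawn from stratum-specific rounded
#' truncated normal distributions; their survival logits are adjusted by the
#' truth slopes applied to the deviation from the stratum mean (so the cell
#' means stay on the stated scale).
#'
#' @param scenario a [study_scenario()].
#' @param cohorts release cohorts, as from [cohort_sizes()].
#' @param seed RNG seed (required for reproducibility).
#' @param truth optional replacement truth list (same fields as
#'   `scenario$truth`).
#' @return A list: `histories` ([encounter_histories()]), `covariates`,
#'   `distances`, `truth`.
#' @export
simulate_histories <- function(scenario = study_scenario(),
                               cohorts = cohort_sizes(scenario = scenario),
                               seed, truth = NULL) {
  if (!missing(seed)) set.seed(seed)
  if (!is.null(truth)) scenario$truth <- utils::modifyList(scenario$truth, truth)
  arr <- truth_arrays(scenario)
  S <- length(scenario$strata)
  T <- length(scenario$years)

  n <- sum(cohorts$n)
  first <- rep(match(cohorts$year, scenario$years), cohorts$n)
  state0 <- rep(match(cohorts$stratum, scenario$strata), cohorts$n)
  juv <- rep(cohorts$age_class == "juvenile", cohorts$n)
  hatch <- band <- numeric(n)
  for (s in seq_len(S)) {
    js <- which(juv & state0 == s)
    if (!length(js)) next
    hd <- scenario$hatch_dist[s, ]
    bd <- scenario$band_dist[s, ]
    hatch[js] <- round_trunc_norm(length(js), hd$mean, hd$sd, hd$lo, hd$hi)
    band[js] <- round_trunc_norm(length(js), bd$mean, bd$sd, bd$lo, bd$hi)
  }
  # centre the covariates entering the truth logit at the stratum mean
  hatch_c <- hatch - scenario$hatch_dist$mean[state0] * juv
  band_c <- band - scenario$band_dist$mean[state0] * juv
  hatch_c[!juv] <- 0; band_c[!juv] <- 0

  codes <- simulate_paths(arr, first, state0, juv, hatch_c, band_c, S, T)
  keep <- rowSums(codes > 0L) > 0L  # always TRUE: release is a detection
  hist <- encounter_histories(
    codes[keep, , drop = FALSE],
    ifelse(juv[keep], "juvenile", "adult"),
    hatch_day = hatch[keep] * juv[keep], band_age = band[keep] * juv[keep],
    strata = scenario$strata, years = scenario$years)
  list(histories = hist, covariates = scenario$covariates,
       distances = scenario$distances, truth = scenario$truth)
}

# Simulation backend for simulate.ms_fit(): same release structure and
# individual covariates as the fitted data
sim_from_arrays <- function(pa, d, strata, years) {
  S <- length(strata); T <- length(years)
  idx <- rep(seq_along(d$first), d$freq)
  arr <- list(phi = pa$phi, p = pa$p, psi = pa$psi,
              phi_eta = pa$phi_eta[, , 2L], phi_fixed = pa$phi_fixed[, , 2L],
              b_hatch = pa$b_hatch, b_band = pa$b_band)
  codes <- simulate_paths(arr, d$first[idx],
                          d$codes[cbind(idx, d$first[idx])],
                          d$juv[idx], d$hatch[idx], d$band[idx], S, T)
  encounter_histories(codes, ifelse(d$juv[idx], "juvenile", "adult"),
                      hatch_day = d$hatch[idx], band_age = d$band[idx],
                      strata = strata, years = years)
}
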