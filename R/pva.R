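#' Flow state of a subpopulation
#'
#' A high-flow year is `HIGH_FLOW` (`years_since_flow = 0`), the year after
#' is `POST_FLOW` (`= 1`), and every later year is `BASELINE` (`>= 2`).
#'
#' @param years_since_flow non-negative integer.
#' @return An object of class `"flow_state"`.
#' @export
flow_state <- function(years_since_flow = 2L) {
  t <- as.integer(years_since_flow)
  if (t < 0L) msg_stop("years_since_flow must be >= 0")
  structure(list(
    state = c("HIGH_FLOW", "POST_FLOW", "BASELINE")[min(t, 2L) + 1L],
    years_since_flow = t), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(x$state, "(years since flow:", x$years_since_flow, ")\n")
  invisible(x)
}

#' Advance the annual flow-state machine
#'
#' With probability `flood_probability` the coming year is a high-flow year
#' (the clock resets to 0 — consecutive floods are possible, as observed in
#' 2010-2011); otherwise the clock advances and the label follows from it.
#'
#' @param state a [flow_state()].
#' @param flood_probability annual high-flow probability in \[0, 1\].
#' @return The new [flow_state()].
#' @export
advance_flow_state <- function(state, flood_probability) {
  if (flood_probability < 0 || flood_probability > 1)
    msg_stop("flood_probability must be a probability")
  if (flood_probability > 0 && runif(1) < flood_probability) flow_state(0L)
  else flow_state(state$years_since_flow + 1L)
}

#' Annual carrying-capacity update
#'
#' Static subpopulations keep `K_max`. For the dynamic (flow-affected)
#' subpopulation: a high-flow year inundates the habitat (`K = 0` for
#' breeding; the decay clock restarts), the post-flood year resets `K` to
#' `K_max` (newly created bare habitat), and every further baseline year
#' erodes it, `K <- floor(K * (1 - d))` with `d ~ Uniform(K_decay_range)`
#' (partial territories are lost to erosion), bounded below by `K_floor`.
#'
#' @param K current carrying capacity (adults).
#' @param state a [flow_state()].
#' @param cfg a [subpop_config()].
#' @param stochastic draw the decay fraction (default) or use its mean.
#' @return The updated integer K.
#' @export
update_carrying_capacity <- function(K, state, cfg, stochastic = TRUE) {
  if (!cfg$dynamic) return(as.integer(cfg$K_max))
  switch(state$state,
    HIGH_FLOW = 0L,
    POST_FLOW = as.integer(cfg$K_max),
    BASELINE = {
      d <- if (stochastic) runif(1, cfg$K_decay_range[1], cfg$K_decay_range[2])
           else mean(cfg$K_decay_range)
      max(as.integer(floor(K * (1 - d))), as.integer(cfg$K_floor))
    })
}

# Mortality rate from a time-since-flood schedule
schedule_rate <- function(sch, tsf) {
  if (tsf == 0L) sch$flood
  else if (tsf <= sch$window) sch$post_flood
  else min(sch$post_flood + sch$increment * (tsf - sch$window), sch$cap)
}

flow_label_idx <- function(tsf) min(tsf, 2L) + 1L  # 1 flood, 2 post, 3 baseline
fec_state <- c("flood", "post_flood", "baseline")
disp_state_idx <- c(2L, 3L, 1L)  # dispersal array order: baseline/flood/post

#' One year of the metapopulation life cycle
#'
#' Executes, in this fixed order: (1) breeding — monogamous pairing,
#' `pairs = min(adult males, adult females)`, Poisson(`pairs * fecundity`)
#' fledglings with Bernoulli(`sex_ratio`) sexes; (2) mortality — one rate
#' per subpopulation x age class drawn from a truncated Normal around the
#' flow-state schedule mean (environmental variation), applied as
#' independent Bernoulli deaths (demographic stochasticity); (3) aging —
#' fledglings become adults, individuals beyond `max_age` die; (4) dispersal
#' — age- and flow-state-specific movement probabilities; (5) carrying-
#' capacity truncation — if adults exceed K, individuals die with
#' probability `1 - K/N` (no truncation in a high-flow year, when the zero
#' breeding-season K reflects inundated habitat rather than winter
#' carrying capacity).
#'
#' With `stochastic = FALSE` every random draw is replaced by its
#' expectation (real-valued counts), which makes the cycle a deterministic
#' two-stage projection.
#'
#' @param state list with elements `N` (array `[S, 2 sexes, max_age + 1]`;
#'   age slot 1 holds this season's fledglings), `K` (integer vector), `tsf`
#'   (integer vector, years since flow per subpopulation).
#' @param cfg a [pva_config()].
#' @param stochastic logical.
#' @return The updated `state`, with `N_pre` (adults after dispersal, before
#'   truncation) attached.
#' @export
annual_cycle <- function(state, cfg, stochastic = TRUE) {
  S <- length(cfg$subpops)
  if (length(state$tsf) != S)
    msg_stop("flow-state vector length does not match the subpopulations")
  N <- state$N
  A1 <- dim(N)[3]
  rbin <- if (stochastic) function(n, p) rbinom(length(n), n, p)
          else function(n, p) n * p

  # (1) breeding
  for (s in seq_len(S)) {
    sp <- cfg$subpops[[s]]
    f <- sp$fecundity[[fec_state[flow_label_idx(state$tsf[s])]]]
    pairs <- min(sum(N[s, 1, -1]), sum(N[s, 2, -1]))
    chicks <- if (stochastic) rpois(1, pairs * f) else pairs * f
    males <- if (stochastic) rbinom(1, chicks, cfg$sex_ratio)
             else chicks * cfg$sex_ratio
    N[s, 1, 1] <- N[s, 1, 1] + males
    N[s, 2, 1] <- N[s, 2, 1] + (chicks - males)
  }

  # (2) mortality: EV draw once per subpop-year-ageclass, then Bernoulli
  for (s in seq_len(S)) {
    sp <- cfg$subpops[[s]]
    for (cl in c("juvenile", "adult")) {
      sch <- sp$mortality[[cl]]
      q <- schedule_rate(sch, state$tsf[s])
      if (stochastic && sp$ev_sd_fraction > 0) {
        q <- rnorm(1, q, sp$ev_sd_fraction * sch$baseline)
        q <- min(max(q, 0), 1)
      }
      slots <- if (cl == "juvenile") 1L else 2:A1
      N[s, , slots] <- rbin(N[s, , slots], 1 - q)
    }
  }

  # (3) aging: fledglings mature, the oldest age class dies
  N[, , 2:A1] <- N[, , 1:(A1 - 1L)]
  N[, , 1] <- 0

  # (4) dispersal, driven by the flow state of the dynamic subpopulation
  dyn <- which(vapply(cfg$subpops, function(x) x$dynamic, logical(1)))
  flow_idx <- if (length(dyn)) flow_label_idx(state$tsf[dyn]) else 3L
  D <- cfg$dispersal[, , , disp_state_idx[flow_idx], drop = FALSE]
  moved_in <- array(0, dim = dim(N))
  for (s in seq_len(S)) {
    dests <- setdiff(seq_len(S), s)
    for (a in 1:2) {  # 1 adult, 2 juvenile (= birds fledged this year, age 1)
      slots <- if (a == 2L) 2L else setdiff(2:A1, 2L)
      rates <- D[s, dests, a, 1]
      tot <- sum(rates)
      if (tot <= 0) next
      here <- N[s, , slots, drop = FALSE]
      movers <- rbin(here, tot)
      N[s, , slots] <- here - movers
      remaining <- movers
      left <- tot
      for (j in seq_along(dests)) {
        take <- if (j == length(dests)) remaining
                else rbin(remaining, rates[j] / left)
        moved_in[dests[j], , slots] <- moved_in[dests[j], , slots] + take
        remaining <- remaining - take
        left <- left - rates[j]
      }
    }
  }
  N <- N + moved_in

  # adults after dispersal, before truncation (used for lambda_stoch)
  N_pre <- vapply(seq_len(S), function(s) sum(N[s, , -1]), numeric(1))

  # (5) K truncation (skipped in a high-flow year, see above)
  for (s in seq_len(S)) {
    if (state$tsf[s] == 0L) next
    n_ad <- sum(N[s, , -1])
    if (n_ad > state$K[s]) {
      keep_p <- state$K[s] / n_ad
      N[s, , -1] <- rbin(N[s, , -1], keep_p)
    }
  }

  state$N <- N
  state$N_pre <- N_pre
  state
}

#' Deterministic finite growth rate of the two-stage life cycle
#'
#' The dominant eigenvalue of the female-based projection matrix with adult
#' survival `s_ad`, first-year survival `s_juv` and `f/2` daughters per
#' female: `lambda = s_ad + s_juv * f / 2`.
#'
#' @param adult_survival,juvenile_survival annual survival probabilities.
#' @param fecundity mean chicks fledged per pair.
#' @return The deterministic lambda.
#' @export
deterministic_lambda <- function(adult_survival, juvenile_survival, fecundity) {
  stopifnot(adult_survival >= 0, adult_survival <= 1,
            juvenile_survival >= 0, juvenile_survival <= 1, fecundity >= 0)
  adult_survival + juvenile_survival * fecundity / 2
}

#' Run the stochastic metapopulation viability simulation
#'
#' Simulates `cfg$replicates` independent trajectories of `cfg$horizon`
#' years. Each year the flow-state machine of every subpopulation advances
#' ([advance_flow_state()]), carrying capacities update
#' ([update_carrying_capacity()]), and the life cycle runs
#' ([annual_cycle()]). A subpopulation is extinct when it lacks at least one
#' male or one female; a recolonization is the return of both sexes after an
#' extinction. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [pva_config()] (see [pva_fixture()] for the canonical one).
#' @param keep_trajectories store per-replicate yearly counts (default TRUE).
#' @param stochastic with `FALSE`, every draw is replaced by its expectation
#'   (test mode: real-valued counts follow the deterministic two-stage
#'   projection when floods and environmental variation are switched off).
#' @return An object of class `"pva_result"`: summaries (see
#'   [summary.pva_result()]) plus `N` (`[replicates, horizon + 1, S]` adult
#'   counts), `K`, and flow-state trajectories.
#' @export
run_pva <- function(cfg, keep_trajectories = TRUE, stochastic = TRUE) {
  set.seed(cfg$seed)
  S <- length(cfg$subpops)
  R <- cfg$replicates
  H <- cfg$horizon
  A1 <- cfg$max_age + 1L

  N_out <- array(0L, c(R, H + 1L, S),
                 dimnames = list(NULL, NULL, cfg$strata))
  K_out <- array(0L, c(R, H + 1L, S))
  tsf_out <- array(0L, c(R, H + 1L, S))
  logr <- matrix(0, S + 1L, 2L)  # sum and count of log growth per subpop + meta
  first_ext <- matrix(NA_integer_, R, S)
  recol <- matrix(0L, R, S)
  ext_end <- matrix(FALSE, R, S)

  init_ages <- function(n) {  # spread initial adults over ages 1..8
    tabulate((seq_len(n) - 1L) %% 8L + 2L, nbins = A1)
  }

  for (r in seq_len(R)) {
    N <- array(0L, c(S, 2L, A1))
    for (s in seq_len(S)) {
      N[s, 1, ] <- init_ages(cfg$subpops[[s]]$initial_males)
      N[s, 2, ] <- init_ages(cfg$subpops[[s]]$initial_females)
    }
    tsf <- rep(2L, S)
    K <- vapply(cfg$subpops, function(sp) as.integer(sp$K_max), integer(1))
    st <- list(N = N, K = K, tsf = tsf)
    extinct <- rep(FALSE, S)
    N_out[r, 1L, ] <- vapply(seq_len(S), function(s) sum(N[s, , -1]), numeric(1))
    K_out[r, 1L, ] <- K
    tsf_out[r, 1L, ] <- tsf

    for (y in seq_len(H)) {
      for (s in seq_len(S)) {
        fs <- advance_flow_state(flow_state(st$tsf[s]),
                                 cfg$subpops[[s]]$flood_probability)
        st$tsf[s] <- fs$years_since_flow
        st$K[s] <- update_carrying_capacity(st$K[s], fs, cfg$subpops[[s]],
                                            stochastic = stochastic)
      }
      n_prev <- N_out[r, y, ]
      st <- annual_cycle(st, cfg, stochastic = stochastic)
      n_ad <- vapply(seq_len(S), function(s) sum(st$N[s, , -1]), numeric(1))
      N_out[r, y + 1L, ] <- n_ad
      K_out[r, y + 1L, ] <- st$K
      tsf_out[r, y + 1L, ] <- st$tsf

      # growth-rate bookkeeping (pre-truncation numerator)
      ok <- n_prev > 0 & st$N_pre > 0
      logr[seq_len(S), 1] <- logr[seq_len(S), 1] +
        ifelse(ok, log(st$N_pre / pmax(n_prev, 1)), 0)
      logr[seq_len(S), 2] <- logr[seq_len(S), 2] + ok
      if (sum(n_prev) > 0 && sum(st$N_pre) > 0) {
        logr[S + 1L, 1] <- logr[S + 1L, 1] + log(sum(st$N_pre) / sum(n_prev))
        logr[S + 1L, 2] <- logr[S + 1L, 2] + 1
      }

      males <- vapply(seq_len(S), function(s) sum(st$N[s, 1, -1]), numeric(1))
      females <- vapply(seq_len(S), function(s) sum(st$N[s, 2, -1]), numeric(1))
      ext_now <- males == 0 | females == 0
      newly_ext <- ext_now & !extinct
      if (any(newly_ext)) {
        idx <- which(newly_ext & is.na(first_ext[r, ]))
        first_ext[r, idx] <- y
      }
      recol[r, ] <- recol[r, ] + as.integer(extinct & !ext_now)
      extinct <- ext_now
    }
    ext_end[r, ] <- extinct
  }

  res <- list(cfg = cfg, N = N_out, K = K_out, tsf = tsf_out,
              first_extinction = first_ext, recolonizations = recol,
              extinct_at_end = ext_end, log_growth = logr)
  res$summary <- summarize_pva(res)
  if (!keep_trajectories) res$N <- res$K <- res$tsf <- NULL
  class(res) <- "pva_result"
  res
}

summarize_pva <- function(res) {
  cfg <- res$cfg
  S <- length(cfg$subpops); R <- cfg$replicates; H <- cfg$horizon
  # extinct at the horizon = lacking at least one sex at the last year end
  ext_sub <- setNames(colMeans(res$extinct_at_end), cfg$strata)
  ext_meta <- mean(rowSums(res$extinct_at_end) == S)
  se_p <- function(p, n) sqrt(p * (1 - p) / n)

  mte <- setNames(vapply(seq_len(S), function(s) {
    t <- res$first_extinction[, s]
    if (all(is.na(t))) NA_real_ else mean(t, na.rm = TRUE)
  }, numeric(1)), cfg$strata)
  mte_se <- vapply(seq_len(S), function(s) {
    t <- res$first_extinction[, s]; t <- t[!is.na(t)]
    if (length(t) < 2L) NA_real_ else stats::sd(t) / sqrt(length(t))
  }, numeric(1))

  yr_idx <- function(y) min(y, H) + 1L
  mean_n <- sapply(c(20, 50, 100), function(y)
    colMeans(matrix(res$N[, yr_idx(y), ], R, S)))
  mean_n_meta <- sapply(c(20, 50, 100), function(y)
    mean(rowSums(matrix(res$N[, yr_idx(y), ], R, S))))

  lam_d <- vapply(cfg$subpops, function(sp)
    deterministic_lambda(1 - sp$mortality$adult$baseline,
                         1 - sp$mortality$juvenile$baseline,
                         sp$fecundity$baseline), numeric(1))
  lam_s <- ifelse(res$log_growth[, 2] > 0,
                  exp(res$log_growth[, 1] / res$log_growth[, 2]), NA_real_)

  dyn <- which(vapply(cfg$subpops, function(x) x$dynamic, logical(1)))
  mean_K_dyn <- if (length(dyn))
    mean(res$K[, -1L, dyn]) else NA_real_

  list(strata = cfg$strata,
       extinction_probability = ext_sub,
       extinction_probability_se = se_p(ext_sub, R),
       metapop_extinction_probability = ext_meta,
       metapop_extinction_probability_se = se_p(ext_meta, R),
       mean_time_to_extinction = mte,
       mean_time_to_extinction_se = mte_se,
       mean_n = matrix(mean_n, S, 3L,
                       dimnames = list(cfg$strata, c("y20", "y50", "y100"))),
       mean_n_metapop = setNames(mean_n_meta, c("y20", "y50", "y100")),
       lambda_deter = setNames(lam_d, cfg$strata),
       lambda_stoch = setNames(lam_s, c(cfg$strata, "metapopulation")),
       recolonizations = setNames(colSums(res$recolonizations), cfg$strata),
       mean_K_dynamic = mean_K_dyn)
}

#' Stochastic finite growth rate from a simulation
#'
#' `exp` of the mean, over replicate-years with positive abundance, of
#' `log(N_pre[t+1] / N[t])`, where the numerator is taken before
#' carrying-capacity truncation.
#'
#' @param result a [run_pva()] result.
#' @param subpop subpopulation name, or `"metapopulation"` (default).
#' @return The stochastic lambda.
#' @export
stochastic_lambda <- function(result, subpop = "metapopulation") {
  ls <- result$summary$lambda_stoch
  if (!subpop %in% names(ls)) msg_stop("unknown subpopulation: ", subpop)
  v <- ls[[subpop]]
  if (is.na(v)) msg_stop("no replicate-years with positive abundance")
  v
}

#' @export
print.pva_result <- function(x, ...) {
  s <- x$summary
  cat("Metapopulation PVA:", x$cfg$replicates, "replicates x",
      x$cfg$horizon, "years\n")
  cat(sprintf("  metapopulation extinction probability: %.1f%% (SE %.1f)\n",
              100 * s$metapop_extinction_probability,
              100 * s$metapop_extinction_probability_se))
  cat(sprintf("  mean metapopulation size at year %d: %.0f adults\n",
              x$cfg$horizon, s$mean_n_metapop[["y100"]]))
  invisible(x)
}

#' Summary table of a PVA run
#'
#' @param object a [run_pva()] result.
#' @param ... unused.
#' @return A data frame with one row per subpopulation plus the
#'   metapopulation: extinction probability (with SE), mean years to first
#'   extinction, mean sizes at years 20/50/100, deterministic and stochastic
#'   lambda, and recolonization totals.
#' @export
summary.pva_result <- function(object, ...) {
  s <- object$summary
  S <- length(s$strata)
  tab <- data.frame(
    subpop = c("Metapopulation", s$strata),
    extinction_probability = c(s$metapop_extinction_probability,
                               s$extinction_probability),
    extinction_se = c(s$metapop_extinction_probability_se,
                      s$extinction_probability_se),
    mean_years_to_extinction = c(NA_real_, s$mean_time_to_extinction),
    n20 = c(s$mean_n_metapop[["y20"]], s$mean_n[, "y20"]),
    n50 = c(s$mean_n_metapop[["y50"]], s$mean_n[, "y50"]),
    n100 = c(s$mean_n_metapop[["y100"]], s$mean_n[, "y100"]),
    lambda_deter = c(NA_real_, s$lambda_deter),
    lambda_stoch = c(s$lambda_stoch[["metapopulation"]],
                     s$lambda_stoch[seq_len(S)]),
    recolonizations = c(NA_real_, s$recolonizations),
    stringsAsFactors = FALSE)
  class(tab) <- c("summary.pva_result", "data.frame")
  tab
}

#' @export
print.summary.pva_result <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Plot mean adult trajectories
#'
#' @param x a [run_pva()] result (with trajectories kept).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pva_result <- function(x, ...) {
  if (is.null(x$N)) msg_stop("trajectories were not kept")
  m <- apply(x$N, c(2, 3), mean)
  graphics::matplot(0:(nrow(m) - 1L), m, type = "l", lty = 1,
                    xlab = "Year", ylab = "Mean adults",
                    main = "Mean subpopulation trajectories", ...)
  graphics::legend("topright", legend = x$cfg$strata, lty = 1,
                   col = seq_len(ncol(m)), bty = "n")
  invisible(x)
}

#' Write per-replicate trajectories in long format
#'
#' Columns: `replicate, year, subpop, N_adult, K, flow_state`.
#'
#' @param result a [run_pva()] result with trajectories.
#' @param path CSV path.
#' @export
write_trajectories <- function(result, path) {
  if (is.null(result$N)) msg_stop("trajectories were not kept")
  d <- dim(result$N)
  lab <- c("HIGH_FLOW", "POST_FLOW", "BASELINE")
  long <- data.frame(
    replicate = rep(seq_len(d[1]), times = d[2] * d[3]),
    year = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    subpop = rep(result$cfg$strata, each = d[1] * d[2]),
    N_adult = as.vector(result$N),
    K = as.vector(result$K),
    flow_state = lab[pmin(as.vector(result$tsf), 2L) + 1L])
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
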