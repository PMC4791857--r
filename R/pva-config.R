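#' Per-subpopulation PVA configuration
#'
#' Describes one subpopulation of the viability model: its carrying-capacity
#' dynamics, its mortality schedules by age class and flow state, its
#' fecundity by flow state, and its annual high-flow probability.
#'
#' Mortality schedules are functions of the time since the last high-flow
#' event (`tsf`): the `flood` rate applies in a high-flow year (`tsf = 0`),
#' the `post_flood` rate for `tsf` in `1..window`, and thereafter the rate
#' rises by `increment` per year from `post_flood`, capped at `cap`. The
#' `baseline` rate anchors the deterministic growth rate and the
#' environmental-variation SD (`ev_sd_fraction * baseline`). Subpopulations
#' with `flood_probability = 0` should use a flat schedule
#' (`flood = post_flood = baseline`, `increment = 0`).
#'
#' @param name subpopulation name.
#' @param K_max carrying capacity (adults); for a `dynamic` subpopulation the
#'   post-flood reset value, otherwise the static ceiling.
#' @param dynamic logical; does K decay between floods and reset after them?
#' @param K_decay_range fraction pair for the annual Uniform habitat decay
#'   (dynamic subpopulations only).
#' @param K_floor minimum K during decay.
#' @param flood_probability annual probability of a high-flow event.
#' @param mortality list with `juvenile` and `adult` schedules, each a list
#'   `baseline`, `flood`, `post_flood`, `increment`, `window`, `cap`.
#' @param fecundity list `baseline`, `flood`, `post_flood`: mean chicks
#'   fledged per pair under each flow state.
#' @param ev_sd_fraction SD of environmental variation in mortality as a
#'   fraction of the baseline rate (default 0.20).
#' @param initial_males,initial_females starting adults.
#' @return A validated list of class `"subpop_config"`.
#' @export
subpop_config <- function(name, K_max, dynamic = FALSE,
                          K_decay_range = c(0.10, 0.60), K_floor = 0,
                          flood_probability = 0, mortality, fecundity,
                          ev_sd_fraction = 0.20,
                          initial_males = 0, initial_females = 0) {
  for (cl in c("juvenile", "adult")) {
    m <- mortality[[cl]]
    rates <- c(m$baseline, m$flood, m$post_flood, m$cap)
    if (any(rates < 0 | rates > 1))
      msg_stop(name, ": ", cl, " mortality rates must lie in [0, 1]")
    if (m$increment < 0 || m$window < 0)
      msg_stop(name, ": increment/window must be non-negative")
  }
  if (any(unlist(fecundity) < 0)) msg_stop(name, ": fecundity must be >= 0")
  if (flood_probability < 0 || flood_probability > 1)
    msg_stop(name, ": flood_probability must be a probability")
  if (dynamic && (any(K_decay_range <= 0) || any(K_decay_range >= 1)))
    msg_stop(name, ": K decay fractions must lie in (0, 1)")
  structure(list(name = name, K_max = K_max, dynamic = dynamic,
                 K_decay_range = K_decay_range, K_floor = K_floor,
                 flood_probability = flood_probability,
                 mortality = mortality, fecundity = fecundity,
                 ev_sd_fraction = ev_sd_fraction,
                 initial_males = initial_males,
                 initial_females = initial_females),
            class = "subpop_config")
}

#' Full PVA scenario configuration
#'
#' @param subpops list of [subpop_config()] objects.
#' @param dispersal array `[S, S, 2, 3]`: annual movement probability from
#'   origin to destination for age class (adult, juvenile) under flow state
#'   (baseline, flood, post_flood) of the flow-affected subpopulation.
#'   Rows must have total out-dispersal `<= 1` in every state.
#' @param replicates number of stochastic replicates (default 1000).
#' @param horizon years simulated (default 100).
#' @param max_age maximum age in years (default 20).
#' @param sex_ratio probability a fledgling is male (default 0.5).
#' @param seed RNG seed.
#' @return A validated list of class `"pva_config"`.
#' @export
pva_config <- function(subpops, dispersal, replicates = 1000L,
                       horizon = 100L, max_age = 20L, sex_ratio = 0.5,
                       seed = 1L) {
  S <- length(subpops)
  nm <- vapply(subpops, `[[`, character(1), "name")
  names(subpops) <- nm
  if (!identical(dim(dispersal), c(S, S, 2L, 3L)))
    msg_stop("dispersal must be an [S, S, 2, 3] array")
  if (any(dispersal < 0 | dispersal > 1))
    msg_stop("dispersal entries must be probabilities")
  for (a in 1:2) for (st in 1:3) {
    d <- matrix(dispersal[, , a, st], S, S)
    diag(d) <- 0
    if (any(rowSums(d) > 1 + 1e-12))
      msg_stop("total out-dispersal exceeds 1 for some origin")
  }
  if (replicates < 1L || horizon < 1L)
    msg_stop("replicates and horizon must be >= 1")
  if (sum(vapply(subpops, function(s) s$dynamic, logical(1))) > 1L)
    msg_stop("at most one dynamic (flow-affected) subpopulation is supported")
  structure(list(subpops = subpops, dispersal = dispersal,
                 replicates = as.integer(replicates),
                 horizon = as.integer(horizon), max_age = as.integer(max_age),
                 sex_ratio = sex_ratio, seed = as.integer(seed),
                 strata = nm),
            class = "pva_config")
}

#' @export
print.pva_config <- function(x, ...) {
  cat("PVA configuration:", length(x$subpops), "subpopulations (",
      paste(x$strata, collapse = ", "), ")\n")
  cat("  replicates:", x$replicates, " horizon:", x$horizon, "years\n")
  for (s in x$subpops)
    cat(sprintf("  %-4s K=%d%s flood p=%.2f init %d+%d\n", s$name, s$K_max,
                if (s$dynamic) " (dynamic)" else "", s$flood_probability,
                s$initial_males, s$initial_females))
  invisible(x)
}

#' Read / write a PVA scenario as JSON
#'
#' The canonical study scenario ships with the package as
#' `canonical_study.json` (see [pva_fixture()]).
#'
#' @param path JSON file path.
#' @return `read_pva_config()` returns a validated [pva_config()].
#' @export
read_pva_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- lapply(j$subpops, function(s)
    subpop_config(s$name, s$K_max, s$dynamic %||% FALSE,
                  unlist(s$K_decay_range %||% c(0.10, 0.60)),
                  s$K_floor %||% 0, s$flood_probability %||% 0,
                  s$mortality, s$fecundity, s$ev_sd_fraction %||% 0.20,
                  s$initial_males, s$initial_females))
  S <- length(sp)
  disp <- array(0, c(S, S, 2L, 3L))
  states <- c("baseline", "flood", "post_flood")
  ages <- c("adult", "juvenile")
  for (st in 1:3) for (a in 1:2)
    disp[, , a, st] <- matrix(unlist(j$dispersal[[states[st]]][[ages[a]]]),
                              S, S, byrow = TRUE)
  pva_config(sp, disp, j$replicates %||% 1000L, j$horizon %||% 100L,
             j$max_age %||% 20L, j$sex_ratio %||% 0.5, j$seed %||% 1L)
}

#' @rdname read_pva_config
#' @param cfg a [pva_config()].
#' @export
write_pva_config <- function(cfg, path) {
  states <- c("baseline", "flood", "post_flood")
  age_cl <- c("adult", "juvenile")
  disp <- list()
  for (st in 1:3) {
    disp[[states[st]]] <- list()
    for (a in 1:2)
      disp[[states[st]]][[age_cl[a]]] <-
        apply(cfg$dispersal[, , a, st], 1L, as.numeric, simplify = FALSE)
  }
  out <- list(subpops = lapply(cfg$subpops, unclass), dispersal = disp,
              replicates = cfg$replicates, horizon = cfg$horizon,
              max_age = cfg$max_age, sex_ratio = cfg$sex_ratio,
              seed = cfg$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The canonical PVA scenario, with optional overrides
#'
#' Loads the frozen study configuration (`canonical_study.json`): three
#' subpopulations, high-flow probability 0.05 at the flow-affected
#' subpopulation only, post-flood carrying-capacity reset with 10-60%/yr
#' decay, environmental-variation SD equal to 20% of baseline mortality,
#' flow-state-dependent mortality/fecundity/dispersal, 1000 replicates of
#' 100 years.
#'
#' @param ... overrides: top-level `pva_config` fields (`replicates`,
#'   `horizon`, `seed`, ...) or a `subpops`/`dispersal` replacement. Unknown
#'   names are an error.
#' @return A validated [pva_config()].
#' @export
pva_fixture <- function(...) {
  path <- system.file("extdata", "canonical_study.json",
                      package = "plovermeta", mustWork = TRUE)
  cfg <- read_pva_config(path)
  ov <- list(...)
  if (length(ov)) {
    special <- "ev_sd_fraction"  # broadcast to every subpopulation
    bad <- setdiff(names(ov), c(names(cfg), special))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == ""))
      msg_stop("unknown override key(s): ",
               paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    if ("ev_sd_fraction" %in% names(ov)) {
      cfg$subpops <- lapply(cfg$subpops, function(s) {
        s$ev_sd_fraction <- ov$ev_sd_fraction
        s
      })
      ov$ev_sd_fraction <- NULL
    }
    cfg[names(ov)] <- ov
    cfg <- pva_config(cfg$subpops, cfg$dispersal, cfg$replicates,
                      cfg$horizon, cfg$max_age, cfg$sex_ratio, cfg$seed)
  }
  cfg
}
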