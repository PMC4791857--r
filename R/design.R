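ages <- c("adult", "juvenile")

# Map symbolic term names to formula pieces over the cell frame
map_terms <- function(terms, cls) {
  subname <- if (cls == "psi") "pair" else "sub"
  out <- character()
  for (tm in terms) {
    out <- c(out, switch(tm,
      "age" = "age",
      "sub" = subname,
      "year" = "year",
      "age:sub" = paste0("age*", subname),
      "age:year" = "age*year",
      "sub:year" = paste0(subname, "*year"),
      "age:sub:year" = paste0("age*", subname, "*year"),
      "success" = "success",
      "age:success" = "success + age:success",
      "distance" = "distance",
      "high_flow" = "high_flow",
      "post_high_flow" = "post_high_flow",
      "hf_emigration" = "hf_emigration",
      "hf_immigration" = "hf_immigration",
      "posthf_immigration" = "posthf_immigration",
      "hatch" = NULL,       # individual covariates, handled separately
      "band_age" = NULL,
      msg_stop("unknown term: ", tm)))
  }
  out
}

cell_model_matrix <- function(terms, cls, cells) {
  pieces <- map_terms(terms, cls)
  f <- as.formula(paste("~", paste(c("1", pieces), collapse = " + ")))
  X <- model.matrix(f, cells)
  attr(X, "assign") <- NULL
  X
}

# Resolve the fixes data frame into a per-cell fixed-value vector (NA = free)
resolve_fixes <- function(cells, fixes, cls, is_psi = FALSE) {
  fixed <- rep(NA_real_, nrow(cells))
  if (is.null(fixes)) return(fixed)
  fx <- fixes[fixes$class == cls, , drop = FALSE]
  for (i in seq_len(nrow(fx))) {
    sel <- rep(TRUE, nrow(cells))
    strat_col <- if (is_psi) cells$origin else cells$sub
    sel <- sel & as.character(strat_col) == fx$stratum[i]
    if (is_psi && !is.na(fx$dest[i]) && fx$dest[i] != "*")
      sel <- sel & as.character(cells$dest) == fx$dest[i]
    if (!is.na(fx$year[i]))
      sel <- sel & as.character(cells$year) == as.character(fx$year[i])
    if (!is.na(fx$age[i]) && fx$age[i] != "*")
      sel <- sel & as.character(cells$age) == fx$age[i]
    if (!any(sel))
      msg_stop("fix row ", i, " (", cls, ") matches no real parameter: ",
               "check stratum/year names")
    fixed[sel] <- fx$value[i]
  }
  fixed
}

# Keep only coefficients that act on at least one free cell
keep_columns <- function(X, fixed) {
  free <- is.na(fixed)
  if (!any(free)) return(integer(0))
  which(colSums(abs(X[free, , drop = FALSE])) > 0)
}

#' Compile a model specification into design matrices
#'
#' Expands the symbolic [ms_spec()] structure over the real-parameter cells of
#' the study — survival and transition cells are (stratum, interval, age
#' class), resight cells are (stratum, occasion, age class) — attaches the
#' year-by-stratum covariates, the distance covariate, and the flow dummies,
#' and lays out one coefficient vector across the three parameter classes.
#' Coefficients that act only on fixed cells are dropped, so `k` counts free
#' coefficients only.
#'
#' @param spec an [ms_spec()] object.
#' @param histories an [encounter_histories()] object.
#' @param occ_cov an [occasion_covariates()] table (may be `NULL` when no
#'   success/flow terms are used).
#' @param dist a [distance_matrix()] (may be `NULL` when `distance` unused).
#' @param flow_stratum stratum affected by high flows; defaults to the
#'   stratum flagged by `hf_emig` in `occ_cov`.
#' @return An object of class `"ms_design"`; its `k` element is the number of
#'   free coefficients.
#' @export
compile_design <- function(spec, histories, occ_cov = NULL, dist = NULL,
                           flow_stratum = NULL) {
  stopifnot(inherits(spec, "ms_spec"), inherits(histories, "encounter_histories"))
  strata <- histories$strata
  years <- histories$years
  S <- length(strata)
  T <- length(years)
  intervals <- years[-T]

  needs_cov <- any(c("success", "age:success", "high_flow", "post_high_flow",
                     "hf_emigration", "hf_immigration", "posthf_immigration")
                   %in% c(spec$phi, spec$p, spec$psi))
  needs_dist <- "distance" %in% spec$psi

  succ <- matrix(0, S, T - 1L, dimnames = list(strata, as.character(intervals)))
  hf_year <- posthf_year <- integer(0)
  if (!is.null(occ_cov)) {
    for (i in seq_len(nrow(occ_cov))) {
      yy <- as.character(occ_cov$year[i])
      if (yy %in% colnames(succ) && occ_cov$stratum[i] %in% strata)
        succ[occ_cov$stratum[i], yy] <- occ_cov$success[i]
    }
    hf_year <- unique(occ_cov$year[occ_cov$hf_emig == 1L | occ_cov$hf_immig == 1L])
    posthf_year <- unique(occ_cov$year[occ_cov$posthf_immig == 1L])
    if (is.null(flow_stratum)) {
      fs <- unique(occ_cov$stratum[occ_cov$hf_emig == 1L])
      flow_stratum <- if (length(fs)) fs[1L] else NA_character_
    }
  } else if (needs_cov) {
    msg_stop("spec uses success/flow terms but occ_cov is NULL")
  }
  if (needs_cov) {
    miss <- setdiff(as.character(intervals),
                    as.character(occ_cov$year))
    if (length(miss) &&
        any(c("success", "age:success") %in% c(spec$phi, spec$psi)))
      msg_stop("covariates missing for interval year(s): ",
               paste(miss, collapse = ", "))
    if (any(c("high_flow", "post_high_flow", "hf_emigration",
              "hf_immigration", "posthf_immigration") %in%
            c(spec$phi, spec$psi)) &&
        (is.na(flow_stratum) || (!length(hf_year) && !length(posthf_year))))
      msg_stop("flow terms requested but occ_cov carries no flow flags")
  }
  if (needs_dist && is.null(dist))
    msg_stop("spec uses the distance term but dist is NULL")
  if (is.null(flow_stratum)) flow_stratum <- NA_character_

  yr_f <- factor(as.character(intervals), levels = as.character(intervals))
  age_f <- factor(ages, levels = ages)

  # --- phi cells: stratum x interval x age -------------------------------
  phi_cells <- expand.grid(sub = factor(strata, levels = strata),
                           year = yr_f, age = age_f,
                           KEEP.OUT.ATTRS = FALSE)
  phi_cells$success <- succ[cbind(as.character(phi_cells$sub),
                                  as.character(phi_cells$year))] *
    (phi_cells$age == "adult")  # success acts on adult survival only
  phi_cells$high_flow <- as.numeric(
    phi_cells$sub == flow_stratum & phi_cells$year %in% as.character(hf_year))
  phi_cells$post_high_flow <- as.numeric(
    phi_cells$sub == flow_stratum & phi_cells$year %in% as.character(posthf_year))
  X_phi <- cell_model_matrix(spec$phi, "phi", phi_cells)
  phi_fixed <- resolve_fixes(phi_cells, spec$fixes, "phi")
  phi_keep <- keep_columns(X_phi, phi_fixed)

  # --- p cells: stratum x occasion (2..T) x age --------------------------
  p_cells <- expand.grid(sub = factor(strata, levels = strata),
                         year = factor(as.character(years[-1L]),
                                       levels = as.character(years[-1L])),
                         age = age_f, KEEP.OUT.ATTRS = FALSE)
  X_p <- cell_model_matrix(spec$p, "p", p_cells)
  p_fixed <- resolve_fixes(p_cells, spec$fixes, "p")
  p_keep <- keep_columns(X_p, p_fixed)

  # --- psi cells: ordered pair x interval x age --------------------------
  grid <- expand.grid(origin = factor(strata, levels = strata),
                      dest = factor(strata, levels = strata),
                      year = yr_f, age = age_f, KEEP.OUT.ATTRS = FALSE)
  off <- as.character(grid$origin) != as.character(grid$dest)
  psi_cells <- grid[off, , drop = FALSE]
  rownames(psi_cells) <- NULL
  pair_levels <- paste(rep(strata, each = S), rep(strata, S), sep = "->")
  pair_levels <- pair_levels[rep(strata, each = S) != rep(strata, S)]
  psi_cells$pair <- factor(paste(psi_cells$origin, psi_cells$dest, sep = "->"),
                           levels = pair_levels)
  psi_cells$distance <- if (is.null(dist)) rep(0, nrow(psi_cells)) else
    dist[cbind(as.character(psi_cells$origin), as.character(psi_cells$dest))]
  psi_cells$success <- succ[cbind(as.character(psi_cells$origin),
                                  as.character(psi_cells$year))]
  in_hf <- psi_cells$year %in% as.character(hf_year)
  in_post <- psi_cells$year %in% as.character(posthf_year)
  psi_cells$hf_emigration <- as.numeric(psi_cells$origin == flow_stratum & in_hf)
  psi_cells$hf_immigration <- as.numeric(psi_cells$dest == flow_stratum & in_hf)
  psi_cells$posthf_immigration <- as.numeric(psi_cells$dest == flow_stratum & in_post)
  X_psi <- cell_model_matrix(spec$psi, "psi", psi_cells)
  psi_fixed <- resolve_fixes(psi_cells, spec$fixes, "psi", is_psi = TRUE)
  psi_keep <- keep_columns(X_psi, psi_fixed)

  # --- index arrays (cell row by [stratum, interval, age]) ---------------
  idx_phi <- array(seq_len(nrow(phi_cells)), dim = c(S, T - 1L, 2L))
  idx_p <- array(seq_len(nrow(p_cells)), dim = c(S, T - 1L, 2L))
  idx_psi <- array(NA_integer_, dim = c(S, S, T - 1L, 2L))
  idx_psi[cbind(match(as.character(psi_cells$origin), strata),
                match(as.character(psi_cells$dest), strata),
                match(as.character(psi_cells$year), as.character(intervals)),
                match(as.character(psi_cells$age), ages))] <-
    seq_len(nrow(psi_cells))

  # --- individual covariates on juvenile survival ------------------------
  ind_cov <- intersect(c("hatch", "band_age"), spec$phi)

  # --- beta layout -------------------------------------------------------
  beta_names <- c(
    if (length(phi_keep)) paste0("phi:", colnames(X_phi)[phi_keep]),
    if ("hatch" %in% ind_cov) "phi:hatch",
    if ("band_age" %in% ind_cov) "phi:band_age",
    if (length(p_keep)) paste0("p:", colnames(X_p)[p_keep]),
    if (length(psi_keep)) paste0("psi:", colnames(X_psi)[psi_keep]))
  k <- length(beta_names)
  n_phi <- length(phi_keep)
  n_ind <- length(ind_cov)
  n_p <- length(p_keep)
  blocks <- list(
    phi = seq_len(n_phi),
    hatch = if ("hatch" %in% ind_cov) n_phi + 1L else integer(0),
    band_age = if ("band_age" %in% ind_cov)
      n_phi + match("band_age", ind_cov) else integer(0),
    p = n_phi + n_ind + seq_len(n_p),
    psi = n_phi + n_ind + n_p + seq_len(length(psi_keep)))

  # --- compiled history data ---------------------------------------------
  first <- max.col(histories$codes > 0L, ties.method = "first")
  data <- list(codes = histories$codes, first = as.integer(first),
               juv = histories$age_class_first == "juvenile",
               hatch = histories$hatch_day, band = histories$band_age,
               freq = histories$frequency)
  # effective sample size: releases = detections that precede further exposure
  ess <- sum(histories$frequency *
               rowSums(histories$codes[, -T, drop = FALSE] > 0L))

  structure(list(
    spec = spec, strata = strata, years = years, intervals = intervals,
    S = S, T = T, flow_stratum = flow_stratum,
    phi = list(cells = phi_cells, X = X_phi, fixed = phi_fixed,
               keep = phi_keep, idx = idx_phi),
    p = list(cells = p_cells, X = X_p, fixed = p_fixed,
             keep = p_keep, idx = idx_p),
    psi = list(cells = psi_cells, X = X_psi, fixed = psi_fixed,
               keep = psi_keep, idx = idx_psi),
    ind_cov = ind_cov, blocks = blocks, beta_names = beta_names, k = k,
    data = data, ess = ess, dist = dist, occ_cov = occ_cov),
    class = "ms_design")
}

#' @export
print.ms_design <- function(x, ...) {
  cat("Compiled multistate design:", x$S, "strata x", x$T, "occasions;",
      x$k, "free coefficients\n")
  cat("  blocks: phi", length(x$blocks$phi) + length(x$ind_cov),
      "| p", length(x$blocks$p), "| psi", length(x$blocks$psi), "\n")
  cat("  fixed real parameters:",
      sum(!is.na(x$phi$fixed)) + sum(!is.na(x$p$fixed)) +
        sum(!is.na(x$psi$fixed)), "\n")
  invisible(x)
}

# Real-parameter probability arrays from a coefficient vector.
# Returns phi [S,T-1,2], p [S,T-1,2] (occasions 2..T) and psi [S,S,T-1,2]
# (stay on the diagonal), plus the juvenile-survival logit pieces the
# likelihood needs for individual covariates.
param_arrays <- function(design, beta) {
  if (length(beta) != design$k)
    msg_stop("beta has length ", length(beta), ", design expects ", design$k)
  S <- design$S; NI <- design$T - 1L
  bl <- design$blocks

  lin <- function(block, part) {
    eta <- rep(0, nrow(part$cells))
    if (length(part$keep) && length(block))
      eta <- as.vector(part$X[, part$keep, drop = FALSE] %*% beta[block])
    eta
  }

  eta_phi <- lin(bl$phi, design$phi)
  eta_p <- lin(bl$p, design$p)
  eta_psi <- lin(bl$psi, design$psi)
  if (any(!is.finite(c(eta_phi, eta_p, eta_psi))))
    msg_stop("non-finite linear predictor")

  phi_prob <- plogis(eta_phi)
  phi_prob[!is.na(design$phi$fixed)] <- design$phi$fixed[!is.na(design$phi$fixed)]
  p_prob <- plogis(eta_p)
  p_prob[!is.na(design$p$fixed)] <- design$p$fixed[!is.na(design$p$fixed)]

  phi <- array(phi_prob[design$phi$idx], dim = c(S, NI, 2L))
  p <- array(p_prob[design$p$idx], dim = c(S, NI, 2L))

  # multinomial logit with "remain" as reference; fixed cells take their
  # value and the free cells share the remaining probability
  psi <- array(0, dim = c(S, S, NI, 2L))
  fixed <- design$psi$fixed
  for (a in 1:2) for (t in seq_len(NI)) for (r in seq_len(S)) {
    rows <- design$psi$idx[r, , t, a]
    dests <- which(!is.na(rows))
    rows <- rows[dests]
    fx <- fixed[rows]
    free <- is.na(fx)
    tot_fix <- sum(fx[!free])
    e <- exp(eta_psi[rows[free]])
    denom <- 1 + sum(e)
    scale <- 1 - tot_fix
    pr <- numeric(length(rows))
    pr[!free] <- fx[!free]
    pr[free] <- scale * e / denom
    psi[r, dests, t, a] <- pr
    psi[r, r, t, a] <- scale / denom
  }

  b1 <- function(block) if (length(block)) beta[block] else 0
  list(phi = phi, p = p, psi = psi,
       phi_eta = array(eta_phi[design$phi$idx], dim = c(S, NI, 2L)),
       phi_fixed = array(design$phi$fixed[design$phi$idx], dim = c(S, NI, 2L)),
       b_hatch = b1(bl$hatch), b_band = b1(bl$band_age))
}

#' Per-history log-probabilities under the forward algorithm
#'
#' @param design an [compile_design()] object.
#' @param beta coefficient vector of length `design$k`.
#' @param data optional compiled data list (defaults to the histories the
#'   design was built from).
#' @return Numeric vector of log-probabilities, one per history row.
#' @export
history_logprob <- function(design, beta, data = NULL) {
  pa <- param_arrays(design, beta)
  d <- data %||% design$data
  ms_forward_logp_cpp(d$codes, d$first, d$juv, d$hatch, d$band,
                      pa$phi[, , 1L], pa$phi_eta[, , 2L],
                      pa$phi_fixed[, , 2L], pa$b_hatch, pa$b_band,
                      pa$p, pa$psi, design$S)
}

#' Negative log-likelihood of the multistate model
#'
#' Computes `-sum(frequency * log P(history | first release))` by a forward
#' pass over the hidden state space (strata plus an absorbing dead state),
#' with the unobserved tail handled by the standard chi recursion. Links are
#' logit for survival and resight, and multinomial logit for transitions with
#' "remain in the current stratum" as the reference category; fixed real
#' parameters are forced before the forward pass.
#'
#' @inheritParams history_logprob
#' @return The negative log-likelihood (a scalar).
#' @export
multistate_nll <- function(beta, design, data = NULL) {
  d <- data %||% design$data
  -sum(d$freq * history_logprob(design, beta, d))
}
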