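#' Fit a multistate mark-recapture model
#'
#' Maximises the Arnason-Schwarz multistate likelihood for a symbolic model
#' structure by quasi-Newton optimisation (BFGS) from a null start plus a
#' configurable number of random restarts. Standard errors come from the
#' inverse observed information scaled by the overdispersion factor `chat`;
#' model ranking uses QAICc.
#'
#' Overdispersion is supplied, not estimated: `chat` enters the
#' quasi-likelihood (`2 nll / chat`) and inflates the variance
#' (`vcov = chat * solve(hessian)`). The deviance convention is
#' `2 * (nll - nll_saturated)`, with the saturated term computed from the
#' empirical frequencies of unique histories within release cohorts
#' (release occasion, release stratum, age class at first capture).
#'
#' @param spec an [ms_spec()] model structure.
#' @param histories an [encounter_histories()] object.
#' @param occ_cov an [occasion_covariates()] table (or `NULL`).
#' @param dist a [distance_matrix()] (or `NULL`).
#' @param chat overdispersion factor, `>= 1`.
#' @param label model label used in ranking tables.
#' @param control list: `n_starts` random restarts (default 5), `maxit`
#'   BFGS iterations (default 500), `start_seed` for restart generation
#'   (default 1), `start_sd` spread of random starts (default 0.5), `gtol`
#'   gradient-norm tolerance for the convergence flag (default 1e-3).
#' @param start optional starting coefficient vector.
#' @param hessian compute the observed information (default `TRUE`).
#' @return An object of class `"ms_fit"` with elements `beta`, `se`, `vcov`,
#'   `nll`, `k`, `ess`, `chat`, `qaicc`, `deviance`, `converged`, `design`.
#'   A coefficient at an effective boundary (zero observed events) has an
#'   unbounded Wald interval and reports `se = Inf`; `NA` means the
#'   information matrix itself could not be computed.
#' @examples
#' sc <- study_scenario()
#' dat <- simulate_histories(sc, cohorts = cohort_sizes(total = 400), seed = 1)
#' f <- ms_fit(ms_spec(phi = "sub", psi = "distance"),
#'             dat$histories, dat$covariates, sc$distances)
#' coef(f)
#' @export
ms_fit <- function(spec, histories, occ_cov = NULL, dist = NULL, chat = 1,
                   label = NULL, control = list(), start = NULL,
                   hessian = TRUE) {
  if (chat < 1) msg_stop("chat must be >= 1")
  ctl <- list(n_starts = 5L, maxit = 500L, start_seed = 1L, start_sd = 0.5,
              gtol = 1e-3)
  ctl[names(control)] <- control
  design <- if (inherits(spec, "ms_design")) spec else
    compile_design(spec, histories, occ_cov, dist)
  k <- design$k
  if (k == 0L)
    msg_stop("model has no free coefficients (all parameters fixed)")

  obj <- function(b) {
    v <- tryCatch(multistate_nll(b, design), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- list(start %||% rep(0, k))
  if (ctl$n_starts > 0L) {
    rs <- local_seed(ctl$start_seed, {
      lapply(seq_len(ctl$n_starts), function(i) rnorm(k, 0, ctl$start_sd))
    })
    starts <- c(starts, rs)
  }

  # scale coefficients of wide-ranging covariates (distance in km, hatch day)
  pscale <- beta_parscale(design)
  run_bfgs <- function(par) tryCatch(
    optim(par, obj, method = "BFGS",
          control = list(maxit = ctl$maxit, reltol = 1e-12,
                         parscale = pscale)),
    error = function(e) NULL)

  best <- NULL
  for (i in seq_along(starts)) {
    opt <- run_bfgs(starts[[i]])
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (i == 1L && opt$convergence == 0L && opt$value < 1e9) break
  }
  if (is.null(best)) msg_stop("optimization failed from every start")
  # polish: restarting BFGS at the optimum resets its curvature approximation
  repolish <- run_bfgs(best$par)
  if (!is.null(repolish) && repolish$value <= best$value) best <- repolish

  beta <- best$par
  nll <- best$value
  grad <- num_grad(obj, beta) * pscale  # gradient in scaled coordinates
  converged <- best$convergence == 0L && max(abs(grad)) < ctl$gtol &&
    nll < 1e9

  # Observed-information variances. A coefficient whose MLE sits at an
  # effective boundary (e.g. a flow dummy with zero observed events runs to
  # -Inf on the logit scale) leaves a near-null eigendirection in the
  # information matrix; its Wald SE is unbounded and reported as Inf, while
  # the remaining coefficients keep proper SEs from the curved subspace.
  se <- rep(NA_real_, k)
  V <- matrix(NA_real_, k, k)
  if (hessian) {
    H <- tryCatch(stats::optimHess(beta, obj), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      H <- (H + t(H)) / 2
      eg <- eigen(H, symmetric = TRUE)
      tol <- max(eg$values, 0) * 1e-9
      kept <- eg$values > tol
      if (any(kept)) {
        Uk <- eg$vectors[, kept, drop = FALSE]
        V <- chat * Uk %*% (t(Uk) / eg$values[kept])
        se <- sqrt(pmax(diag(V), 0))
        flat <- rowSums(eg$vectors[, !kept, drop = FALSE]^2) > 0.01
        se[flat] <- Inf
      }
    }
  }
  names(beta) <- names(se) <- design$beta_names

  sat <- saturated_nll(design)
  qa <- if (design$ess > k + 1L) qaicc(nll, chat, k, design$ess) else NA_real_

  structure(list(
    beta = beta, se = se, vcov = V, nll = nll, k = k, ess = design$ess,
    chat = chat, qaicc = qa, deviance = 2 * (nll - sat) / chat,
    saturated_nll = sat, converged = converged, grad_norm = max(abs(grad)),
    design = design, label = label %||% format_spec_label(design$spec)),
    class = "ms_fit")
}

# Run code under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# One parscale entry per coefficient: inverse of the largest absolute design
# value it multiplies, so a unit step in scaled space moves the linear
# predictor by about one
beta_parscale <- function(design) {
  sc <- rep(1, design$k)
  for (cls in c("phi", "p", "psi")) {
    part <- design[[cls]]
    if (!length(part$keep)) next
    cmax <- apply(abs(part$X[, part$keep, drop = FALSE]), 2L, max)
    sc[design$blocks[[cls]]] <- 1 / pmax(cmax, 1e-8)
  }
  d <- design$data
  if (length(design$blocks$hatch))
    sc[design$blocks$hatch] <- 1 / max(abs(d$hatch), 1)
  if (length(design$blocks$band_age))
    sc[design$blocks$band_age] <- 1 / max(abs(d$band), 1)
  pmin(sc, 1)
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

format_spec_label <- function(spec) {
  fmt <- function(t) if (length(t)) paste(t, collapse = "+") else "1"
  paste0("phi(", fmt(spec$phi), ") p(", fmt(spec$p), ") psi(", fmt(spec$psi), ")")
}

# Saturated multinomial nll: each unique history within its release cohort
# gets its empirical frequency
saturated_nll <- function(design) {
  d <- design$data
  hist_str <- apply(d$codes, 1L, paste, collapse = "")
  cohort <- paste(d$first, hist_str_first(d), d$juv, sep = "|")
  key <- paste(cohort, hist_str, sep = "#")
  n_h <- tapply(d$freq, key, sum)
  coh_of <- sub("#.*", "", names(n_h))
  N_g <- tapply(n_h, coh_of, sum)
  -sum(n_h * log(n_h / N_g[coh_of]))
}

hist_str_first <- function(d) d$codes[cbind(seq_len(nrow(d$codes)), d$first)]

#' Quasi-likelihood AICc
#'
#' `2 nll / chat + 2 k + 2 k (k + 1) / (ess - k - 1)`.
#'
#' @param nll negative log-likelihood.
#' @param chat overdispersion factor (>= 1).
#' @param k number of free coefficients.
#' @param ess effective sample size (releases).
#' @return The QAICc value.
#' @export
qaicc <- function(nll, chat, k, ess) {
  if (ess <= k + 1) msg_stop("QAICc undefined: ess must exceed k + 1")
  2 * nll / chat + 2 * k + 2 * k * (k + 1) / (ess - k - 1)
}

#' @export
print.ms_fit <- function(x, ...) {
  cat("Multistate mark-recapture fit:", x$label, "\n")
  cat(sprintf("  k = %d, ess = %d, chat = %.2f\n", x$k, x$ess, x$chat))
  cat(sprintf("  -logLik = %.3f, deviance = %.3f, QAICc = %.3f\n",
              x$nll, x$deviance, x$qaicc))
  cat("  converged:", x$converged,
      sprintf("(max |gradient| %.2g)\n", x$grad_norm))
  invisible(x)
}

#' @export
coef.ms_fit <- function(object, ...) object$beta

#' @export
vcov.ms_fit <- function(object, ...) object$vcov

#' @export
logLik.ms_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, class = "logLik")
}

#' @export
summary.ms_fit <- function(object, ...) {
  out <- list(fit = object, wald = wald(object))
  class(out) <- "summary.ms_fit"
  out
}

#' @export
print.summary.ms_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (Wald):\n")
  w <- x$wald
  w$estimate <- round(w$estimate, 3)
  w$se <- round(w$se, 3)
  w$z <- round(w$z, 3)
  w$lower <- round(w$lower, 3)
  w$upper <- round(w$upper, 3)
  print(w, row.names = FALSE)
  invisible(x)
}

#' Wald table for a fitted model
#'
#' Per-coefficient estimate, standard error, `|beta/SE|`, and 95% confidence
#' interval (`estimate +/- 1.96 SE`). Coefficients whose SE is unavailable
#' (singular information) are flagged with `NA`.
#'
#' @param fit an [ms_fit()] object.
#' @return A data frame with columns `term`, `estimate`, `se`, `z`, `lower`,
#'   `upper`.
#' @export
wald <- function(fit) {
  b <- fit$beta; s <- fit$se
  data.frame(term = names(b), estimate = unname(b), se = unname(s),
             z = abs(unname(b) / unname(s)),
             lower = unname(b) - 1.96 * unname(s),
             upper = unname(b) + 1.96 * unname(s),
             stringsAsFactors = FALSE)
}

#' Real-scale parameter estimates from a fit
#'
#' Back-transforms the fitted coefficients to probability-scale survival,
#' resight, or transition estimates for every real-parameter cell, with
#' delta-method standard errors. `newdata` can override covariate columns
#' of the cell table (e.g. evaluate transition rates at a given
#' reproductive-success value); values outside the fitted covariate range
#' trigger a warning but are extrapolated.
#'
#' @param object an [ms_fit()] object.
#' @param type `"phi"`, `"p"` or `"psi"`.
#' @param newdata optional named list of covariate overrides.
#' @param ... unused.
#' @return The cell table with `estimate` and `se` columns appended.
#' @export
predict.ms_fit <- function(object, type = c("phi", "p", "psi"),
                           newdata = NULL, ...) {
  type <- match.arg(type)
  design <- object$design
  if (!is.null(newdata)) design <- override_cells(design, type, newdata)
  cells <- design[[type]]$cells
  est <- cell_estimates(design, type, object$beta)
  J <- vapply(seq_along(object$beta), function(i) {
    h <- 1e-5
    e <- numeric(length(object$beta)); e[i] <- h
    (cell_estimates(design, type, object$beta + e) -
       cell_estimates(design, type, object$beta - e)) / (2 * h)
  }, numeric(length(est)))
  J <- matrix(J, nrow = length(est))
  se <- rep(NA_real_, length(est))
  if (all(is.finite(object$vcov))) {
    v <- rowSums((J %*% object$vcov) * J)
    se <- sqrt(pmax(v, 0))
  }
  out <- cells
  out$estimate <- est
  out$se <- se
  out$fixed <- !is.na(design[[type]]$fixed)
  out
}

override_cells <- function(design, type, newdata) {
  part <- design[[type]]
  for (nm in names(newdata)) {
    if (!nm %in% names(part$cells))
      msg_stop("unknown covariate override: ", nm)
    rng <- range(part$cells[[nm]])
    if (any(newdata[[nm]] < rng[1] | newdata[[nm]] > rng[2]))
      warning("covariate '", nm, "' outside the fitted support; extrapolating",
              call. = FALSE)
    part$cells[[nm]] <- newdata[[nm]]
  }
  part$X <- cell_model_matrix(design$spec[[type]], type, part$cells)
  design[[type]] <- part
  design
}

# Cell tables are laid out in the same (stratum-fastest) order as the
# probability arrays, so extraction is direct.
cell_estimates <- function(design, type, beta) {
  pa <- param_arrays(design, beta)
  if (type == "psi") pa$psi[outer_idx(design)] else as.vector(pa[[type]])
}

outer_idx <- function(design) {
  cells <- design$psi$cells
  cbind(match(as.character(cells$origin), design$strata),
        match(as.character(cells$dest), design$strata),
        match(as.character(cells$year), as.character(design$intervals)),
        match(as.character(cells$age), ages))
}

#' Simulate encounter histories from a fitted model
#'
#' Draws new encounter histories from the fitted real-parameter arrays using
#' the same release structure (occasions, strata, age classes, individual
#' covariates) as the original data.
#'
#' @param object an [ms_fit()] object.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of [encounter_histories()] objects (length `nsim`).
#' @export
simulate.ms_fit <- function(object, nsim = 1, seed = NULL, ...) {
  design <- object$design
  pa <- param_arrays(design, object$beta)
  d <- design$data
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(r) {
    sim_from_arrays(pa, d, design$strata, design$years)
  })
}
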