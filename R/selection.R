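#' Rank fitted models by QAICc and compute Akaike weights
#'
#' Computes `delta = QAICc - min(QAICc)` and weights
#' `w = exp(-delta/2) / sum(exp(-delta/2))`, sorted ascending by QAICc with
#' ties broken by smaller `k`, then label order.
#'
#' @param fits a list of [ms_fit()] objects (or a single fit).
#' @return An object of class `"ms_model_set"`: the sorted fits plus a
#'   ranking table.
#' @export
rank_and_weight <- function(fits) {
  if (inherits(fits, "ms_fit")) fits <- list(fits)
  if (!length(fits)) msg_stop("need at least one fitted model")
  qa <- vapply(fits, function(f) f$qaicc, numeric(1))
  kk <- vapply(fits, function(f) f$k, numeric(1))
  lab <- vapply(fits, function(f) f$label, character(1))
  ord <- order(qa, kk, lab)
  fits <- fits[ord]; qa <- qa[ord]; kk <- kk[ord]; lab <- lab[ord]
  delta <- qa - qa[1L]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(model = lab, k = kk,
                    deviance = vapply(fits, function(f) f$deviance, numeric(1)),
                    qaicc = qa, delta = delta, weight = w,
                    converged = vapply(fits, function(f) f$converged, logical(1)),
                    stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab), class = "ms_model_set")
}

#' @export
print.ms_model_set <- function(x, digits = 3, ...) {
  cat("Multistate model set (", nrow(x$table), " models)\n", sep = "")
  tab <- x$table
  tab$deviance <- round(tab$deviance, digits)
  tab$qaicc <- round(tab$qaicc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Model-averaged real-scale estimates
#'
#' Averages the probability-scale cell estimates of every model in the set
#' with its Akaike weight, and reports the unconditional standard error
#' `sqrt( sum_i w_i * (se_i^2 + (theta_i - theta_bar)^2) )`, i.e. the
#' conditional variance plus the squared deviation from the average.
#'
#' @param modelset an [rank_and_weight()] model set.
#' @param type `"phi"`, `"p"` or `"psi"`.
#' @param newdata optional covariate overrides passed to [predict.ms_fit()].
#' @return The cell table with `estimate` (averaged) and `se` (unconditional).
#' @export
model_average <- function(modelset, type = c("phi", "p", "psi"),
                          newdata = NULL) {
  type <- match.arg(type)
  w <- modelset$table$weight
  preds <- lapply(modelset$fits, predict, type = type, newdata = newdata)
  est <- sapply(preds, `[[`, "estimate")
  se <- sapply(preds, `[[`, "se")
  est <- matrix(est, ncol = length(w))
  se <- matrix(se, ncol = length(w))
  avg <- drop(est %*% w)
  vu <- drop((se^2 + (est - avg)^2) %*% w)
  out <- preds[[1L]]
  out$estimate <- avg
  out$se <- sqrt(pmax(vu, 0))
  out
}

# ---------------------------------------------------------------------------
# Sequential model selection
# ---------------------------------------------------------------------------

# All additive subsets of {age, sub, year} plus the multiplicative variants;
# 15 structures (the additive 8 + age:sub, age:year, sub:year, age:sub:year,
# and the three two-way-interaction-plus-main combinations)
factor_structures <- function(mandatory = character()) {
  base <- list(character(0), "age", "sub", "year",
               c("age", "sub"), c("age", "year"), c("sub", "year"),
               c("age", "sub", "year"),
               "age:sub", "age:year", "sub:year", "age:sub:year",
               c("age:sub", "year"), c("age:year", "sub"),
               c("sub:year", "age"))
  lapply(base, function(tm) unique(c(mandatory, tm)))
}

#' Candidate catalogue for the four-stage selection procedure
#'
#' Builds the default candidate lists: stage 1 varies the resight structure
#' with survival and transitions at their most complex (`age:sub:year`);
#' stage 2 varies survival (always controlling for age class and the
#' hatch-date and banding-age covariates); stage 3 varies transitions
#' (including a constant model); stage 4 substitutes biological covariates
#' (distance, flow dummies, reproductive success) for the `sub`/`year`
#' factors in every transition structure retained within `delta_max` QAICc
#' of the stage-3 leader, crossed with survival structures augmented by flow
#' and success terms.
#'
#' @param p_mandatory terms forced into every resight structure (the study
#'   controlled for subpopulation differences in search effort).
#' @param phi_mandatory terms forced into every survival structure.
#' @param delta_max QAICc window for carrying transition structures into
#'   stage 4 (default 4).
#' @return A list with elements `p`, `phi`, `psi`, `phi_stage4_extras`,
#'   `delta_max`, `maximal`.
#' @export
selection_catalogue <- function(p_mandatory = "sub",
                                phi_mandatory = c("age", "hatch", "band_age"),
                                delta_max = 4) {
  list(
    p = factor_structures(p_mandatory),
    phi = factor_structures(phi_mandatory),
    psi = factor_structures(),
    phi_stage4_extras = list(character(0),
                             c("high_flow", "post_high_flow"),
                             "success",
                             c("high_flow", "post_high_flow", "success")),
    delta_max = delta_max,
    maximal = "age:sub:year")
}

#' Substitute biological covariates into a transition structure
#'
#' Implements the stage-4 replacement grammar: every occurrence of `sub`
#' becomes `distance`; every occurrence of `year` becomes one of the three
#' variants `{flow dummies}`, `{success}`, `{flow dummies + success}`; when
#' the structure contains `age`, success enters with its age interaction.
#' Interactions involving a replaced factor are decomposed additively (the
#' substituted covariates enter as main effects, as in the reported models).
#'
#' @param terms character vector of transition-model terms.
#' @return A list of substituted term vectors (no duplicates). Structures
#'   containing `year` expand to three variants; others to one.
#' @export
expand_psi_structure <- function(terms) {
  flat <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  has_age <- "age" %in% flat
  has_sub <- "sub" %in% flat
  has_year <- "year" %in% flat
  keep <- setdiff(flat, c("sub", "year"))
  base <- c(keep, if (has_sub) "distance")
  flow <- c("hf_emigration", "hf_immigration", "posthf_immigration")
  succ <- if (has_age) c("success", "age:success") else "success"
  variants <- if (has_year)
    list(c(base, flow), c(base, succ), c(base, flow, succ))
  else list(base)
  unique(lapply(variants, unique))
}

#' Four-stage sequential model selection
#'
#' Reduces the candidate space stage by stage: (1) choose the resight
#' structure holding survival and transitions maximal; (2) choose the
#' survival structure holding transitions maximal; (3) rank transition
#' structures; (4) substitute distance/flow/success covariates into every
#' transition structure within `delta_max` of the stage-3 leader
#' ([expand_psi_structure()]), cross with the augmented survival structures,
#' and rank the resulting models. The best (lowest-QAICc) structure is
#' carried forward at each stage.
#'
#' @inheritParams ms_fit
#' @param catalogue a [selection_catalogue()] (or a compatible list).
#' @param fixes fixed real parameters applied to every model (default
#'   [standard_fixes()] when `occ_cov` carries flow flags, otherwise none).
#' @param control,chat passed to [ms_fit()].
#' @param verbose print stage progress.
#' @return A list with per-stage model sets (`stage1` ... `stage4`) and
#'   `final` (the stage-4 [rank_and_weight()] set).
#' @export
sequential_selection <- function(histories, occ_cov = NULL, dist = NULL,
                                 catalogue = selection_catalogue(),
                                 fixes = NULL, chat = 1, control = list(),
                                 verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  fit1 <- function(phi, p, psi) {
    sp <- ms_spec(phi = phi, p = p, psi = psi, fixes = fixes)
    ms_fit(sp, histories, occ_cov, dist, chat = chat, control = control)
  }
  fit_all <- function(specs) rank_and_weight(lapply(specs, function(s)
    fit1(s$phi, s$p, s$psi)))
  maximal <- catalogue$maximal %||% "age:sub:year"

  if (!length(catalogue$p) || !length(catalogue$phi) || !length(catalogue$psi))
    msg_stop("empty candidate list")

  say("stage 1: resight structure (", length(catalogue$p), " models)")
  s1 <- fit_all(lapply(catalogue$p, function(p)
    list(phi = unique(c("age:sub:year", "hatch", "band_age")),
         p = p, psi = maximal)))
  best_p <- s1$fits[[1L]]$design$spec$p

  say("stage 2: survival structure (", length(catalogue$phi), " models)")
  s2 <- fit_all(lapply(catalogue$phi, function(phi)
    list(phi = phi, p = best_p, psi = maximal)))
  best_phi <- s2$fits[[1L]]$design$spec$phi

  say("stage 3: transition structure (", length(catalogue$psi), " models)")
  s3 <- fit_all(lapply(catalogue$psi, function(psi)
    list(phi = best_phi, p = best_p, psi = psi)))
  retained <- s3$table$delta <= (catalogue$delta_max %||% 4)
  psi_keep <- lapply(s3$fits[retained], function(f) f$design$spec$psi)

  say("stage 4: covariate substitution")
  psi_vars <- unique(unlist(lapply(psi_keep, expand_psi_structure),
                            recursive = FALSE))
  phi_vars <- lapply(catalogue$phi_stage4_extras %||% list(character(0)),
                     function(extra) unique(c(best_phi, extra)))
  specs <- list()
  for (phi in phi_vars) for (psi in psi_vars)
    specs[[length(specs) + 1L]] <- list(phi = phi, p = best_p, psi = psi)
  say("  ", length(specs), " models")
  s4 <- fit_all(specs)

  list(stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4, final = s4)
}
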