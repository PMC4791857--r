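#' Chicks fledged per pair
#'
#' The reproductive-output estimator: clutch size x probability that a
#' female has a successful nest (which accounts for renesting after
#' failures) x chick survival to fledging.
#'
#' @param clutch_size mean eggs per clutch (default 3.73).
#' @param female_success probability a female has a successful nest.
#' @param chick_survival probability a chick survives to fledging.
#' @return Chicks fledged per pair.
#' @export
chicks_per_pair <- function(clutch_size = 3.73, female_success, chick_survival) {
  if (clutch_size <= 0) msg_stop("clutch_size must be positive")
  if (any(c(female_success, chick_survival) < 0) ||
      any(c(female_success, chick_survival) > 1))
    msg_stop("female_success and chick_survival must be probabilities")
  clutch_size * female_success * chick_survival
}

#' Mean annual reproductive output per subpopulation
#'
#' Arithmetic mean of yearly chicks-fledged-per-pair values, reported to two
#' decimals in the output tables.
#'
#' @param x a numeric matrix (rows = subpopulations, columns = years), a
#'   data frame of the same shape, or a single numeric vector of yearly
#'   values.
#' @return Named numeric vector of per-subpopulation means.
#' @export
mean_reproductive_output <- function(x) {
  if (is.null(dim(x))) {
    if (!length(x)) msg_stop("no yearly values supplied")
    return(mean(as.numeric(x)))
  }
  x <- as.matrix(x)
  if (!ncol(x)) msg_stop("no yearly values supplied")
  rowMeans(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> fit -> model averaging -> PVA -> report with one
#' master seed, writing every artifact plus a provenance log to `out_dir`.
#' Stage seeds are derived from the master seed by one `sample.int()` draw
#' per stage under `set.seed(seed)`, so stages are independently
#' reproducible.
#'
#' The `fit` stage ranks a compact candidate set around the generating
#' structure (with/without the distance and flow covariates) rather than the
#' full four-stage cascade; use [sequential_selection()] directly for the
#' latter.
#'
#' @param stages character subset of `c("simulate", "fit", "pva", "report")`.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param scenario a [study_scenario()].
#' @param cohorts release cohorts (default the study banding totals).
#' @param pva_cfg a [pva_config()]; default [pva_fixture()].
#' @param chat overdispersion input for QAICc.
#' @return A `"report_bundle"` list with the tables produced (ranked model
#'   table, coefficient table, model-averaged rates, reproductive-output
#'   table, PVA summary), invisibly also written to `out_dir`.
#' @export
run_pipeline <- function(stages = c("simulate", "fit", "pva", "report"),
                         seed = 1L, out_dir = tempfile("pipeline"),
                         scenario = study_scenario(),
                         cohorts = cohort_sizes(scenario = scenario),
                         pva_cfg = NULL, chat = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- local_seed(seed, sample.int(2^31 - 2, 4L))
  bundle <- list(seed = seed)
  fail <- function(stage, e) msg_stop("stage '", stage, "' failed: ",
                                      conditionMessage(e))

  dat <- NULL
  if ("simulate" %in% stages) {
    dat <- tryCatch(
      simulate_histories(scenario, cohorts, seed = stage_seed[1]),
      error = function(e) fail("simulate", e))
    write_encounters(dat$histories, file.path(out_dir, "encounters.csv"))
    write_covariates(dat$covariates, file.path(out_dir, "covariates.csv"))
    write_inp(dat$histories, file.path(out_dir, "encounters.inp"))
    jsonlite::write_json(
      list(seed = stage_seed[1], n_birds = sum(dat$histories$frequency),
           truth = dat$truth),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("fit" %in% stages) {
    if (is.null(dat))
      dat <- simulate_histories(scenario, cohorts, seed = stage_seed[1])
    fits <- tryCatch({
      base_psi <- c("age", "distance", "hf_emigration", "hf_immigration",
                    "posthf_immigration")
      cand <- list(
        scenario$generating_spec,
        ms_spec(phi = scenario$generating_spec$phi, p = "age:sub",
                psi = c("age", "distance"), fixes = standard_fixes()),
        ms_spec(phi = scenario$generating_spec$phi, p = "age:sub",
                psi = "age", fixes = standard_fixes()),
        ms_spec(phi = c("age:sub", "hatch", "band_age"), p = "age:sub",
                psi = base_psi, fixes = standard_fixes()))
      lapply(cand, ms_fit, histories = dat$histories,
             occ_cov = dat$covariates, dist = scenario$distances, chat = chat)
    }, error = function(e) fail("fit", e))
    mset <- rank_and_weight(fits)
    bundle$model_table <- mset$table
    bundle$coefficients <- wald(mset$fits[[1L]])
    bundle$averaged_phi <- model_average(mset, "phi")
    bundle$averaged_psi <- model_average(mset, "psi")
    write.csv(round_cols(bundle$model_table, 3), row.names = FALSE,
              file.path(out_dir, "model_table.csv"))
    write.csv(round_cols(bundle$coefficients, 3), row.names = FALSE,
              file.path(out_dir, "coefficients.csv"))
    write.csv(round_cols(bundle$averaged_phi, 2), row.names = FALSE,
              file.path(out_dir, "averaged_phi.csv"))
    write.csv(round_cols(bundle$averaged_psi, 2), row.names = FALSE,
              file.path(out_dir, "averaged_psi.csv"))
    jsonlite::write_json(
      lapply(mset$fits, function(f)
        list(label = f$label, beta = f$beta, se = f$se, nll = f$nll,
             k = f$k, qaicc = f$qaicc)),
      file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("pva" %in% stages) {
    cfg <- pva_cfg %||% pva_fixture()
    cfg$seed <- as.integer(stage_seed[3] %% 2^31)
    tf <- tempfile(fileext = ".json")
    write_pva_config(cfg, tf)
    bundle$pva_config_md5 <- unname(tools::md5sum(tf))
    unlink(tf)
    pva <- tryCatch(run_pva(cfg), error = function(e) fail("pva", e))
    bundle$pva_summary <- summary(pva)
    jsonlite::write_json(pva$summary, file.path(out_dir, "pva_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    succ <- scenario$success
    bundle$reproductive_output <- data.frame(
      subpopulation = rownames(succ),
      round(succ, 2),
      mean = round(mean_reproductive_output(succ), 2),
      check.names = FALSE)
    write.csv(bundle$reproductive_output, row.names = FALSE,
              file.path(out_dir, "reproductive_output.csv"))
  }

  prov <- list(seed = seed, stage_seeds = stage_seed, stages = stages,
               pva_config_md5 = bundle$pva_config_md5,
               package_version = as.character(utils::packageVersion("plovermeta")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle$out_dir <- out_dir
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

round_cols <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Pipeline report bundle (seed", x$seed, ") with:",
      paste(setdiff(names(x), c("seed", "out_dir")), collapse = ", "), "\n")
  cat("  artifacts in:", x$out_dir, "\n")
  invisible(x)
}
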