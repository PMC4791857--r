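#' Symbolic model specification for the multistate model
#'
#' Declares, for each parameter class — apparent survival `phi`, resight `p`,
#' and transition `psi` — the covariate structure of its linear predictor,
#' plus any real parameters fixed to known probabilities.
#'
#' Recognised terms (an intercept is always included):
#' \describe{
#'   \item{`age`}{juvenile vs adult (adult is the reference). Age is a
#'     time-varying state: a bird first captured as a juvenile has juvenile
#'     rates for its first interval only, adult rates thereafter.}
#'   \item{`sub`}{for `phi`/`p`, the stratum; for `psi`, the ordered
#'     origin:destination pair (so its coefficients are pair intercepts,
#'     the structure that the distance covariate replaces).}
#'   \item{`year`}{interval (for `phi`, `psi`) or occasion (for `p`) factor.}
#'   \item{`age:sub`, `age:year`, `sub:year`, `age:sub:year`}{full factorial
#'     interactions (main effects are added automatically).}
#'   \item{`hatch`, `band_age`}{individual covariates on juvenile survival
#'     (day of season hatched; age in days at banding); `phi` only.}
#'   \item{`success`, `age:success`}{reproductive success (chicks
#'     fledged/pair) at the bird's stratum (for `phi`) or the origin stratum
#'     (for `psi`) in the interval-start year.}
#'   \item{`distance`}{pairwise distance (km) between origin and destination;
#'     `psi` only.}
#'   \item{`high_flow`, `post_high_flow`}{flow dummies on survival at the
#'     flow-affected stratum; `phi` only.}
#'   \item{`hf_emigration`, `hf_immigration`, `posthf_immigration`}{flow
#'     dummies on transitions out of / into the flow-affected stratum;
#'     `psi` only.}
#' }
#'
#' @param phi,p,psi character vectors of term names (use `character(0)` or
#'   `"1"` for an intercept-only structure).
#' @param fixes `NULL` or a data frame with columns `class` ("phi", "p" or
#'   "psi"), `stratum` (origin stratum), `dest` (`NA` except for psi; a
#'   destination name or `"*"` for all), `year` (interval-start year, or `NA`
#'   for all), `age` ("juvenile", "adult" or `"*"`), `value` (probability in
#'   \[0, 1\]). See [standard_fixes()].
#' @return An object of class `"ms_spec"`.
#' @seealso [compile_design()], [ms_fit()]
#' @export
ms_spec <- function(phi = character(), p = character(), psi = character(),
                    fixes = NULL) {
  norm <- function(x) {
    x <- as.character(x)
    x[x != "1"]
  }
  phi <- norm(phi); p <- norm(p); psi <- norm(psi)
  shared <- c("age", "sub", "year", "age:sub", "age:year", "sub:year",
              "age:sub:year")
  allowed <- list(
    phi = c(shared, "hatch", "band_age", "success", "age:success",
            "high_flow", "post_high_flow"),
    p = shared,
    psi = c(shared, "distance", "success", "age:success",
            "hf_emigration", "hf_immigration", "posthf_immigration"))
  for (cls in c("phi", "p", "psi")) {
    bad <- setdiff(get(cls), allowed[[cls]])
    if (length(bad))
      msg_stop("unknown ", cls, " term(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(fixes)) {
    need <- c("class", "stratum", "dest", "year", "age", "value")
    if (!all(need %in% names(fixes)))
      msg_stop("fixes needs columns: ", paste(need, collapse = ", "))
    if (any(fixes$value < 0 | fixes$value > 1))
      msg_stop("fixed values must be probabilities in [0, 1]")
  }
  structure(list(phi = phi, p = p, psi = psi, fixes = fixes),
            class = "ms_spec")
}

#' @export
print.ms_spec <- function(x, ...) {
  fmt <- function(t) if (length(t)) paste(t, collapse = " + ") else "1"
  cat("Multistate model specification\n")
  cat("  phi ~", fmt(x$phi), "\n")
  cat("  p   ~", fmt(x$p), "\n")
  cat("  psi ~", fmt(x$psi), "\n")
  if (!is.null(x$fixes)) cat("  fixed real parameters:", nrow(x$fixes), "\n")
  invisible(x)
}

#' Mandatory fixed parameters for the flood years
#'
#' No chicks fledged at the flow-affected subpopulation in the two high-flow
#' years, so juvenile survival there and juvenile emigration out of it are
#' fixed to 0 for the intervals starting in those years — these cells have no
#' releases and would otherwise be inestimable.
#'
#' @param flow_stratum name of the flow-affected stratum.
#' @param years interval-start years to fix (default the two flood years).
#' @return A `fixes` data frame for [ms_spec()].
#' @export
standard_fixes <- function(flow_stratum = "M1F", years = c(2010L, 2011L)) {
  rbind(
    data.frame(class = "phi", stratum = flow_stratum, dest = NA_character_,
               year = years, age = "juvenile", value = 0,
               stringsAsFactors = FALSE),
    data.frame(class = "psi", stratum = flow_stratum, dest = "*",
               year = years, age = "juvenile", value = 0,
               stringsAsFactors = FALSE))
}
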