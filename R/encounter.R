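#' Encounter-history container
#'
#' Builds the basic data object of the multistate analysis: one row per bird
#' (or per group of birds with an identical history), a state code for every
#' annual occasion, and the individual covariates carried by birds first
#' captured as chicks.
#'
#' State codes are `0` (not seen that year) or the stratum index `1..S`, where
#' the strata are the subpopulations. Birds first captured as juveniles carry
#' `hatch_day` (day of season) and `band_age` (days between hatching and
#' banding); adults carry the reference value 0 for both.
#'
#' @param codes integer matrix, one row per bird, one column per occasion;
#'   entries in `0..length(strata)`.
#' @param age_class_first character/factor, `"adult"` or `"juvenile"`, age
#'   class at first capture.
#' @param hatch_day,band_age numeric vectors (days); must be 0 for adults.
#' @param bird_id optional identifiers (default `h1, h2, ...`).
#' @param frequency positive integer counts of identical histories (default 1).
#' @param strata character vector of stratum names (default `A`, `B`, ...).
#' @param years occasion labels (default `1..T`).
#' @return An object of class `"encounter_histories"`.
#' @export
encounter_histories <- function(codes, age_class_first,
                                hatch_day = NULL, band_age = NULL,
                                bird_id = NULL, frequency = NULL,
                                strata = NULL, years = NULL) {
  codes <- as.matrix(codes)
  dimnames(codes) <- NULL
  storage.mode(codes) <- "integer"
  n <- nrow(codes)
  S <- if (is.null(strata)) max(codes) else length(strata)
  if (is.null(strata)) strata <- LETTERS[seq_len(max(S, 1L))]
  if (is.null(years)) years <- seq_len(ncol(codes))
  age <- as.character(age_class_first)
  if (length(age) == 1L) age <- rep(age, n)
  if (!all(age %in% c("adult", "juvenile")))
    msg_stop("age_class_first must be 'adult' or 'juvenile'")
  hatch_day <- if (is.null(hatch_day)) numeric(n) else as.numeric(hatch_day)
  band_age <- if (is.null(band_age)) numeric(n) else as.numeric(band_age)
  frequency <- if (is.null(frequency)) rep(1L, n) else as.integer(frequency)
  bird_id <- if (is.null(bird_id)) paste0("h", seq_len(n)) else as.character(bird_id)

  if (any(codes < 0L | codes > S))
    msg_stop("state codes must lie in 0..", S, " (stratum index or 0 = unseen)")
  if (any(rowSums(codes > 0L) == 0L))
    msg_stop("every history needs at least one detection")
  if (any(frequency < 1L)) msg_stop("frequency must be >= 1")
  adult <- age == "adult"
  if (any(hatch_day[adult] != 0) || any(band_age[adult] != 0))
    msg_stop("hatch_day/band_age carry the reference value 0 for adults")
  if (length(age) != n || length(hatch_day) != n || length(band_age) != n ||
      length(frequency) != n || length(bird_id) != n)
    msg_stop("all per-bird vectors must match nrow(codes)")

  structure(
    list(codes = codes, age_class_first = age, hatch_day = hatch_day,
         band_age = band_age, frequency = frequency, bird_id = bird_id,
         strata = strata, years = years),
    class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("Encounter histories:", nrow(x$codes), "rows (",
      sum(x$frequency), "birds ),", ncol(x$codes), "occasions,",
      length(x$strata), "strata (", paste(x$strata, collapse = ", "), ")\n")
  cat("  occasions:", paste(x$years, collapse = " "), "\n")
  cat("  age at first capture:",
      sum(x$frequency[x$age_class_first == "adult"]), "adult /",
      sum(x$frequency[x$age_class_first == "juvenile"]), "juvenile\n")
  invisible(x)
}

#' Read / write encounter-history CSV files
#'
#' The CSV schema is one row per bird: `bird_id`, `age_class_first`,
#' `hatch_day`, `band_age`, `frequency`, then one `y<year>` column per
#' occasion holding the state code (0 = unseen, otherwise stratum index).
#'
#' @param path file path.
#' @param strata stratum names; defaults to `A`, `B`, ... up to the largest
#'   code in the file.
#' @return `read_encounters()` returns an [encounter_histories] object;
#'   `write_encounters()` invisibly returns `path`.
#' @export
read_encounters <- function(path, strata = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ycols <- grep("^y", names(df), value = TRUE)
  if (length(ycols) < 2L) msg_stop("no y<year> occasion columns found in ", path)
  years <- as.integer(sub("^y", "", ycols))
  codes <- as.matrix(df[ycols])
  encounter_histories(
    codes, df$age_class_first,
    hatch_day = df$hatch_day, band_age = df$band_age,
    bird_id = df$bird_id,
    frequency = if ("frequency" %in% names(df)) df$frequency else NULL,
    strata = strata, years = years)
}

#' @rdname read_encounters
#' @param x an `encounter_histories` object.
#' @export
write_encounters <- function(x, path) {
  df <- data.frame(bird_id = x$bird_id, age_class_first = x$age_class_first,
                   hatch_day = x$hatch_day, band_age = x$band_age,
                   frequency = x$frequency, stringsAsFactors = FALSE)
  codes <- as.data.frame(x$codes)
  names(codes) <- paste0("y", x$years)
  write.csv(cbind(df, codes), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export histories in MARK-style `.inp` format
#'
#' One line per unique history: stratum letters (`A`, `B`, `C`, ... with `0`
#' for unseen), whitespace, the summed frequency, and a terminating `;`.
#' Individual covariates are not exported; identical code rows are pooled.
#'
#' @param x an [encounter_histories] object.
#' @param path output file path.
#' @return Invisibly, the lines written.
#' @export
write_inp <- function(x, path) {
  chr <- matrix(c("0", LETTERS)[x$codes + 1L], nrow = nrow(x$codes))
  hist_str <- apply(chr, 1L, paste, collapse = "")
  freq <- tapply(x$frequency, hist_str, sum)
  lines <- paste0(names(freq), " ", as.integer(freq), ";")
  writeLines(lines, path)
  invisible(lines)
}

#' Year-by-stratum occasion covariates
#'
#' Reproductive success (chicks fledged per pair) and the three high-flow
#' indicator variables. Rows are (year, stratum) pairs; the flags attach to
#' the *interval* that starts in `year`:
#' `hf_emig` marks intervals in which high flow elevated emigration out of the
#' flow-affected stratum, `hf_immig` intervals in which it suppressed
#' immigration into it, and `posthf_immig` the post-high-flow interval with
#' elevated immigration into the newly created habitat.
#'
#' @param year interval-start year (one row per year x stratum).
#' @param stratum stratum name.
#' @param success chicks fledged/pair at that stratum in that year.
#' @param hf_emig,hf_immig,posthf_immig 0/1 interval flags (see above).
#' @return A `data.frame` of class `"occasion_covariates"`.
#' @export
occasion_covariates <- function(year, stratum, success,
                                hf_emig = 0, hf_immig = 0, posthf_immig = 0) {
  df <- data.frame(year = as.integer(year), stratum = as.character(stratum),
                   success = as.numeric(success),
                   hf_emig = as.integer(hf_emig),
                   hf_immig = as.integer(hf_immig),
                   posthf_immig = as.integer(posthf_immig),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$success)) || any(df$success < 0))
    msg_stop("success must be finite and >= 0")
  flags <- c(df$hf_emig, df$hf_immig, df$posthf_immig)
  if (any(!flags %in% c(0L, 1L))) msg_stop("flow flags must be 0/1")
  if (anyDuplicated(df[c("year", "stratum")]))
    msg_stop("duplicate (year, stratum) rows")
  class(df) <- c("occasion_covariates", "data.frame")
  df
}

#' @rdname occasion_covariates
#' @param path file path.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  occasion_covariates(df$year, df$stratum, df$success,
                      df$hf_emig, df$hf_immig, df$posthf_immig)
}

#' @rdname occasion_covariates
#' @param x an `occasion_covariates` object.
#' @export
write_covariates <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise distance matrix between strata
#'
#' @param d numeric `S x S` matrix (km) with stratum names as dimnames, or a
#'   named vector of pair distances like `c("HC-M1F" = 182, ...)` together
#'   with `strata`.
#' @param strata stratum names (required for the vector form).
#' @return A validated symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(d, strata = NULL) {
  if (!is.matrix(d)) {
    if (is.null(strata)) msg_stop("strata required when d is a pair vector")
    m <- matrix(0, length(strata), length(strata),
                dimnames = list(strata, strata))
    for (nm in names(d)) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1L]]
      m[pair[1L], pair[2L]] <- m[pair[2L], pair[1L]] <- d[[nm]]
    }
    d <- m
  }
  if (!isSymmetric(unname(d))) msg_stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) msg_stop("distance matrix must have a zero diagonal")
  if (any(d[upper.tri(d)] <= 0)) msg_stop("off-diagonal distances must be positive")
  d
}
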