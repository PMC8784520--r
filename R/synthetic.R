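#' Simulate a trial arm and its digitized Kaplan-Meier summary
#'
#' Draws censored individual-patient survival data from a stated generating
#' distribution and computes the Kaplan-Meier curve and number-at-risk table
#' at one-month resolution — a synthetic stand-in for digitizing published
#' trial curves, used to exercise the reconstruction and refitting pipeline
#' end to end. Censoring combines an administrative cutoff with optional
#' random (exponential) censoring.
#'
#' The defaults emulate a modern first-line NSCLC trial arm: 400 patients
#' followed for 30 months with light non-administrative censoring.
#'
#' @param n Number of subjects.
#' @param dist `"loglogistic"` (parameters `theta`, `kappa`) or
#'   `"exponential"` (parameter `rate`).
#' @param theta,kappa Log-logistic parameters (time in months).
#' @param rate Exponential rate per month.
#' @param cutoff Administrative censoring time in months.
#' @param censor_rate Monthly rate of random censoring (0 disables).
#' @param seed Optional RNG seed; fixed seeds give byte-identical output.
#' @return A list with `ipd` (tibble `time`, `event` — the truth) and `km`
#'   (a [km_digitization()] at monthly resolution).
#' @export
simulate_km <- function(n = 400, dist = c("loglogistic", "exponential"),
                        theta = 0.01422, kappa = 1.80138, rate = 0.05,
                        cutoff = 30, censor_rate = 0.01, seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(n >= 1, cutoff > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  true_t <- switch(dist,
    loglogistic = (u / ((1 - u) * theta))^(1 / kappa),
    exponential = -log(u) / rate
  )
  cens <- rep(cutoff, n)
  if (censor_rate > 0) {
    cens <- pmin(cens, stats::rexp(n, censor_rate))
  }
  time <- pmin(true_t, cens)
  event <- as.integer(true_t <= cens)
  ipd <- tibble(time = time, event = event)

  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  grid <- 0:ceiling(cutoff)
  sm <- summary(fit, times = grid, extend = TRUE)
  km <- km_digitization(
    coords = tibble(time = sm$time, surv = sm$surv),
    risk_table = tibble(time = sm$time, n_risk = sm$n.risk),
    total_events = sum(event)
  )
  list(ipd = ipd, km = km)
}

#' Build a registry-style conditional-survival table
#'
#' Annual conditional survival probabilities for the years beyond the
#' parametric-extrapolation window (the splice occurs at five years, so the
#' table starts at year 6). A single probability is recycled across the
#' required years.
#'
#' @param annual_survivals Probabilities in (0, 1\]; length 1 or one per
#'   year.
#' @param first_year First covered year (default 6).
#' @param n_years Number of covered years (default 16, reaching the 20-year
#'   horizon plus the utility lookahead year).
#' @return A validated registry tibble with columns `year`, `cond_surv`.
#' @export
make_registry_table <- function(annual_survivals, first_year = 6,
                                n_years = max(16, length(annual_survivals))) {
  if (length(annual_survivals) == 0) {
    abort("no annual survival probabilities supplied", class = "psmcea_error")
  }
  if (length(annual_survivals) == 1) {
    annual_survivals <- rep(annual_survivals, n_years)
  }
  tab <- tibble(year = first_year + seq_along(annual_survivals) - 1,
                cond_surv = annual_survivals)
  validate_registry_table(tab)
}

#' Bundled synthetic registry table
#'
#' An illustrative distant-stage NSCLC conditional-survival schedule (not a
#' registry transcription): annual conditional survival improving from 0.84
#' the year after the splice toward a 0.95 plateau, reflecting the selection
#' of long-term survivors typical of registry conditional-survival series.
#'
#' @return A registry tibble covering years 6-21.
#' @export
default_registry_table <- function() {
  make_registry_table(pmin(0.84 + 0.01 * (0:15), 0.95))
}

#' Build an age-indexed life table
#'
#' @param start_age First tabulated age in years.
#' @param annual_mortality Annual all-cause death probabilities, one per age,
#'   covering at least 20 years.
#' @return A validated life-table tibble with columns `age`, `q`.
#' @export
make_life_table <- function(start_age, annual_mortality) {
  if (length(annual_mortality) < 20) {
    abort("life table must cover at least 20 years", class = "psmcea_error")
  }
  if (any(annual_mortality < 0 | annual_mortality > 1)) {
    abort("mortality probabilities must lie in [0, 1]",
          class = "psmcea_validation_error")
  }
  validate_life_table(
    tibble(age = start_age + seq_along(annual_mortality) - 1,
           q = annual_mortality)
  )
}

#' Bundled synthetic life table
#'
#' Gompertz-shaped all-cause mortality from age 64 (not a national
#' life-table transcription): `q(age) = 0.012 * exp(0.09 * (age - 64))`,
#' capped at 1 — roughly the magnitude of US general-population mortality at
#' these ages.
#'
#' @return A life-table tibble covering ages 64-86.
#' @export
default_life_table <- function() {
  ages <- 64:86
  make_life_table(64, pmin(0.012 * exp(0.09 * (ages - 64)), 1))
}

#' Write a registry table or life table as delimited text
#'
#' @param table A registry or life-table tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_fixture <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
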