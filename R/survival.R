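#' Survival curve objects
#'
#' A `surv_curve` wraps a vectorized evaluator `S(t)` over time in months,
#' tagged with the provenance of the curve (`parametric`, `hr_adjusted`,
#' `spliced`, `tabulated` or `background_mortality`). All constructors in the
#' package guarantee `S(0) = 1`, `S` non-increasing, and values in \[0, 1\].
#'
#' @param fn Vectorized function of non-negative time (months) returning
#'   survival probabilities.
#' @param provenance Provenance tag.
#' @return A `surv_curve` object.
#' @export
surv_curve <- function(fn, provenance = "parametric") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, provenance = provenance), class = "surv_curve")
}

#' Evaluate a survival curve
#'
#' @param curve A `surv_curve`.
#' @param t Times in months (non-negative).
#' @return Survival probabilities, clamped to \[0, 1\].
#' @export
surv_prob <- function(curve, t) {
  stopifnot(inherits(curve, "surv_curve"))
  if (any(t < 0)) {
    abort("survival curves are defined for t >= 0", class = "psmcea_domain_error")
  }
  pmin(pmax(curve$fn(t), 0), 1)
}

#' @export
print.surv_curve <- function(x, ...) {
  cat("<surv_curve> provenance:", x$provenance, "\n")
  tt <- c(0, 6, 12, 24, 60, 120, 240)
  print(tibble(month = tt, surv = round(surv_prob(x, tt), 4)))
  invisible(x)
}

#' Export a curve as a (time, survival) table
#'
#' @param curve A `surv_curve`.
#' @param times Evaluation grid in months.
#' @return A tibble with columns `month` and `surv`.
#' @export
curve_table <- function(curve, times = 0:240) {
  tibble(month = times, surv = surv_prob(curve, times))
}

#' Log-logistic survival function
#'
#' The two-parameter log-logistic family used for trial-based extrapolation,
#' parameterized as `S(t) = 1 / (1 + theta * t^kappa)` with time in months.
#' Its median is `(1/theta)^(1/kappa)`.
#'
#' @param t Time in months (non-negative).
#' @param theta Rate-like parameter, positive.
#' @param kappa Shape parameter, positive.
#' @return Survival probability in (0, 1\].
#' @examples
#' loglogistic_survival(12, theta = 0.01422, kappa = 1.80138)
#' @export
loglogistic_survival <- function(t, theta, kappa) {
  stopifnot(theta > 0, kappa > 0)
  if (any(t < 0)) {
    abort("t must be non-negative", class = "psmcea_domain_error")
  }
  1 / (1 + theta * t^kappa)
}

#' Log-logistic survival curve object
#'
#' @inheritParams loglogistic_survival
#' @return A `surv_curve` with provenance `parametric`.
#' @export
loglogistic_curve <- function(theta, kappa) {
  force(theta); force(kappa)
  surv_curve(function(t) loglogistic_survival(t, theta, kappa), "parametric")
}

#' Apply a hazard ratio to a survival curve
#'
#' The hazard ratio acts on the cumulative-hazard scale, `S'(t) = S(t)^hr`
#' (proportional cumulative hazards). With `hr > 1` the adjusted curve lies
#' everywhere at or below the base curve.
#'
#' @param base A `surv_curve`.
#' @param hr Hazard ratio, positive.
#' @return A `surv_curve` with provenance `hr_adjusted`.
#' @export
apply_hazard_ratio <- function(base, hr) {
  stopifnot(inherits(base, "surv_curve"))
  if (!is.numeric(hr) || length(hr) != 1 || !is.finite(hr) || hr <= 0) {
    abort("hr must be a positive number", class = "psmcea_domain_error")
  }
  fn <- base$fn
  surv_curve(function(t) fn(t)^hr, "hr_adjusted")
}

#' Per-cycle event probability from a survival curve
#'
#' Conditional probability of the event during `(t, t + dt]` given
#' event-free survival to `t`: `1 - S(t + dt) / S(t)`.
#'
#' @param curve A `surv_curve`.
#' @param t Cycle-start time in months.
#' @param dt Cycle length in months (default 1).
#' @return Probability in \[0, 1\] (vectorized over `t`).
#' @export
per_cycle_event_probability <- function(curve, t, dt = 1) {
  s0 <- surv_prob(curve, t)
  if (any(s0 <= 0)) {
    abort("S(t) = 0: state is degenerate, no conditional probability",
          class = "psmcea_degenerate_error")
  }
  pmin(pmax(1 - surv_prob(curve, t + dt) / s0, 0), 1)
}

#' Splice a parametric curve with a registry conditional-survival table
#'
#' Long-term extrapolation strategy used by the base case: the trial-based
#' parametric curve carries the first years (through `switch_time`), after
#' which survival follows annual conditional survival probabilities from a
#' cancer-registry table. Within a registry year the curve is interpolated at
#' constant hazard, so `S(switch + 12k + m) = S(switch) * prod(cs[1..k]) *
#' cs[k+1]^(m/12)`. The spliced curve is continuous at the switch time.
#'
#' @param parametric A `surv_curve`.
#' @param table A conditional-survival table from [make_registry_table()] or
#'   [read_registry_table()]: tibble with columns `year` (contiguous integers
#'   starting the year after the splice) and `cond_surv` in (0, 1\].
#' @param switch_time Splice time in months (default 60, i.e. five years).
#' @return A `surv_curve` with provenance `spliced`.
#' @export
splice_with_registry <- function(parametric, table, switch_time = 60) {
  stopifnot(inherits(parametric, "surv_curve"), switch_time > 0)
  validate_registry_table(table, first_year = floor(switch_time / 12) + 1)
  cs <- table$cond_surv
  log_cs <- log(cs)
  cum_log <- c(0, cumsum(log_cs))   # cum_log[k+1] = sum of first k years
  n_years <- length(cs)
  anchor <- surv_prob(parametric, switch_time)
  pfn <- parametric$fn

  fn <- function(t) {
    t <- as.numeric(t)
    out <- numeric(length(t))
    pre <- t <= switch_time
    out[pre] <- pfn(t[pre])
    if (any(!pre)) {
      y <- (t[!pre] - switch_time) / 12
      k <- floor(y)
      frac <- y - k
      if (any(k + (frac > 0) > n_years)) {
        abort("registry table does not cover the requested horizon",
              class = "psmcea_coverage_error")
      }
      idx <- pmin(k + 1, n_years)   # year in progress (frac == 0 unaffected)
      out[!pre] <- anchor * exp(cum_log[k + 1] + frac * log_cs[idx])
    }
    out
  }
  surv_curve(fn, "spliced")
}

#' Background-mortality survival curve
#'
#' Alternative long-term survival used by the second scenario analysis:
#' monthly death probabilities derive from an age-indexed life table
#' (annual probabilities converted at constant hazard,
#' `q_month = 1 - (1 - q_year)^(1/12)`), with the probability of a fatal
#' treatment-related adverse event applied as a one-off excess in the first
#' cycle. The curve is the cumulative product of monthly survival
#' complements, interpolated log-linearly within months.
#'
#' @param life_table Tibble with contiguous `age` (years) and `q` (annual
#'   all-cause mortality probability) columns; see [make_life_table()].
#' @param start_age Cohort age at model entry (years).
#' @param fatal_ae_prob One-off probability of fatal treatment-related
#'   adverse event (default 0).
#' @param horizon Months of coverage required (default 252, one year beyond
#'   the 240-cycle horizon to serve the time-to-death utility lookahead).
#' @return A `surv_curve` with provenance `background_mortality`.
#' @export
background_mortality_curve <- function(life_table, start_age,
                                       fatal_ae_prob = 0, horizon = 252) {
  validate_life_table(life_table)
  stopifnot(fatal_ae_prob >= 0, fatal_ae_prob < 1, horizon > 0)
  months <- 0:ceiling(horizon)
  ages <- floor(start_age + months / 12)
  i <- match(ages, life_table$age)
  if (anyNA(i[-length(i)])) {
    abort("life table does not cover ages reached within the horizon",
          class = "psmcea_coverage_error")
  }
  i[is.na(i)] <- match(max(life_table$age), life_table$age)
  q_year <- life_table$q[i]
  q_month <- 1 - (1 - q_year)^(1 / 12)
  s_grid <- cumprod(c(1, 1 - q_month[-length(q_month)]))
  s_grid[-1] <- s_grid[-1] * (1 - fatal_ae_prob)
  log_s <- log(pmax(s_grid, 1e-300))

  fn <- function(t) {
    if (any(t > max(months))) {
      abort("background-mortality curve evaluated beyond its horizon",
            class = "psmcea_coverage_error")
    }
    k <- floor(t)
    frac <- t - k
    lo <- log_s[k + 1]
    hi <- log_s[pmin(k + 2, length(log_s))]
    exp(lo + frac * (hi - lo))
  }
  surv_curve(fn, "background_mortality")
}

#' Bucher adjusted indirect comparison of two hazard ratios
#'
#' With a single common comparator in each trial network, a fixed-effect
#' indirect comparison reduces to the ratio of the two direct hazard ratios,
#' with standard errors pooled on the log scale:
#' `SE = sqrt(SE_A^2 + SE_B^2)` where each `SE = (log(hi) - log(lo)) /
#' (2 * 1.96)`, and a 95% CI `exp(log(hr) +/- 1.96 * SE)`.
#'
#' @param hr_a,hr_b Hazard-ratio estimates versus the common comparator:
#'   lists or tibbles with elements `hr`, `ci_low`, `ci_high`.
#' @return A tibble with columns `hr`, `ci_low`, `ci_high`, `log_se`.
#' @examples
#' bucher_indirect_hr(list(hr = 0.6, ci_low = 0.4, ci_high = 0.9),
#'                    list(hr = 0.9, ci_low = 0.6, ci_high = 1.35))
#' @export
bucher_indirect_hr <- function(hr_a, hr_b) {
  check <- function(x, label) {
    if (any(unlist(x[c("hr", "ci_low", "ci_high")]) <= 0)) {
      abort(paste0("non-positive hazard ratio or CI bound in ", label),
            class = "psmcea_domain_error")
    }
    if (!(x$ci_low <= x$hr && x$hr <= x$ci_high)) {
      abort(paste0("CI must bracket the estimate in ", label),
            class = "psmcea_domain_error")
    }
  }
  check(hr_a, "hr_a"); check(hr_b, "hr_b")
  se <- function(x) (log(x$ci_high) - log(x$ci_low)) / (2 * 1.96)
  log_hr <- log(hr_a$hr) - log(hr_b$hr)
  log_se <- sqrt(se(hr_a)^2 + se(hr_b)^2)
  tibble(
    hr = exp(log_hr),
    ci_low = exp(log_hr - 1.96 * log_se),
    ci_high = exp(log_hr + 1.96 * log_se),
    log_se = log_se
  )
}

# ---- registry / life-table readers -----------------------------------------

validate_registry_table <- function(table, first_year = NULL) {
  if (!all(c("year", "cond_surv") %in% names(table)) || nrow(table) == 0) {
    abort("registry table needs non-empty columns year, cond_surv",
          class = "psmcea_validation_error")
  }
  if (any(table$cond_surv <= 0 | table$cond_surv > 1)) {
    abort("conditional survival probabilities must lie in (0, 1]",
          class = "psmcea_validation_error")
  }
  if (!all(diff(table$year) == 1)) {
    abort("registry years must be contiguous", class = "psmcea_coverage_error")
  }
  if (!is.null(first_year) && table$year[1] != first_year) {
    abort(paste0("registry table must start at year ", first_year,
                 " (the year following the splice)"),
          class = "psmcea_coverage_error")
  }
  invisible(table)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "q") %in% names(lt)) || nrow(lt) == 0) {
    abort("life table needs non-empty columns age, q",
          class = "psmcea_validation_error")
  }
  if (any(lt$q < 0 | lt$q > 1)) {
    abort("mortality probabilities must lie in [0, 1]",
          class = "psmcea_validation_error")
  }
  if (!all(diff(lt$age) == 1)) {
    abort("life-table ages must be contiguous", class = "psmcea_coverage_error")
  }
  invisible(lt)
}

#' Read a conditional-survival registry table from delimited text
#'
#' Expects tab- or comma-delimited text with columns `year` and `cond_surv`.
#'
#' @param path File path.
#' @return A validated registry tibble.
#' @export
read_registry_table <- function(path) {
  tab <- utils::read.delim(path, sep = "", header = TRUE) |> as_tibble()
  validate_registry_table(tab)
}

#' Read an age-indexed life table from delimited text
#'
#' Expects tab- or comma-delimited text with columns `age` and `q`.
#'
#' @param path File path.
#' @return A validated life-table tibble.
#' @export
read_life_table <- function(path) {
  tab <- utils::read.delim(path, sep = "", header = TRUE) |> as_tibble()
  validate_life_table(tab)
}

#' @method autoplot surv_curve
#' @export
autoplot.surv_curve <- function(object, times = 0:240, ...) {
  ggplot2::ggplot(curve_table(object, times),
                  ggplot2::aes(x = .data$month, y = .data$surv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Month", y = "Survival probability",
                  title = paste0("Survival curve (", object$provenance, ")")) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
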