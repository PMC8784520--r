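#' Digitized Kaplan-Meier input
#'
#' Bundles digitized survival coordinates and the published number-at-risk
#' table for one trial arm, the inputs to pseudo individual-patient-data
#' reconstruction.
#'
#' @param coords Tibble with columns `time` (months, non-decreasing, starting
#'   at 0) and `surv` (non-increasing, `surv[1] == 1`).
#' @param risk_table Tibble with columns `time` and `n_risk` (non-increasing
#'   counts), at least two rows.
#' @param total_events Optional reported total number of events.
#' @return A `km_digitization` object.
#' @export
km_digitization <- function(coords, risk_table, total_events = NULL) {
  coords <- as_tibble(coords)
  risk_table <- as_tibble(risk_table)
  stopifnot(all(c("time", "surv") %in% names(coords)),
            all(c("time", "n_risk") %in% names(risk_table)))
  if (nrow(risk_table) < 2) {
    abort("risk table needs at least two intervals", class = "psmcea_validation_error")
  }
  if (coords$time[1] != 0 || abs(coords$surv[1] - 1) > 1e-12) {
    abort("coordinates must start at (0, 1)", class = "psmcea_validation_error")
  }
  if (is.unsorted(coords$time) || any(diff(coords$surv) > 1e-12)) {
    abort("times must be non-decreasing and survival non-increasing",
          class = "psmcea_validation_error")
  }
  if (any(diff(risk_table$n_risk) > 0)) {
    abort("number at risk cannot increase over time",
          class = "psmcea_validation_error")
  }
  structure(list(coords = coords, risk_table = risk_table,
                 total_events = total_events),
            class = "km_digitization")
}

#' @export
print.km_digitization <- function(x, ...) {
  cat("<km_digitization>", nrow(x$coords), "coordinates,",
      nrow(x$risk_table), "risk-table rows\n")
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Guyot-style iterative algorithm: within each number-at-risk interval,
#' censoring counts are proposed, spread uniformly over the interval, and
#' adjusted until the implied number at risk at the next risk-table time
#' matches the published count; event counts at each digitized step are
#' chosen so the running Kaplan-Meier estimate tracks the digitized
#' coordinates. Event times are placed at the digitized step coordinates.
#' Patients still at risk after the last coordinate are censored there.
#'
#' @param km A [km_digitization()] object.
#' @return A tibble of records with columns `time` (months) and `event`
#'   (1 = event, 0 = censored); the record count equals the initial number
#'   at risk.
#' @references Guyot P, Ades AE, Ouwens MJ, Welton NJ (2012). Enhanced
#'   secondary analysis of survival data: reconstructing the data from
#'   published Kaplan-Meier survival curves. BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "km_digitization"))
  t_s <- km$coords$time
  s <- km$coords$surv
  t_risk <- km$risk_table$time
  n_risk <- km$risk_table$n_risk
  n <- length(t_s)
  K <- length(t_risk)

  # step-function value of the digitized curve at an arbitrary time
  s_at <- function(tt) s[max(which(t_s <= tt + 1e-12))]

  # intervals are left-open, (t_risk[k], t_risk[k+1]]: a digitized drop
  # sitting exactly on a risk-table time belongs to the interval it closes
  bound <- c(t_risk, max(t_s) + 1e-9)
  lower <- purrr::map_int(seq_len(K), \(k) {
    i <- which(t_s > t_risk[k] & t_s <= bound[k + 1])
    if (length(i) == 0) NA_integer_ else min(i)
  })
  upper <- purrr::map_int(seq_len(K), \(k) {
    i <- which(t_s > t_risk[k] & t_s <= bound[k + 1])
    if (length(i) == 0) NA_integer_ else max(i)
  })

  n_hat <- rep(n_risk[1], n + 1)
  cen <- d <- integer(n)
  cen_times <- vector("list", n)   # actual censoring times, binned per gap
  km_hat <- rep(1, n)
  last <- 1                        # index of the last event coordinate
  carry <- n_risk[1]               # at-risk entering the current interval

  for (k in seq_len(K)) {
    carry <- n_risk[k]
    if (is.na(lower[k])) {
      # no digitized coordinate inside the interval: censor the whole
      # published decrement mid-interval
      if (k < K) {
        n_cen <- n_risk[k] - n_risk[k + 1]
        if (n_cen > 0) {
          j <- max(which(t_s <= t_risk[k] + 1e-12))
          mid <- (t_risk[k] + t_risk[k + 1]) / 2
          cen[j] <- cen[j] + n_cen
          cen_times[[j]] <- c(cen_times[[j]], rep(mid, n_cen))
        }
      }
      next
    }
    if (k < K) {
      n_cen <- round(n_risk[k] * s_at(t_risk[k + 1]) / s_at(t_risk[k]) -
                       n_risk[k + 1])
    } else {
      n_cen <- 0
    }
    n_cen <- max(0, n_cen)
    for (iter in 1:60) {
      # spread censorings uniformly over the interval and bin them to the
      # digitized-coordinate gaps (times before the first coordinate attach
      # to it)
      if (k < K && n_cen > 0) {
        ct <- t_risk[k] + (1:n_cen) * (t_risk[k + 1] - t_risk[k]) / (n_cen + 1)
      } else {
        ct <- numeric(0)
      }
      gap_breaks <- c(t_s[lower[k]:upper[k]], bound[k + 1] + 1e-9)
      bins <- pmax(findInterval(ct, gap_breaks), 1)
      last_k <- last
      km_k <- km_hat
      n_run <- carry
      for (j in lower[k]:upper[k]) {
        jj <- j - lower[k] + 1
        cen[j] <- sum(bins == jj)
        cen_times[[j]] <- ct[bins == jj]
        if (j == 1) {
          d[j] <- 0
        } else {
          d[j] <- round(n_run * (1 - s[j] / km_k[last_k]))
          d[j] <- max(0, min(d[j], n_run))
        }
        km_k[j] <- km_k[last_k] * (1 - d[j] / max(n_run, 1))
        n_hat[j] <- n_run
        n_run <- n_run - d[j] - cen[j]
        if (d[j] != 0) last_k <- j
      }
      if (k == K) { last <- last_k; km_hat <- km_k; break }
      gap <- n_run - n_risk[k + 1]
      if (gap == 0 || (gap < 0 && n_cen == 0)) {
        last <- last_k; km_hat <- km_k
        break
      }
      n_cen <- max(0, n_cen + gap)
      if (iter == 60) { last <- last_k; km_hat <- km_k }
    }
  }
  remaining_at_risk <- if (is.na(upper[K])) n_risk[K] else
    n_hat[upper[K]] - d[upper[K]] - cen[upper[K]]

  event_times <- rep(t_s, pmax(d, 0))
  censor_times <- unlist(purrr::map(seq_len(n), \(j) {
    ts <- cen_times[[j]]
    if (cen[j] > length(ts)) ts <- c(ts, rep(mean(c(t_s[j], max(t_s))), cen[j] - length(ts)))
    ts[seq_len(cen[j])]
  }))
  # remaining at risk leave the data censored at maximum follow-up
  if (remaining_at_risk > 0) {
    censor_times <- c(censor_times, rep(max(t_s), remaining_at_risk))
  }

  out <- bind_rows(
    tibble(time = event_times, event = 1L),
    tibble(time = censor_times, event = 0L)
  ) |>
    filter(.data$time > 0) |>
    arrange(.data$time, desc(.data$event))
  out
}

#' Fit a parametric distribution to (possibly censored) pseudo-IPD
#'
#' Maximum-likelihood fitting of right-censored survival data through
#' \pkg{flexsurv}, returning the censored-data log-likelihood together with
#' AIC (`2k - 2logL`) and BIC (`k log n - 2logL`, with `n` the number of
#' records).
#'
#' @param ipd Tibble with columns `time` and `event`.
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @return A `cea_fit` object: list with `distribution`, `params` (named
#'   vector, natural parameterization; for the log-logistic the rate-form
#'   `theta`/`kappa` are included), `loglik`, `k`, `n`, `n_events`, `aic`,
#'   `bic`.
#' @export
fit_distribution <- function(ipd,
                             family = c("exponential", "weibull",
                                        "loglogistic", "lognormal",
                                        "gompertz")) {
  family <- match.arg(family)
  ipd <- as_tibble(ipd)
  if (nrow(ipd) < 10) {
    abort("need at least 10 records to fit", class = "psmcea_fit_error")
  }
  if (sum(ipd$event) < 5) {
    abort("need at least 5 events to fit", class = "psmcea_fit_error")
  }
  dist <- c(exponential = "exp", weibull = "weibull", loglogistic = "llogis",
            lognormal = "lnorm", gompertz = "gompertz")[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd), dist = dist),
    error = function(e) {
      abort(paste0("fit for family '", family, "' failed: ",
                   conditionMessage(e)),
            class = "psmcea_fit_error")
    }
  )
  params <- setNames(fit$res[, "est"], rownames(fit$res))
  if (family == "loglogistic") {
    # flexsurv llogis: S(t) = 1/(1 + (t/scale)^shape); rate form theta/kappa
    params <- c(params,
                theta = unname(params["scale"]^(-params["shape"])),
                kappa = unname(params["shape"]))
  }
  k <- fit$npars
  n <- nrow(ipd)
  structure(
    list(distribution = family, params = params, loglik = fit$loglik,
         k = k, n = n, n_events = sum(ipd$event),
         aic = 2 * k - 2 * fit$loglik,
         bic = k * log(n) - 2 * fit$loglik,
         res = fit$res,   # natural-scale estimates with SEs and CIs
         vcov = stats::vcov(fit)),
    class = "cea_fit"
  )
}

#' @export
print.cea_fit <- function(x, ...) {
  cat("<cea_fit>", x$distribution, "| logLik", round(x$loglik, 2),
      "| AIC", round(x$aic, 2), "| BIC", round(x$bic, 2), "\n")
  print(round(x$params, 5))
  invisible(x)
}

#' @method tidy cea_fit
#' @export
tidy.cea_fit <- function(x, ...) {
  tibble(distribution = x$distribution,
         term = names(x$params), estimate = unname(x$params))
}

#' @method glance cea_fit
#' @export
glance.cea_fit <- function(x, ...) {
  tibble(distribution = x$distribution, logLik = x$loglik, AIC = x$aic,
         BIC = x$bic, df = x$k, nobs = x$n, n_events = x$n_events)
}

#' Select the best-fitting distribution
#'
#' Picks the candidate with the lowest AIC; ties are broken by lowest BIC,
#' then by fewest parameters. A warning is raised when the AIC-best and
#' BIC-best candidates disagree.
#'
#' @param fits A list of [fit_distribution()] results.
#' @return The selected `cea_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) {
    abort("no fits supplied", class = "psmcea_error")
  }
  stats <- purrr::map_dfr(fits, \(f) tibble(
    distribution = f$distribution, aic = f$aic, bic = f$bic, k = f$k))
  aic_best <- order(stats$aic, stats$bic, stats$k)[1]
  bic_best <- which.min(stats$bic)
  if (stats$distribution[aic_best] != stats$distribution[bic_best]) {
    warn(paste0("AIC favours ", stats$distribution[aic_best],
                " but BIC favours ", stats$distribution[bic_best],
                "; AIC takes precedence"))
  }
  fits[[aic_best]]
}

#' Read a digitized KM curve and risk table from delimited text
#'
#' @param coords_path Delimited text with columns `time`, `surv`.
#' @param risk_path Delimited text with columns `time`, `n_risk`.
#' @param total_events Optional reported event total.
#' @return A `km_digitization` object.
#' @export
read_km_digitization <- function(coords_path, risk_path, total_events = NULL) {
  km_digitization(
    utils::read.delim(coords_path, sep = "", header = TRUE),
    utils::read.delim(risk_path, sep = "", header = TRUE),
    total_events = total_events
  )
}
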