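#' Build a partitioned-survival cohort trace
#'
#' State occupancy follows the partitioned-survival construction: total
#' progression-free occupancy equals `S_PFS(t)`, the dead compartment equals
#' `1 - S_OS(t)`, and progressive disease is the (clipped) difference. Within
#' the progression-free state the on-treatment fraction decays each cycle by
#' the per-drug probabilities of discontinuation due to adverse events, and a
#' drug stops contributing once its maximum number of administrations is
#' exhausted. Where the curves cross (`S_PFS > S_OS`), PFS occupancy is
#' clipped to OS and a warning is logged.
#'
#' Per-cycle increments of new progressions and new deaths are recorded for
#' the one-off cost events; deaths are apportioned between the
#' progression-free and progressed compartments in proportion to their
#' occupancy at the preceding cycle.
#'
#' @param os,pfs `surv_curve` objects for overall and progression-free
#'   survival.
#' @param regimen A [regimen_table()] for the arm.
#' @param horizon Number of monthly cycles (default 240, a 20-year horizon).
#' @return A `cea_trace` tibble with one row per cycle: `cycle`, occupancies
#'   `pfs_on`, `pfs_off`, `pd`, `dead`, increments `new_prog`, `new_death`,
#'   and one `frac_<drug>` column per regimen drug (fraction of the cohort on
#'   that drug). The OS/PFS curves and regimen travel along as attributes.
#' @export
build_trace <- function(os, pfs, regimen, horizon = 240) {
  stopifnot(inherits(os, "surv_curve"), inherits(pfs, "surv_curve"),
            horizon >= 1)
  t <- 0:(horizon - 1)
  s_os <- surv_prob(os, t)
  s_pfs_raw <- surv_prob(pfs, t)
  if (any(s_pfs_raw > s_os + 1e-12)) {
    warn("PFS curve exceeds OS curve; progressive-disease occupancy clipped to 0")
  }
  s_pfs <- pmin(s_pfs_raw, s_os)
  pd <- pmax(s_os - s_pfs, 0)
  dead <- 1 - s_os

  frac <- purrr::pmap(regimen, function(drug, disc_prob, admin_rate,
                                        max_administrations, ...) {
    active <- (max_administrations - admin_rate * t) > 0
    s_pfs * (1 - disc_prob)^t * active
  })
  names(frac) <- paste0("frac_", regimen$drug)
  pfs_on <- purrr::reduce(frac, pmax)
  pfs_off <- pmax(s_pfs - pfs_on, 0)

  new_death <- c(dead[1], diff(dead))
  alive_prev <- c(1, (s_pfs + pd)[-horizon])
  pd_prev <- c(0, pd[-horizon])
  death_from_pd <- ifelse(alive_prev > 0, new_death * pd_prev / alive_prev, 0)
  new_prog <- pmax(0, c(pd[1], diff(pd)) + death_from_pd)

  out <- tibble(cycle = t, pfs_on = pfs_on, pfs_off = pfs_off, pd = pd,
                dead = dead, new_prog = new_prog, new_death = new_death)
  out <- dplyr::bind_cols(out, as_tibble(frac))
  structure(out, class = c("cea_trace", class(out)),
            os = os, pfs = pfs, regimen = regimen)
}

#' Expected time-to-death utility for a patient alive at time t
#'
#' Quality of life declines with proximity to death. Utility at `t` is the
#' mixture of the window utilities weighted by the conditional probability of
#' dying within 1, 1-6, or 6-12 months, or surviving at least a further 12
#' months: `P(death in (t+a, t+b] | alive at t) = (S(t+a) - S(t+b)) / S(t)`.
#'
#' @param os A `surv_curve` for overall survival.
#' @param t Time(s) in months; requires `S(t) > 0`.
#' @param u Named utilities `c(u_ge12=, u_6_12=, u_1_6=, u_le1=)`.
#' @return Expected utility value(s), strictly between `u_le1` and `u_ge12`
#'   for non-degenerate curves.
#' @export
time_to_death_utility <- function(os, t, u) {
  stopifnot(all(c("u_ge12", "u_6_12", "u_1_6", "u_le1") %in% names(u)))
  s0 <- surv_prob(os, t)
  if (any(s0 <= 0)) {
    abort("S(t) = 0: no patients alive at t", class = "psmcea_degenerate_error")
  }
  s1 <- surv_prob(os, t + 1)
  s6 <- surv_prob(os, t + 6)
  s12 <- surv_prob(os, t + 12)
  (u[["u_le1"]] * (s0 - s1) + u[["u_1_6"]] * (s1 - s6) +
      u[["u_6_12"]] * (s6 - s12) + u[["u_ge12"]] * s12) / s0
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle the model accrues: first-line drug and administration costs
#' through [cycle_drug_cost()]; routine follow-up (a monthly physician visit
#' and an imaging examination every third cycle) for all alive states; best
#' supportive care for the progressed fraction not receiving subsequent
#' anticancer therapy; and quality-adjusted time via the time-to-death
#' utility. One-off events: the adverse-event cost and QALY decrement at
#' model entry, the subsequent-therapy cost (times uptake) at each new
#' progression, and the death-associated cost at each new death. Costs and
#' QALYs are discounted at the annual rate as `(1 + r)^(-t/12)`.
#'
#' @param trace A [build_trace()] result.
#' @param ps A `cea_parameters` object.
#' @param arm `"pembro"` or `"pembro_chemo"`.
#' @param half_cycle Apply a half-cycle correction to state-occupancy
#'   accruals (default `FALSE`).
#' @return A `cea_strategy` object with discounted and undiscounted totals
#'   and per-component breakdowns.
#' @export
accrue <- function(trace, ps, arm = c("pembro", "pembro_chemo"),
                   half_cycle = FALSE) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cea_trace"))
  regimen <- attr(trace, "regimen")
  os <- attr(trace, "os")
  t <- trace$cycle
  H <- length(t)
  rate <- param_value(ps, "discount_rate") / 100
  disc <- (1 + rate)^(-t / 12)
  hc <- if (half_cycle) c(0.5, rep(1, H - 1)) else rep(1, H)

  suffix <- if (arm == "pembro") "pembro" else "pembro_chemo"
  uptake <- param_value(ps, "subsq_uptake")
  u <- c(u_ge12 = param_value(ps, "u_ge12"),
         u_6_12 = param_value(ps, "u_6_12"),
         u_1_6 = param_value(ps, "u_1_6"),
         u_le1 = param_value(ps, "u_le1"))

  alive <- trace$pfs_on + trace$pfs_off + trace$pd
  frac_cols <- paste0("frac_", regimen$drug)
  drug_cost <- purrr::map_dbl(t, \(tt) {
    fr <- unlist(trace[tt + 1, frac_cols])
    names(fr) <- regimen$drug
    cycle_drug_cost(regimen, tt, fr)
  })
  followup <- alive * (param_value(ps, "cost_physician_visit") +
                         ifelse(t %% 3 == 0, param_value(ps, "cost_imaging"), 0))
  bsc <- trace$pd * (1 - uptake) * param_value(ps, "cost_bsc")
  subsq <- trace$new_prog * uptake *
    param_value(ps, paste0("subsq_cost_", suffix))
  death <- trace$new_death * param_value(ps, "cost_death")
  ae_cost <- c(param_value(ps, paste0("ae_cost_", suffix)), rep(0, H - 1))

  ut <- numeric(H)
  pos <- (1 - trace$dead) > 0
  ut[pos] <- time_to_death_utility(os, t[pos], u)
  qaly_pfs_cycle <- (trace$pfs_on + trace$pfs_off) * ut / 12
  qaly_pd_cycle <- trace$pd * ut / 12
  disutil <- c(param_value(ps, paste0("disutility_", suffix)), rep(0, H - 1))
  ly_cycle <- alive / 12

  components <- tibble(
    component = c("drug_administration", "followup", "bsc",
                  "subsequent_therapy", "death", "adverse_events"),
    cost = c(sum(drug_cost * disc * hc), sum(followup * disc * hc),
             sum(bsc * disc * hc), sum(subsq * disc), sum(death * disc),
             sum(ae_cost * disc)),
    cost_undiscounted = c(sum(drug_cost * hc), sum(followup * hc),
                          sum(bsc * hc), sum(subsq), sum(death), sum(ae_cost))
  )

  structure(
    list(
      arm = arm, histology = ps$histology,
      cost = sum(components$cost),
      qaly = sum((qaly_pfs_cycle + qaly_pd_cycle) * disc * hc) -
        sum(disutil * disc),
      life_years = sum(ly_cycle * disc * hc),
      qaly_pfs = sum(qaly_pfs_cycle * disc * hc) - sum(disutil * disc),
      qaly_pd = sum(qaly_pd_cycle * disc * hc),
      cost_undiscounted = sum(components$cost_undiscounted),
      qaly_undiscounted = sum((qaly_pfs_cycle + qaly_pd_cycle) * hc) -
        sum(disutil),
      life_years_undiscounted = sum(ly_cycle * hc),
      components = components,
      discount_rate = rate
    ),
    class = "cea_strategy"
  )
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat("<cea_strategy>", x$arm, "|", x$histology, "\n")
  cat(sprintf("  cost $%s | QALYs %.2f (PFS %.2f, PD %.2f) | LYs %.2f\n",
              format(round(x$cost), big.mark = ","), x$qaly, x$qaly_pfs,
              x$qaly_pd, x$life_years))
  invisible(x)
}

#' @method tidy cea_strategy
#' @export
tidy.cea_strategy <- function(x, ...) {
  tibble(arm = x$arm, histology = x$histology, cost = x$cost,
         qaly_pfs = x$qaly_pfs, qaly_pd = x$qaly_pd, qaly = x$qaly,
         life_years = x$life_years,
         cost_undiscounted = x$cost_undiscounted,
         qaly_undiscounted = x$qaly_undiscounted)
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (cost_a - cost_b) / (qaly_a - qaly_b)` with `b` the reference
#' arm. When the signs oppose, a dominance flag replaces the ratio:
#' `dominated` (more costly, less effective) or `dominant` (less costly,
#' more effective). Equal effectiveness with higher cost is flagged
#' `higher cost, equal effect`.
#'
#' @param a Intervention [accrue()] result (or list with `cost`, `qaly`).
#' @param b Reference result.
#' @return A `cea_icer` object with `d_cost`, `d_qaly`, `icer`, `dominance`.
#' @export
icer <- function(a, b) {
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  dominance <- NA_character_
  ratio <- NA_real_
  if (abs(d_qaly) < 1e-9) {
    dominance <- if (d_cost > 0) "higher cost, equal effect" else
      if (d_cost < 0) "lower cost, equal effect" else "equivalent"
  } else if (d_cost > 0 && d_qaly < 0) {
    dominance <- "dominated"
  } else if (d_cost < 0 && d_qaly > 0) {
    dominance <- "dominant"
  } else {
    ratio <- d_cost / d_qaly
  }
  structure(list(d_cost = d_cost, d_qaly = d_qaly, icer = ratio,
                 dominance = dominance),
            class = "cea_icer")
}

#' Net monetary benefit of the incremental comparison
#'
#' `NMB = wtp x dQALY - dCost`; positive values favour the intervention.
#' Defined even where the ICER is not (dominance), which makes it the scale
#' used for dominance-aware tornado ordering.
#'
#' @param x A `cea_icer` object.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(x, wtp = 1e5) {
  wtp * x$d_qaly - x$d_cost
}

#' @export
print.cea_icer <- function(x, ...) {
  if (is.na(x$icer)) {
    cat(sprintf("<cea_icer> dCost $%s, dQALY %.3f: %s\n",
                format(round(x$d_cost), big.mark = ","), x$d_qaly,
                x$dominance))
  } else {
    cat(sprintf("<cea_icer> dCost $%s, dQALY %.3f, ICER $%s/QALY\n",
                format(round(x$d_cost), big.mark = ","), x$d_qaly,
                format(round(x$icer), big.mark = ",")))
  }
  invisible(x)
}

#' @method tidy cea_icer
#' @export
tidy.cea_icer <- function(x, ...) {
  tibble(d_cost = x$d_cost, d_qaly = x$d_qaly, icer = x$icer,
         dominance = x$dominance)
}

#' @method autoplot cea_trace
#' @export
autoplot.cea_trace <- function(object, ...) {
  long <- object |>
    select("cycle", "pfs_on", "pfs_off", "pd", "dead") |>
    tidyr::pivot_longer(-"cycle", names_to = "state", values_to = "occupancy") |>
    mutate(state = factor(.data$state,
                          levels = c("dead", "pd", "pfs_off", "pfs_on")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (month)", y = "State occupancy",
                  fill = "Health state")
}
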