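#' Overall- and progression-free-survival curves for one arm
#'
#' The combination arm uses the trial-fitted log-logistic curves directly;
#' the monotherapy arm applies the indirect-comparison hazard ratios on the
#' cumulative-hazard scale. Long-term survival depends on the mode:
#' * `scenario1` — pure parametric extrapolation over the whole horizon;
#' * `base` — parametric OS for the first five years, registry annual
#'   conditional survival afterwards ([splice_with_registry()]);
#' * `scenario2` — OS from age-matched background mortality plus the arm's
#'   one-off fatal adverse-event probability
#'   ([background_mortality_curve()]).
#'
#' PFS is parametric (hazard-ratio adjusted for monotherapy) in every mode
#' and is clipped to OS inside the trace.
#'
#' @param ps A `cea_parameters` object.
#' @param arm `"pembro"` or `"pembro_chemo"`.
#' @param mode `"base"`, `"scenario1"` or `"scenario2"`.
#' @param registry Conditional-survival table (required for `base`; defaults
#'   to the bundled synthetic fixture).
#' @param life_table Life table (required for `scenario2`; defaults to the
#'   bundled synthetic fixture).
#' @param horizon Cycles, used to size table coverage checks.
#' @return List with `surv_curve` elements `os` and `pfs`.
#' @export
arm_curves <- function(ps, arm = c("pembro", "pembro_chemo"),
                       mode = c("scenario1", "base", "scenario2"),
                       registry = NULL, life_table = NULL, horizon = 240) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  os <- loglogistic_curve(param_value(ps, "os_theta"),
                          param_value(ps, "os_kappa"))
  pfs <- loglogistic_curve(param_value(ps, "pfs_theta"),
                           param_value(ps, "pfs_kappa"))
  if (arm == "pembro") {
    os <- apply_hazard_ratio(os, param_value(ps, "hr_os"))
    pfs <- apply_hazard_ratio(pfs, param_value(ps, "hr_pfs"))
  }
  if (mode == "base") {
    registry <- registry %||% default_registry_table()
    os <- splice_with_registry(os, registry, switch_time = 60)
  } else if (mode == "scenario2") {
    life_table <- life_table %||% default_life_table()
    fatal <- param_value(ps, paste0(
      "fatal_ae_", if (arm == "pembro") "pembro" else "pembro_chemo"))
    os <- background_mortality_curve(life_table,
                                     start_age = param_value(ps, "start_age"),
                                     fatal_ae_prob = fatal,
                                     horizon = horizon + 12)
  }
  list(os = os, pfs = pfs)
}

#' Run one strategy arm through the cohort model
#'
#' Builds the arm's survival curves for the requested mode, runs the
#' 240-cycle partitioned-survival trace and accrues discounted costs and
#' QALYs.
#'
#' @inheritParams arm_curves
#' @param half_cycle Apply a half-cycle correction (default `FALSE`).
#' @return A `cea_strategy` object (see [accrue()]); the trace is attached
#'   as attribute `"trace"`.
#' @export
run_strategy <- function(ps, arm = c("pembro", "pembro_chemo"),
                         mode = c("scenario1", "base", "scenario2"),
                         registry = NULL, life_table = NULL, horizon = 240,
                         half_cycle = FALSE) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  curves <- arm_curves(ps, arm, mode, registry, life_table, horizon)
  trace <- build_trace(curves$os, curves$pfs, regimen_table(ps, arm),
                       horizon = horizon)
  res <- accrue(trace, ps, arm, half_cycle = half_cycle)
  res$mode <- mode
  attr(res, "trace") <- trace
  res
}

#' Compare the two first-line strategies
#'
#' Runs both arms under a common mode and computes the incremental
#' comparison, with pembrolizumab monotherapy as the reference arm.
#'
#' @inheritParams run_strategy
#' @return A `cea_comparison` object: list with `pembro_chemo`, `pembro`
#'   (both `cea_strategy`), `icer` (a `cea_icer`), `mode`, `histology`.
#' @examples
#' ps <- load_parameters(psmcea_example("nonsquamous_table1.yaml"))
#' cmp <- run_comparison(ps, mode = "scenario1")
#' tidy(cmp)
#' @export
run_comparison <- function(ps, mode = c("scenario1", "base", "scenario2"),
                           registry = NULL, life_table = NULL, horizon = 240,
                           half_cycle = FALSE) {
  mode <- match.arg(mode)
  combo <- run_strategy(ps, "pembro_chemo", mode, registry, life_table,
                        horizon, half_cycle)
  mono <- run_strategy(ps, "pembro", mode, registry, life_table,
                       horizon, half_cycle)
  structure(
    list(pembro_chemo = combo, pembro = mono, icer = icer(combo, mono),
         mode = mode, histology = ps$histology),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison>", x$histology, "|", x$mode, "\n")
  print(tidy(x))
  invisible(x)
}

#' Summary-table-shaped tidy method for a comparison
#'
#' One row per strategy with cost, the QALY partition (progression-free,
#' progressed, overall), increments versus the reference arm and the ICER or
#' dominance flag.
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) {
  ic <- x$icer
  tibble(
    histology = x$histology, mode = x$mode,
    strategy = c("pembro", "pembro_chemo"),
    cost = c(x$pembro$cost, x$pembro_chemo$cost),
    qaly_pfs = c(x$pembro$qaly_pfs, x$pembro_chemo$qaly_pfs),
    qaly_pd = c(x$pembro$qaly_pd, x$pembro_chemo$qaly_pd),
    qaly = c(x$pembro$qaly, x$pembro_chemo$qaly),
    d_cost = c(NA, ic$d_cost),
    d_qaly = c(NA, ic$d_qaly),
    icer = c(NA, ic$icer),
    dominance = c(NA, ic$dominance)
  )
}

#' @method glance cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble(histology = x$histology, mode = x$mode,
         d_cost = x$icer$d_cost, d_qaly = x$icer$d_qaly,
         icer = x$icer$icer, dominance = x$icer$dominance,
         nmb_100k = net_monetary_benefit(x$icer, 1e5))
}

#' Write a comparison summary as delimited text
#'
#' @param x A `cea_comparison`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  utils::write.table(tidy(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
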