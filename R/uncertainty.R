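#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the incremental comparison with each parameter set to its
#' low and high bound in turn, all others at baseline, and ranks parameters
#' by the spread of the resulting ICERs. Where an ICER is undefined at a
#' bound (dominance), the ordering falls back to the net-monetary-benefit
#' scale at `wtp`.
#'
#' @param ps A `cea_parameters` object.
#' @param mode Extrapolation mode passed to [run_comparison()].
#' @param wtp Willingness-to-pay threshold used for the dominance-aware
#'   ordering (USD/QALY).
#' @param parameters Optional character vector restricting the sweep.
#' @param ... Passed to [run_comparison()] (registry, life_table, horizon).
#' @return A `cea_dsa` tibble: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `nmb_low`, `nmb_high`, `spread`, sorted by descending
#'   spread.
#' @export
one_way_dsa <- function(ps, mode = "scenario1", wtp = 1e5,
                        parameters = NULL, ...) {
  varied <- ps$params |>
    filter(.data$low < .data$high)
  if (!is.null(parameters)) {
    varied <- filter(varied, .data$name %in% parameters)
  }
  dots <- list(...)
  base <- do.call(run_comparison, c(list(ps, mode = mode), dots))
  base_icer <- base$icer$icer

  rows <- purrr::pmap(varied, function(name, value, low, high, ...) {
    at <- function(v) {
      cmp <- do.call(run_comparison,
                     c(list(set_parameters(ps, setNames(v, name)),
                            mode = mode), dots))
      cmp$icer
    }
    lo <- at(low)
    hi <- at(high)
    both_defined <- !is.na(lo$icer) && !is.na(hi$icer)
    spread <- if (both_defined) abs(hi$icer - lo$icer) else
      abs(net_monetary_benefit(hi, wtp) - net_monetary_benefit(lo, wtp)) /
        max(abs(base$icer$d_qaly), 1e-9)
    tibble(parameter = name, low = low, high = high,
           icer_low = lo$icer, icer_high = hi$icer,
           dominance_low = lo$dominance, dominance_high = hi$dominance,
           nmb_low = net_monetary_benefit(lo, wtp),
           nmb_high = net_monetary_benefit(hi, wtp),
           spread = spread)
  })
  out <- bind_rows(rows) |> arrange(desc(.data$spread))
  structure(out, class = c("cea_dsa", class(out)),
            base_icer = base_icer, wtp = wtp)
}

#' @method autoplot cea_dsa
#' @export
autoplot.cea_dsa <- function(object, top = 10, ...) {
  base_icer <- attr(object, "base_icer")
  dat <- head(object, top) |>
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)),
           lo = pmin(.data$icer_low, .data$icer_high),
           hi = pmax(.data$icer_low, .data$icer_high))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)")
}

#' Draw parameter values from their probabilistic distributions
#'
#' Sampling conventions: log-normal draws take the baseline as the median
#' with the log-scale SD implied by the range treated as a 95% CI; beta and
#' gamma draws are moment-matched to the baseline mean and
#' `SD = (high - low) / (2 x 1.96)`; normal draws are truncated at the
#' range bounds; `fixed` (and degenerate-range) parameters stay at baseline.
#' When beta moments are infeasible the draw falls back to uniform over the
#' range, with a warning.
#'
#' @param ps A `cea_parameters` object.
#' @param n Number of joint draws.
#' @return A tibble with `n` rows, one column per parameter. Reproducible
#'   under a fixed RNG seed.
#' @export
draw_parameters <- function(ps, n = 1) {
  draws <- purrr::pmap(ps$params, function(name, value, low, high, dist,
                                           units, table1) {
    if (dist == "fixed" || high <= low) {
      return(rep(value, n))
    }
    sd <- (high - low) / (2 * 1.96)
    switch(dist,
      lognormal = {
        sdlog <- (log(high) - log(low)) / (2 * 1.96)
        rlnorm(n, meanlog = log(value), sdlog = sdlog)
      },
      beta = {
        m <- value
        if (m <= 0 || m >= 1 || sd^2 >= m * (1 - m)) {
          warn(paste0("infeasible beta moments for '", name,
                      "'; falling back to uniform(low, high)"))
          runif(n, low, high)
        } else {
          nu <- m * (1 - m) / sd^2 - 1
          rbeta(n, m * nu, (1 - m) * nu)
        }
      },
      gamma = {
        rgamma(n, shape = (value / sd)^2, rate = value / sd^2)
      },
      normal = {
        qnorm(runif(n, pnorm(low, value, sd), pnorm(high, value, sd)),
              value, sd)
      },
      abort(paste0("unknown distribution family: ", dist),
            class = "psmcea_error")
    )
  })
  names(draws) <- ps$params$name
  as_tibble(draws)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo evaluation of the incremental comparison under joint
#' parameter uncertainty: each iteration draws one value per parameter from
#' its assigned distribution and re-runs both arms. Iterations that fail are
#' dropped with a warning reporting the count.
#'
#' @param ps A `cea_parameters` object.
#' @param n_iter Number of Monte-Carlo iterations.
#' @param mode Extrapolation mode.
#' @param seed Optional RNG seed for reproducibility.
#' @param ... Passed to [run_comparison()].
#' @return A `cea_psa` tibble: `iter`, per-arm `cost_*` and `qaly_*`,
#'   `d_cost`, `d_qaly`.
#' @export
run_psa <- function(ps, n_iter = 1000, mode = "scenario1", seed = NULL, ...) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_parameters(ps, n_iter)
  rows <- purrr::map(seq_len(n_iter), function(i) {
    vals <- unlist(draws[i, ])
    tryCatch({
      psi <- ps
      psi$params$value <- unname(vals[psi$params$name])
      cmp <- run_comparison(psi, mode = mode, ...)
      tibble(iter = i,
             cost_pembro_chemo = cmp$pembro_chemo$cost,
             qaly_pembro_chemo = cmp$pembro_chemo$qaly,
             cost_pembro = cmp$pembro$cost,
             qaly_pembro = cmp$pembro$qaly,
             d_cost = cmp$icer$d_cost, d_qaly = cmp$icer$d_qaly)
    }, error = function(e) NULL)
  })
  failed <- sum(purrr::map_lgl(rows, is.null))
  if (failed > 0) {
    warn(paste0(failed, " of ", n_iter, " PSA iterations failed and were excluded"))
  }
  out <- bind_rows(rows)
  structure(out, class = c("cea_psa", class(out)),
            draws = draws, mode = mode)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic
#' iterations in which the combination strategy has positive net monetary
#' benefit (`wtp x dQALY - dCost > 0`).
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid (USD/QALY); default $0-$300,000
#'   in $10,000 steps.
#' @return A `cea_ceac` tibble with `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 3e5, by = 1e4)) {
  if (nrow(samples) == 0) {
    abort("no PSA samples", class = "psmcea_error")
  }
  out <- tibble(
    wtp = wtp_grid,
    prob_cost_effective = purrr::map_dbl(
      wtp_grid, \(l) mean(l * samples$d_qaly - samples$d_cost > 0))
  )
  structure(out, class = c("cea_ceac", class(out)))
}

#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                       y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) x / 1000) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($1,000/QALY)",
                  y = "P(combination cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
}

#' Incremental cost-effectiveness scatter for PSA samples
#'
#' @param object A `cea_psa` tibble.
#' @param wtp Threshold line (USD/QALY).
#' @param ... Unused.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, wtp = 1e5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Probabilistic sensitivity analysis")
}
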