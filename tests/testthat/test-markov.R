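test_that("an immortal untreated-progression-free cohort never leaves PFS on-treatment", {
  trace <- build_trace(flat_curve(), flat_curve(), toy_regimen(disc_prob = 0),
                       horizon = 24)
  expect_true(all(trace$pfs_on == 1))
  expect_true(all(trace$pd == 0) && all(trace$dead == 0))
})

test_that("on-treatment fraction decays by the discontinuation probability", {
  ps <- nsq_params()
  mono <- run_strategy(ps, "pembro", mode = "scenario1")
  trace <- attr(mono, "trace")
  s_pfs12 <- loglogistic_survival(12, 0.01422, 1.80138)^1.53
  expect_equal(trace$frac_pembrolizumab[trace$cycle == 12],
               s_pfs12 * (1 - 0.005559)^12, tolerance = 1e-12)
})

test_that("crossing curves clip progressive disease to zero with a warning", {
  os <- exp_curve(0.10)
  pfs <- exp_curve(0.05)   # above OS: inconsistent inputs
  expect_warning(trace <- build_trace(os, pfs, toy_regimen(), horizon = 12),
                 "clipped")
  expect_true(all(trace$pd == 0))
  expect_equal(trace$pfs_on + trace$pfs_off, surv_prob(os, 0:11),
               tolerance = 1e-12)
})

test_that("occupancies conserve mass and death is absorbing in every mode", {
  for (ps in list(nsq_params(), sq_params())) {
    for (mode in c("scenario1", "base", "scenario2")) {
      for (arm in c("pembro", "pembro_chemo")) {
        res <- suppressWarnings(run_strategy(ps, arm, mode = mode))
        tr <- attr(res, "trace")
        occupancy <- tr$pfs_on + tr$pfs_off + tr$pd + tr$dead
        expect_true(all(abs(occupancy - 1) < 1e-10))
        expect_true(all(diff(tr$dead) >= -1e-12))
        expect_true(all(tr$frac_pembrolizumab <= tr$pfs_on + 1e-12))
      }
    }
  }
})

test_that("time-to-death utility is the window mixture", {
  u <- c(u_ge12 = 0.834, u_6_12 = 0.765, u_1_6 = 0.709, u_le1 = 0.563)
  expect_equal(time_to_death_utility(flat_curve(), 5, u), 0.834)
  doomed <- surv_curve(function(t) pmax(1 - t, 0))   # all dead within 1 month
  expect_equal(time_to_death_utility(doomed, 0, u), 0.563)
  ll <- loglogistic_curve(0.03084, 0.92588)
  mid <- time_to_death_utility(ll, 0, u)
  expect_gt(mid, 0.563)
  expect_lt(mid, 0.834)
  dead <- surv_curve(function(t) ifelse(t < 1, 1, 0))
  expect_error(time_to_death_utility(dead, 2, u),
               class = "psmcea_degenerate_error")
})

test_that("undiscounted immortal cohort accrues utility times twenty years", {
  ps <- set_parameters(nsq_params(), discount_rate = 0, u_ge12 = 0.834,
                       u_6_12 = 0.834, u_1_6 = 0.834, u_le1 = 0.834,
                       disutility_pembro = 0)
  trace <- build_trace(flat_curve(), flat_curve(), toy_regimen(), horizon = 240)
  res <- accrue(trace, ps, "pembro")
  expect_equal(res$qaly, 0.834 * 20, tolerance = 1e-9)
  expect_equal(res$life_years, 20, tolerance = 1e-9)
})

test_that("discounting applies (1+r)^(-t/12) to cycle events", {
  # all deaths in cycle 12 with a unit death cost: present value 1/1.03
  ps <- set_parameters(nsq_params(), cost_death = 1)
  # zero out every other cost channel
  ps <- set_parameters(ps, cost_physician_visit = 0, cost_imaging = 0,
                       cost_bsc = 0, ae_cost_pembro = 0,
                       subsq_cost_pembro = 0)
  step_os <- surv_curve(function(t) ifelse(t < 12, 1, 0.4))
  step_pfs <- surv_curve(function(t) ifelse(t < 12, 1, 0.4))
  trace <- build_trace(step_os, step_pfs, toy_regimen(), horizon = 24)
  res <- accrue(trace, ps, "pembro")
  death_row <- res$components[res$components$component == "death", ]
  expect_equal(death_row$cost, 0.6 * 1 / 1.03, tolerance = 1e-9)
  expect_equal(death_row$cost_undiscounted, 0.6, tolerance = 1e-12)
})

test_that("every accrued death eventually pays the death-associated cost", {
  ps <- nsq_params()
  res <- run_strategy(ps, "pembro", mode = "scenario1")
  tr <- attr(res, "trace")
  death_row <- res$components[res$components$component == "death", ]
  expect_equal(death_row$cost_undiscounted,
               9433 * tr$dead[nrow(tr)], tolerance = 1e-6)
})

test_that("ICER arithmetic and dominance flags", {
  expect_equal(icer(list(cost = 100, qaly = 2), list(cost = 0, qaly = 0))$icer, 50)
  # published rounded increments divide to ~168,687/QALY
  expect_equal(icer(list(cost = 182182, qaly = 1.08),
                    list(cost = 0, qaly = 0))$icer, 168687.04, tolerance = 1e-2)
  dom <- icer(list(cost = 10, qaly = -1), list(cost = 0, qaly = 0))
  expect_identical(dom$dominance, "dominated")
  expect_true(is.na(dom$icer))
  dominant <- icer(list(cost = -10, qaly = 1), list(cost = 0, qaly = 0))
  expect_identical(dominant$dominance, "dominant")
  flat <- icer(list(cost = 10, qaly = 1e-12), list(cost = 0, qaly = 0))
  expect_identical(flat$dominance, "higher cost, equal effect")
  expect_equal(net_monetary_benefit(icer(list(cost = 100, qaly = 0.002),
                                         list(cost = 0, qaly = 0)), 1e5),
               100, tolerance = 1e-9)
})

test_that("QALYs equal life-years when utilities are one and decrements zero", {
  ps <- set_parameters(nsq_params(), u_ge12 = 1, u_6_12 = 1, u_1_6 = 1,
                       u_le1 = 1, disutility_pembro = 0,
                       disutility_pembro_chemo = 0)
  for (arm in c("pembro", "pembro_chemo")) {
    res <- run_strategy(ps, arm, mode = "scenario1")
    expect_equal(res$qaly, res$life_years, tolerance = 1e-12)
  }
})

test_that("total cost is linear: doubling every unit cost doubles the total", {
  ps <- nsq_params()
  cost_names <- ps$params$name[ps$params$units %in% c("usd", "usd_per_mg")]
  doubled <- ps
  doubled$params$value[doubled$params$name %in% cost_names] <-
    2 * doubled$params$value[doubled$params$name %in% cost_names]
  for (arm in c("pembro", "pembro_chemo")) {
    base <- run_strategy(ps, arm, mode = "scenario1")
    twice <- run_strategy(doubled, arm, mode = "scenario1")
    expect_equal(twice$cost, 2 * base$cost, tolerance = 1e-9)
    expect_equal(twice$qaly, base$qaly, tolerance = 1e-12)
  }
})

test_that("discounting can only shrink costs and QALYs", {
  ps <- nsq_params()
  undisc <- set_parameters(ps, discount_rate = 0)
  for (arm in c("pembro", "pembro_chemo")) {
    d <- run_strategy(ps, arm, mode = "scenario1")
    u <- run_strategy(undisc, arm, mode = "scenario1")
    expect_lt(d$cost, u$cost)
    expect_lt(d$qaly, u$qaly)
    expect_equal(d$cost_undiscounted, u$cost, tolerance = 1e-9)
    expect_equal(u$qaly, u$qaly_undiscounted, tolerance = 1e-9)
  }
})

test_that("identical arms produce zero increments", {
  ps <- set_parameters(nsq_params(), hr_os = 1, hr_pfs = 1,
                       ae_cost_pembro_chemo = param_value(nsq_params(), "ae_cost_pembro"),
                       subsq_cost_pembro_chemo = param_value(nsq_params(), "subsq_cost_pembro"),
                       disutility_pembro_chemo = param_value(nsq_params(), "disutility_pembro"))
  ps$regimens$pembro_chemo <- ps$regimens$pembro
  cmp <- run_comparison(ps, mode = "scenario1")
  expect_equal(cmp$icer$d_cost, 0, tolerance = 1e-9)
  expect_equal(cmp$icer$d_qaly, 0, tolerance = 1e-12)
})

test_that("half-cycle correction halves only the entry-cycle state accruals", {
  ps <- set_parameters(nsq_params(), discount_rate = 0)
  full <- run_strategy(ps, "pembro", mode = "scenario1")
  half <- run_strategy(ps, "pembro", mode = "scenario1", half_cycle = TRUE)
  expect_lt(half$qaly, full$qaly)
  expect_gt(half$qaly, full$qaly - 1 / 12)
})
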