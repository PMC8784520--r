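#' Carboplatin dose by the Calvert formula
#'
#' `dose (mg) = target AUC x (CrCl + 25)`.
#'
#' @param target_auc Target area under the concentration curve (mg*min/mL).
#' @param crcl Creatinine clearance (mL/min), positive.
#' @return Dose in mg.
#' @examples
#' carboplatin_dose(5, 70)
#' @export
carboplatin_dose <- function(target_auc, crcl) {
  if (any(target_auc <= 0) || any(crcl <= 0)) {
    abort("target AUC and creatinine clearance must be positive",
          class = "psmcea_domain_error")
  }
  target_auc * (crcl + 25)
}

#' Body-surface-area scaled dose
#'
#' @param per_m2 Dose intensity in mg per square metre, positive.
#' @param bsa Body surface area in square metres, positive.
#' @return Dose in mg (unrounded).
#' @examples
#' bsa_dose(500, 1.79)
#' @export
bsa_dose <- function(per_m2, bsa) {
  if (any(per_m2 <= 0) || any(bsa <= 0)) {
    abort("dose intensity and body surface area must be positive",
          class = "psmcea_domain_error")
  }
  per_m2 * bsa
}

#' Round a required dose up to whole single-use vials
#'
#' Billed drug quantity is the smallest total achievable with whole vials
#' that covers the required dose (drug-wastage costing); among totals with
#' the same overage the combination with the fewest vials is used.
#'
#' @param required Required dose in mg, non-negative.
#' @param vials Available single-use vial sizes in mg.
#' @param max_count Search bound on vials of any one size (default 40).
#' @return A list with `billed_mg` and `vial_counts` (named integer vector).
#' @examples
#' round_to_vials(895, c(100, 500))
#' @export
round_to_vials <- function(required, vials, max_count = 40) {
  if (length(vials) == 0) {
    abort("no vial sizes supplied", class = "psmcea_error")
  }
  stopifnot(required >= 0, all(vials > 0))
  if (required == 0) {
    return(list(billed_mg = 0,
                vial_counts = setNames(integer(length(vials)),
                                       as.character(vials))))
  }
  vials <- sort(unique(vials), decreasing = TRUE)
  # bounded dynamic programme over achievable totals
  upper <- required + max(vials)
  step <- min(vials)
  best_count <- rep(Inf, ceiling(upper / min(gcd_vec(vials), step)) + 1)
  # simple DP on integer mg grid scaled by the gcd of vial sizes
  g <- gcd_vec(vials)
  grid_max <- as.integer(ceiling(upper / g))
  counts <- rep(Inf, grid_max + 1)
  from <- rep(NA_integer_, grid_max + 1)
  counts[1] <- 0
  v_units <- as.integer(round(vials / g))
  for (i in seq_len(grid_max)) {
    for (vi in seq_along(v_units)) {
      prev <- i - v_units[vi]
      if (prev >= 0 && is.finite(counts[prev + 1]) &&
          counts[prev + 1] + 1 < counts[i + 1]) {
        counts[i + 1] <- counts[prev + 1] + 1
        from[i + 1] <- vi
      }
    }
  }
  req_units <- ceiling(required / g - 1e-9)
  feasible <- which(is.finite(counts) & seq_along(counts) - 1 >= req_units)
  if (length(feasible) == 0) {
    abort("no vial combination covers the required dose", class = "psmcea_error")
  }
  billed_units <- feasible[1] - 1   # smallest achievable total >= required
  vial_counts <- setNames(integer(length(vials)), as.character(vials))
  i <- billed_units
  while (i > 0) {
    vi <- from[i + 1]
    vial_counts[vi] <- vial_counts[vi] + 1L
    i <- i - v_units[vi]
  }
  list(billed_mg = billed_units * g, vial_counts = vial_counts)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
gcd_vec <- function(x) Reduce(gcd2, as.integer(round(x * 100))) / 100

#' Resolve a regimen definition against a parameter set
#'
#' Computes, for each drug in the arm's regimen, the administered dose
#' (flat, body-surface-area scaled, or Calvert AUC based), the vial-rounded
#' billed quantity, the acquisition cost per administration, the infusion
#' fee (first hour at the 1-hour rate, each additional hour at the add-on
#' rate), the per-cycle discontinuation probability, and the administration
#' rate per monthly cycle (`30.44 / interval_days`).
#'
#' @param ps A `cea_parameters` object.
#' @param arm `"pembro"` or `"pembro_chemo"`.
#' @return A `cea_regimen` tibble, one row per drug.
#' @export
regimen_table <- function(ps, arm = c("pembro", "pembro_chemo")) {
  arm <- match.arg(arm)
  rg <- ps$regimens[[arm]]
  bsa <- param_value(ps, "bsa")
  crcl <- param_value(ps, "crcl")
  fee1 <- param_value(ps, "cost_infusion_first_hour")
  fee_extra <- param_value(ps, "cost_infusion_extra_hour")

  rows <- purrr::pmap(rg, function(drug, dose_type, dose, interval_days,
                                   max_administrations, disc_param) {
    spec <- ps$drugs[[drug]]
    required <- switch(dose_type,
      flat = dose,
      per_m2 = bsa_dose(dose, bsa),
      auc = carboplatin_dose(dose, crcl),
      abort(paste0("unknown dose_type: ", dose_type), class = "psmcea_error")
    )
    rounded <- round_to_vials(required, unlist(spec$vials))
    hours <- spec$infusion_hours
    fee <- fee1 + max(0, ceiling(hours - 1)) * fee_extra
    tibble(
      drug = drug,
      required_mg = required,
      billed_mg = rounded$billed_mg,
      price_per_mg = param_value(ps, spec$price_param),
      drug_cost_per_admin = rounded$billed_mg * param_value(ps, spec$price_param),
      infusion_fee = fee,
      admin_rate = DAYS_PER_MONTH / interval_days,
      max_administrations = max_administrations,
      disc_prob = param_value(ps, disc_param)
    )
  })
  structure(bind_rows(rows), class = c("cea_regimen", class(tibble())))
}

#' Drug and administration cost for one model cycle
#'
#' For each drug still within its maximum number of administrations, the
#' cycle accrues `(billed mg x price/mg + infusion fee) x administrations in
#' the cycle x fraction of the cohort on the drug`. Administrations per
#' monthly cycle follow the schedule conversion `30.44 / interval_days`,
#' truncated when the remaining allowance is less than a full cycle's worth.
#'
#' @param regimen A [regimen_table()] result.
#' @param cycle_index Zero-based cycle number (months since model entry).
#' @param on_drug_fractions Named per-drug fractions of the cohort on each
#'   drug (in \[0, 1\]); a single unnamed value is recycled.
#' @return Cost in USD for the cycle.
#' @export
cycle_drug_cost <- function(regimen, cycle_index, on_drug_fractions) {
  if (is.null(names(on_drug_fractions)) && length(on_drug_fractions) == 1) {
    on_drug_fractions <- setNames(rep(on_drug_fractions, nrow(regimen)),
                                  regimen$drug)
  }
  frac <- on_drug_fractions[regimen$drug]
  if (anyNA(frac)) {
    abort("on_drug_fractions must name every regimen drug", class = "psmcea_error")
  }
  if (any(frac < 0 | frac > 1)) {
    abort("fractions must lie in [0, 1]", class = "psmcea_domain_error")
  }
  admins <- pmin(regimen$admin_rate,
                 pmax(0, regimen$max_administrations -
                        regimen$admin_rate * cycle_index))
  sum((regimen$drug_cost_per_admin + regimen$infusion_fee) * admins * frac)
}

#' Frequency-weighted adverse-event burden
#'
#' Aggregates a per-event adverse-event profile (grade 3+ events with
#' incidence of at least 1%) into the one-off cost and QALY decrement the
#' model applies at entry: `cost = sum(incidence x unit cost)` and
#' `QALY decrement = sum(incidence x disutility x duration) / 12` with
#' durations in months.
#'
#' @param profile Tibble with columns `incidence`, `unit_cost`, `disutility`,
#'   `duration_months`. Zero rows yield zero burden.
#' @return A list with `cost` (USD) and `qaly_decrement` (QALYs).
#' @export
ae_burden <- function(profile) {
  profile <- as_tibble(profile)
  if (nrow(profile) == 0) {
    return(list(cost = 0, qaly_decrement = 0))
  }
  stopifnot(all(c("incidence", "unit_cost", "disutility",
                  "duration_months") %in% names(profile)))
  if (any(profile$incidence < 0 | profile$incidence > 1)) {
    abort("incidences must lie in [0, 1]", class = "psmcea_domain_error")
  }
  list(
    cost = sum(profile$incidence * profile$unit_cost),
    qaly_decrement = sum(profile$incidence * profile$disutility *
                           profile$duration_months) / 12
  )
}
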