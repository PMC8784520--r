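#' Load and validate a model-input registry
#'
#' Reads a YAML configuration holding every model input — survival parameters,
#' hazard ratios, per-cycle discontinuation probabilities, prices, costs,
#' utilities, disutilities and patient constants — together with its
#' deterministic sensitivity range and probabilistic distribution family, plus
#' the regimen definitions (drug, dose rule, schedule, maximum number of
#' administrations) and drug presentations (vial sizes, price parameter,
#' infusion duration) for both treatment arms.
#'
#' Two registries are bundled, one per histology:
#' `psmcea_example("nonsquamous_table1.yaml")` and
#' `psmcea_example("squamous_table1.yaml")`.
#'
#' Validation enforces: `low <= value <= high`; probabilities and utilities in
#' \[0, 1\]; costs and prices non-negative; hazard ratios positive; exactly
#' one regimen per arm; and that every parameter referenced by a regimen
#' (discontinuation and price parameters) is present. A parameter with a
#' non-fixed distribution but no stated range is defaulted to
#' [default_range()] and the defaulting is reported via a message.
#'
#' @param path Path to a YAML registry file.
#' @return A `cea_parameters` object: list with elements `histology`,
#'   `params` (a tibble with columns `name`, `value`, `low`, `high`, `dist`,
#'   `units`, `table1`), `regimens` (named list of regimen tibbles) and
#'   `drugs` (named list of drug presentations).
#' @examples
#' ps <- load_parameters(psmcea_example("nonsquamous_table1.yaml"))
#' param_value(ps, "hr_os")
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path), class = "psmcea_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$histology) ||
      !raw$histology %in% c("non_squamous", "squamous")) {
    abort("config must declare histology: non_squamous or squamous",
          class = "psmcea_validation_error")
  }
  if (is.null(raw$parameters) || length(raw$parameters) == 0) {
    abort("config has no parameters block", class = "psmcea_validation_error")
  }

  params <- purrr::imap(raw$parameters, function(p, nm) {
    value <- p$value
    dist <- p$dist %||% "fixed"
    low <- p$low
    high <- p$high
    if (is.null(low) || is.null(high)) {
      if (dist == "fixed") {
        low <- high <- value
      } else {
        rng <- default_range(value)
        low <- rng[[1]]
        high <- rng[[2]]
        message("parameter '", nm, "': no range supplied, defaulted to ±50%")
      }
    }
    tibble(
      name = nm, value = as.numeric(value),
      low = as.numeric(low), high = as.numeric(high),
      dist = dist, units = p$units %||% "dimensionless",
      table1 = isTRUE(p$table1)
    )
  }) |>
    bind_rows()

  if (anyDuplicated(params$name) > 0) {
    abort("duplicate parameter names in config", class = "psmcea_validation_error")
  }

  regimens <- purrr::map(raw$regimens, function(rg) {
    purrr::map(rg, \(d) tibble(
      drug = d$drug,
      dose_type = d$dose_type,
      dose = as.numeric(d$dose),
      interval_days = as.numeric(d$interval_days),
      max_administrations = if (is.null(d$max_administrations)) Inf else
        as.numeric(d$max_administrations),
      disc_param = d$disc_param
    )) |> bind_rows()
  })

  ps <- structure(
    list(histology = raw$histology, params = params,
         regimens = regimens, drugs = raw$drugs),
    class = "cea_parameters"
  )
  validate_parameters(ps)
  ps
}

#' Validate a parameter set
#'
#' @param ps A `cea_parameters` object.
#' @return `ps`, invisibly, or an error describing the violated invariant or
#'   the missing parameters.
#' @export
validate_parameters <- function(ps) {
  p <- ps$params

  required <- c(
    "os_theta", "os_kappa", "pfs_theta", "pfs_kappa", "hr_os", "hr_pfs",
    "cost_infusion_first_hour", "cost_infusion_extra_hour",
    "cost_physician_visit", "cost_imaging", "cost_bsc", "cost_death",
    "ae_cost_pembro", "ae_cost_pembro_chemo",
    "subsq_cost_pembro", "subsq_cost_pembro_chemo",
    "u_ge12", "u_6_12", "u_1_6", "u_le1",
    "disutility_pembro", "disutility_pembro_chemo",
    "bsa", "crcl", "discount_rate", "subsq_uptake",
    "fatal_ae_pembro", "fatal_ae_pembro_chemo", "start_age"
  )
  # every parameter a regimen refers to must exist
  referenced <- unique(unlist(purrr::map(
    ps$regimens, \(rg) c(rg$disc_param,
                         purrr::map_chr(rg$drug, \(d) {
                           spec <- ps$drugs[[d]]
                           if (is.null(spec)) NA_character_ else spec$price_param
                         }))
  )))
  undefined_drugs <- setdiff(
    unique(unlist(purrr::map(ps$regimens, "drug"))), names(ps$drugs))
  if (length(undefined_drugs) > 0) {
    abort(paste0("regimen drug(s) missing from drugs block: ",
                 paste(undefined_drugs, collapse = ", ")),
          class = "psmcea_validation_error")
  }
  missing <- setdiff(c(required, referenced[!is.na(referenced)]), p$name)
  if (length(missing) > 0) {
    abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")),
          class = "psmcea_missing_parameter_error")
  }

  if (!setequal(names(ps$regimens), c("pembro", "pembro_chemo"))) {
    abort("config must define exactly one regimen per arm: pembro, pembro_chemo",
          class = "psmcea_validation_error")
  }

  bad_order <- p$name[!(p$low <= p$value & p$value <= p$high)]
  if (length(bad_order) > 0) {
    abort(paste0("low <= value <= high violated for: ",
                 paste(bad_order, collapse = ", ")),
          class = "psmcea_validation_error")
  }
  unit_in_01 <- p$units %in% c("probability", "utility")
  bad01 <- p$name[unit_in_01 & (p$value < 0 | p$value > 1 | p$low < 0 | p$high > 1)]
  if (length(bad01) > 0) {
    abort(paste0(p$units[match(bad01[1], p$name)], " out of [0,1]: ",
                 paste(bad01, collapse = ", ")),
          class = "psmcea_validation_error")
  }
  is_cost <- p$units %in% c("usd", "usd_per_mg")
  bad_cost <- p$name[is_cost & p$low < 0]
  if (length(bad_cost) > 0) {
    abort(paste0("negative cost: ", paste(bad_cost, collapse = ", ")),
          class = "psmcea_validation_error")
  }
  is_hr <- p$units == "hazard_ratio"
  bad_hr <- p$name[is_hr & p$low <= 0]
  if (length(bad_hr) > 0) {
    abort(paste0("hazard ratio must be positive: ",
                 paste(bad_hr, collapse = ", ")),
          class = "psmcea_validation_error")
  }
  invisible(ps)
}

#' Default deterministic sensitivity range
#'
#' When a model input has no reported 95% confidence interval, its one-way
#' sensitivity range defaults to plus or minus 50% of the baseline value.
#'
#' @param value Baseline value (finite numeric scalar).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' default_range(637)
#' @export
default_range <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  c(0.5 * value, 1.5 * value)
}

#' Read a single parameter value
#'
#' @param ps A `cea_parameters` object.
#' @param name Parameter name.
#' @return The baseline numeric value.
#' @export
param_value <- function(ps, name) {
  i <- match(name, ps$params$name)
  if (is.na(i)) {
    abort(paste0("unknown parameter: ", name), class = "psmcea_error")
  }
  ps$params$value[i]
}

#' Replace parameter values
#'
#' Returns a modified copy of the parameter set with the named baseline
#' values replaced; used by the sensitivity-analysis drivers.
#'
#' @param ps A `cea_parameters` object.
#' @param ... Named numeric values, e.g. `hr_os = 2.87`.
#' @param validate Re-run range validation (disable when setting a value
#'   outside its deterministic range, as probabilistic draws may).
#' @return The modified `cea_parameters` object.
#' @export
set_parameters <- function(ps, ..., validate = FALSE) {
  new <- c(...)
  i <- match(names(new), ps$params$name)
  if (anyNA(i)) {
    abort(paste0("unknown parameter: ",
                 paste(names(new)[is.na(i)], collapse = ", ")),
          class = "psmcea_error")
  }
  ps$params$value[i] <- unname(new)
  if (validate) validate_parameters(ps)
  ps
}

#' Serialize a parameter set back to YAML
#'
#' Writes a registry file that [load_parameters()] reads back to an identical
#' object (round-trip property).
#'
#' @param ps A `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  par_list <- purrr::pmap(ps$params, function(name, value, low, high, dist,
                                              units, table1) {
    list(value = value, low = low, high = high, dist = dist,
         units = units, table1 = table1)
  })
  names(par_list) <- ps$params$name
  reg_list <- purrr::map(ps$regimens, function(rg) {
    purrr::pmap(rg, function(drug, dose_type, dose, interval_days,
                             max_administrations, disc_param) {
      list(drug = drug, dose_type = dose_type, dose = dose,
           interval_days = interval_days,
           max_administrations = if (is.infinite(max_administrations)) NULL else
             max_administrations,
           disc_param = disc_param)
    })
  })
  yaml::write_yaml(
    list(histology = ps$histology, parameters = par_list,
         drugs = ps$drugs, regimens = reg_list),
    path
  )
  invisible(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters> histology:", x$histology, "\n")
  cat(" ", nrow(x$params), "parameters;",
      length(x$regimens), "regimens (",
      paste(names(x$regimens), collapse = ", "), ")\n")
  print(x$params, n = 8)
  invisible(x)
}

#' @method tidy cea_parameters
#' @export
tidy.cea_parameters <- function(x, ...) x$params
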