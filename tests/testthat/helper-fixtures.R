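# Shared fixtures: bundled parameter registries and small curve builders.

nsq_params <- function() load_parameters(psmcea_example("nonsquamous_table1.yaml"))
sq_params <- function() load_parameters(psmcea_example("squamous_table1.yaml"))

flat_curve <- function(level = 1) {
  surv_curve(function(t) ifelse(t == 0, 1, level), "tabulated")
}

exp_curve <- function(rate) {
  surv_curve(function(t) exp(-rate * t), "parametric")
}

# single-drug regimen with explicit knobs, for trace unit tests
toy_regimen <- function(disc_prob = 0, admin_rate = 1, max_admin = Inf,
                        cost_per_admin = 0, fee = 0) {
  structure(
    tibble::tibble(
      drug = "pembrolizumab", required_mg = 200, billed_mg = 200,
      price_per_mg = cost_per_admin / 200,
      drug_cost_per_admin = cost_per_admin, infusion_fee = fee,
      admin_rate = admin_rate, max_administrations = max_admin,
      disc_prob = disc_prob
    ),
    class = c("cea_regimen", class(tibble::tibble()))
  )
}

# edit one scalar in a YAML registry and return a temp path
patched_config <- function(path, pattern, replacement) {
  txt <- readLines(path)
  hit <- grepl(pattern, txt)
  stopifnot(any(hit))
  txt[hit] <- sub(pattern, replacement, txt[hit])
  out <- withr::local_tempfile(fileext = ".yaml",
                               .local_envir = parent.frame())
  writeLines(txt, out)
  out
}
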