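#' Load and validate a model configuration
#'
#' Reads the complete parameter set of the cost-utility model from a YAML (or
#' JSON) document and validates every invariant. The returned object is the
#' single source of truth for all downstream modules: clinical schedules,
#' the Markov engine, cost/utility accrual and the sensitivity analyses.
#'
#' @param path Path to a YAML or JSON configuration file. Keys mirror the
#'   fields of the returned object; see the shipped default at
#'   `system.file("extdata", "default_config.yaml", package = "glaucomaCUA")`.
#' @return A validated `cua_params` object (a named list).
#' @seealso [default_params()], [write_params()], [validate_params()]
#' @export
#' @examples
#' p <- default_params()
#' p$discount_rate_costs
load_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "cua_validation_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(raw)
}

#' Default base-case parameters
#'
#' The shipped configuration: trial-derived IOP schedules, Italian NHS unit
#' costs and monitoring intensities, Dutch vision-related utilities, and the
#' calibrated lognormal time-to-progression.
#'
#' @return A validated `cua_params` object.
#' @export
default_params <- function() {
  load_params(system.file("extdata", "default_config.yaml",
                          package = "glaucomaCUA", mustWork = TRUE))
}

#' Build a parameter object from a plain list
#'
#' @param raw Named list with the same structure as the YAML config.
#' @return A validated `cua_params` object.
#' @export
params_from_list <- function(raw) {
  defaultable <- list(
    max_age = 110,
    cycle_length = 1,
    half_cycle_correction = FALSE,
    psa_settings = list(n_reps = 1000, seed = 20210817),
    dsa_settings = list(default_rel_width = 0.20, iop_rel_width = 0.10)
  )
  for (key in names(defaultable)) {
    if (is.null(raw[[key]])) raw[[key]] <- defaultable[[key]]
  }
  required <- c(
    "cohort_start_age", "initial_state_split", "discount_rate_costs",
    "discount_rate_effects", "untreated_vf_decline",
    "decline_reduction_per_mmhg", "progression_hr_per_mmhg",
    "band_widths", "nat_progression_lognormal",
    "trabeculectomy_iop_reduction", "discontinuation_mean_time",
    "unmedicated_iop_offset", "iop_schedule", "costs", "utilities",
    "disutilities"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required config key(s): ",
                 paste(missing, collapse = ", ")),
          class = "cua_validation_error")
  }
  p <- raw
  p$initial_state_split <- unlist(p$initial_state_split)[.states]
  p$band_widths <- unlist(p$band_widths)[c("mild", "moderate", "advanced")]
  p$utilities <- unlist(p$utilities)[.states]
  p$iop_schedule <- lapply(p$iop_schedule, as.numeric)
  med <- p$costs$medications
  if (is.data.frame(med)) {
    p$costs$medications <- tibble::as_tibble(med)
  } else {
    p$costs$medications <- purrr::map_dfr(med, tibble::as_tibble)
  }
  class(p) <- c("cua_params", "list")
  validate_params(p)
  p
}

#' Validate a parameter object
#'
#' Checks every structural invariant: the initial state split sums to one,
#' probabilities and utilities lie in \[0, 1\], costs are non-negative, each
#' arm's IOP schedule covers years 1..10 plus a terminal "10+" value and is
#' non-increasing after year one, band widths are positive and discount rates
#' lie in \[0, 1).
#'
#' @param p A `cua_params` object (or compatible list).
#' @return `p`, invisibly, if valid; otherwise a `cua_validation_error`
#'   naming the offending field and constraint.
#' @export
validate_params <- function(p) {
  fail <- function(field, constraint) {
    abort(paste0("invalid parameter `", field, "`: ", constraint),
          class = "cua_validation_error")
  }
  split <- p$initial_state_split
  if (length(split) != 4 || anyNA(split)) {
    fail("initial_state_split", "must name all four living states")
  }
  if (abs(sum(split) - 1) > 1e-12) fail("initial_state_split", "must sum to 1")
  if (any(split < 0 | split > 1)) fail("initial_state_split", "entries must be in [0, 1]")

  for (field in c("discount_rate_costs", "discount_rate_effects")) {
    r <- p[[field]]
    if (!is.numeric(r) || r < 0 || r >= 1) fail(field, "must be in [0, 1)")
  }
  if (p$cohort_start_age <= 0 || p$cohort_start_age >= p$max_age) {
    fail("cohort_start_age", "must be positive and below max_age")
  }
  if (p$untreated_vf_decline < 0) fail("untreated_vf_decline", "must be >= 0 (stored positive)")
  if (p$decline_reduction_per_mmhg < 0 || p$decline_reduction_per_mmhg >= 1) {
    fail("decline_reduction_per_mmhg", "must be in [0, 1)")
  }
  if (p$progression_hr_per_mmhg <= 0) fail("progression_hr_per_mmhg", "must be > 0")
  if (any(p$band_widths <= 0) || anyNA(p$band_widths)) {
    fail("band_widths", "must be strictly positive for mild, moderate, advanced")
  }
  ln <- p$nat_progression_lognormal
  if (is.null(ln$meanlog) || is.null(ln$sdlog) || ln$sdlog <= 0) {
    fail("nat_progression_lognormal", "needs meanlog and sdlog > 0")
  }
  if (p$discontinuation_mean_time <= 0) fail("discontinuation_mean_time", "must be > 0")

  for (arm in .arms) {
    sched <- p$iop_schedule[[arm]]
    if (is.null(sched)) fail("iop_schedule", paste0("missing arm `", arm, "`"))
    if (length(sched) != 11) {
      fail("iop_schedule", paste0("arm `", arm, "` needs 11 values (years 1..10 and \"10+\")"))
    }
    if (any(sched < 0)) fail("iop_schedule", "reductions must be >= 0")
    if (any(diff(sched) > 1e-12)) {
      fail("iop_schedule", paste0("arm `", arm, "` must be non-increasing after year 1"))
    }
  }

  costs <- p$costs
  for (key in c("procedure", "trabeculectomy", "medications", "medication_factor",
                "monitoring", "adverse_events")) {
    if (is.null(costs[[key]])) fail(paste0("costs.", key), "missing")
  }
  flat_costs <- c(
    unlist(costs$procedure), costs$trabeculectomy,
    costs$medications$price, unlist(costs$monitoring$unit_costs),
    unlist(costs$adverse_events$unit_costs)
  )
  if (any(flat_costs < 0)) fail("costs", "all unit costs must be >= 0")
  if (any(unlist(costs$medication_factor) < 0)) {
    fail("costs.medication_factor", "must be >= 0")
  }
  inc <- costs$monitoring$incidence
  if (!all(.states %in% names(inc))) fail("costs.monitoring.incidence", "must cover all states")
  if (any(unlist(inc) < 0)) fail("costs.monitoring.incidence", "must be >= 0")
  ae_inc <- unlist(costs$adverse_events$incidence)
  if (any(ae_inc < 0 | ae_inc > 1)) fail("costs.adverse_events.incidence", "must be in [0, 1]")

  if (any(p$utilities < 0 | p$utilities > 1) || anyNA(p$utilities)) {
    fail("utilities", "must be in [0, 1] for all four states")
  }
  du <- unlist(p$disutilities)
  if (!all(c("trabeculectomy", "medication_ae", "medication_ae_incidence") %in% names(du))) {
    fail("disutilities", "must name trabeculectomy, medication_ae, medication_ae_incidence")
  }
  if (any(du < 0 | du > 1)) fail("disutilities", "must be in [0, 1]")
  invisible(p)
}

#' Write a parameter object back to YAML
#'
#' Round-trips with [load_params()]: writing and re-reading reproduces an
#' identical parameter set.
#'
#' @param p A `cua_params` object.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  out <- unclass(p)
  out$initial_state_split <- as.list(p$initial_state_split)
  out$band_widths <- as.list(p$band_widths)
  out$utilities <- as.list(p$utilities)
  out$costs$medications <- purrr::pmap(p$costs$medications, list)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.cua_params <- function(x, ...) {
  cat("<cua_params> lifetime cost-utility model configuration\n")
  cat(sprintf("  cohort start age : %.1f y (states: %s)\n",
              x$cohort_start_age,
              paste(sprintf("%s %.0f%%", .states, 100 * x$initial_state_split),
                    collapse = ", ")))
  cat(sprintf("  discounting      : costs %.1f%%/y, effects %.1f%%/y\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_effects))
  cat(sprintf("  VF decline       : %.4f dB/mo untreated, -%.1f%%/mmHg\n",
              x$untreated_vf_decline, 100 * x$decline_reduction_per_mmhg))
  cat(sprintf("  progression HR   : %.2f per mmHg; trabeculectomy effect %.2f mmHg\n",
              x$progression_hr_per_mmhg, x$trabeculectomy_iop_reduction))
  cat(sprintf("  IOP reduction y1 : stent-arm %.1f vs cataract %.1f mmHg\n",
              x$iop_schedule$istent[1], x$iop_schedule$cataract[1]))
  invisible(x)
}
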