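#' Calibrate the baseline time-to-progression lognormal
#'
#' The location and scale of the untreated lognormal time-to-progression
#' (months) that drives the switch to trabeculectomy are not directly
#' observable. This routine grid-searches them against paired-arm lifetime
#' targets: per-arm discounted QALYs and, when supplied, the per-arm
#' discounted trabeculectomy procedure spend (a monotone proxy for
#' trabeculectomy uptake). The objective is the sum of squared relative
#' errors over all supplied targets; the search is deterministic for a
#' fixed grid and returns the exhaustive argmin.
#'
#' @param params A `cua_params` object (its current lognormal is ignored).
#' @param lt A `cua_life_table`.
#' @param targets List with `qaly` (named vector, `istent` and `cataract`)
#'   and optionally `d_qaly` (the incremental QALYs, the decision-relevant
#'   effectiveness quantity) and/or `trab_cost` (named vector; discounted
#'   trabeculectomy spend in EUR).
#' @param meanlog_grid,sdlog_grid Grids over the lognormal location (log
#'   months) and scale.
#' @return A list: `meanlog`, `sdlog`, `error` (achieved objective),
#'   `params` (input params with the calibrated lognormal), and `grid`
#'   (tibble of every evaluated point).
#' @export
calibrate_progression <- function(params, lt, targets,
                                  meanlog_grid = log(seq(40, 400, by = 30)),
                                  sdlog_grid = seq(0.3, 1.7, by = 0.2)) {
  if (length(meanlog_grid) == 0 || length(sdlog_grid) == 0) {
    abort("empty calibration grid", class = "cua_validation_error")
  }
  if (is.null(targets$qaly)) {
    abort("targets must include per-arm discounted QALYs",
          class = "cua_validation_error")
  }
  objective <- function(meanlog, sdlog) {
    p <- params
    p$nat_progression_lognormal <- list(meanlog = meanlog, sdlog = sdlog)
    err <- 0
    qaly <- c(istent = NA_real_, cataract = NA_real_)
    for (arm in .arms) {
      tot <- trace_totals(run_cohort(p, lt, arm))
      qaly[[arm]] <- tot$qaly
      err <- err + ((tot$qaly - targets$qaly[[arm]]) / targets$qaly[[arm]])^2
      if (!is.null(targets$trab_cost)) {
        trab <- tot$cost_procedures - p$costs$procedure[[arm]]
        err <- err +
          ((trab - targets$trab_cost[[arm]]) / targets$trab_cost[[arm]])^2
      }
    }
    if (!is.null(targets$d_qaly)) {
      err <- err +
        ((qaly[["istent"]] - qaly[["cataract"]] - targets$d_qaly) /
           targets$d_qaly)^2
    }
    err
  }
  grid <- tidyr::expand_grid(meanlog = meanlog_grid, sdlog = sdlog_grid) |>
    dplyr::mutate(error = purrr::map2_dbl(.data$meanlog, .data$sdlog,
                                          objective))
  best <- grid |> dplyr::slice_min(.data$error, n = 1, with_ties = FALSE)
  out_params <- params
  out_params$nat_progression_lognormal <-
    list(meanlog = best$meanlog, sdlog = best$sdlog)
  list(meanlog = best$meanlog, sdlog = best$sdlog, error = best$error,
       params = out_params, grid = grid)
}
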