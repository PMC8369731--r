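#' Paired-arm cost-utility summary
#'
#' Collapses two cohort traces (intervention vs comparator, run on the same
#' parameters and life table) into the base-case economic summary: per-arm
#' discounted cost categories and totals, life years and QALYs, incremental
#' cost and QALYs, and the ICER (with dominance flags when the increments
#' disagree in sign).
#'
#' @param trace_intervention `cua_trace` for the stent + cataract arm.
#' @param trace_comparator `cua_trace` for the cataract-alone arm.
#' @return A `cua_cea` object; see [tidy.cua_cea()] and [glance.cua_cea()].
#' @export
summarize_cea <- function(trace_intervention, trace_comparator) {
  arms <- dplyr::bind_rows(
    trace_totals(trace_intervention),
    trace_totals(trace_comparator)
  )
  stopifnot(abs(arms$cost_total -
                  (arms$cost_procedures + arms$cost_medications +
                     arms$cost_progression + arms$cost_ae)) < 1e-6)
  d_cost <- arms$cost_total[1] - arms$cost_total[2]
  d_qaly <- arms$qaly[1] - arms$qaly[2]
  d_ly <- arms$ly[1] - arms$ly[2]
  if (d_qaly == 0) {
    icer <- NA_real_
    dominance <- if (d_cost == 0) "equivalent" else "undefined"
  } else if (d_qaly > 0 && d_cost <= 0) {
    icer <- d_cost / d_qaly
    dominance <- "dominant"
  } else if (d_qaly < 0 && d_cost >= 0) {
    icer <- d_cost / d_qaly
    dominance <- "dominated"
  } else {
    icer <- d_cost / d_qaly
    dominance <- "icer"
  }
  structure(
    list(arms = arms,
         incremental = list(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                            icer = icer, dominance = dominance)),
    class = "cua_cea"
  )
}

#' Run the full base case
#'
#' Convenience wrapper: runs both arms through [run_cohort()] and summarises
#' with [summarize_cea()]. The traces are attached as attributes.
#'
#' @param params A `cua_params` object.
#' @param lt A `cua_life_table`.
#' @return A `cua_cea` object with `trace_istent` / `trace_cataract`
#'   attributes.
#' @export
#' @examples
#' res <- run_cea(default_params(), generate_life_table())
#' glance(res)
run_cea <- function(params, lt) {
  tr_i <- run_cohort(params, lt, "istent")
  tr_c <- run_cohort(params, lt, "cataract")
  out <- summarize_cea(tr_i, tr_c)
  attr(out, "trace_istent") <- tr_i
  attr(out, "trace_cataract") <- tr_c
  out
}

#' Tidy a cost-utility result
#'
#' @param x A `cua_cea` object.
#' @param ... Unused.
#' @return A tibble, one row per arm, with cost categories, total cost,
#'   life years and QALYs.
#' @method tidy cua_cea
#' @export
tidy.cua_cea <- function(x, ...) {
  x$arms
}

#' One-row summary of a cost-utility result
#'
#' @param x A `cua_cea` object.
#' @param ... Unused.
#' @return One-row tibble with incremental cost, incremental QALYs,
#'   incremental life years, the ICER and its dominance flag.
#' @method glance cua_cea
#' @export
glance.cua_cea <- function(x, ...) {
  inc <- x$incremental
  tibble::tibble(d_cost = inc$d_cost, d_qaly = inc$d_qaly, d_ly = inc$d_ly,
                 icer = inc$icer, dominance = inc$dominance)
}

#' @export
print.cua_cea <- function(x, ...) {
  a <- x$arms
  cat("Cost-utility analysis (discounted, lifetime horizon)\n\n")
  lab <- c("stent + cataract surgery", "cataract surgery alone")
  for (i in 1:2) {
    cat(sprintf("%s:\n", lab[i]))
    cat(sprintf("  procedures %9.2f  medications %7.2f  progression %8.2f  AEs %6.2f\n",
                a$cost_procedures[i], a$cost_medications[i],
                a$cost_progression[i], a$cost_ae[i]))
    cat(sprintf("  total cost %9.2f EUR   LY %.3f   QALY %.3f\n",
                a$cost_total[i], a$ly[i], a$qaly[i]))
  }
  inc <- x$incremental
  cat(sprintf("\nincremental: cost %.2f EUR, QALY %.4f", inc$d_cost, inc$d_qaly))
  if (inc$dominance == "icer") {
    cat(sprintf(", ICER %.2f EUR/QALY\n", inc$icer))
  } else {
    cat(sprintf(" (%s)\n", inc$dominance))
  }
  invisible(x)
}
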