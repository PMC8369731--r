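#' Monthly disease-monitoring cost per severity state
#'
#' Sums, over ophthalmologist consultation, gonioscopy, visual-field test
#' and optic-disc imaging, the product of the state-specific monthly
#' incidence and the unit cost.
#'
#' @param state One of `"mild"`, `"moderate"`, `"advanced"`, `"severe"`;
#'   vectorised.
#' @param params A `cua_params` object.
#' @return Cost in EUR per patient-month.
#' @export
#' @examples
#' monthly_monitoring_cost("mild", default_params())
monthly_monitoring_cost <- function(state, params) {
  mon <- params$costs$monitoring
  uc <- unlist(mon$unit_costs)
  vapply(state, function(s) {
    s <- match.arg(s, .states)
    inc <- unlist(mon$incidence[[s]])
    sum(inc[names(uc)] * uc)
  }, numeric(1), USE.NAMES = !is.null(names(state)) || length(state) > 1)
}

#' Market-share-weighted monthly medication cost
#'
#' Dot product of the seven topical-therapy monthly prices with their
#' national market shares, the shares renormalised to exactly one (the
#' printed shares sum to 100.1%).
#'
#' @param params A `cua_params` object.
#' @return Cost in EUR per patient-month on one medication.
#' @export
weighted_medication_cost <- function(params) {
  med <- params$costs$medications
  total_share <- sum(med$share)
  if (total_share < 0.95 || total_share > 1.05) {
    abort("medication market shares must sum to 1 within 5%",
          class = "cua_validation_error")
  }
  sum(med$price * med$share) / total_share
}

#' One-time adverse-event cost per arm
#'
#' Hyperaemia and stent obstruction (the only events differing by at least
#' three percentage points between arms) costed as incidence times unit
#' cost; applied once, undiscounted, at cycle 0.
#'
#' @param arm `"istent"` or `"cataract"`.
#' @param params A `cua_params` object.
#' @return Cost in EUR.
#' @export
#' @examples
#' one_time_ae_cost("cataract", default_params())
one_time_ae_cost <- function(arm, params) {
  arm <- match.arg(arm, .arms)
  ae <- params$costs$adverse_events
  uc <- unlist(ae$unit_costs)
  inc <- unlist(ae$incidence[[arm]])
  sum(inc[names(uc)] * uc)
}

#' Per-cycle utility of a severity state with disutilities
#'
#' State utility (per year) minus the medication adverse-event decrement --
#' AE disutility times the weighted AE incidence times the fraction still
#' on medication -- minus the trabeculectomy decrement applied to the
#' fraction switching this cycle; floored at zero and scaled to one monthly
#' cycle.
#'
#' @param state Severity state name; vectorised with the fractions.
#' @param on_medication_fraction Proportion on topical medication, \[0, 1\].
#' @param trab_event_fraction Proportion undergoing trabeculectomy this
#'   cycle, \[0, 1\].
#' @param params A `cua_params` object.
#' @return Utility accrued over one month (utility-years per cycle).
#' @export
cycle_utility <- function(state, on_medication_fraction, trab_event_fraction,
                          params) {
  stopifnot(all(on_medication_fraction >= 0 & on_medication_fraction <= 1),
            all(trab_event_fraction >= 0 & trab_event_fraction <= 1))
  u <- params$utilities[state]
  du <- p_disutilities(params)
  annual <- u - du$med_ae * du$med_ae_incidence * on_medication_fraction -
    du$trab * trab_event_fraction
  pmax(annual, 0) / 12
}

p_disutilities <- function(params) {
  du <- params$disutilities
  list(trab = du$trabeculectomy, med_ae = du$medication_ae,
       med_ae_incidence = du$medication_ae_incidence)
}
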