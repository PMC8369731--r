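#' Cycle-indexed treatment schedule for one arm
#'
#' Expands the year-step IOP-reduction table into a per-month schedule:
#' the effective IOP reduction `delta_iop` is the year value for the model
#' year containing the cycle (months 1-12 use the year-1 value, and so on),
#' constant at the terminal "10+" value beyond year 10; the proportion still
#' on topical medication decays exponentially with the configured mean
#' time-to-discontinuation; `delta_iop_trab` is the IOP reduction that
#' replaces the arm effect after a switch to trabeculectomy.
#'
#' @param params A `cua_params` object.
#' @param arm `"istent"` (stent + cataract surgery) or `"cataract"`.
#' @param horizon_months Number of monthly cycles to cover (`>= 1`).
#' @return A tibble with columns `cycle`, `delta_iop`, `med_persistence`,
#'   `delta_iop_trab`, plus an `arm` attribute.
#' @export
#' @examples
#' sched <- build_iop_schedule(default_params(), "istent", 24)
#' sched[c(6, 13), ]
build_iop_schedule <- function(params, arm, horizon_months) {
  arm <- match.arg(arm, .arms)
  stopifnot(horizon_months >= 1)
  t <- seq_len(horizon_months)
  yr <- pmin(ceiling(t / 12), 11L)  # 11th entry is the "10+" plateau
  out <- tibble::tibble(
    cycle = t,
    delta_iop = params$iop_schedule[[arm]][yr],
    med_persistence = medication_persistence(t, params),
    delta_iop_trab = params$trabeculectomy_iop_reduction
  )
  attr(out, "arm") <- arm
  out
}

#' Visual-field decline rate under IOP lowering
#'
#' The untreated mean-deviation decline (dB/month) is reduced
#' multiplicatively by a fixed fraction per mmHg of IOP reduction:
#' `decline = untreated * (1 - reduction_per_mmhg)^delta_iop`. The
#' multiplicative form keeps the decline strictly positive at any
#' achievable IOP reduction.
#'
#' @param delta_iop Effective IOP reduction (mmHg), `>= 0`; vectorised.
#' @param params A `cua_params` object.
#' @return Decline in dB per month (positive, monotone decreasing in
#'   `delta_iop`).
#' @export
vf_decline_rate <- function(delta_iop, params) {
  if (any(delta_iop < 0)) {
    abort("delta_iop must be >= 0", class = "cua_validation_error")
  }
  params$untreated_vf_decline *
    (1 - params$decline_reduction_per_mmhg)^delta_iop
}

#' Monthly probability of crossing into the next severity band
#'
#' Assuming mean-deviation values uniformly distributed within the current
#' band, a cohort losing `decline` dB per month moves a fraction
#' `decline / band_width` of its mass across the band boundary each month
#' (capped at 1).
#'
#' @param decline VF decline in dB/month, `>= 0`; vectorised.
#' @param band_width Width of the current severity band in dB, `> 0`.
#' @return Transition probability in \[0, 1\].
#' @export
severity_transition_prob <- function(decline, band_width) {
  if (any(band_width <= 0)) {
    abort("band_width must be > 0", class = "cua_validation_error")
  }
  if (any(decline < 0)) {
    abort("decline must be >= 0", class = "cua_validation_error")
  }
  pmin(1, decline / band_width)
}

#' Per-cycle probability of switching to trabeculectomy
#'
#' Time to disease progression severe enough to need filtering surgery
#' follows a lognormal distribution untreated; IOP lowering acts through
#' proportional hazards, `S(t) = S0(t)^(HR^delta_iop)` with HR the
#' per-mmHg hazard ratio. The switch probability at cycle `t` is the
#' discrete conditional probability `(S(t-1) - S(t)) / S(t-1)`, taken as 1
#' once `S(t-1)` has vanished.
#'
#' @param cycle Month index, `>= 1`; vectorised.
#' @param delta_iop Effective IOP reduction (mmHg) during that cycle;
#'   scalar or same length as `cycle`.
#' @param params A `cua_params` object (lognormal location/scale and hazard
#'   ratio are read from it).
#' @return Probability in \[0, 1\], decreasing in `delta_iop` at fixed `t`.
#' @export
trabeculectomy_switch_prob <- function(cycle, delta_iop, params) {
  stopifnot(all(cycle >= 1))
  ln <- params$nat_progression_lognormal
  k <- params$progression_hr_per_mmhg^delta_iop
  s_prev <- (1 - plnorm(cycle - 1, ln$meanlog, ln$sdlog))^k
  s_now <- (1 - plnorm(cycle, ln$meanlog, ln$sdlog))^k
  ifelse(s_prev <= 0, 1, pmin(1, pmax(0, (s_prev - s_now) / s_prev)))
}

#' IOP reduction after trabeculectomy
#'
#' The post-switch IOP reduction that replaces the arm's effect from the
#' switch cycle onward; switched patients face no further switching.
#'
#' @param params A `cua_params` object.
#' @return IOP reduction in mmHg.
#' @export
trabeculectomy_effect <- function(params) {
  params$trabeculectomy_iop_reduction
}

#' Proportion still on topical medication
#'
#' Exponential persistence with the configured mean time-to-discontinuation
#' (months): `exp(-cycle / mean_time)`. Weights medication costs and the
#' medication adverse-event disutility; the IOP consequence of
#' discontinuation is already embedded in the arm schedules.
#'
#' @param cycle Month index, `>= 0`; vectorised.
#' @param params A `cua_params` object.
#' @return Proportion in (0, 1\].
#' @export
medication_persistence <- function(cycle, params) {
  stopifnot(all(cycle >= 0))
  exp(-cycle / params$discontinuation_mean_time)
}
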