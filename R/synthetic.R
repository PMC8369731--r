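#' Seeded random perturbations of a parameter set
#'
#' Test fixture generator for the sensitivity machinery and the engine's
#' property checks: multiplies each scalar model input (utilities,
#' disutilities, unit costs, clinical effect sizes, and each arm's IOP
#' schedule as a block) by an independent uniform factor in
#' `[1 - width, 1 + width]`, clipping probabilities and utilities back to
#' \[0, 1\] so every draw passes validation.
#'
#' @param base A `cua_params` object.
#' @param relative_width Fraction in (0, 1); `0` returns copies of `base`.
#' @param seed Integer seed; same seed, same sequence.
#' @param n Number of perturbed parameter sets.
#' @return A list of `n` validated `cua_params` objects.
#' @export
generate_param_perturbations <- function(base, relative_width, seed, n = 1) {
  stopifnot(relative_width >= 0, relative_width < 1, n >= 1)
  set.seed(seed)
  fac <- function() runif(1, 1 - relative_width, 1 + relative_width)
  clip01 <- function(x) min(max(x, 0), 1)
  purrr::map(seq_len(n), function(i) {
    p <- base
    for (s in .states) p$utilities[[s]] <- clip01(p$utilities[[s]] * fac())
    p$disutilities <- lapply(p$disutilities, function(x) clip01(x * fac()))
    p$untreated_vf_decline <- p$untreated_vf_decline * fac()
    p$decline_reduction_per_mmhg <-
      min(p$decline_reduction_per_mmhg * fac(), 0.999)
    p$progression_hr_per_mmhg <- p$progression_hr_per_mmhg * fac()
    p$trabeculectomy_iop_reduction <- p$trabeculectomy_iop_reduction * fac()
    p$discontinuation_mean_time <- p$discontinuation_mean_time * fac()
    p$nat_progression_lognormal$meanlog <-
      p$nat_progression_lognormal$meanlog * fac()
    p$nat_progression_lognormal$sdlog <-
      p$nat_progression_lognormal$sdlog * fac()
    for (arm in .arms) {
      p$iop_schedule[[arm]] <- p$iop_schedule[[arm]] * fac()
      p$costs$procedure[[arm]] <- p$costs$procedure[[arm]] * fac()
      p$costs$medication_factor[[arm]] <-
        p$costs$medication_factor[[arm]] * fac()
    }
    p$costs$trabeculectomy <- p$costs$trabeculectomy * fac()
    p$costs$medications$price <-
      p$costs$medications$price * vapply(seq_len(nrow(p$costs$medications)),
                                         function(j) fac(), numeric(1))
    p$costs$monitoring$unit_costs <-
      lapply(p$costs$monitoring$unit_costs, function(x) x * fac())
    p$costs$adverse_events$unit_costs <-
      lapply(p$costs$adverse_events$unit_costs, function(x) x * fac())
    p$costs$adverse_events$incidence <-
      lapply(p$costs$adverse_events$incidence,
             function(a) lapply(a, function(x) clip01(x * fac())))
    validate_params(p)
    p
  })
}
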