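#' Parameter registry for the sensitivity analyses
#'
#' Enumerates every parameter varied in the one-way deterministic and
#' probabilistic sensitivity analyses, with its base value, low/high bounds
#' (95% CI where one exists -- the two disutilities -- else a relative
#' variation: the configured default width, and a narrower trial-precision
#' width for the IOP-reduction schedules), its PSA distribution family
#' (beta for utilities/probabilities, gamma for costs, truncated normal for
#' efficacy), and a setter that writes a value back into a parameter object.
#' State utilities are varied through their decrement from full health so
#' the severity ordering is preserved at the bounds.
#'
#' @param params A `cua_params` object.
#' @return A tibble with columns `parameter`, `family`, `base`, `low`,
#'   `high`, `sd` and a list-column `set` of functions
#'   `(params, value) -> params`.
#' @export
cua_parameter_set <- function(params) {
  w <- params$dsa_settings$default_rel_width
  w_iop <- params$dsa_settings$iop_rel_width
  rows <- list()
  add <- function(parameter, family, base, low, high, set) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      parameter = parameter, family = family, base = base,
      low = low, high = high, sd = (high - low) / (2 * 1.96),
      set = list(set))
  }

  for (s in .states) {
    u <- params$utilities[[s]]
    add(paste0("utility_", s), "beta", u,
        1 - (1 - u) * (1 + w), 1 - (1 - u) * (1 - w),
        local({
          s0 <- s
          function(p, v) { p$utilities[[s0]] <- min(max(v, 0), 1); p }
        }))
  }

  add("disutility_trabeculectomy", "beta",
      params$disutilities$trabeculectomy, 0.005, 0.009,
      function(p, v) { p$disutilities$trabeculectomy <- min(max(v, 0), 1); p })
  add("disutility_medication_ae", "beta",
      params$disutilities$medication_ae, 0.076, 0.126,
      function(p, v) { p$disutilities$medication_ae <- min(max(v, 0), 1); p })
  add("medication_ae_incidence", "beta",
      params$disutilities$medication_ae_incidence,
      params$disutilities$medication_ae_incidence * (1 - w),
      params$disutilities$medication_ae_incidence * (1 + w),
      function(p, v) {
        p$disutilities$medication_ae_incidence <- min(max(v, 0), 1); p
      })

  scalar <- function(field, family = "normal", lower = 0, upper = Inf) {
    base <- params[[field]]
    add(field, family, base, base * (1 - w), base * (1 + w),
        local({
          f <- field; lo <- lower; up <- upper
          function(p, v) { p[[f]] <- min(max(v, lo), up); p }
        }))
  }
  scalar("untreated_vf_decline")
  scalar("decline_reduction_per_mmhg", upper = 0.999)
  scalar("progression_hr_per_mmhg", lower = 1e-6)
  scalar("trabeculectomy_iop_reduction")
  scalar("discontinuation_mean_time", lower = 1e-6)

  for (arm in .arms) {
    add(paste0("iop_reduction_", arm), "normal", 1, 1 - w_iop, 1 + w_iop,
        local({
          a <- arm
          function(p, v) {
            p$iop_schedule[[a]] <- p$iop_schedule[[a]] * max(v, 0); p
          }
        }))
  }

  for (arm in .arms) {
    add(paste0("cost_procedure_", arm), "gamma",
        params$costs$procedure[[arm]],
        params$costs$procedure[[arm]] * (1 - w),
        params$costs$procedure[[arm]] * (1 + w),
        local({
          a <- arm
          function(p, v) { p$costs$procedure[[a]] <- max(v, 0); p }
        }))
  }
  add("cost_trabeculectomy", "gamma", params$costs$trabeculectomy,
      params$costs$trabeculectomy * (1 - w),
      params$costs$trabeculectomy * (1 + w),
      function(p, v) { p$costs$trabeculectomy <- max(v, 0); p })
  add("cost_medications", "gamma", 1, 1 - w, 1 + w,
      function(p, v) { p$costs$medications$price <-
        p$costs$medications$price * max(v, 0); p })
  add("cost_monitoring", "gamma", 1, 1 - w, 1 + w,
      function(p, v) {
        p$costs$monitoring$unit_costs <-
          lapply(p$costs$monitoring$unit_costs, function(x) x * max(v, 0)); p
      })
  add("cost_adverse_events", "gamma", 1, 1 - w, 1 + w,
      function(p, v) {
        p$costs$adverse_events$unit_costs <-
          lapply(p$costs$adverse_events$unit_costs, function(x) x * max(v, 0)); p
      })

  dplyr::bind_rows(rows)
}

set_cua_parameter <- function(params, registry, parameter, value) {
  i <- match(parameter, registry$parameter)
  if (is.na(i)) abort(paste0("unknown parameter: ", parameter))
  p <- registry$set[[i]](params, value)
  validate_params(p)
  p
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the paired-arm model once per bound per registry parameter,
#' everything else held at base, and reports the ICER at each bound and the
#' spread between them, sorted descending. A bound that produces an invalid
#' parameter set is flagged, not silently dropped.
#'
#' @param params A `cua_params` object (the base case).
#' @param lt A `cua_life_table`.
#' @param registry Optional parameter registry; defaults to
#'   [cua_parameter_set()].
#' @return A `cua_dsa` tibble with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, `flagged`; the base-case ICER is in
#'   the `base_icer` attribute.
#' @export
run_dsa <- function(params, lt, registry = cua_parameter_set(params)) {
  base <- glance(run_cea(params, lt))
  icer_at <- function(parameter, value) {
    tryCatch({
      p <- set_cua_parameter(params, registry, parameter, value)
      glance(run_cea(p, lt))$icer
    }, cua_validation_error = function(e) NA_real_)
  }
  out <- registry |>
    dplyr::select("parameter", "low", "high") |>
    dplyr::mutate(
      icer_low = purrr::map2_dbl(.data$parameter, .data$low, icer_at),
      icer_high = purrr::map2_dbl(.data$parameter, .data$high, icer_at),
      spread = abs(.data$icer_high - .data$icer_low),
      flagged = is.na(.data$icer_low) | is.na(.data$icer_high)
    ) |>
    dplyr::arrange(dplyr::desc(.data$spread))
  structure(out, class = c("cua_dsa", class(out)), base_icer = base$icer)
}

#' @method tidy cua_dsa
#' @export
tidy.cua_dsa <- function(x, ...) {
  tibble::as_tibble(x)
}

draw_psa_value <- function(family, mean, sd) {
  if (sd == 0) return(mean)
  switch(family,
    beta = {
      v <- sd^2
      if (v >= mean * (1 - mean) || mean <= 0 || mean >= 1) {
        warn("beta method-of-moments infeasible; falling back to clamped normal")
        min(max(rnorm(1, mean, sd), 0), 1)
      } else {
        nu <- mean * (1 - mean) / v - 1
        rbeta(1, mean * nu, (1 - mean) * nu)
      }
    },
    gamma = {
      if (mean <= 0) return(mean)
      rgamma(1, shape = mean^2 / sd^2, scale = sd^2 / mean)
    },
    normal = max(rnorm(1, mean, sd), 0)
  )
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Samples every registry parameter from its tagged distribution -- beta by
#' method of moments on (mean, SD) for \[0, 1\] quantities, gamma
#' (shape/scale from mean and SD) for costs, normal truncated at zero for
#' efficacy -- and applies the draws to the base parameters. SDs derive
#' from the 95% CI width where one exists, else from the relative DSA
#' width. Infeasible beta moments fall back to a clamped normal with a
#' warning.
#'
#' @param params Base `cua_params`.
#' @param seed Optional integer seed (omit when drawing inside a seeded
#'   loop).
#' @param registry Optional registry from [cua_parameter_set()].
#' @return A validated `cua_params` draw.
#' @export
sample_psa_params <- function(params, seed = NULL,
                              registry = cua_parameter_set(params)) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  for (i in seq_len(nrow(registry))) {
    v <- draw_psa_value(registry$family[i], registry$base[i], registry$sd[i])
    p <- registry$set[[i]](p, v)
  }
  validate_params(p)
  p
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_reps` paired-arm evaluations on jointly sampled parameter sets
#' (the life table is held fixed) and derives the cost-effectiveness
#' acceptability curve: for each willingness-to-pay value on the grid, the
#' fraction of replications with positive net monetary benefit
#' `wtp * dQALY - dcost`.
#'
#' @param params Base `cua_params`.
#' @param lt A `cua_life_table`.
#' @param n_reps Number of replications, `>= 1` (base-case analysis uses
#'   1000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param wtp_grid Willingness-to-pay grid in EUR/QALY.
#' @return A `cua_psa` object: `$reps` (per-replication increments),
#'   `$ceac` (tibble `wtp`, `prob_cost_effective`), `$n_reps`, `$seed`.
#' @export
run_psa <- function(params, lt, n_reps = params$psa_settings$n_reps,
                    seed = params$psa_settings$seed,
                    wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  registry <- cua_parameter_set(params)
  reps <- purrr::map_dfr(seq_len(n_reps), function(rep) {
    p <- sample_psa_params(params, registry = registry)
    g <- glance(run_cea(p, lt))
    tibble::tibble(rep = rep, d_cost = g$d_cost, d_qaly = g$d_qaly)
  })
  out <- structure(
    list(reps = reps, ceac = ceac(reps, wtp_grid),
         n_reps = n_reps, seed = seed),
    class = "cua_psa")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' @param reps A `cua_psa` object or a tibble with `d_cost` and `d_qaly`.
#' @param wtp_grid Willingness-to-pay grid in EUR/QALY.
#' @return Tibble with `wtp` and `prob_cost_effective` in \[0, 1\].
#' @export
ceac <- function(reps, wtp_grid = seq(0, 100000, by = 1000)) {
  if (inherits(reps, "cua_psa")) reps <- reps$reps
  tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid,
      function(l) mean(l * reps$d_qaly - reps$d_cost > 0),
      numeric(1))
  )
}

#' @method tidy cua_psa
#' @export
tidy.cua_psa <- function(x, ...) {
  x$reps
}

#' One-row PSA summary
#'
#' @param x A `cua_psa` object.
#' @param ... Unused.
#' @return Tibble with mean increments, their Monte-Carlo standard errors,
#'   and the probability of cost-effectiveness at 50,000 EUR/QALY.
#' @method glance cua_psa
#' @export
glance.cua_psa <- function(x, ...) {
  r <- x$reps
  tibble::tibble(
    n_reps = x$n_reps,
    mean_d_cost = mean(r$d_cost),
    se_d_cost = stats::sd(r$d_cost) / sqrt(nrow(r)),
    mean_d_qaly = mean(r$d_qaly),
    se_d_qaly = stats::sd(r$d_qaly) / sqrt(nrow(r)),
    prob_ce_50k = mean(50000 * r$d_qaly - r$d_cost > 0)
  )
}

#' @export
print.cua_psa <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("PSA: %d replications (seed %s)\n", x$n_reps, format(x$seed)))
  cat(sprintf("  mean increments: cost %.2f EUR, QALY %.4f\n",
              g$mean_d_cost, g$mean_d_qaly))
  cat(sprintf("  P(cost-effective at 50k EUR/QALY) = %.1f%%\n",
              100 * g$prob_ce_50k))
  invisible(x)
}
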