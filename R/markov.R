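# Stratum layout used throughout the engine: the four severity states before
# trabeculectomy, the four after, then dead.
.strata <- c(paste0(.states, "_pre"), paste0(.states, "_post"), "dead")

# Precompute every per-cycle probability and weight the engine needs for one
# arm: death, severity progression (pre/post switch), switch hazard,
# medication persistence and discount factors.
cycle_inputs <- function(params, lt, arm, horizon = NULL) {
  arm <- match.arg(arm, .arms)
  end_age <- min(params$max_age, lt$age[nrow(lt)] + 1)
  if (is.null(horizon)) {
    horizon <- max(1L, ceiling((end_age - params$cohort_start_age) * 12))
  }
  sched <- build_iop_schedule(params, arm, horizon)
  t <- sched$cycle
  age <- params$cohort_start_age + (t - 1) / 12
  decline_pre <- vf_decline_rate(sched$delta_iop, params)
  decline_post <- vf_decline_rate(params$trabeculectomy_iop_reduction, params)
  bw <- params$band_widths
  list(
    horizon = horizon,
    age = age,
    pd = monthly_death_prob_clamped(lt, age),
    # progression probabilities out of mild/moderate/advanced (severe is terminal)
    pp_pre = rbind(
      severity_transition_prob(decline_pre, bw[["mild"]]),
      severity_transition_prob(decline_pre, bw[["moderate"]]),
      severity_transition_prob(decline_pre, bw[["advanced"]])
    ),
    pp_post = c(
      severity_transition_prob(decline_post, bw[["mild"]]),
      severity_transition_prob(decline_post, bw[["moderate"]]),
      severity_transition_prob(decline_post, bw[["advanced"]])
    ),
    psw = trabeculectomy_switch_prob(t, sched$delta_iop, params),
    m = sched$med_persistence,
    df_c = (1 + params$discount_rate_costs)^(-t / 12),
    df_e = (1 + params$discount_rate_effects)^(-t / 12)
  )
}

#' Single-cycle transition matrix over model strata
#'
#' Builds the row-stochastic transition matrix for one monthly cycle of one
#' arm, over the nine strata (four severity states before trabeculectomy,
#' four after, and dead). Competing risks are composed conditionally, in
#' order: death (possible from every state), then severity progression among
#' survivors, then switch to trabeculectomy among surviving
#' non-progressors (pre-switch mild to advanced states only). A cycle can
#' therefore move a patient at most one severity state, and never backward.
#'
#' @param params A `cua_params` object.
#' @param lt A `cua_life_table`.
#' @param arm `"istent"` or `"cataract"`.
#' @param cycle Month index, `>= 1`.
#' @return A 9 x 9 row-stochastic matrix with dimnames over the strata.
#' @export
build_transition_matrix <- function(params, lt, arm, cycle) {
  stopifnot(cycle >= 1)
  ci <- cycle_inputs(params, lt, arm, horizon = cycle)
  pd <- ci$pd[cycle]
  pp_pre <- ci$pp_pre[, cycle]
  pp_post <- ci$pp_post
  psw <- ci$psw[cycle]

  M <- matrix(0, 9, 9, dimnames = list(.strata, .strata))
  M["dead", "dead"] <- 1
  for (s in 1:4) {
    pre <- s
    post <- s + 4
    M[pre, "dead"] <- pd
    M[post, "dead"] <- pd
    if (s < 4) {
      M[pre, pre + 1] <- (1 - pd) * pp_pre[s]               # progress
      M[pre, post] <- (1 - pd) * (1 - pp_pre[s]) * psw      # switch
      M[post, post + 1] <- (1 - pd) * pp_post[s]
    }
    M[pre, pre] <- 1 - sum(M[pre, -pre])
    M[post, post] <- 1 - sum(M[post, -post])
  }
  bad <- abs(rowSums(M) - 1) > 1e-10
  if (any(bad) || any(M < -1e-12)) {
    abort("internal error: transition matrix rows must be stochastic",
          class = "cua_internal_error")
  }
  M
}

#' Run the monthly-cycle cohort simulation for one arm
#'
#' Evolves the cohort from its initial severity split (all pre-switch) until
#' the cohort reaches the maximum age or living mass is exhausted, accruing
#' per cycle: discounted life years, discounted QALYs (state utilities minus
#' medication-AE and trabeculectomy disutilities), and discounted costs by
#' category. The index procedure and one-time adverse-event costs enter at
#' cycle 0 undiscounted; the trabeculectomy procedure cost and disutility
#' attach to the switching mass at the switch cycle.
#'
#' @param params A `cua_params` object.
#' @param lt A `cua_life_table`.
#' @param arm `"istent"` or `"cataract"`.
#' @param horizon Optional number of cycles; defaults to the months from the
#'   start age to `max_age` (or the end of the life table).
#' @return A `cua_trace` tibble, one row per cycle (row one is cycle 0),
#'   with stratum occupancies, deaths and trabeculectomy events, and
#'   discounted `ly`, `qaly` and cost-by-category increments.
#' @export
#' @examples
#' lt <- generate_life_table()
#' tr <- run_cohort(default_params(), lt, "istent")
#' sum(tr$qaly)
run_cohort <- function(params, lt, arm, horizon = NULL) {
  arm <- match.arg(arm, .arms)
  ci <- cycle_inputs(params, lt, arm, horizon)
  horizon <- ci$horizon
  half_cycle <- isTRUE(params$half_cycle_correction)

  u <- params$utilities
  du <- p_disutilities(params)
  mon <- monthly_monitoring_cost(.states, params)
  wmed <- weighted_medication_cost(params) *
    params$costs$medication_factor[[arm]]
  trab_cost <- params$costs$trabeculectomy

  x_pre <- as.numeric(params$initial_state_split)
  x_post <- numeric(4)
  dead <- 0

  n_out <- horizon + 1
  occ <- matrix(0, n_out, 9, dimnames = list(NULL, .strata))
  occ[1, 1:4] <- x_pre
  acc <- matrix(0, n_out, 8, dimnames = list(NULL, c(
    "deaths", "trab_events", "ly", "qaly",
    "cost_procedures", "cost_medications", "cost_progression", "cost_ae")))
  acc[1, "cost_procedures"] <- params$costs$procedure[[arm]]
  acc[1, "cost_ae"] <- one_time_ae_cost(arm, params)

  last <- 1
  for (t in seq_len(horizon)) {
    pd <- ci$pd[t]
    pp_pre <- ci$pp_pre[, t]
    psw <- ci$psw[t]

    d <- (sum(x_pre) + sum(x_post)) * pd
    s_pre <- x_pre * (1 - pd)
    s_post <- x_post * (1 - pd)
    prog_pre <- c(s_pre[1:3] * pp_pre, 0)
    sw <- c((s_pre[1:3] - prog_pre[1:3]) * psw, 0)
    prog_post <- c(s_post[1:3] * ci$pp_post, 0)

    x_pre_new <- s_pre - prog_pre - sw + c(0, prog_pre[1:3])
    x_post_new <- s_post - prog_post + c(0, prog_post[1:3]) + sw
    trab_t <- sum(sw)
    dead <- dead + d

    # accrual weights: end-of-cycle occupancy, or the start/end average
    # under the optional half-cycle correction
    w_pre <- if (half_cycle) (x_pre + x_pre_new) / 2 else x_pre_new
    w_post <- if (half_cycle) (x_post + x_post_new) / 2 else x_post_new
    w_state <- w_pre + w_post
    alive <- sum(w_state)

    df_e <- ci$df_e[t]
    df_c <- ci$df_c[t]
    util <- sum(w_state * u) -
      alive * du$med_ae * du$med_ae_incidence * ci$m[t] -
      du$trab * trab_t
    acc[t + 1, ] <- c(
      d, trab_t,
      alive / 12 * df_e,
      max(util, 0) / 12 * df_e,
      trab_t * trab_cost * df_c,
      alive * wmed * ci$m[t] * df_c,
      sum(w_state * mon) * df_c,
      0
    )
    x_pre <- x_pre_new
    x_post <- x_post_new
    occ[t + 1, ] <- c(x_pre, x_post, dead)
    last <- t + 1
    if (sum(x_pre) + sum(x_post) < 1e-9) break
  }

  keep <- seq_len(last)
  out <- tibble::tibble(
    cycle = keep - 1L,
    age = params$cohort_start_age + (keep - 1) / 12
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(occ[keep, , drop = FALSE]),
                          tibble::as_tibble(acc[keep, , drop = FALSE]))
  structure(out, class = c("cua_trace", class(out)),
            arm = arm, half_cycle = half_cycle)
}

#' Arm totals from a cohort trace
#'
#' @param trace A `cua_trace`.
#' @return One-row tibble with discounted cost categories, total cost,
#'   life years, QALYs and total trabeculectomy events.
#' @export
trace_totals <- function(trace) {
  tibble::tibble(
    arm = attr(trace, "arm") %||% NA_character_,
    cost_procedures = sum(trace$cost_procedures),
    cost_medications = sum(trace$cost_medications),
    cost_progression = sum(trace$cost_progression),
    cost_ae = sum(trace$cost_ae),
    cost_total = cost_procedures + cost_medications +
      cost_progression + cost_ae,
    ly = sum(trace$ly),
    qaly = sum(trace$qaly),
    trab_events = sum(trace$trab_events)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Individual-level microsimulation of one arm
#'
#' Monte-Carlo validation oracle for [run_cohort()]: simulates `n_patients`
#' one at a time (vectorised) through exactly the same per-cycle
#' probabilities and accrual rules as the cohort engine, and reports mean
#' discounted outcomes with standard errors.
#'
#' @param params A `cua_params` object.
#' @param lt A `cua_life_table`.
#' @param arm `"istent"` or `"cataract"`.
#' @param n_patients Number of simulated patients, `>= 1`.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A list with `n`, and mean/standard-error pairs for `ly`, `qaly`
#'   and `cost_total`, plus mean cost categories.
#' @export
microsimulate <- function(params, lt, arm, n_patients, seed = 1L) {
  arm <- match.arg(arm, .arms)
  stopifnot(n_patients >= 1)
  set.seed(seed)
  ci <- cycle_inputs(params, lt, arm)
  u <- params$utilities
  du <- p_disutilities(params)
  mon <- monthly_monitoring_cost(.states, params)
  wmed <- weighted_medication_cost(params) *
    params$costs$medication_factor[[arm]]
  trab_cost <- params$costs$trabeculectomy

  n <- n_patients
  state <- sample.int(4, n, replace = TRUE,
                      prob = as.numeric(params$initial_state_split))
  post <- logical(n)
  alive <- rep(TRUE, n)
  ly_i <- numeric(n)
  qaly_i <- numeric(n)
  cost_i <- rep(params$costs$procedure[[arm]] + one_time_ae_cost(arm, params), n)
  cost_cat <- c(procedures = params$costs$procedure[[arm]],
                medications = 0, progression = 0,
                ae = one_time_ae_cost(arm, params)) * n

  for (t in seq_len(ci$horizon)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    k <- length(idx)
    dies <- runif(k) < ci$pd[t]
    alive[idx[dies]] <- FALSE
    idx <- idx[!dies]
    if (length(idx) == 0) next
    st <- state[idx]
    po <- post[idx]
    can_prog <- st < 4
    pp <- ifelse(po, ci$pp_post[pmin(st, 3)], ci$pp_pre[pmin(st, 3), t])
    progresses <- can_prog & (runif(length(idx)) < pp)
    switches <- !po & can_prog & !progresses & (runif(length(idx)) < ci$psw[t])
    state[idx[progresses]] <- st[progresses] + 1L
    post[idx[switches]] <- TRUE

    st_new <- state[idx]
    df_e <- ci$df_e[t]
    df_c <- ci$df_c[t]
    ly_i[idx] <- ly_i[idx] + df_e / 12
    util <- u[st_new] - du$med_ae * du$med_ae_incidence * ci$m[t] -
      du$trab * switches
    qaly_i[idx] <- qaly_i[idx] + pmax(util, 0) / 12 * df_e
    c_mon <- mon[st_new] * df_c
    c_med <- wmed * ci$m[t] * df_c
    c_trab <- trab_cost * df_c * switches
    cost_i[idx] <- cost_i[idx] + c_mon + c_med + c_trab
    cost_cat["progression"] <- cost_cat["progression"] + sum(c_mon)
    cost_cat["medications"] <- cost_cat["medications"] + c_med * length(idx)
    cost_cat["procedures"] <- cost_cat["procedures"] + sum(c_trab)
  }

  list(
    n = n,
    ly = mean(ly_i), ly_se = stats::sd(ly_i) / sqrt(n),
    qaly = mean(qaly_i), qaly_se = stats::sd(qaly_i) / sqrt(n),
    cost_total = mean(cost_i), cost_se = stats::sd(cost_i) / sqrt(n),
    cost_by_category = cost_cat / n
  )
}
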