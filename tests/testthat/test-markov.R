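test_that("transition matrix is row-stochastic with the required zero pattern", {
  p <- base_params()
  lt <- base_lt()
  M <- build_transition_matrix(p, lt, "istent", 1)
  expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
  expect_true(all(M >= 0))
  # no state-skipping and no backward flow from the mild pre-switch row:
  # mass may only stay, progress one state, switch, or die
  allowed <- c("mild_pre", "moderate_pre", "mild_post", "dead")
  expect_true(all(M["mild_pre", setdiff(colnames(M), allowed)] == 0))
  # severe patients can no longer progress or switch
  expect_true(all(M["severe_pre", c("severe_post", "dead")] >= 0))
  expect_equal(sum(M["severe_pre", c("severe_pre", "dead")]), 1)
  # post-switch strata never switch again
  expect_equal(unname(M["mild_post", "mild_pre"]), 0)
})

test_that("mild-state row composes death, progression and switch conditionally", {
  p <- base_params()
  lt <- base_lt()
  M <- build_transition_matrix(p, lt, "istent", 1)
  pd <- monthly_death_prob(lt, p$cohort_start_age)
  pp <- severity_transition_prob(
    vf_decline_rate(p$iop_schedule$istent[1], p), p$band_widths[["mild"]])
  psw <- trabeculectomy_switch_prob(1, p$iop_schedule$istent[1], p)
  expect_equal(unname(M["mild_pre", "dead"]), pd)
  expect_equal(unname(M["mild_pre", "moderate_pre"]), (1 - pd) * pp)
  expect_equal(unname(M["mild_pre", "mild_post"]), (1 - pd) * (1 - pp) * psw)
  expect_equal(unname(M["mild_pre", "mild_pre"]),
               (1 - pd) * (1 - pp) * (1 - psw))
})

test_that("all hazards zero gives the identity; certain death empties all rows", {
  p <- inert_params()
  lt0 <- flat_lt(0)
  M <- build_transition_matrix(p, lt0, "istent", 1)
  expect_equal(unname(M), diag(9), tolerance = 1e-12)

  lt1 <- flat_lt(1)
  M1 <- build_transition_matrix(base_params(), lt1, "istent", 1)
  expect_equal(unname(M1[, "dead"]), rep(1, 9))
})

test_that("the cohort trace advances by the transition matrix", {
  p <- base_params()
  lt <- base_lt()
  tr <- run_cohort(p, lt, "cataract", horizon = 36)
  occ <- as.matrix(tr[, strata_cols()])
  for (t in c(1, 13, 30)) {
    M <- build_transition_matrix(p, lt, "cataract", t)
    expect_equal(occ[t + 1, ], drop(occ[t, ] %*% M), tolerance = 1e-12)
  }
})

test_that("trace conserves mass and never flows backward (randomized configs)", {
  perturbed <- generate_param_perturbations(base_params(), 0.3,
                                            seed = 2024, n = 20)
  lt <- base_lt()
  for (p in perturbed[1:10]) {
    expect_valid_trace(run_cohort(p, lt, "istent"))
  }
  for (p in perturbed[11:20]) {
    expect_valid_trace(run_cohort(p, lt, "cataract"))
  }
})

test_that("undiscounted immortal cohort accrues exactly one life year in 12 cycles", {
  p <- inert_params()
  p$discount_rate_costs <- 0
  p$discount_rate_effects <- 0
  tr <- run_cohort(p, flat_lt(0), "istent", horizon = 12)
  expect_equal(sum(tr$ly), 1)
})

test_that("identical arm schedules give identical traces", {
  p <- base_params()
  p$iop_schedule$cataract <- p$iop_schedule$istent
  p$costs$medication_factor$cataract <- p$costs$medication_factor$istent
  p$costs$adverse_events$incidence$cataract <-
    p$costs$adverse_events$incidence$istent
  p$costs$procedure$cataract <- p$costs$procedure$istent
  lt <- base_lt()
  tr_i <- run_cohort(p, lt, "istent")
  tr_c <- run_cohort(p, lt, "cataract")
  expect_identical(tr_i$qaly, tr_c$qaly)
  expect_identical(tr_i$cost_procedures, tr_c$cost_procedures)
  expect_identical(as.matrix(tr_i[, strata_cols()]),
                   as.matrix(tr_c[, strata_cols()]))
})

test_that("constant mortality reproduces the closed-form discounted life years", {
  q <- 0.04
  p <- inert_params()
  tr <- run_cohort(p, flat_lt(q), "istent")
  qm <- 1 - (1 - q)^(1 / 12)
  t <- seq_len(nrow(tr) - 1)
  closed_form <- sum((1 - qm)^t * 1.035^(-t / 12)) / 12
  expect_equal(sum(tr$ly), closed_form, tolerance = 1e-8)
})

test_that("discounting and utility weighting only shrink accruals", {
  p <- base_params()
  lt <- base_lt()
  tot <- trace_totals(run_cohort(p, lt, "istent"))
  p0 <- p
  p0$discount_rate_costs <- 0
  p0$discount_rate_effects <- 0
  tot0 <- trace_totals(run_cohort(p0, lt, "istent"))
  expect_lt(tot$ly, tot0$ly)
  expect_lt(tot$cost_total, tot0$cost_total)
  expect_lt(tot$qaly, tot$ly)   # utilities are below 1
})

test_that("monotonicity: utilities and IOP reduction act in the right direction", {
  p <- base_params()
  lt <- base_lt()
  base <- trace_totals(run_cohort(p, lt, "istent"))

  up <- p
  up$utilities[["moderate"]] <- min(1, p$utilities[["moderate"]] + 0.05)
  expect_gt(trace_totals(run_cohort(up, lt, "istent"))$qaly, base$qaly)

  more_iop <- p
  more_iop$iop_schedule$istent <- p$iop_schedule$istent * 1.25
  boosted <- trace_totals(run_cohort(more_iop, lt, "istent"))
  expect_gt(boosted$qaly, base$qaly)
  expect_lt(boosted$trab_events, base$trab_events)
})

test_that("half-cycle correction changes accruals only modestly and conserves mass", {
  p <- base_params()
  p$half_cycle_correction <- TRUE
  lt <- base_lt()
  tr <- expect_valid_trace(run_cohort(p, lt, "istent"))
  plain <- run_cohort(base_params(), lt, "istent")
  expect_gt(sum(tr$ly), sum(plain$ly))  # start-of-cycle mass is larger
  expect_lt(abs(sum(tr$ly) - sum(plain$ly)) / sum(plain$ly), 0.02)
})

test_that("microsimulation is seed-reproducible and agrees with the cohort engine", {
  p <- base_params()
  lt <- base_lt()
  ms1 <- microsimulate(p, lt, "cataract", 2000, seed = 11)
  ms2 <- microsimulate(p, lt, "cataract", 2000, seed = 11)
  expect_identical(ms1, ms2)

  ms <- microsimulate(p, lt, "cataract", 20000, seed = 5)
  ct <- trace_totals(run_cohort(p, lt, "cataract"))
  expect_lt(abs(ms$qaly - ct$qaly), 3 * ms$qaly_se)
  expect_lt(abs(ms$ly - ct$ly), 3 * ms$ly_se)
  expect_lt(abs(ms$cost_total - ct$cost_total), 3 * ms$cost_se)
})
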