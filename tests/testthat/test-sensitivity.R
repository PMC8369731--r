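test_that("registry covers the varied parameters with families and setters", {
  p <- base_params()
  reg <- cua_parameter_set(p)
  expect_gte(nrow(reg), 15)
  expect_setequal(unique(reg$family), c("beta", "gamma", "normal"))
  # CI-backed disutility bounds are the published intervals
  trab <- reg[reg$parameter == "disutility_trabeculectomy", ]
  expect_equal(c(trab$low, trab$high), c(0.005, 0.009))
  # setters round-trip: applying the base value changes nothing material
  for (i in seq_len(nrow(reg))) {
    p2 <- reg$set[[i]](p, reg$base[i])
    expect_s3_class(validate_params(p2), "cua_params")
  }
})

test_that("tornado: zero-width bounds give zero spread, wide bounds move the ICER", {
  p <- base_params()
  lt <- base_lt()
  reg <- cua_parameter_set(p)
  small <- reg[reg$parameter %in%
                 c("utility_mild", "cost_procedure_istent"), ]
  small$low[small$parameter == "utility_mild"] <- small$base[small$parameter == "utility_mild"]
  small$high[small$parameter == "utility_mild"] <- small$base[small$parameter == "utility_mild"]
  dsa <- run_dsa(p, lt, registry = small)
  expect_equal(dsa$spread[dsa$parameter == "utility_mild"], 0)
  expect_gt(dsa$spread[dsa$parameter == "cost_procedure_istent"], 0)
})

test_that("utility bounds move the ICER in opposite directions around base", {
  p <- base_params()
  lt <- base_lt()
  reg <- cua_parameter_set(p)
  one <- reg[reg$parameter == "utility_severe", ]
  dsa <- run_dsa(p, lt, registry = one)
  base_icer <- attr(dsa, "base_icer")
  expect_true((dsa$icer_low - base_icer) * (dsa$icer_high - base_icer) < 0)
})

test_that("full tornado brackets the base case and is input-order invariant", {
  p <- base_params()
  lt <- base_lt()
  reg <- cua_parameter_set(p)
  dsa <- run_dsa(p, lt, registry = reg)
  base_icer <- attr(dsa, "base_icer")
  icers <- c(dsa$icer_low, dsa$icer_high)
  expect_lt(min(icers, na.rm = TRUE), base_icer)
  expect_gt(max(icers, na.rm = TRUE), base_icer)
  expect_false(any(dsa$flagged))

  shuffled <- reg[rev(seq_len(nrow(reg))), ]
  dsa2 <- run_dsa(p, lt, registry = shuffled)
  expect_equal(tibble::as_tibble(dsa2), tibble::as_tibble(dsa))
})

test_that("PSA draws recover the requested moments and respect supports", {
  p <- base_params()
  reg <- cua_parameter_set(p)

  # beta: utility draws centred on the base utility
  set.seed(99)
  i <- which(reg$parameter == "utility_mild")
  draws <- replicate(1000, {
    v <- glaucomaCUA:::draw_psa_value("beta", reg$base[i], reg$sd[i])
  })
  expect_lt(abs(mean(draws) - reg$base[i]), 2 * reg$sd[i] / sqrt(1000))
  expect_true(all(draws > 0 & draws < 1))

  # gamma: cost draws non-negative, mean recovered
  set.seed(100)
  costs <- replicate(1000,
    glaucomaCUA:::draw_psa_value("gamma", 1969.10, 200.9))
  expect_true(all(costs >= 0))
  expect_lt(abs(mean(costs) - 1969.10), 3 * 200.9 / sqrt(1000))

  # infeasible beta moments fall back with a warning
  expect_warning(glaucomaCUA:::draw_psa_value("beta", 0.5, 0.6),
                 "infeasible")
})

test_that("zero-SD sampling returns the base case exactly", {
  p <- base_params()
  reg <- cua_parameter_set(p)
  reg$sd <- rep(0, nrow(reg))
  drawn <- sample_psa_params(p, seed = 1, registry = reg)
  expect_equal(drawn$utilities, p$utilities)
  expect_equal(drawn$costs$procedure, p$costs$procedure)
  expect_equal(drawn$iop_schedule, p$iop_schedule)
})

test_that("PSA is seed-reproducible and its CEAC behaves", {
  p <- base_params()
  lt <- base_lt()
  psa1 <- run_psa(p, lt, n_reps = 8, seed = 123)
  psa2 <- run_psa(p, lt, n_reps = 8, seed = 123)
  expect_identical(psa1$reps, psa2$reps)
  expect_equal(nrow(psa1$reps), 8)

  # CEAC at zero willingness-to-pay is the fraction of cost-saving draws
  expect_equal(psa1$ceac$prob_cost_effective[psa1$ceac$wtp == 0],
               mean(psa1$reps$d_cost < 0))
  expect_true(all(psa1$ceac$prob_cost_effective >= 0 &
                    psa1$ceac$prob_cost_effective <= 1))
  # QALY gains are positive here, so the curve is monotone in WTP
  expect_false(is.unsorted(psa1$ceac$prob_cost_effective))
})

test_that("sensitivity results have working plot methods", {
  p <- base_params()
  lt <- base_lt()
  dsa <- run_dsa(p, lt, registry = head(cua_parameter_set(p), 3))
  expect_s3_class(autoplot(dsa), "ggplot")
  psa <- run_psa(p, lt, n_reps = 4, seed = 2)
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(plot_ce_plane(psa), "ggplot")
})
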