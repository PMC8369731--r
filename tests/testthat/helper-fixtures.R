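# Shared fixtures: everything is generated in code, no stored data.

base_params <- function() default_params()

base_lt <- function() generate_life_table()

# life table with the same annual death probability at every age
flat_lt <- function(q, max_age = 110) {
  qx <- rep(q, max_age + 1)
  qx[max_age + 1] <- 1
  glaucomaCUA:::new_life_table(0:max_age, qx)
}

# parameters with progression and switching effectively disabled
inert_params <- function(p = base_params()) {
  p$untreated_vf_decline <- 0
  p$nat_progression_lognormal <- list(meanlog = 30, sdlog = 0.5)
  p
}

strata_cols <- function() {
  c("mild_pre", "moderate_pre", "advanced_pre", "severe_pre",
    "mild_post", "moderate_post", "advanced_post", "severe_post", "dead")
}

expect_valid_trace <- function(trace, tol = 1e-10) {
  occ <- as.matrix(trace[, strata_cols()])
  expect_true(all(occ >= -tol))
  expect_true(all(abs(rowSums(occ) - 1) < tol))
  # irreversibility: cumulative mass at-or-beyond each severity level can
  # only grow (flows never run backward)
  cum_beyond <- function(cols) rowSums(occ[, cols, drop = FALSE])
  for (cols in list(
    "dead",
    c("severe_pre", "severe_post", "dead"),
    c("advanced_pre", "advanced_post", "severe_pre", "severe_post", "dead"),
    setdiff(colnames(occ), c("mild_pre", "mild_post")))) {
    expect_true(all(diff(cum_beyond(cols)) >= -tol))
  }
  # trabeculectomy status is absorbing: post-switch mass only grows while
  # the cohort is alive
  post <- rowSums(occ[, c("mild_post", "moderate_post", "advanced_post",
                          "severe_post")]) + occ[, "dead"]
  expect_true(all(diff(post) >= -tol))
  invisible(trace)
}
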