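test_that("the perfect-classifier limit yields all-1 metrics downstream", {
  p <- simulation_params(n = 2000, seed = 3,
                         capture = c(1, 1), contamination = c(0, 0),
                         misreport = 0)
  sim <- generate_survey(p)
  for (t in p$target_groups) {
    tc <- pipeline_metrics(sim, t)
    expect_equal(tc$sensitivity, 1)
    expect_equal(tc$specificity, 1)
    expect_equal(tc$ppv, 1)
    expect_equal(tc$npv, 1)
    em <- expected_metrics(p, t)
    expect_equal(em$sensitivity, 1)
    expect_equal(em$ppv, 1)
  }
})

test_that("generation is deterministic given the seed, down to written files", {
  p <- simulation_params(n = 400, seed = 123)
  s1 <- generate_survey(p)
  s2 <- generate_survey(p)
  expect_identical(s1$roster, s2$roster)
  expect_identical(s1$survey, s2$survey)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(s1$survey, f1)
  write_survey(s2$survey, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed produces different data
  s3 <- generate_survey(simulation_params(n = 400, seed = 124))
  expect_false(identical(s1$roster$surname, s3$roster$surname))
})

test_that("the closed form reproduces the single-group PPV identity", {
  p <- simulation_params(n = 1000, target_groups = "South Asian",
                         prevalence = 0.05, capture = 0.5,
                         contamination = 0.003, misreport = 0,
                         strata_effects = flat_effects())
  em <- expected_metrics(p, "South Asian")
  expect_equal(em$sensitivity, 0.5, tolerance = 1e-12)
  expect_equal(em$ppv, 0.025 / (0.025 + 0.95 * 0.003), tolerance = 1e-12)
  expect_equal(em$ppv, 0.8977, tolerance = 5e-4)
  expect_equal(em$specificity, 1 - 0.003, tolerance = 1e-12)
  # zero contamination: PPV is 1 whatever the prevalence and capture
  p0 <- simulation_params(n = 10, target_groups = "South Asian",
                          prevalence = 0.02, capture = 0.7,
                          contamination = 0, strata_effects = flat_effects())
  expect_equal(expected_metrics(p0, "South Asian")$ppv, 1)
  # zero capture: no sensitivity, PPV undefined when nothing is detected
  ps <- simulation_params(n = 10, target_groups = "South Asian",
                          prevalence = 0.05, capture = 0,
                          contamination = 0, strata_effects = flat_effects())
  es <- expected_metrics(ps, "South Asian")
  expect_identical(es$sensitivity, 0)
  expect_true(is.na(es$ppv))
})

test_that("expected PPV falls with contamination and rises with prevalence", {
  grid_pi <- c(0.02, 0.05)
  grid_c <- c(0.001, 0.003, 0.005)
  for (pi in grid_pi) {
    ppvs <- vapply(grid_c, function(cc) {
      p <- simulation_params(n = 10, target_groups = "South Asian",
                             prevalence = pi, capture = 0.5,
                             contamination = cc,
                             strata_effects = flat_effects())
      expected_metrics(p, "South Asian")$ppv
    }, numeric(1))
    expect_true(all(diff(ppvs) < 0))
  }
  for (cc in grid_c) {
    ppvs <- vapply(grid_pi, function(pi) {
      p <- simulation_params(n = 10, target_groups = "South Asian",
                             prevalence = pi, capture = 0.5,
                             contamination = cc,
                             strata_effects = flat_effects())
      expected_metrics(p, "South Asian")$ppv
    }, numeric(1))
    expect_true(all(diff(ppvs) > 0))
  }
})

test_that("probabilities pushed past 1 by strata multipliers are rejected by stratum name", {
  lv <- names(flat_effects()$capture)
  eff <- flat_effects()
  eff$capture[["Born in Canada"]] <- 2.5
  expect_error(
    simulation_params(n = 10, capture = c(0.504, 0.802),
                      strata_effects = eff),
    "Born in Canada")
})

test_that("moment estimates recover the empirical generating quantities exactly", {
  sim <- generate_survey(simulation_params(n = 5000, seed = 9))
  est <- recover_parameters(sim, "South Asian")
  # independent recomputation by explicit filtering
  tr <- sim$truth
  memb <- tr[tr$true_group == "South Asian", ]
  nonm <- tr[tr$true_group != "South Asian", ]
  expect_equal(est[["prevalence"]], nrow(memb) / nrow(tr), tolerance = 1e-15)
  expect_equal(est[["capture"]],
               mean(memb$name_source == "South Asian"), tolerance = 1e-15)
  expect_equal(est[["contamination"]],
               mean(nonm$name_source == "South Asian"), tolerance = 1e-15)
})

test_that("estimates from independent seeds both cover the generating parameters", {
  p <- function(seed) simulation_params(
    n = 30000, seed = seed, target_groups = "South Asian",
    prevalence = 0.05, capture = 0.5, contamination = 0.004,
    strata_effects = flat_effects())
  for (seed in c(101, 202)) {
    est <- recover_parameters(generate_survey(p(seed)), "South Asian")
    n <- attr(est, "n")
    expect_lt(abs(est[["prevalence"]] - 0.05),
              3 * sqrt(0.05 * 0.95 / n[["total"]]))
    expect_lt(abs(est[["capture"]] - 0.5),
              3 * sqrt(0.5 * 0.5 / n[["members"]]))
    expect_lt(abs(est[["contamination"]] - 0.004),
              3 * sqrt(0.004 * 0.996 / n[["nonmembers"]]))
  }
})

test_that("the default calibration depresses native-born PPV in the closed form", {
  p <- simulation_params(n = 10)
  for (t in p$target_groups) {
    by_stratum <- vapply(colnames(p$immigration_dist), function(h) {
      expected_metrics(p, t, immigration = h)$ppv
    }, numeric(1))
    expect_identical(names(which.min(by_stratum)), "Born in Canada")
    expect_gt(by_stratum[["Immigrant <=10 years"]],
              by_stratum[["Born in Canada"]])
  }
})
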