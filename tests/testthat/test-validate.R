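test_that("cross-tabulation matches a brute-force double loop, weighted and unweighted", {
  fx <- random_validation_fixture(100, seed = 13)
  tab <- cross_tabulate(fx$assignments, fx$gold, fx$respondents)
  labels <- tab$labels
  for (r in labels) {
    for (c in labels) {
      in_cell <- fx$assignments$group == r & fx$gold$group == c
      expect_identical(tab$unweighted[r, c], sum(in_cell))
      expect_equal(tab$weighted[r, c], sum(fx$respondents$weight[in_cell]),
                   tolerance = 1e-12)
    }
  }
  expect_identical(sum(tab$unweighted), 100L)
  expect_equal(sum(tab$weighted), sum(fx$respondents$weight))
})

test_that("a lone respondent fills a single cell and missing links are fatal", {
  asg <- data.frame(person_id = "p1", group = "Chinese")
  gold <- data.frame(person_id = "p1", group = "South Asian")
  resp <- data.frame(person_id = "p1", weight = 2.5)
  tab <- cross_tabulate(asg, gold, resp)
  expect_identical(tab$unweighted["Chinese", "South Asian"], 1L)
  expect_identical(sum(tab$unweighted), 1L)
  resp2 <- data.frame(person_id = c("p1", "p2"), weight = c(1, 1))
  expect_error(cross_tabulate(asg, rbind(gold, data.frame(
    person_id = "p2", group = "Chinese")), resp2), "no surname-derived.*p2")
})

test_that("an all-diagonal table yields perfect test characteristics", {
  m <- diag(c(10, 20, 30))
  dimnames(m) <- rep(list(c("A", "B", "C")), 2)
  for (t in c("A", "B", "C")) {
    tc <- test_characteristics(as_crosstab(m), t, weighted = FALSE)
    expect_equal(tc$sensitivity, 1)
    expect_equal(tc$specificity, 1)
    expect_equal(tc$ppv, 1)
    expect_equal(tc$npv, 1)
  }
})

test_that("the four definitions reproduce hand-computed 2x2 values", {
  m <- rbind(Pos = c(Pos = 8, Neg = 1), Neg = c(Pos = 2, Neg = 89))
  tc <- test_characteristics(as_crosstab(m), "Pos", weighted = FALSE)
  expect_equal(tc$sensitivity, 8 / 10)
  expect_equal(tc$specificity, 89 / 90)
  expect_equal(tc$ppv, 8 / 9)
  expect_equal(tc$npv, 89 / 91)
  expect_identical(unname(tc$counts), c(8, 1, 2, 89))
})

test_that("the reference Ontario confusion table yields its implied unweighted metrics", {
  rc <- reference_crosstab()
  sa <- test_characteristics(rc, "South Asian", weighted = FALSE)
  expect_equal(sa$ppv, 654 / 787, tolerance = 1e-12)
  expect_equal(sa$sensitivity, 654 / 1400, tolerance = 1e-12)
  cn <- test_characteristics(rc, "Chinese", weighted = FALSE)
  expect_equal(cn$ppv, 899 / (9 + 899 + 139), tolerance = 1e-12)
  expect_equal(cn$sensitivity, 899 / 1129, tolerance = 1e-12)
})

test_that("empty denominators are reported as undefined, never zero", {
  # no predicted positives for A: PPV undefined, sensitivity 0
  m <- rbind(A = c(A = 0, B = 0), B = c(A = 5, B = 10))
  tc <- test_characteristics(as_crosstab(m), "A", weighted = FALSE)
  expect_true(is.na(tc$ppv))
  expect_identical(tc$sensitivity, 0)
  expect_true("ppv" %in% tc$undefined)
  # no gold positives: sensitivity undefined
  m2 <- rbind(A = c(A = 0, B = 3), B = c(A = 0, B = 10))
  tc2 <- test_characteristics(as_crosstab(m2), "A", weighted = FALSE)
  expect_true(is.na(tc2$sensitivity))
})

test_that("metrics are invariant to global weight rescaling", {
  fx <- random_validation_fixture(150, seed = 17)
  tab <- cross_tabulate(fx$assignments, fx$gold, fx$respondents)
  for (k in c(0.01, 3.7, 1e6)) {
    fx2 <- fx
    fx2$respondents$weight <- fx$respondents$weight * k
    tab2 <- cross_tabulate(fx2$assignments, fx2$gold, fx2$respondents)
    for (m in c("sensitivity", "specificity", "ppv", "npv")) {
      expect_equal(test_characteristics(tab2, "Chinese")[[m]],
                   test_characteristics(tab, "Chinese")[[m]],
                   tolerance = 1e-12)
    }
  }
})

test_that("with two groups, sensitivity of one equals specificity of the other", {
  fx <- random_validation_fixture(120, seed = 19, labels = c("A", "B"))
  tab <- cross_tabulate(fx$assignments, fx$gold, fx$respondents)
  ta <- test_characteristics(tab, "A")
  tb <- test_characteristics(tab, "B")
  expect_equal(ta$sensitivity, tb$specificity, tolerance = 1e-12)
  expect_equal(tb$sensitivity, ta$specificity, tolerance = 1e-12)
})

test_that("stratified characteristics reduce to the overall result for one stratum", {
  fx <- random_validation_fixture(200, seed = 23)
  fx$respondents$sex <- "Female"
  strat <- stratified_characteristics(fx$assignments, fx$gold,
                                      fx$respondents, "sex", "Chinese")
  expect_named(strat, "Female")
  overall <- test_characteristics(
    cross_tabulate(fx$assignments, fx$gold, fx$respondents), "Chinese")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(strat[["Female"]][[m]], overall[[m]], tolerance = 1e-12)
  }
  expect_error(
    stratified_characteristics(fx$assignments, fx$gold, fx$respondents,
                               "height", "Chinese"), "stratify_by")
})

test_that("a stratum without predicted positives reports undefined PPV", {
  asg <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                    group = c("A", "Gen", "Gen", "Gen"))
  gold <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                     group = c("A", "A", "Gen", "Gen"))
  resp <- data.frame(person_id = c("p1", "p2", "p3", "p4"),
                     weight = 1,
                     sex = c("Male", "Female", "Female", "Female"))
  strat <- stratified_characteristics(asg, gold, resp, "sex", "A")
  expect_true(is.na(strat[["Female"]]$ppv))
  expect_identical(strat[["Female"]]$sensitivity, 0)
  expect_equal(strat[["Male"]]$ppv, 1)
})

test_that("comparing a list against itself yields zero differences", {
  fx <- random_validation_fixture(80, seed = 29)
  roster <- data.frame(person_id = fx$respondents$person_id,
                       surname = sample(c("Patel", "Wong", "Smith"), 80,
                                        replace = TRUE))
  coll <- starter_collection()
  cmp <- compare_lists(coll, coll, roster, fx$gold, fx$respondents,
                       "South Asian")
  expect_true(all(abs(cmp$difference) < 1e-15))
})

test_that("adding a name borne only by non-members trades PPV without touching sensitivity", {
  ids <- sprintf("p%d", 1:6)
  roster <- data.frame(person_id = ids,
                       surname = c("Patel", "Patel", "Smith", "Smith",
                                   "Jones", "Singh"))
  gold <- data.frame(person_id = ids,
                     group = c("South Asian", "South Asian",
                               "General Population", "General Population",
                               "General Population", "South Asian"))
  resp <- data.frame(person_id = ids, weight = c(1, 2, 1, 3, 1, 2))
  a <- list_collection(build_list(c("Patel", "Singh"), "South Asian"))
  # SMITH is carried only by gold non-members
  b <- list_collection(build_list(c("Patel", "Singh", "Smith"),
                                  "South Asian"))
  cmp <- compare_lists(a, b, roster, gold, resp, "South Asian")
  expect_equal(cmp$difference[["sensitivity"]], 0)
  expect_true(cmp$b$ppv < cmp$a$ppv)
  # a name carried only by gold members instead raises sensitivity
  a2 <- list_collection(build_list("Patel", "South Asian"))
  cmp2 <- compare_lists(a2, a, roster, gold, resp, "South Asian")
  expect_true(cmp2$b$sensitivity > cmp2$a$sensitivity)
})

test_that("bootstrap intervals are reproducible and collapse for constant metrics", {
  fx <- random_validation_fixture(150, seed = 37)
  ci1 <- bootstrap_ci(fx$assignments, fx$gold, fx$respondents, "Chinese",
                      "ppv", B = 200, seed = 99)
  ci2 <- bootstrap_ci(fx$assignments, fx$gold, fx$respondents, "Chinese",
                      "ppv", B = 200, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(ci1[["lower"]] <= ci1[["upper"]])
  # degenerate population: every respondent predicted and gold positive
  ids <- sprintf("d%d", 1:30)
  const <- list(
    assignments = data.frame(person_id = ids, group = "A"),
    gold = data.frame(person_id = ids, group = "A"),
    respondents = data.frame(person_id = ids, weight = runif(30) + 0.5))
  ci <- bootstrap_ci(const$assignments, const$gold, const$respondents,
                     "A", "sensitivity", B = 50, seed = 1)
  expect_equal(as.vector(ci), c(1, 1))
  # metric undefined in every replicate is an error, not an interval
  none <- const
  none$assignments$group <- "B"
  expect_error(
    bootstrap_ci(none$assignments, none$gold, none$respondents, "A",
                 "ppv", B = 20, seed = 1), "undefined")
})

test_that("bootstrap intervals bracket the point estimate on simulated data", {
  sim <- generate_survey(simulation_params(n = 3000, seed = 41))
  asg <- assign_roster(sim$roster, starter_collection())
  gold <- resolve_survey(sim$survey, sim$params$target_groups)
  surv <- pool_weights(sim$survey, sim$params$cycles)
  tab <- cross_tabulate(asg, gold, surv)
  point <- test_characteristics(tab, "Chinese")$sensitivity
  ci <- bootstrap_ci(asg, gold, surv, "Chinese", "sensitivity",
                     B = 200, seed = 7)
  expect_true(ci[["lower"]] <= point && point <= ci[["upper"]])
  expect_true(ci[["upper"]] - ci[["lower"]] < 0.2)
})
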