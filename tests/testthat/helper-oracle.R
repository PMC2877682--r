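# Brute-force per-respondent oracle for the four test characteristics,
# deliberately independent of the package's crosstab path: one explicit loop
# accumulating the 2x2 cells, then the textbook ratios.
brute_metrics <- function(pred, truth, w, target) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == target
    t <- truth[i] == target
    if (p && t) tp <- tp + w[i]
    if (p && !t) fp <- fp + w[i]
    if (!p && t) fn <- fn + w[i]
    if (!p && !t) tn <- tn + w[i]
  }
  r <- function(num, den) if (den <= 0) NA_real_ else num / den
  c(sensitivity = r(tp, tp + fn), specificity = r(tn, tn + fp),
    ppv = r(tp, tp + fp), npv = r(tn, tn + fn))
}

# Monte-Carlo standard error of a weighted proportion with expected value p,
# over the denominator respondents' weights (Kish effective sample size).
mc_se_prop <- function(p, w) {
  if (!length(w)) return(Inf)
  sqrt(p * (1 - p) * sum(w^2)) / sum(w)
}

# Random linked (assignments, gold, respondents) fixture over three groups.
random_validation_fixture <- function(n, seed,
                                      labels = c("South Asian", "Chinese",
                                                 "General Population")) {
  set.seed(seed)
  ids <- sprintf("R%05d", seq_len(n))
  p_pred <- if (length(labels) == 3L) c(0.1, 0.1, 0.8) else NULL
  p_gold <- if (length(labels) == 3L) c(0.15, 0.1, 0.75) else NULL
  list(
    assignments = data.frame(
      person_id = ids,
      group = sample(labels, n, replace = TRUE, prob = p_pred),
      stringsAsFactors = FALSE),
    gold = data.frame(
      person_id = ids,
      group = sample(labels, n, replace = TRUE, prob = p_gold),
      stringsAsFactors = FALSE),
    respondents = data.frame(
      person_id = ids,
      cycle = sample(c("2001", "2002", "2003"), n, replace = TRUE),
      weight = stats::rlnorm(n, log(100), 0.7),
      sex = sample(c("Male", "Female"), n, replace = TRUE),
      age_band = sample(c("44 or younger", "45 to 64", "65 or older"),
                        n, replace = TRUE),
      immigration = sample(c("Born in Canada", "Immigrant <=10 years"),
                           n, replace = TRUE),
      stringsAsFactors = FALSE)
  )
}

# Strata multipliers that switch the nativity gradient off.
flat_effects <- function() {
  lv <- c("Born in Canada", "Immigrant <=10 years",
          "Immigrant 11 to 20 years", "Immigrant > 20 years")
  list(capture = stats::setNames(rep(1, 4), lv),
       contamination = stats::setNames(rep(1, 4), lv))
}

# Weighted pipeline metrics for one target group from a generated survey.
pipeline_metrics <- function(sim, target, weighted = TRUE) {
  asg <- assign_roster(sim$roster, starter_collection())
  gold <- resolve_survey(sim$survey, sim$params$target_groups)
  surv <- pool_weights(sim$survey, sim$params$cycles)
  tab <- cross_tabulate(asg, gold, surv)
  test_characteristics(tab, target, weighted = weighted)
}
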