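IMM_LEVELS <- c("Born in Canada", "Immigrant <=10 years",
                "Immigrant 11 to 20 years", "Immigrant > 20 years")
AGE_LEVELS <- c("44 or younger", "45 to 64", "65 or older")
SEX_LEVELS <- c("Male", "Female")

# Stratum composition defaults: weighted distributions of immigration, sex
# and age within each group, matching the published baseline profile of the
# Ontario validation population (minorities concentrated among immigrants).
default_imm_dist <- function(groups) {
  d <- rbind(
    "South Asian"        = c(0.070, 0.472, 0.259, 0.199),
    "Chinese"            = c(0.096, 0.381, 0.283, 0.240),
    "General Population" = c(0.737, 0.060, 0.048, 0.155)
  )
  colnames(d) <- IMM_LEVELS
  out <- d[intersect(groups, rownames(d)), , drop = FALSE]
  extra <- setdiff(groups, rownames(d))
  for (g in extra) {
    out <- rbind(out, stats::setNames(c(0.737, 0.060, 0.048, 0.155),
                                      IMM_LEVELS))
    rownames(out)[nrow(out)] <- g
  }
  out[groups, , drop = FALSE]
}

default_sex_p_male <- function(groups) {
  p <- c("South Asian" = 0.547, "Chinese" = 0.525,
         "General Population" = 0.484)
  out <- ifelse(groups %in% names(p), p[groups], 0.5)
  stats::setNames(out, groups)
}

default_age_dist <- function(groups) {
  d <- rbind(
    "South Asian"        = c(0.644, 0.292, 0.064),
    "Chinese"            = c(0.626, 0.276, 0.098),
    "General Population" = c(0.520, 0.314, 0.166)
  )
  colnames(d) <- AGE_LEVELS
  out <- matrix(rep(c(0.520, 0.314, 0.166), length(groups)),
                ncol = 3, byrow = TRUE,
                dimnames = list(groups, AGE_LEVELS))
  known <- intersect(groups, rownames(d))
  out[known, ] <- d[known, ]
  out
}

#' Parameters of the synthetic roster-and-survey generator
#'
#' Defines a complete generative model for a weighted cross-sectional survey
#' linked to a population roster, with known ground truth. Each respondent is
#' drawn as: true group (by `prevalence`) -> strata (immigration, sex, age
#' band, with group-specific distributions) -> surname source (own-group list
#' with probability `capture`, another group's list with probability
#' `contamination`, otherwise a general-population name; both probabilities
#' multiplied by per-immigration-stratum `strata_effects`) -> a surname drawn
#' from the packaged starter fixtures with frequencies proportional to the
#' printed Ontario counts (Zipf-extended beyond the ten printed names) ->
#' self-report answers (the target token on both questions with probability
#' `1 - misreport` for group members; distractor tokens otherwise) ->
#' lognormal person-level weight and a survey cycle.
#'
#' The default calibration emulates the published Ontario regime: minority
#' prevalences of 5.4% and 4.0%, capture probabilities 0.504 and 0.802, and
#' contamination back-solved so the expected overall PPV is 89.3% and 91.9%,
#' with contamination elevated among the native-born (and damped among
#' recent immigrants) to reproduce the qualitative nativity gradient. These
#' are generator inputs describing the emulated study conditions, not test
#' targets.
#'
#' @param n Number of respondents (>= 1).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param target_groups Labels of the minority groups with surname lists.
#' @param default_label Residual group label.
#' @param prevalence Named proportions of `target_groups` (unweighted
#'   sampling proportions); the default group takes the remainder.
#' @param capture Named probabilities that a group member bears a surname on
#'   their own group's list.
#' @param contamination Named probabilities that a non-member bears a
#'   surname on a target group's list; `NULL` back-solves the defaults from
#'   `ppv_target`.
#' @param ppv_target Named overall PPV values used only to calibrate the
#'   default contamination.
#' @param misreport Probability that a true group member self-reports a
#'   non-target token on both questions.
#' @param strata_effects List with named numeric vectors `capture` and
#'   `contamination`: per-immigration-level multipliers.
#' @param weight_meanlog,weight_sdlog Lognormal parameters of the
#'   person-level weight (persons represented per respondent).
#' @param cycles Cycle labels; `cycle_mix` gives their mixing proportions
#'   (default equal).
#' @param cycle_mix Optional mixing proportions for `cycles`.
#' @param immigration_dist Matrix (group x immigration level) of stratum
#'   probabilities per group.
#' @return An object of class `simulation_params`.
#' @seealso [generate_survey()], [expected_metrics()]
#' @export
simulation_params <- function(n,
                              seed = 1,
                              target_groups = c("South Asian", "Chinese"),
                              default_label = "General Population",
                              prevalence = NULL,
                              capture = NULL,
                              contamination = NULL,
                              ppv_target = NULL,
                              misreport = 0,
                              strata_effects = NULL,
                              weight_meanlog = log(130),
                              weight_sdlog = 0.6,
                              cycles = c("2001", "2002", "2003"),
                              cycle_mix = NULL,
                              immigration_dist = NULL) {
  stopifnot(n >= 1, length(target_groups) >= 1)
  if (default_label %in% target_groups) {
    stop("default_label must differ from every target group", call. = FALSE)
  }
  named_or_default <- function(x, default) {
    if (is.null(x)) {
      stats::setNames(default[seq_along(target_groups)], target_groups)
    } else {
      if (length(x) != length(target_groups)) {
        stop("supply one value per target group", call. = FALSE)
      }
      if (is.null(names(x))) names(x) <- target_groups
      if (!setequal(names(x), target_groups)) {
        stop("names must match target_groups", call. = FALSE)
      }
      x[target_groups]
    }
  }
  prevalence <- named_or_default(prevalence, c(0.054, 0.040))
  capture <- named_or_default(capture, c(0.504, 0.802))
  ppv_target <- named_or_default(ppv_target, c(0.893, 0.919))
  if (any(prevalence < 0) || sum(prevalence) >= 1) {
    stop("target prevalences must be nonnegative and sum to < 1",
         call. = FALSE)
  }
  if (any(capture < 0 | capture > 1) || misreport < 0 || misreport > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  groups <- c(target_groups, default_label)
  if (is.null(immigration_dist)) {
    immigration_dist <- default_imm_dist(groups)
  }
  stopifnot(all(abs(rowSums(immigration_dist) - 1) < 1e-8))
  if (is.null(strata_effects)) {
    strata_effects <- list(
      capture = stats::setNames(rep(1, 4), IMM_LEVELS),
      contamination = stats::setNames(c(2.0, 0.5, 1.0, 1.5), IMM_LEVELS)
    )
  }
  stopifnot(setequal(names(strata_effects$capture), colnames(immigration_dist)),
            setequal(names(strata_effects$contamination),
                     colnames(immigration_dist)))
  if (is.null(contamination)) {
    contamination <- calibrate_contamination(
      prevalence, capture, ppv_target, default_label,
      immigration_dist, strata_effects$contamination)
  } else {
    contamination <- named_or_default(contamination, contamination)
  }
  if (any(contamination < 0 | contamination > 1)) {
    stop("contamination probabilities must lie in [0, 1]", call. = FALSE)
  }
  # after strata adjustment every Bernoulli probability must stay in [0, 1]
  for (h in colnames(immigration_dist)) {
    if (any(capture * strata_effects$capture[h] > 1)) {
      stop("capture probability exceeds 1 after strata adjustment in ",
           "stratum ", sQuote(h), call. = FALSE)
    }
    if (any(contamination * strata_effects$contamination[h] > 1)) {
      stop("contamination probability exceeds 1 after strata adjustment ",
           "in stratum ", sQuote(h), call. = FALSE)
    }
  }
  if (is.null(cycle_mix)) cycle_mix <- rep(1 / length(cycles), length(cycles))
  stopifnot(length(cycle_mix) == length(cycles),
            abs(sum(cycle_mix) - 1) < 1e-8)
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      target_groups = target_groups, default_label = default_label,
      groups = groups,
      prevalence = prevalence, capture = capture,
      contamination = contamination, misreport = misreport,
      strata_effects = strata_effects,
      weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
      cycles = cycles, cycle_mix = cycle_mix,
      immigration_dist = immigration_dist,
      sex_p_male = default_sex_p_male(groups),
      age_dist = default_age_dist(groups)
    ),
    class = "simulation_params"
  )
}

# Back-solve default contamination c so the expected overall PPV equals the
# calibration value, given the PPV identity PPV = pi*s / (pi*s + D) with
# D = c * sum over non-member groups of pi_g * E_h[contamination multiplier].
calibrate_contamination <- function(prevalence, capture, ppv_target,
                                    default_label, imm_dist, conmult) {
  groups <- rownames(imm_dist)
  pi_all <- c(prevalence,
              stats::setNames(1 - sum(prevalence), default_label))
  vapply(names(prevalence), function(t) {
    d_needed <- prevalence[[t]] * capture[[t]] *
      (1 - ppv_target[[t]]) / ppv_target[[t]]
    others <- setdiff(groups, t)
    denom <- sum(vapply(others, function(g) {
      pi_all[[g]] * sum(imm_dist[g, ] * conmult[colnames(imm_dist)])
    }, numeric(1)))
    d_needed / denom
  }, numeric(1))
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("<simulation_params> n = ", x$n, ", seed = ", x$seed, "\n", sep = "")
  for (t in x$target_groups) {
    cat(sprintf("  %s: prevalence %.3f, capture %.3f, contamination %.5f\n",
                t, x$prevalence[[t]], x$capture[[t]], x$contamination[[t]]))
  }
  cat("  misreport ", x$misreport, "; cycles ",
      paste(x$cycles, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# Name pools with emission weights: printed Ontario counts for the ten most
# common names, Zipf tail (count_10 * 10 / rank) for the rest of each list.
name_pool <- function(group) {
  lst <- starter_list(group)
  counts <- ontario_name_counts()
  top <- counts[counts$group == group, ]
  rest <- sort(setdiff(lst$names, top$name))
  tail_w <- top$ontario_count[10] * 10 / seq(11, 10 + length(rest))
  data.frame(name = c(top$name, rest),
             w = c(top$ontario_count, tail_w),
             stringsAsFactors = FALSE)
}

sample_cat_rows <- function(groups_of, dist_matrix) {
  # one categorical draw per row, probabilities taken from the row of
  # dist_matrix matching each element's group
  out <- character(length(groups_of))
  for (g in rownames(dist_matrix)) {
    idx <- which(groups_of == g)
    if (length(idx)) {
      out[idx] <- sample(colnames(dist_matrix), length(idx),
                         replace = TRUE, prob = dist_matrix[g, ])
    }
  }
  out
}

#' Generate a synthetic roster and weighted survey with known truth
#'
#' Draws `params$n` respondents from the generative model described in
#' [simulation_params()] and returns the three linked artifacts every
#' upstream module consumes: a population roster (`person_id`, `surname`), a
#' survey table in the standard schema, and a truth table recording each
#' respondent's true group, which list (if any) their surname was emitted
#' from, and whether they misreported. Output is deterministic given
#' `params$seed`.
#'
#' @param params A `simulation_params` object.
#' @return List with data frames `roster`, `survey`, `truth`, plus `params`.
#' @examples
#' sim <- generate_survey(simulation_params(n = 500, seed = 7))
#' head(sim$survey)
#' @export
generate_survey <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)
  n <- params$n
  targets <- params$target_groups
  pi_all <- c(params$prevalence,
              stats::setNames(1 - sum(params$prevalence),
                              params$default_label))
  grp <- sample(params$groups, n, replace = TRUE, prob = pi_all)
  imm <- sample_cat_rows(grp, params$immigration_dist)
  age <- sample_cat_rows(grp, params$age_dist)
  sex <- ifelse(stats::runif(n) < params$sex_p_male[grp], "Male", "Female")

  # surname source: sequential Bernoulli over target lists in collection
  # order, with conditional probability capture (member) or contamination
  # (non-member), scaled by the immigration-stratum multipliers
  capm <- params$strata_effects$capture[imm]
  conm <- params$strata_effects$contamination[imm]
  source <- rep(params$default_label, n)
  remaining <- rep(TRUE, n)
  for (t in targets) {
    q <- ifelse(grp == t, params$capture[[t]] * capm,
                params$contamination[[t]] * conm)
    hit <- remaining & (stats::runif(n) < q)
    source[hit] <- t
    remaining <- remaining & !hit
  }

  pools <- lapply(stats::setNames(params$groups, params$groups), function(g) {
    if (g %in% c("South Asian", "Chinese", "General Population")) {
      name_pool(g)
    } else {
      data.frame(name = starter_list("General Population")$names, w = 1)
    }
  })
  surname <- character(n)
  for (g in unique(source)) {
    idx <- which(source == g)
    pool <- pools[[g]]
    surname[idx] <- sample(pool$name, length(idx), replace = TRUE,
                           prob = pool$w)
  }

  # self-report: members answer their own token on both questions unless
  # they misreport; everyone else answers from distractor pools, including
  # an occasional multi-response listing a target token among others (which
  # the gold-standard rule sends to the residual group)
  distractors <- c("Southeast Asian", "Aboriginal", "Other")
  euro <- c("English", "French", "Scottish", "Irish", "German", "Italian",
            "Dutch", "Polish", "Ukrainian")
  backgrounds <- c("White", "Black", "Other", "Southeast Asian")
  member <- grp %in% targets
  mis <- member & stats::runif(n) < params$misreport
  q_anc <- q_bgd <- character(n)
  ok <- member & !mis
  q_anc[ok] <- grp[ok]
  q_bgd[ok] <- grp[ok]
  if (any(mis)) {
    q_anc[mis] <- sample(distractors, sum(mis), replace = TRUE)
    q_bgd[mis] <- "Other"
  }
  gen <- !member
  if (any(gen)) {
    n_gen <- sum(gen)
    first <- sample(euro, n_gen, replace = TRUE)
    second <- sample(euro, n_gen, replace = TRUE)
    multi <- stats::runif(n_gen) < 0.4
    # a sliver of residual-group respondents list a target ancestry among
    # several; "single response" resolution keeps them in the residual group
    mixed <- stats::runif(n_gen) < 0.02
    anc <- ifelse(multi, paste(first, second, sep = ";"), first)
    anc[mixed] <- paste(sample(targets, sum(mixed), replace = TRUE),
                        first[mixed], sep = ";")
    q_anc[gen] <- anc
    q_bgd[gen] <- sample(backgrounds, n_gen, replace = TRUE)
  }

  weight <- stats::rlnorm(n, params$weight_meanlog, params$weight_sdlog)
  cycle <- sample(params$cycles, n, replace = TRUE, prob = params$cycle_mix)
  person_id <- sprintf("P%07d", seq_len(n))

  list(
    roster = data.frame(person_id = person_id, surname = surname,
                        stringsAsFactors = FALSE),
    survey = data.frame(person_id = person_id, cycle = cycle,
                        weight = weight, q_ancestry = q_anc,
                        q_background = q_bgd, sex = sex, age_band = age,
                        immigration = imm, stringsAsFactors = FALSE),
    truth = data.frame(person_id = person_id, true_group = grp,
                       name_source = source, misreported = mis,
                       immigration = imm, weight = weight,
                       stringsAsFactors = FALSE),
    params = params
  )
}

#' Closed-form expected test characteristics of the generative model
#'
#' Computes the exact population-level sensitivity, specificity, PPV and NPV
#' implied by a `simulation_params` object for one target group, by
#' enumeration over (true group x immigration stratum x surname source).
#' With a single target group, one stratum and no misreporting this reduces
#' to the familiar identities `sensitivity = s` and
#' `PPV = pi*s / (pi*s + (1 - pi)*c)` for prevalence `pi`, capture `s` and
#' contamination `c`. The weighted and unweighted metrics of a generated
#' survey both converge to these values because weights are drawn
#' independently of every other variable.
#'
#' @param params A `simulation_params` object.
#' @param target_group One of `params$target_groups`.
#' @param immigration Optional immigration level; when given, metrics are
#'   computed conditionally within that stratum (the closed-form oracle for
#'   stratified PPV).
#' @return A `test_characteristics` object whose `counts` are outcome-class
#'   probabilities; attribute `formulas` documents each expression.
#' @examples
#' p <- simulation_params(n = 1000, target_groups = "South Asian",
#'                        prevalence = 0.05, capture = 0.5,
#'                        contamination = 0.003)
#' expected_metrics(p, "South Asian")
#' @export
expected_metrics <- function(params, target_group, immigration = NULL) {
  stopifnot(inherits(params, "simulation_params"),
            target_group %in% params$target_groups)
  targets <- params$target_groups
  pi_all <- c(params$prevalence,
              stats::setNames(1 - sum(params$prevalence),
                              params$default_label))
  imm_levels <- colnames(params$immigration_dist)
  if (!is.null(immigration)) {
    stopifnot(immigration %in% imm_levels)
  }
  mis <- params$misreport

  tp <- det <- pos <- tot <- 0
  for (g in params$groups) {
    for (h in imm_levels) {
      if (!is.null(immigration) && h != immigration) next
      w_gh <- pi_all[[g]] * params$immigration_dist[g, h]
      if (w_gh == 0) next
      capm <- params$strata_effects$capture[[h]]
      conm <- params$strata_effects$contamination[[h]]
      # sequential name-source probabilities over targets in order
      rem <- 1
      p_det <- 0
      for (t in targets) {
        q <- if (g == t) params$capture[[t]] * capm
             else params$contamination[[t]] * conm
        if (t == target_group) p_det <- rem * q
        rem <- rem * (1 - q)
      }
      is_member <- g == target_group
      p_gold <- if (is_member) 1 - mis else 0
      tot <- tot + w_gh
      pos <- pos + w_gh * p_gold
      det <- det + w_gh * p_det
      tp <- tp + w_gh * p_gold * p_det  # report draw independent of source
    }
  }
  # condition on the stratum if one was requested
  tp <- tp / tot; det <- det / tot; pos <- pos / tot
  fp <- det - tp
  fn <- pos - tp
  tn <- 1 - tp - fp - fn
  metrics <- c(
    sensitivity = safe_ratio(tp, pos),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, det),
    npv = safe_ratio(tn, tn + fn)
  )
  out <- new_test_characteristics(
    metrics, c(TP = tp, FP = fp, FN = fn, TN = tn), target_group,
    weighted = NA)
  attr(out, "formulas") <- c(
    "P(gold+) = pi_t * (1 - misreport)",
    "P(detect | g, h) = q_t(g, h) * prod_{t' before t} (1 - q_t'(g, h))",
    "q_t(g, h) = capture_t * capmult_h if g == t else contamination_t * conmult_h",
    "sensitivity = P(detect & gold+) / P(gold+)",
    "specificity = P(!detect & gold-) / P(gold-)",
    "PPV = P(detect & gold+) / P(detect)",
    "NPV = P(!detect & gold-) / P(!detect)"
  )
  out
}

#' Moment estimates of the generating parameters from a synthetic survey
#'
#' Recovers the prevalence, capture and contamination of one target group
#' from a generated survey and its truth table by direct empirical
#' proportions: prevalence is the fraction of respondents whose true group
#' is the target; capture the fraction of members whose surname came from
#' the target list; contamination the fraction of non-members whose surname
#' came from the target list.
#'
#' @param sim Result of [generate_survey()] (or any list with a `truth`
#'   data frame of the same schema).
#' @param target_group Target group label.
#' @return Named numeric `c(prevalence, capture, contamination)` with
#'   attribute `n` giving the denominators used.
#' @export
recover_parameters <- function(sim, target_group) {
  truth <- sim$truth
  member <- truth$true_group == target_group
  on_list <- truth$name_source == target_group
  est <- c(
    prevalence = mean(member),
    capture = if (any(member)) mean(on_list[member]) else NA_real_,
    contamination = if (any(!member)) mean(on_list[!member]) else NA_real_
  )
  attr(est, "n") <- c(total = nrow(truth), members = sum(member),
                      nonmembers = sum(!member))
  est
}
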