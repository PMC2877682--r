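#' Cross-tabulate surname-derived against gold-standard ethnicity
#'
#' Links every respondent (by `person_id`) to their surname-derived group and
#' their gold-standard group and fills a k-by-k table twice: unweighted
#' respondent counts and person-level-weight sums. Rows are surname-derived
#' groups, columns gold-standard groups; both dimensions share one label set.
#'
#' @param assignments Data frame `person_id`, `group` from [assign_roster()].
#' @param gold Data frame `person_id`, `group` from [resolve_survey()].
#' @param respondents Survey data frame supplying `person_id` and (pooled)
#'   `weight`.
#' @param labels Optional character vector fixing label order; defaults to
#'   the sorted union of labels seen in `assignments` and `gold`.
#' @return An object of class `crosstab` with fields `labels`, `unweighted`
#'   (integer matrix) and `weighted` (numeric matrix).
#' @export
cross_tabulate <- function(assignments, gold, respondents, labels = NULL) {
  ids <- respondents$person_id
  i_asg <- match(ids, assignments$person_id)
  if (anyNA(i_asg)) {
    miss <- ids[is.na(i_asg)]
    stop("respondent(s) with no surname-derived assignment: ",
         paste(sQuote(utils::head(miss, 5L)), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (and %d more)", length(miss) - 5L),
         call. = FALSE)
  }
  i_gold <- match(ids, gold$person_id)
  if (anyNA(i_gold)) {
    miss <- ids[is.na(i_gold)]
    stop("respondent(s) with no gold-standard label: ",
         paste(sQuote(utils::head(miss, 5L)), collapse = ", "),
         call. = FALSE)
  }
  pred <- assignments$group[i_asg]
  truth <- gold$group[i_gold]
  if (is.null(labels)) labels <- sort(unique(c(pred, truth)))
  pf <- factor(pred, levels = labels)
  tf <- factor(truth, levels = labels)
  unw <- table(pf, tf, dnn = NULL)
  w <- respondents$weight
  wtd <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  agg <- tapply(w, list(pf, tf), sum, default = 0)
  wtd[rownames(agg), colnames(agg)] <- agg
  as_crosstab(matrix(as.integer(unw), length(labels),
                     dimnames = list(labels, labels)),
              weighted = wtd)
}

#' Construct a crosstab from count matrices
#'
#' Wraps already tabulated counts — for example a published confusion table —
#' in the same `crosstab` container that [cross_tabulate()] produces, so test
#' characteristics can be computed from printed tables.
#'
#' @param unweighted Square numeric matrix of respondent counts with
#'   identical row and column dimnames (rows: surname-derived; columns:
#'   gold standard).
#' @param weighted Optional numeric matrix of weighted counts with the same
#'   shape; defaults to `unweighted`.
#' @return A `crosstab` object.
#' @export
as_crosstab <- function(unweighted, weighted = NULL) {
  unweighted <- as.matrix(unweighted)
  if (nrow(unweighted) != ncol(unweighted)) {
    stop("crosstab matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(unweighted)) ||
      !identical(rownames(unweighted), colnames(unweighted))) {
    stop("crosstab matrix needs identical row and column names",
         call. = FALSE)
  }
  if (any(unweighted < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(weighted)) weighted <- unweighted
  stopifnot(identical(dim(weighted), dim(unweighted)))
  structure(
    list(labels = rownames(unweighted),
         unweighted = unweighted,
         weighted = weighted),
    class = "crosstab"
  )
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> surname-derived (rows) vs gold standard (columns)\n")
  cat("unweighted counts (n = ", format(sum(x$unweighted), big.mark = ","),
      "):\n", sep = "")
  print(x$unweighted)
  if (!identical(x$weighted, x$unweighted)) {
    cat("weighted total: ", format(round(sum(x$weighted), 1),
                                   big.mark = ","), "\n", sep = "")
  }
  invisible(x)
}

#' Reference confusion table from the published Ontario validation
#'
#' The unweighted cross-tabulation of surname-derived against self-identified
#' ethnicity among the 69,859 Ontario survey respondents used to validate the
#' packaged starter lists, as printed in the published validation of those
#' lists.
#'
#' @return A `crosstab` with groups South Asian, Chinese and General
#'   Population.
#' @export
reference_crosstab <- function() {
  path <- system.file("extdata", "ontario_validation_counts.csv",
                      package = "namecohort", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_crosstab(m)
}

# Collapse a k x k matrix to (TP, FP, FN, TN) for one target group.
collapse_2x2 <- function(m, target) {
  if (!target %in% rownames(m)) {
    stop("target group ", sQuote(target), " not among crosstab labels",
         call. = FALSE)
  }
  tp <- m[target, target]
  fp <- sum(m[target, ]) - tp
  fn <- sum(m[, target]) - tp
  tn <- sum(m) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

safe_ratio <- function(num, den) {
  if (den <= 0) NA_real_ else num / den
}

#' Diagnostic test characteristics of a surname list
#'
#' Collapses the k-by-k crosstab to a 2-by-2 table for one target group and
#' computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`.
#' A metric whose denominator is zero is reported as undefined (`NA`), never
#' as zero: a stratum with no predicted positives has no PPV.
#'
#' @param tab A `crosstab`.
#' @param target_group Group label to treat as positive.
#' @param weighted Use the weighted (`TRUE`, default) or unweighted counts.
#' @return An object of class `test_characteristics`: a list with the four
#'   metrics as raw proportions, the collapsed `counts`, per-metric
#'   denominators `n_effective`, the names of `undefined` metrics, and
#'   optional `ci`.
#' @examples
#' test_characteristics(reference_crosstab(), "South Asian",
#'                      weighted = FALSE)
#' @export
test_characteristics <- function(tab, target_group, weighted = TRUE) {
  stopifnot(inherits(tab, "crosstab"))
  m <- if (weighted) tab$weighted else tab$unweighted
  k <- collapse_2x2(m, target_group)
  metrics <- c(
    sensitivity = safe_ratio(k[["TP"]], k[["TP"]] + k[["FN"]]),
    specificity = safe_ratio(k[["TN"]], k[["TN"]] + k[["FP"]]),
    ppv         = safe_ratio(k[["TP"]], k[["TP"]] + k[["FP"]]),
    npv         = safe_ratio(k[["TN"]], k[["TN"]] + k[["FN"]])
  )
  new_test_characteristics(metrics, k, target_group, weighted)
}

new_test_characteristics <- function(metrics, counts, target_group,
                                     weighted) {
  denoms <- c(
    sensitivity = counts[["TP"]] + counts[["FN"]],
    specificity = counts[["TN"]] + counts[["FP"]],
    ppv         = counts[["TP"]] + counts[["FP"]],
    npv         = counts[["TN"]] + counts[["FN"]]
  )
  structure(
    list(
      target_group = target_group,
      weighted = weighted,
      counts = counts,
      sensitivity = metrics[["sensitivity"]],
      specificity = metrics[["specificity"]],
      ppv = metrics[["ppv"]],
      npv = metrics[["npv"]],
      n_effective = denoms,
      undefined = names(metrics)[is.na(metrics)],
      ci = NULL
    ),
    class = "test_characteristics"
  )
}

# Round half-up to `digits` decimals (printed tables use half-up percentages,
# while base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pct <- function(x) {
  ifelse(is.na(x), "undefined",
         sprintf("%.1f%%", round_half_up(100 * x, 1)))
}

#' @export
print.test_characteristics <- function(x, ...) {
  kind <- if (is.na(x$weighted)) " (expected, closed form)"
          else if (isTRUE(x$weighted)) " (weighted)" else " (unweighted)"
  cat("<test_characteristics> target ", sQuote(x$target_group), kind, "\n",
      sep = "")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-12s %s", m, format_pct(x[[m]])))
    if (!is.null(x$ci) && m %in% names(x$ci)) {
      cat(sprintf("  [%s, %s]", format_pct(x$ci[[m]][1]),
                  format_pct(x$ci[[m]][2])))
    }
    cat("\n")
  }
  invisible(x)
}

#' Test characteristics within strata
#'
#' Computes the four test characteristics independently within each level of
#' one stratification field (`sex`, `age_band` or `immigration`). Strata
#' with an empty denominator report that metric as undefined.
#'
#' @inheritParams cross_tabulate
#' @param stratify_by One of `"sex"`, `"age_band"`, `"immigration"`.
#' @param target_group Group label treated as positive.
#' @param weighted Use weighted counts (default `TRUE`).
#' @return Named list mapping each stratum level to a
#'   `test_characteristics` object.
#' @export
stratified_characteristics <- function(assignments, gold, respondents,
                                       stratify_by, target_group,
                                       weighted = TRUE) {
  ok <- c("sex", "age_band", "immigration")
  if (!is.character(stratify_by) || length(stratify_by) != 1L ||
      !stratify_by %in% ok) {
    stop("stratify_by must be one of ",
         paste(sQuote(ok), collapse = ", "), call. = FALSE)
  }
  levels <- unique(respondents[[stratify_by]])
  out <- lapply(levels, function(lv) {
    sub <- respondents[respondents[[stratify_by]] == lv, , drop = FALSE]
    tab <- cross_tabulate(assignments, gold, sub)
    if (!target_group %in% tab$labels) {
      # stratum contains neither predicted nor gold positives for the target
      empty <- stats::setNames(rep(NA_real_, 4),
                               c("sensitivity", "specificity", "ppv", "npv"))
      k <- c(TP = 0, FP = 0, FN = 0,
             TN = if (weighted) sum(sub$weight) else nrow(sub))
      tc <- new_test_characteristics(
        c(sensitivity = NA_real_, specificity = 1, ppv = NA_real_, npv = 1),
        k, target_group, weighted)
      return(tc)
    }
    test_characteristics(tab, target_group, weighted = weighted)
  })
  stats::setNames(out, levels)
}

#' Compare two surname-list collections against one gold standard
#'
#' Assigns the same roster under two collections and computes both sets of
#' test characteristics on identical respondents and weights, reporting the
#' metric differences (B minus A). This is how a revised list is judged
#' against the list it was derived from.
#'
#' @param collection_a,collection_b Two `list_collection`s valid on the
#'   roster.
#' @param roster Data frame `person_id`, `surname` covering all respondents.
#' @inheritParams stratified_characteristics
#' @return List with elements `a`, `b` (`test_characteristics`) and
#'   `difference` (named numeric, `b - a`).
#' @export
compare_lists <- function(collection_a, collection_b, roster, gold,
                          respondents, target_group, weighted = TRUE) {
  tc_for <- function(coll) {
    asg <- assign_roster(roster, coll)
    tab <- cross_tabulate(asg, gold, respondents)
    test_characteristics(tab, target_group, weighted = weighted)
  }
  a <- tc_for(collection_a)
  b <- tc_for(collection_b)
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  diff <- stats::setNames(
    vapply(metrics, function(m) b[[m]] - a[[m]], numeric(1)), metrics)
  list(a = a, b = b, difference = diff)
}

# Metric for one target group straight from per-respondent vectors; used by
# the bootstrap to avoid rebuilding full crosstabs per replicate.
metric_from_vectors <- function(pred, truth, w, target, metric) {
  pos_p <- pred == target
  pos_t <- truth == target
  tp <- sum(w[pos_p & pos_t]); fp <- sum(w[pos_p & !pos_t])
  fn <- sum(w[!pos_p & pos_t]); tn <- sum(w[!pos_p & !pos_t])
  switch(metric,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    ppv = safe_ratio(tp, tp + fp),
    npv = safe_ratio(tn, tn + fn)
  )
}

#' Percentile-bootstrap confidence interval for a test characteristic
#'
#' Resamples respondents with replacement (weights carried along with their
#' respondent: weights here are population-representation constants, not
#' sampling probabilities) and returns the percentile interval of the metric
#' over `B` replicates. Reproducible for a fixed `seed`.
#'
#' @inheritParams stratified_characteristics
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` with attribute `replicates`.
#' @export
bootstrap_ci <- function(assignments, gold, respondents, target_group,
                         metric = c("sensitivity", "specificity",
                                    "ppv", "npv"),
                         B = 1000, seed = 1, weighted = TRUE,
                         conf = 0.95) {
  metric <- match.arg(metric)
  stopifnot(B >= 1)
  ids <- respondents$person_id
  pred <- assignments$group[match(ids, assignments$person_id)]
  truth <- gold$group[match(ids, gold$person_id)]
  if (anyNA(pred) || anyNA(truth)) {
    stop("every respondent needs an assignment and a gold label",
         call. = FALSE)
  }
  w <- if (weighted) respondents$weight else rep(1, length(ids))
  n <- length(ids)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric_from_vectors(pred[idx], truth[idx], w[idx], target_group, metric)
  }, numeric(1))
  if (mean(is.na(reps)) > 0.5) {
    stop(metric, " undefined in more than half of the bootstrap ",
         "replicates; a larger sample is needed", call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(c(lower = ci[1], upper = ci[2]), replicates = reps)
}
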