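# Split a semicolon-delimited multi-response field into trimmed tokens.
split_responses <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(v) trimws(as.character(v))))
  }
  lapply(strsplit(as.character(x), ";", fixed = TRUE), trimws)
}

#' Resolve multi-response self-reported ethnicity into a gold-standard group
#'
#' The gold standard comes from two survey questions that both permit
#' multiple responses: one on ancestral ethnic groups and one on cultural or
#' racial background. A respondent triggers target group G when at least one
#' of the two questions carries exactly one (deduplicated) response and that
#' response equals G's token, compared case-insensitively. Respondents
#' triggering no target group — including anyone listing a target group among
#' several ancestries — fall to the residual default group. The two questions
#' are interchangeable ("either question"), so swapping the answer sets never
#' changes the result.
#'
#' Respondents who trigger two different target groups (one question a single
#' response of one token, the other a single response of another) are not
#' covered by per-group rules with a residual; by default they are assigned
#' the default label with a warning, the conservative reading that protects
#' positive predictive value. `conflict = "precedence"` instead assigns the
#' earliest triggered group in `target_groups` order.
#'
#' @param answers_ancestry,answers_background Multi-response answers: either
#'   character vectors of semicolon-delimited tokens or lists of character
#'   vectors, one element per respondent.
#' @param target_groups Ordered character vector of target-group tokens.
#' @param default_label Residual label.
#' @param conflict `"default"` or `"precedence"`.
#' @return Character vector of group labels, one per respondent.
#' @examples
#' resolve_self_report("Scottish", "Chinese", c("South Asian", "Chinese"))
#' resolve_self_report("Scottish;South Asian", "White",
#'                     c("South Asian", "Chinese"))
#' @export
resolve_self_report <- function(answers_ancestry, answers_background,
                                target_groups,
                                default_label = "General Population",
                                conflict = c("default", "precedence")) {
  conflict <- match.arg(conflict)
  a1 <- split_responses(answers_ancestry)
  a2 <- split_responses(answers_background)
  if (length(a1) != length(a2)) {
    stop("the two answer vectors must have the same length", call. = FALSE)
  }
  tg_lower <- tolower(target_groups)

  single_token <- function(ans) {
    # deduplicate case-insensitively before the single-response test:
    # a repeated identical answer is still one ethnic response
    ans <- ans[nzchar(ans)]
    uniq <- unique(tolower(ans))
    if (length(uniq) == 1L) uniq else NA_character_
  }

  s1 <- vapply(a1, single_token, character(1))
  s2 <- vapply(a2, single_token, character(1))
  triggered <- mapply(function(x, y) {
    hits <- tg_lower %in% c(x, y)
    which(hits)
  }, s1, s2, SIMPLIFY = FALSE)

  n_hit <- lengths(triggered)
  out <- rep(default_label, length(a1))
  one <- n_hit == 1L
  out[one] <- target_groups[unlist(triggered[one])]
  multi <- n_hit > 1L
  if (any(multi)) {
    if (conflict == "precedence") {
      out[multi] <- target_groups[vapply(triggered[multi], min, integer(1))]
    } else {
      warning(sum(multi), " respondent(s) triggered more than one target ",
              "group; assigned to ", sQuote(default_label), call. = FALSE)
    }
  }
  out
}

#' Resolve a survey table into gold-standard labels
#'
#' Convenience wrapper applying [resolve_self_report()] to a respondent data
#' frame of the survey schema.
#'
#' @param respondents Data frame with at least `person_id`, `q_ancestry`,
#'   `q_background`.
#' @inheritParams resolve_self_report
#' @return Data frame with columns `person_id`, `group`.
#' @export
resolve_survey <- function(respondents, target_groups,
                           default_label = "General Population",
                           conflict = c("default", "precedence")) {
  data.frame(
    person_id = respondents$person_id,
    group = resolve_self_report(respondents$q_ancestry,
                                respondents$q_background,
                                target_groups, default_label,
                                match.arg(conflict)),
    stringsAsFactors = FALSE
  )
}

#' Pool person-level weights across survey cycles
#'
#' A person-level weight is the number of population members a respondent
#' represents; one cycle's weights sum to the population. Combining several
#' cycles would count the population once per cycle, so each weight is
#' divided by the number of cycles pooled. All downstream test
#' characteristics are ratios of weighted sums, so they are invariant to this
#' global rescaling — pooling fixes the weighted totals, not the metrics.
#'
#' @param respondents Data frame with columns `cycle` and `weight`.
#' @param cycles Character vector of the cycle labels being combined; every
#'   respondent's cycle must be among them.
#' @return `respondents` with `weight` divided by `length(cycles)`.
#' @export
pool_weights <- function(respondents, cycles) {
  stopifnot(is.data.frame(respondents),
            all(c("cycle", "weight") %in% names(respondents)))
  outside <- setdiff(unique(respondents$cycle), cycles)
  if (length(outside)) {
    stop("respondent cycle(s) outside the declared set: ",
         paste(sQuote(outside), collapse = ", "), call. = FALSE)
  }
  respondents$weight <- respondents$weight / length(cycles)
  respondents
}

#' Read and write survey respondent files
#'
#' Survey files are UTF-8 CSV with header
#' `person_id,cycle,weight,q_ancestry,q_background,sex,age_band,immigration`;
#' multi-response answers are semicolon-delimited within their field.
#'
#' @param path File path.
#' @return `read_survey()`: data frame of that schema with numeric `weight`.
#' @export
read_survey <- function(path) {
  want <- c("person_id", "cycle", "weight", "q_ancestry", "q_background",
            "sex", "age_band", "immigration")
  head1 <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (gsub("[\"[:space:]]", "", head1) != paste(want, collapse = ",")) {
    stop("malformed survey header in ", sQuote(path), ": expected ",
         sQuote(paste(want, collapse = ",")), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  df$weight <- as.numeric(df$weight)
  if (any(!is.finite(df$weight) | df$weight <= 0)) {
    stop("survey weights must be positive numbers", call. = FALSE)
  }
  df
}

#' @rdname read_survey
#' @param respondents Survey data frame of the declared schema.
#' @export
write_survey <- function(respondents, path) {
  want <- c("person_id", "cycle", "weight", "q_ancestry", "q_background",
            "sex", "age_band", "immigration")
  utils::write.csv(respondents[want], path, row.names = FALSE)
  invisible(path)
}
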