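# Build the canonical-name -> group-label lookup for a collection.
# Refuses overlapping lists unless a precedence order is declared; with
# precedence, the earliest list in that order wins.
collection_lookup <- function(collection) {
  stopifnot(inherits(collection, "list_collection"))
  labels <- group_labels(collection)
  if (length(labels) >= 2L && !is_disjoint(collection) &&
      is.null(collection$precedence)) {
    overlap <- check_disjoint(collection)
    stop("surname lists overlap (", nrow(overlap), " shared name(s), e.g. ",
         paste(sQuote(utils::head(unique(overlap$name), 5L)),
               collapse = ", "),
         ") and no precedence order is declared; refusing to assign",
         call. = FALSE)
  }
  order <- if (is.null(collection$precedence)) labels else collection$precedence
  lookup <- character(0)
  for (lab in rev(order)) {  # earlier lists overwrite later ones
    nm <- collection$lists[[lab]]$names
    lookup[nm] <- lab
  }
  lookup
}

#' Assign one surname to an ethnic group
#'
#' Normalizes the surname and matches it by exact whole-name equality against
#' each list in the collection; a name on no list falls to the residual
#' default group. No prefix, substring or phonetic matching is done: exact
#' matching against deliberately screened lists is what keeps positive
#' predictive value high at the price of sensitivity. Unnormalizable input
#' (no letters) is assigned to the default group with a warning rather than
#' an error, so bulk runs never crash on a blank field.
#'
#' @param surname_raw Character vector of raw surnames.
#' @param collection A `list_collection`.
#' @return Character vector of group labels, one per surname.
#' @examples
#' assign_one(c("Patel", "Lee"), starter_collection())
#' @export
assign_one <- function(surname_raw, collection) {
  lookup <- collection_lookup(collection)
  assign_with_lookup(surname_raw, lookup, collection$default_label)
}

assign_with_lookup <- function(surname_raw, lookup, default_label) {
  canon <- normalize_quiet(surname_raw)
  n_bad <- sum(is.na(canon))
  if (n_bad > 0L) {
    warning(n_bad, " surname(s) could not be normalized; assigned to ",
            sQuote(default_label), call. = FALSE)
  }
  grp <- unname(lookup[canon])
  grp[is.na(grp)] <- default_label
  grp
}

#' Assign every roster record to an ethnic group
#'
#' Applies the surname lists to a population roster to produce the
#' surname-derived ethnic identification file: one `(person_id, group)` row
#' per roster record, in roster order, partitioning the whole roster across
#' the collection's groups plus the residual default group.
#'
#' @param roster Data frame with columns `person_id` (unique) and `surname`.
#' @param collection A `list_collection`.
#' @return Data frame with columns `person_id` and `group`, carrying
#'   attributes `counts` (named integer vector over every label, summing to
#'   `nrow(roster)`) and `n_unnormalizable`. Retrieve the counts with
#'   [group_counts()].
#' @export
assign_roster <- function(roster, collection) {
  stopifnot(is.data.frame(roster),
            all(c("person_id", "surname") %in% names(roster)))
  if (anyDuplicated(roster$person_id)) {
    dup <- unique(roster$person_id[duplicated(roster$person_id)])
    stop("duplicate person_id in roster: ",
         paste(sQuote(utils::head(dup, 5L)), collapse = ", "),
         call. = FALSE)
  }
  lookup <- collection_lookup(collection)
  canon <- normalize_quiet(roster$surname)
  n_bad <- sum(is.na(canon))
  grp <- unname(lookup[canon])
  grp[is.na(grp)] <- collection$default_label
  if (n_bad > 0L) {
    warning(n_bad, " surname(s) could not be normalized; assigned to ",
            sQuote(collection$default_label), call. = FALSE)
  }
  counts <- vapply(all_labels(collection), function(l) sum(grp == l),
                   integer(1))
  out <- data.frame(person_id = roster$person_id, group = grp,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  attr(out, "n_unnormalizable") <- n_bad
  out
}

#' @rdname assign_roster
#' @param assignments The result of `assign_roster()`.
#' @export
group_counts <- function(assignments) {
  attr(assignments, "counts")
}

#' Rank surnames by frequency within each assigned group
#'
#' Reproduces, for any roster, the computation behind a "most common
#' surnames per group" table: assign every record, then count canonical
#' surnames within each group, sorted by descending count with lexicographic
#' tie-break.
#'
#' @param roster Data frame with columns `person_id`, `surname`.
#' @param collection A `list_collection`.
#' @return Named list (one element per group label, including the default
#'   group) of data frames with columns `name`, `count`.
#' @export
surname_frequency <- function(roster, collection) {
  labels <- all_labels(collection)
  if (!nrow(roster)) {
    empty <- data.frame(name = character(), count = integer(),
                        stringsAsFactors = FALSE)
    return(stats::setNames(rep(list(empty), length(labels)), labels))
  }
  lookup <- collection_lookup(collection)
  canon <- normalize_quiet(roster$surname)
  grp <- unname(lookup[canon])
  grp[is.na(grp)] <- collection$default_label
  out <- lapply(labels, function(l) {
    nm <- canon[grp == l & !is.na(canon)]
    if (!length(nm)) {
      return(data.frame(name = character(), count = integer(),
                        stringsAsFactors = FALSE))
    }
    tab <- table(nm)
    df <- data.frame(name = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$name), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  stats::setNames(out, labels)
}

#' Read and write population roster files
#'
#' Rosters are CSV files with header `person_id,surname`, standing in for a
#' health-registry extract of identifiers and surnames. Assignments are
#' written as `person_id,group`.
#'
#' @param path File path.
#' @return `read_roster()`: data frame with columns `person_id`, `surname`.
#' @export
read_roster <- function(path) {
  head1 <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (gsub("\\s", "", head1) != "person_id,surname") {
    stop("malformed roster header in ", sQuote(path),
         ": expected 'person_id,surname'", call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", encoding = "UTF-8")
}

#' @rdname read_roster
#' @param assignments Data frame from [assign_roster()].
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments[c("person_id", "group")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
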