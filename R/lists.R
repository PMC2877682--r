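#' Build a surname list from raw names
#'
#' A surname list is the classifier's entire model for one ethnic group: a
#' duplicate-free set of canonical surnames plus a group label. Raw names are
#' normalized with [normalize_surname()] and collapsed to unique canonical
#' forms, so "Wong", "WONG" and "wong" contribute a single entry.
#'
#' @param raw_names Character vector of raw surnames (non-empty).
#' @param group_label Single string naming the ethnic group the list detects.
#' @param provenance Optional character vector of free-text notes recording
#'   where the names came from and what was done to them.
#' @return An object of class `surname_list` with fields `group_label`,
#'   `names` (sorted canonical surnames), `provenance`, `n_input` and
#'   `n_unique`.
#' @examples
#' build_list(c("Wong", "WONG", "wong"), "Chinese")
#' @export
build_list <- function(raw_names, group_label, provenance = character()) {
  stopifnot(is.character(group_label), length(group_label) == 1L,
            nzchar(group_label))
  if (length(raw_names) == 0L) {
    stop("`raw_names` must contain at least one name", call. = FALSE)
  }
  canon <- normalize_quiet(raw_names)
  bad <- is.na(canon)
  if (any(bad)) {
    stop(
      "unnormalizable name(s) in input for group ", sQuote(group_label), ": ",
      paste(sQuote(raw_names[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  uniq <- sort(unique(canon))
  new_surname_list(uniq, group_label, provenance,
                   n_input = length(raw_names))
}

new_surname_list <- function(names, group_label, provenance, n_input) {
  structure(
    list(
      group_label = group_label,
      names = names,
      provenance = as.character(provenance),
      n_input = n_input,
      n_unique = length(names)
    ),
    class = "surname_list"
  )
}

#' @export
length.surname_list <- function(x) length(x$names)

#' @export
print.surname_list <- function(x, ...) {
  cat("<surname_list> ", x$group_label, ": ", x$n_unique,
      " unique canonical surnames (from ", x$n_input, " input names)\n",
      sep = "")
  show <- utils::head(x$names, 8L)
  cat("  ", paste(show, collapse = ", "),
      if (x$n_unique > 8L) ", ..." else "", "\n", sep = "")
  for (p in x$provenance) cat("  note: ", p, "\n", sep = "")
  invisible(x)
}

#' Remove an exclusion set from a candidate surname list
#'
#' Screening is how uniqueness is enforced: candidate names judged not to be
#' unique to the target group are removed wholesale. The result keeps the
#' candidate list's label and gains a provenance note recording how many
#' names were removed. Conservation holds by construction:
#' `length(candidates) == length(result) + |candidates ∩ exclusions|`.
#'
#' @param candidates A `surname_list` of candidate names.
#' @param exclusions Character vector of canonical surnames to remove.
#' @return A `surname_list` with the exclusions removed.
#' @export
screen_exclusions <- function(candidates, exclusions) {
  stopifnot(inherits(candidates, "surname_list"))
  exclusions <- as.character(exclusions)
  if (length(exclusions) && !all(is_canonical(exclusions))) {
    bad <- exclusions[!is_canonical(exclusions)]
    stop("exclusions must be canonical surnames; offending: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  kept <- setdiff(candidates$names, exclusions)
  n_removed <- length(candidates$names) - length(kept)
  if (length(kept) == 0L) {
    stop("screening removed every candidate name; a usable list must ",
         "retain at least one surname", call. = FALSE)
  }
  new_surname_list(
    kept, candidates$group_label,
    c(candidates$provenance,
      sprintf("screened: removed %d of %d candidate names",
              n_removed, length(candidates$names))),
    n_input = candidates$n_input
  )
}

#' Bundle surname lists into a classification collection
#'
#' A collection is an ordered set of surname lists with distinct group labels
#' plus a residual default label for everyone matched by no list. Roster
#' assignment refuses to run on a collection whose lists overlap unless a
#' precedence order is declared, because silent precedence would corrupt the
#' positive-predictive-value semantics of uniquely identifying lists.
#'
#' @param ... `surname_list` objects (or a single list of them).
#' @param default_label Label for the residual group.
#' @param precedence Optional character vector of group labels; when lists
#'   overlap, a name is assigned to the earliest list in this order that
#'   contains it.
#' @return An object of class `list_collection`.
#' @seealso [check_disjoint()]
#' @export
list_collection <- function(..., default_label = "General Population",
                            precedence = NULL) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1L]], "surname_list")) {
    lists <- lists[[1L]]
  }
  if (!length(lists) || !all(vapply(lists, inherits, logical(1), "surname_list"))) {
    stop("supply one or more surname_list objects", call. = FALSE)
  }
  labels <- vapply(lists, `[[`, character(1), "group_label")
  if (anyDuplicated(labels)) {
    stop("group labels must be distinct; duplicated: ",
         paste(sQuote(unique(labels[duplicated(labels)])), collapse = ", "),
         call. = FALSE)
  }
  if (default_label %in% labels) {
    stop("default_label ", sQuote(default_label),
         " collides with a group label", call. = FALSE)
  }
  if (!is.null(precedence)) {
    if (!setequal(precedence, labels)) {
      stop("precedence must be a permutation of the group labels",
           call. = FALSE)
    }
  }
  names(lists) <- labels
  structure(
    list(lists = lists, default_label = default_label,
         precedence = precedence),
    class = "list_collection"
  )
}

#' @export
print.list_collection <- function(x, ...) {
  cat("<list_collection> ", length(x$lists), " lists; default group ",
      sQuote(x$default_label), "\n", sep = "")
  for (l in x$lists) {
    cat("  ", l$group_label, ": ", l$n_unique, " surnames\n", sep = "")
  }
  if (!is.null(x$precedence)) {
    cat("  precedence: ", paste(x$precedence, collapse = " > "), "\n",
        sep = "")
  }
  invisible(x)
}

group_labels <- function(collection) {
  names(collection$lists)
}

all_labels <- function(collection) {
  c(group_labels(collection), collection$default_label)
}

#' Report surnames shared between lists of a collection
#'
#' Uniqueness of each list is the design principle the screening step exists
#' to enforce; this reports every violation. A name appearing on two or more
#' lists is listed once per offending list pair.
#'
#' @param collection A `list_collection` with at least two lists.
#' @return A data frame with columns `list_a`, `list_b`, `name`, one row per
#'   shared name per list pair; zero rows iff the lists are pairwise
#'   disjoint.
#' @export
check_disjoint <- function(collection) {
  stopifnot(inherits(collection, "list_collection"))
  labels <- group_labels(collection)
  if (length(labels) < 2L) {
    stop("check_disjoint needs a collection of at least two lists",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(length(labels) - 1L)) {
    for (j in seq(i + 1L, length(labels))) {
      shared <- intersect(collection$lists[[i]]$names,
                          collection$lists[[j]]$names)
      if (length(shared)) {
        out[[length(out) + 1L]] <- data.frame(
          list_a = labels[i], list_b = labels[j], name = sort(shared),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(list_a = character(), list_b = character(),
               name = character(), stringsAsFactors = FALSE)
  }
}

is_disjoint <- function(collection) {
  nrow(check_disjoint(collection)) == 0L
}

#' Read and write surname list files
#'
#' Two plain-text formats are supported, chosen by file extension. `.txt`
#' files carry one surname per line with `#`-prefixed comment lines ignored;
#' the group label must then be supplied by the caller (or is recorded in a
#' `# group:` comment when written by [write_list_file()]). `.csv` files
#' carry a `name,group` header and must contain a single group. Files are
#' UTF-8; names are normalized on read, so a round trip through
#' `write_list_file()` then `read_list_file()` reproduces the list exactly.
#'
#' @param path File path ending in `.txt` or `.csv`.
#' @param group_label Group label for `.txt` files without a `# group:`
#'   comment; ignored for `.csv`.
#' @return `read_list_file()` returns a `surname_list`;
#'   `write_list_file()` returns `path` invisibly.
#' @export
read_list_file <- function(path, group_label = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "txt") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    grp_line <- grep("^#\\s*group:", lines, value = TRUE)
    if (is.null(group_label) && length(grp_line)) {
      group_label <- trimws(sub("^#\\s*group:", "", grp_line[1L]))
    }
    names <- trimws(grep("^\\s*#", lines, value = TRUE, invert = TRUE))
    names <- names[nzchar(names)]
    if (!length(names)) {
      stop("list file ", sQuote(path), " contains no surnames",
           call. = FALSE)
    }
    if (is.null(group_label)) {
      stop("supply `group_label` for one-name-per-line files without a ",
           "'# group:' comment", call. = FALSE)
    }
    build_list(names, group_label,
               provenance = sprintf("read from %s", basename(path)))
  } else if (ext == "csv") {
    head1 <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
    if (gsub("\\s", "", head1) != "name,group") {
      stop("malformed CSV header in ", sQuote(path),
           ": expected 'name,group'", call. = FALSE)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    if (!nrow(df)) {
      stop("list file ", sQuote(path), " contains no surnames",
           call. = FALSE)
    }
    grp <- unique(df$group)
    if (length(grp) != 1L) {
      stop("CSV list file must contain a single group; found: ",
           paste(sQuote(grp), collapse = ", "), call. = FALSE)
    }
    build_list(df$name, grp,
               provenance = sprintf("read from %s", basename(path)))
  } else {
    stop("unknown list-file extension ", sQuote(ext),
         "; use .txt or .csv", call. = FALSE)
  }
}

#' @rdname read_list_file
#' @param x A `surname_list` to write.
#' @export
write_list_file <- function(x, path) {
  stopifnot(inherits(x, "surname_list"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "txt") {
    writeLines(
      c(sprintf("# group: %s", x$group_label),
        sprintf("# %s", x$provenance),
        x$names),
      path, useBytes = TRUE
    )
  } else if (ext == "csv") {
    utils::write.csv(
      data.frame(name = x$names, group = x$group_label,
                 stringsAsFactors = FALSE),
      path, row.names = FALSE, quote = FALSE
    )
  } else {
    stop("unknown list-file extension ", sQuote(ext),
         "; use .txt or .csv", call. = FALSE)
  }
  invisible(path)
}

#' Packaged starter surname lists
#'
#' The package ships the 200 most common surnames from the Ontario South
#' Asian and Chinese lists, and the 200 most common general-population
#' surnames in Ontario, as plain-text fixtures. `starter_list()` loads one of
#' them; `starter_collection()` bundles the two minority lists into a ready
#' classification collection. The general-population fixture is not a
#' classification list (the residual group needs none) but is used by the
#' survey simulator to emit realistic off-list surnames.
#'
#' @param group One of `"South Asian"`, `"Chinese"`, `"General Population"`.
#' @return `starter_list()`: a `surname_list` of 200 names;
#'   `starter_collection()`: a `list_collection` of the two minority lists.
#' @examples
#' starter_collection()
#' @export
starter_list <- function(group = c("South Asian", "Chinese",
                                   "General Population")) {
  group <- match.arg(group)
  file <- switch(group,
    "South Asian" = "southasian_top200.txt",
    "Chinese" = "chinese_top200.txt",
    "General Population" = "general_top200.txt"
  )
  path <- system.file("extdata", file, package = "namecohort",
                      mustWork = TRUE)
  read_list_file(path, group_label = group)
}

#' @rdname starter_list
#' @export
starter_collection <- function() {
  list_collection(starter_list("South Asian"), starter_list("Chinese"))
}

#' Printed Ontario frequencies of the ten most common names per group
#'
#' Frequencies of the ten most common surnames in each group among Ontario
#' residents, as published with the starter lists. The simulator extends
#' these with a Zipf tail to weight name emission across all 200 names.
#'
#' @return Data frame with columns `name`, `group`, `ontario_count`.
#' @export
ontario_name_counts <- function() {
  path <- system.file("extdata", "ontario_top10_counts.csv",
                      package = "namecohort", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df$name <- normalize_surname(df$name)
  df
}
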