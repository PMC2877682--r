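#' Normalize a raw surname to canonical form
#'
#' Canonical form is the key on which all list membership and roster matching
#' operates: uppercase basic Latin letters, with internal single spaces and
#' hyphens permitted. The pipeline is: compatibility transliteration to ASCII
#' (diacritics folded, so "Bélanger" becomes "BELANGER"), uppercasing, removal
#' of apostrophes and periods (so "D'Souza" becomes "DSOUZA", not "D SOUZA"),
#' replacement of any remaining non-letter character by a space, collapsing of
#' whitespace runs, and trimming. Hyphens are kept, so compound surnames stay
#' distinct from their components.
#'
#' Normalization is deterministic and idempotent: applying it to an already
#' canonical surname returns it unchanged.
#'
#' @param raw Character vector of raw surnames.
#' @return Character vector of canonical surnames, same length as `raw`.
#' @examples
#' normalize_surname(c("Patel", "D'Souza  ", "da  Silva"))
#' @export
normalize_surname <- function(raw) {
  if (!is.character(raw)) {
    stop("`raw` must be a character vector", call. = FALSE)
  }
  out <- normalize_quiet(raw)
  bad <- is.na(out)
  if (any(bad)) {
    stop(
      "unnormalizable name(s): no letters remain after cleaning: ",
      paste(sQuote(raw[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Non-erroring normalization used by bulk paths: unnormalizable -> NA.
normalize_quiet <- function(raw) {
  x <- stringi::stri_trans_general(raw, "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("[.'’]", "", x)
  x <- gsub("[^A-Z -]", " ", x)
  x <- gsub("-{2,}", "-", x)
  x <- gsub(" +", " ", trimws(x))
  x <- gsub("^-+|-+$", "", x)
  x[is.na(raw) | !grepl("[A-Z]", x)] <- NA_character_
  x
}

is_canonical <- function(x) {
  !is.na(x) & x == vapply(x, function(s) {
    n <- normalize_quiet(s)
    if (is.na(n)) "" else n
  }, character(1))
}
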