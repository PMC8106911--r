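#' Keyword specification for selecting lysogeny-associated domains
#'
#' The default specification is the curated search strategy for domains
#' mechanistically involved in lysogeny: six whole-word terms matched
#' case-insensitively as substrings of the domain description
#' (`integrase`, `excisionase`, `recombinase`, `transposase`, `lysogen`,
#' `temperate`), plus a case-sensitive term for plasmid/phage partitioning
#' proteins, `parA |ParA |parB |ParB` — each alternative carries its
#' trailing space because the bare four-letter strings collide with common
#' English words (e.g. "separate", "apparatus").
#'
#' @param terms Character vector of search patterns. Alternatives within
#'   one term are separated by `|` and matched as fixed substrings.
#' @param case_sensitive Logical vector (recycled) saying whether each term
#'   matches case-sensitively.
#' @return A tibble with columns `term` and `case_sensitive`.
#' @export
keyword_spec <- function(terms, case_sensitive = FALSE) {
  stopifnot(is.character(terms), length(terms) > 0)
  tibble(
    term = terms,
    case_sensitive = rep_len(as.logical(case_sensitive), length(terms))
  )
}

#' @rdname keyword_spec
#' @export
lysogeny_keywords <- function() {
  dplyr::bind_rows(
    keyword_spec(c(
      "integrase", "excisionase", "recombinase",
      "transposase", "lysogen", "temperate"
    )),
    keyword_spec("parA |ParA |parB |ParB", case_sensitive = TRUE)
  )
}

# Which descriptions match one term (alternatives are fixed substrings).
term_matches <- function(descriptions, term, case_sensitive) {
  alts <- strsplit(term, "|", fixed = TRUE)[[1]]
  hit <- rep(FALSE, length(descriptions))
  subject <- if (case_sensitive) descriptions else tolower(descriptions)
  for (alt in alts) {
    pat <- if (case_sensitive) alt else tolower(alt)
    hit <- hit | grepl(pat, subject, fixed = TRUE)
  }
  hit
}

#' Select domain profiles whose description matches a keyword spec
#'
#' Returns the profiles (in input order, each at most once) whose
#' description matches at least one term of `keywords`.
#'
#' @param profiles A data frame with columns `accession` and `description`;
#'   one row per domain profile.
#' @param keywords A keyword spec from [keyword_spec()] /
#'   [lysogeny_keywords()].
#' @return The matching rows of `profiles`, as a tibble.
#' @export
keyword_select <- function(profiles, keywords = lysogeny_keywords()) {
  stopifnot(
    is.data.frame(profiles),
    all(c("accession", "description") %in% names(profiles))
  )
  if (anyDuplicated(profiles$accession)) {
    abort("duplicated accessions in `profiles`")
  }
  hit <- rep(FALSE, nrow(profiles))
  for (i in seq_len(nrow(keywords))) {
    hit <- hit | term_matches(
      profiles$description, keywords$term[[i]], keywords$case_sensitive[[i]]
    )
  }
  as_tibble(profiles[hit, , drop = FALSE])
}

#' Per-term match counts over a set of domain descriptions
#'
#' Counts, for each search term, how many domain descriptions contain it.
#' A description containing several terms is counted once per term, so
#' counts may sum to more than the number of domains.
#'
#' @inheritParams keyword_select
#' @return A tibble with columns `term` and `n_domains`.
#' @export
count_terms <- function(profiles, keywords = lysogeny_keywords()) {
  tibble(
    term = keywords$term,
    n_domains = map_int(seq_len(nrow(keywords)), function(i) {
      sum(term_matches(
        profiles$description, keywords$term[[i]], keywords$case_sensitive[[i]]
      ))
    })
  )
}
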