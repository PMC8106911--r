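#' Assemble a labeled presence/absence dataset
#'
#' Joins per-genome presence vectors with lifestyle labels into the tidy
#' labeled dataset used for training and evaluation: one row per genome,
#' columns `genome_id`, `lifestyle`, then one 0/1 column per domain
#' accession (in presence-matrix column order). Row order follows the
#' input presence rows. Every genome must carry exactly one label.
#'
#' @param presence Wide presence tibble from [build_presence_matrix()]
#'   (column `genome_id` plus 0/1 accession columns).
#' @param labels Data frame with columns `genome_id` and `lifestyle`
#'   (values `"virulent"` or `"temperate"`).
#' @return A labeled dataset tibble.
#' @export
assemble_dataset <- function(presence, labels) {
  stopifnot(
    is.data.frame(presence), "genome_id" %in% names(presence),
    is.data.frame(labels),
    all(c("genome_id", "lifestyle") %in% names(labels))
  )
  if (anyDuplicated(labels$genome_id)) {
    abort(sprintf(
      "duplicated labels for genome(s): %s",
      paste(unique(labels$genome_id[duplicated(labels$genome_id)]), collapse = ", ")
    ))
  }
  missing <- setdiff(presence$genome_id, labels$genome_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "no label for genome(s): %s", paste(missing, collapse = ", ")
    ))
  }
  lifestyle <- as_lifestyle(
    labels$lifestyle[match(presence$genome_id, labels$genome_id)]
  )
  check_binary_features(presence[setdiff(names(presence), "genome_id")])
  dplyr::bind_cols(
    tibble(
      genome_id = presence$genome_id,
      lifestyle = as.character(lifestyle)
    ),
    presence[setdiff(names(presence), "genome_id")]
  )
}

dataset_accessions <- function(dataset) {
  setdiff(names(dataset), c("genome_id", "lifestyle"))
}

dataset_features <- function(dataset) {
  m <- as.matrix(dataset[dataset_accessions(dataset)])
  storage.mode(m) <- "numeric"
  m
}

check_binary_features <- function(df) {
  vals <- unlist(df, use.names = FALSE)
  if (length(vals) > 0 && (anyNA(vals) || !all(vals %in% c(0, 1)))) {
    abort("feature values must all be 0 or 1 (presence/absence)")
  }
  invisible(df)
}

#' Filter domains by training-set prevalence
#'
#' Applies the two training-set filters that condense a keyword-selected
#' domain list to the putatively useful set: a domain (column) is dropped
#' if it is present in `min_genomes - 1` or fewer training genomes
#' (default: two or fewer, counting both classes), or if its
#' class-conditional prevalence *fraction* is strictly greater among
#' virulent than among temperate genomes (a domain more prevalent among
#' virulent phages cannot be evidence of lysogeny). Equal fractions retain
#' the domain. Fractions, not raw counts, are compared because the classes
#' are generally unbalanced. The two rules commute, so their order does
#' not matter.
#'
#' @param dataset A labeled dataset from [assemble_dataset()]; must be the
#'   training split only and contain both classes.
#' @param min_genomes Minimum number of genomes a domain must be present
#'   in to be retained (inclusive, default 3).
#' @return A tibble of surviving domains in original column order, with
#'   columns `accession`, `n_present`, `prev_temperate`, `prev_virulent`.
#' @export
prevalence_filter <- function(dataset, min_genomes = 3) {
  lifestyle <- as_lifestyle(dataset$lifestyle, arg = "dataset$lifestyle")
  n_by_class <- table(lifestyle)
  if (any(n_by_class == 0)) {
    abort("`dataset` must contain both lifestyles; prevalence comparison is undefined for a single class")
  }
  feats <- dataset_features(dataset)
  check_binary_features(as.data.frame(feats))
  is_temp <- lifestyle == "temperate"
  n_present <- colSums(feats)
  prev_t <- colSums(feats[is_temp, , drop = FALSE]) / sum(is_temp)
  prev_v <- colSums(feats[!is_temp, , drop = FALSE]) / sum(!is_temp)
  keep <- n_present >= min_genomes & prev_v <= prev_t
  tibble(
    accession = colnames(feats)[keep],
    n_present = as.integer(n_present[keep]),
    prev_temperate = unname(prev_t[keep]),
    prev_virulent = unname(prev_v[keep])
  )
}

#' Restrict a labeled dataset to a domain subset
#'
#' @param dataset A labeled dataset.
#' @param accessions Character vector (or a tibble with an `accession`
#'   column, e.g. the result of [prevalence_filter()]) of domains to keep.
#' @return The dataset with only the requested feature columns, in the
#'   requested order.
#' @export
select_domains <- function(dataset, accessions) {
  if (is.data.frame(accessions)) {
    accessions <- accessions$accession
  }
  missing <- setdiff(accessions, dataset_accessions(dataset))
  if (length(missing) > 0) {
    abort(sprintf(
      "domain(s) not in dataset: %s", paste(missing, collapse = ", ")
    ))
  }
  out <- dataset[c("genome_id", "lifestyle", accessions)]
  attr(out, "partition") <- attr(dataset, "partition", exact = TRUE)
  out
}
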