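kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    abort(sprintf("sequence shorter than k = %d", k))
  }
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Estimate pairwise genome similarity by k-mer containment
#'
#' A lightweight, deterministic stand-in for whole-genome average
#' nucleotide identity: `coverage` is the fraction of the smaller
#' genome's distinct k-mers (the genome with the smaller distinct k-mer
#' set) that also occur in the other genome (containment), and
#' `identity` is the standard k-mer-to-identity transform
#' `containment^(1/k)` — the per-base identity that would, under
#' independent substitutions, preserve that fraction of k-mers.
#'
#' @param a,b One-row data frames (or lists) with `genome_id` and `seq`.
#' @param k K-mer size (default 16).
#' @return A one-row tibble: `id_a`, `id_b`, `identity`, `coverage`.
#' @export
estimate_similarity <- function(a, b, k = 16) {
  ka <- kmer_set(toupper(a$seq[[1]]), k)
  kb <- kmer_set(toupper(b$seq[[1]]), k)
  if (length(ka) <= length(kb)) {
    containment <- mean(ka %in% kb)
  } else {
    containment <- mean(kb %in% ka)
  }
  tibble(
    id_a = a$genome_id[[1]], id_b = b$genome_id[[1]],
    identity = containment^(1 / k),
    coverage = containment
  )
}

#' Are two genomes phylogenetically related?
#'
#' Relatedness uses the stringent criterion of more than 80% sequence
#' identity across more than 80% of the genome: both inequalities are
#' strict, so identity exactly at the threshold does not make a pair
#' related.
#'
#' @param pair A similarity tibble (columns `identity`, `coverage`), e.g.
#'   from [estimate_similarity()]; may have several rows.
#' @param id_threshold,cov_threshold Strict lower bounds (default 0.8).
#' @return Logical vector, one element per row of `pair`.
#' @export
related <- function(pair, id_threshold = 0.8, cov_threshold = 0.8) {
  pair$identity > id_threshold & pair$coverage > cov_threshold
}

#' Phylogenetically independent test subset
#'
#' Returns the test genomes with no relative in the training set: a test
#' genome is excluded as soon as any single training genome is related to
#' it (single linkage). Similarities are computed with the internal k-mer
#' containment estimator unless a precomputed pairwise table is supplied
#' (columns `id_a`, `id_b`, `identity`, `coverage`; unordered pairs), in
#' which case missing pairs are treated as unrelated.
#'
#' @param genomes Genome tibble (`genome_id`, `seq`) covering all ids.
#' @param train_ids,test_ids Disjoint character vectors of genome ids.
#' @param k K-mer size for the internal estimator.
#' @param id_threshold,cov_threshold Relatedness thresholds (strict).
#' @param similarities Optional precomputed pairwise similarity table.
#' @return Character vector of independent test ids, in `test_ids` order.
#' @export
independent_test_subset <- function(genomes, train_ids, test_ids, k = 16,
                                    id_threshold = 0.8, cov_threshold = 0.8,
                                    similarities = NULL) {
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort("`train_ids` and `test_ids` must be disjoint")
  }
  lookup <- function(test_id, train_id) {
    if (!is.null(similarities)) {
      hit <- similarities[
        (similarities$id_a == test_id & similarities$id_b == train_id) |
          (similarities$id_a == train_id & similarities$id_b == test_id), ,
        drop = FALSE
      ]
      if (nrow(hit) == 0) {
        return(FALSE)
      }
      return(any(related(hit, id_threshold, cov_threshold)))
    }
    a <- genomes[genomes$genome_id == test_id, , drop = FALSE]
    b <- genomes[genomes$genome_id == train_id, , drop = FALSE]
    related(estimate_similarity(a, b, k), id_threshold, cov_threshold)
  }
  keep <- map_lgl(test_ids, function(tid) {
    !any(map_lgl(train_ids, function(rid) lookup(tid, rid)))
  })
  test_ids[keep]
}
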