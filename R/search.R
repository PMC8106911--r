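#' Search backends for domain detection
#'
#' A search backend takes a table of translation products and reports
#' candidate domain hits (one row per product x domain detection). Two
#' backends are provided:
#'
#' * `motif_backend(motif_table)` — exact amino-acid substring match
#'   against a table of diagnostic motifs (columns `accession`, `motif`).
#'   Used by the synthetic fixtures; a match is reported with a nominal
#'   E-value of `1e-30` and score 100 so it always clears any reasonable
#'   significance threshold.
#' * `hmmer_backend(hmm_db)` — runs the external `hmmsearch` executable
#'   (HMMER 3) against a profile-HMM database file and parses its
#'   per-target tabular output. Profile names in the database must be the
#'   domain accessions.
#'
#' @param motif_table Data frame with columns `accession` and `motif`
#'   (amino-acid substrings).
#' @param hmm_db Path to a HMMER3 profile database (e.g. built with
#'   [build_hmm_db()]).
#' @param hmmsearch Name or path of the `hmmsearch` executable.
#' @return A backend object for [search_products()].
#' @export
motif_backend <- function(motif_table) {
  stopifnot(
    is.data.frame(motif_table),
    all(c("accession", "motif") %in% names(motif_table))
  )
  structure(
    list(motif_table = as_tibble(motif_table)),
    class = c("motif_backend", "search_backend")
  )
}

#' @rdname motif_backend
#' @export
hmmer_backend <- function(hmm_db, hmmsearch = "hmmsearch") {
  if (!file.exists(hmm_db)) {
    abort(sprintf("profile database not found: '%s'", hmm_db))
  }
  structure(
    list(hmm_db = hmm_db, hmmsearch = hmmsearch),
    class = c("hmmer_backend", "search_backend")
  )
}

empty_hits <- function() {
  tibble(
    domain_accession = character(), genome_id = character(),
    frame = integer(), start_nt = integer(),
    evalue = numeric(), score = numeric()
  )
}

run_backend <- function(backend, products) {
  UseMethod("run_backend")
}

#' @export
run_backend.motif_backend <- function(backend, products) {
  mt <- backend$motif_table
  hits <- purrr::map(seq_len(nrow(mt)), function(i) {
    found <- stringr::str_detect(
      products$aa_seq, stringr::fixed(mt$motif[[i]])
    )
    if (!any(found)) {
      return(NULL)
    }
    tibble(
      domain_accession = mt$accession[[i]],
      genome_id = products$genome_id[found],
      frame = products$frame[found],
      start_nt = products$start_nt[found],
      evalue = 1e-30,
      score = 100
    )
  })
  dplyr::bind_rows(c(list(empty_hits()), hits))
}

#' @export
run_backend.hmmer_backend <- function(backend, products) {
  if (Sys.which(backend$hmmsearch) == "" && !file.exists(backend$hmmsearch)) {
    abort(sprintf(
      "search backend executable '%s' not found on PATH; install HMMER 3 or use motif_backend()",
      backend$hmmsearch
    ))
  }
  if (nrow(products) == 0) {
    return(empty_hits())
  }
  fa <- tempfile(fileext = ".faa")
  tbl <- tempfile(fileext = ".tblout")
  on.exit(unlink(c(fa, tbl)), add = TRUE)
  write_products_fasta(products, fa)
  status <- system2(
    backend$hmmsearch,
    c("--tblout", tbl, "--noali", "-E", "10", backend$hmm_db, fa),
    stdout = FALSE, stderr = FALSE
  )
  if (status != 0) {
    abort(sprintf("'%s' exited with status %d", backend$hmmsearch, status))
  }
  parse_hmmer_tblout(tbl)
}

#' Parse HMMER3 per-target tabular output (tblout)
#'
#' Parses the `--tblout` format of `hmmsearch`: comment lines (leading
#' `#`) are skipped and the whitespace-delimited fields target name, query
#' name, full-sequence E-value and full-sequence bit score are extracted.
#' Target names are expected to be product headers of the form
#' `genome_id|frame|start_nt` (as written by [write_products_fasta()]);
#' query names are domain accessions.
#'
#' @param path Path to a tblout file.
#' @return A hit tibble with columns `domain_accession`, `genome_id`,
#'   `frame`, `start_nt`, `evalue`, `score`.
#' @export
parse_hmmer_tblout <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("tblout file not found: '%s'", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(empty_hits())
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  short <- lengths(fields) < 6L
  if (any(short)) {
    abort(sprintf(
      "malformed tblout line %d: fewer than 6 fields", lineno[short][1]
    ))
  }
  target <- map_chr(fields, 1)
  query <- map_chr(fields, 3)
  ev_chr <- map_chr(fields, 5)
  sc_chr <- map_chr(fields, 6)
  evalue <- suppressWarnings(as.numeric(ev_chr))
  score <- suppressWarnings(as.numeric(sc_chr))
  bad <- is.na(evalue) | is.na(score)
  if (any(bad)) {
    abort(sprintf(
      "malformed tblout line %d: non-numeric E-value or score ('%s', '%s')",
      lineno[bad][1], ev_chr[bad][1], sc_chr[bad][1]
    ))
  }
  dplyr::bind_cols(
    tibble(domain_accession = query),
    parse_product_header(target),
    tibble(evalue = evalue, score = score)
  )
}

#' Search translation products for domains of a domain set
#'
#' Runs a search backend over the products and returns all hits with
#' full-sequence E-value at or below `evalue_threshold`. Hits reported by
#' the backend for accessions not in `domain_set` are dropped with a
#' warning. One row is kept per (product, domain) detection, so a domain
#' hit on several products yields several rows; presence/absence collapses
#' multiplicity later via [build_presence_vector()].
#'
#' @param products Product tibble from [translate_six_frames()].
#' @param domain_set Data frame with an `accession` column giving the
#'   ordered domain set.
#' @param backend A backend from [motif_backend()] or [hmmer_backend()].
#' @param evalue_threshold Inclusive significance threshold on the
#'   full-sequence E-value (default `1e-5`).
#' @return A hit tibble ordered by accession, genome, frame and position.
#' @export
search_products <- function(products, domain_set, backend,
                            evalue_threshold = 1e-5) {
  stopifnot(inherits(backend, "search_backend"))
  if (nrow(domain_set) == 0) {
    abort("`domain_set` must be non-empty")
  }
  if (evalue_threshold <= 0) {
    abort("`evalue_threshold` must be positive")
  }
  if (nrow(products) == 0) {
    return(empty_hits())
  }
  hits <- run_backend(backend, products)
  unknown <- setdiff(unique(hits$domain_accession), domain_set$accession)
  if (length(unknown) > 0) {
    warn(sprintf(
      "dropping %d hit(s) for accessions outside the domain set: %s",
      sum(hits$domain_accession %in% unknown),
      paste(unknown, collapse = ", ")
    ))
    hits <- hits[!hits$domain_accession %in% unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  dplyr::arrange(hits, .data$domain_accession, .data$genome_id, .data$frame, .data$start_nt)
}

#' Presence/absence vectors over a fixed ordered domain set
#'
#' `build_presence_vector()` turns the hits of one genome into a single
#' 0/1 row aligned to `domain_set$accession` (1 iff the genome has at
#' least one hit for that domain — idempotent under duplicate hits).
#' `build_presence_matrix()` does the same for many genomes at once,
#' emitting one row per requested `genome_id` (genomes without hits get
#' all-zero rows).
#'
#' @param genome_id Genome identifier (scalar) or, for the matrix version,
#'   character vector of genome ids defining the row order.
#' @param hits Hit tibble from [search_products()].
#' @param domain_set Data frame with an `accession` column; its row order
#'   defines the column order.
#' @return A tibble with column `genome_id` followed by one 0/1 column per
#'   accession, in domain-set order.
#' @export
build_presence_vector <- function(genome_id, hits, domain_set) {
  stopifnot(length(genome_id) == 1)
  build_presence_matrix(genome_id, hits, domain_set)
}

#' @rdname build_presence_vector
#' @param genome_ids Character vector of genome ids (row order of result).
#' @export
build_presence_matrix <- function(genome_ids, hits, domain_set) {
  acc <- domain_set$accession
  if (anyDuplicated(acc)) {
    abort("duplicated accessions in `domain_set`")
  }
  hits <- hits[hits$genome_id %in% genome_ids, , drop = FALSE]
  mat <- matrix(
    0L, nrow = length(genome_ids), ncol = length(acc),
    dimnames = list(NULL, acc)
  )
  if (nrow(hits) > 0) {
    i <- match(hits$genome_id, genome_ids)
    j <- match(hits$domain_accession, acc)
    ok <- !is.na(j)
    mat[cbind(i[ok], j[ok])] <- 1L
  }
  dplyr::bind_cols(tibble(genome_id = genome_ids), as_tibble(mat))
}

#' Build a HMMER3 profile database from diagnostic motifs
#'
#' Runs `hmmbuild` once per motif (treating each motif as a single-sequence
#' alignment, named by its accession) and concatenates the resulting
#' profiles into one database file usable with [hmmer_backend()]. Requires
#' the HMMER 3 suite on the PATH.
#'
#' @param motif_table Data frame with columns `accession` and `motif`.
#' @param path Output path for the profile database.
#' @param hmmbuild Name or path of the `hmmbuild` executable.
#' @return `path`, invisibly.
#' @export
build_hmm_db <- function(motif_table, path, hmmbuild = "hmmbuild") {
  if (Sys.which(hmmbuild) == "" && !file.exists(hmmbuild)) {
    abort(sprintf("'%s' not found on PATH; install HMMER 3", hmmbuild))
  }
  parts <- map_chr(seq_len(nrow(motif_table)), function(i) {
    fa <- tempfile(fileext = ".faa")
    hmm <- tempfile(fileext = ".hmm")
    writeLines(c(
      paste0(">", motif_table$accession[[i]]), motif_table$motif[[i]]
    ), fa)
    status <- system2(
      hmmbuild, c("-n", motif_table$accession[[i]], "--amino", hmm, fa),
      stdout = FALSE, stderr = FALSE
    )
    unlink(fa)
    if (status != 0) {
      abort(sprintf("hmmbuild failed for '%s'", motif_table$accession[[i]]))
    }
    hmm
  })
  on.exit(unlink(parts), add = TRUE)
  txt <- unlist(lapply(parts, readLines))
  writeLines(txt, path)
  invisible(path)
}
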