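AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# One (non-stop) codon per amino acid under the standard code.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  vapply(AA20, function(aa) names(gc)[gc == aa][1], character(1))
}

MARKER_AA_LEN <- 45L
MARKER_NT_LEN <- 3L * MARKER_AA_LEN
BLOCK_NT <- MARKER_NT_LEN + 6L

fixture_descriptions <- function(n) {
  themes <- c(
    "phage integrase, site-specific",
    "putative excisionase (Xis family)",
    "tyrosine recombinase domain",
    "IS-family transposase",
    "lysogeny control region protein",
    "repressor of temperate phage",
    "partitioning ATPase ParA ",
    "partitioning protein ParB "
  )
  paste0("synthetic ", themes[(seq_len(n) - 1L) %% length(themes) + 1L],
         sprintf(" #%03d", seq_len(n)))
}

#' Generate a synthetic labeled phage fixture
#'
#' Builds an offline, fully deterministic stand-in for a labeled phage
#' genome collection, sized so the complete pipeline (translation, domain
#' search, training, evaluation) runs in seconds. Each of `n_domains`
#' synthetic domains is defined by a unique random 45-amino-acid
#' diagnostic motif, reverse-translated into a 135-nt stop-free coding
#' insert. Every temperate genome carries `markers_per_temperate`
#' distinct markers, each overwritten into the random background at a
#' random non-overlapping position, in a random reading frame on a random
#' strand; virulent genomes carry each marker independently with
#' probability `leak_rate` (default 0: perfectly clean classes).
#' Generation verifies its own construction by running six-frame
#' translation plus the motif backend and checking that exactly the
#' planted (genome, domain) pairs are recovered — a chance motif
#' collision with the background would trigger regeneration.
#'
#' Domain descriptions name lysogeny-related functions so the fixture
#' also exercises keyword selection.
#'
#' @param n_temperate,n_virulent Number of genomes per class (defaults
#'   30 and 30).
#' @param genome_length Genome length in nt (default 5000; must be at
#'   least 360 so 40-aa products can exist).
#' @param n_domains Number of synthetic domains (default 10).
#' @param markers_per_temperate Markers planted per temperate genome
#'   (default 3).
#' @param leak_rate Probability a virulent genome carries any given
#'   marker (default 0).
#' @param seed Integer seed; the same seed reproduces the fixture
#'   byte-for-byte.
#' @return A list with elements `genomes` (tibble `genome_id`, `seq`),
#'   `labels` (`genome_id`, `lifestyle`), `domain_set` (`accession`,
#'   `description`), `motif_table` (`accession`, `motif`), and `planted`
#'   (`genome_id`, `accession`): the ground-truth presence pairs.
#' @export
generate_fixture <- function(n_temperate = 30, n_virulent = 30,
                             genome_length = 5000, n_domains = 10,
                             markers_per_temperate = 3, leak_rate = 0,
                             seed = 1L) {
  if (genome_length < 360) {
    abort("`genome_length` must be >= 360 nt so 40-aa products can exist")
  }
  if (markers_per_temperate < 1 || markers_per_temperate > n_domains) {
    abort("`markers_per_temperate` must be in [1, n_domains]")
  }
  if (leak_rate < 0 || leak_rate > 1) {
    abort("`leak_rate` must be in [0, 1]")
  }
  n_blocks <- genome_length %/% BLOCK_NT
  if (n_blocks < markers_per_temperate) {
    abort("markers do not fit in the genome: increase `genome_length`")
  }
  codons <- codon_table()
  withr::with_seed(seed, {
    for (attempt in 1:10) {
      motifs <- replicate(
        n_domains, paste(sample(AA20, MARKER_AA_LEN, replace = TRUE), collapse = "")
      )
      if (anyDuplicated(motifs)) next
      motif_table <- tibble(
        accession = sprintf("SYN%03d", seq_len(n_domains)),
        motif = motifs
      )
      marker_nt <- map_chr(motifs, function(m) {
        paste(codons[strsplit(m, "")[[1]]], collapse = "")
      })
      labels <- tibble(
        genome_id = c(
          sprintf("temperate_%02d", seq_len(n_temperate)),
          sprintf("virulent_%02d", seq_len(n_virulent))
        ),
        lifestyle = rep(c("temperate", "virulent"), c(n_temperate, n_virulent))
      )
      planted_rows <- list()
      seqs <- map_chr(seq_len(nrow(labels)), function(g) {
        bg <- paste(
          sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
          collapse = ""
        )
        if (labels$lifestyle[[g]] == "temperate") {
          which_markers <- sort(sample.int(n_domains, markers_per_temperate))
        } else {
          which_markers <- which(stats::runif(n_domains) < leak_rate)
        }
        if (length(which_markers) > 0) {
          blocks <- sample.int(n_blocks, length(which_markers))
          for (j in seq_along(which_markers)) {
            ins <- marker_nt[[which_markers[[j]]]]
            if (stats::runif(1) < 0.5) ins <- revcomp(ins)
            pos <- (blocks[[j]] - 1L) * BLOCK_NT + sample(0:2, 1) + 1L
            substr(bg, pos, pos + MARKER_NT_LEN - 1L) <- ins
          }
          planted_rows[[length(planted_rows) + 1L]] <<- tibble(
            genome_id = labels$genome_id[[g]],
            accession = motif_table$accession[which_markers]
          )
        }
        bg
      })
      genomes <- tibble(genome_id = labels$genome_id, seq = seqs)
      planted <- dplyr::bind_rows(planted_rows)
      if (nrow(planted) == 0) {
        planted <- tibble(genome_id = character(), accession = character())
      }
      domain_set <- tibble(
        accession = motif_table$accession,
        description = fixture_descriptions(n_domains)
      )
      # Construction check: the pipeline must recover exactly the
      # planted presence pattern.
      products <- translate_six_frames(genomes)
      hits <- search_products(products, domain_set, motif_backend(motif_table))
      found <- dplyr::distinct(hits[c("genome_id", "domain_accession")])
      found <- dplyr::arrange(found, .data$genome_id, .data$domain_accession)
      want <- dplyr::arrange(
        dplyr::distinct(planted), .data$genome_id, .data$accession
      )
      if (identical(found$genome_id, want$genome_id) &&
          identical(found$domain_accession, want$accession)) {
        return(list(
          genomes = genomes, labels = labels, domain_set = domain_set,
          motif_table = motif_table, planted = planted
        ))
      }
    }
    abort("could not generate a collision-free fixture in 10 attempts")
  })
}

#' Write a synthetic fixture to a directory
#'
#' Writes `genomes.fasta`, `labels.tsv`, `domains.tsv` and `motifs.tsv`
#' into `dir` (created if needed), all plain text.
#'
#' @param fixture A fixture from [generate_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(fixture$genomes$seq)
  names(ss) <- fixture$genomes$genome_id
  Biostrings::writeXStringSet(ss, file.path(dir, "genomes.fasta"))
  readr::write_tsv(fixture$labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(fixture$domain_set, file.path(dir, "domains.tsv"))
  readr::write_tsv(fixture$motif_table, file.path(dir, "motifs.tsv"))
  invisible(dir)
}

#' Golden ten-genome pipeline case
#'
#' A small fixed fixture (5 temperate + 5 virulent genomes of 2,400 nt,
#' 4 domains, 2 markers per temperate genome, no leakage, fixed seed)
#' bundled with its construction-derived expectations: the exact
#' presence matrix every search backend must produce, and the lifestyle
#' call expected for every genome from any model fit on cleanly
#' separable data. Used as the human-inspectable end-to-end oracle.
#'
#' @return The [generate_fixture()] list plus `expected_presence` (wide
#'   0/1 tibble) and `expected_calls` (`genome_id`, `call`).
#' @export
golden_pipeline_case <- function() {
  fx <- generate_fixture(
    n_temperate = 5, n_virulent = 5, genome_length = 2400,
    n_domains = 4, markers_per_temperate = 2, leak_rate = 0, seed = 404L
  )
  hits <- tibble(
    domain_accession = fx$planted$accession,
    genome_id = fx$planted$genome_id,
    frame = NA_integer_, start_nt = NA_integer_,
    evalue = 1e-30, score = 100
  )
  fx$expected_presence <- build_presence_matrix(
    fx$genomes$genome_id, hits, fx$domain_set
  )
  fx$expected_calls <- tibble(
    genome_id = fx$labels$genome_id,
    call = fx$labels$lifestyle
  )
  fx
}
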