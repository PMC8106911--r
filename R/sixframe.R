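#' Read phage genomes from a FASTA file
#'
#' Reads nucleotide FASTA into the tidy genome table used throughout the
#' package. Sequences are uppercased on input. In `"per_record"` mode every
#' FASTA record is treated as an independent genome; in `"whole_file"` mode
#' all records are concatenated (in file order, separated by nothing) into a
#' single genome named after the first record, for multi-contig assemblies
#' of a single phage.
#'
#' @param path Path to a (possibly multi-record) nucleotide FASTA file.
#' @param mode `"per_record"` (default) or `"whole_file"`.
#' @return A tibble with columns `genome_id` and `seq`.
#' @export
read_genomes <- function(path, mode = c("per_record", "whole_file")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(sprintf("genome FASTA not found: '%s'", path))
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (mode == "whole_file" && length(ss) > 1) {
    ids <- ids[1]
    seqs <- paste(seqs, collapse = "")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicated genome ids in '%s': %s",
      path, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  tibble(genome_id = ids, seq = unname(seqs))
}

#' Reverse-complement a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented to their ambiguity-code
#' complements (e.g. `R` to `Y`, `N` to `N`).
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

IUPAC_NT <- "ACGTRYSWKMBDHVN"

check_nucleotides <- function(seq, genome_id) {
  m <- regexpr(sprintf("[^%s]", IUPAC_NT), seq)
  if (m != -1L) {
    abort(sprintf(
      "genome '%s' contains non-IUPAC nucleotide character '%s' at position %d",
      genome_id, substr(seq, m, m), as.integer(m)
    ))
  }
  invisible(seq)
}

SIX_FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

empty_products <- function() {
  tibble(
    genome_id = character(), frame = integer(),
    start_nt = integer(), aa_seq = character()
  )
}

#' Six-frame translation products of phage genomes
#'
#' Translates each genome in all three reading frames of both strands with
#' the standard genetic code and returns every maximal stop-free run of at
#' least `min_len` amino acids. These are stop-to-stop translation products,
#' not ORFs: no start codon is required, and a product may begin mid-gene.
#' Codons containing any non-ACGT base translate to `'X'` and never act as
#' stops. Trailing partial codons are ignored.
#'
#' Frames are `+1, +2, +3` on the input strand and `-1, -2, -3` on the
#' reverse complement; `start_nt` is the 0-based offset of the product's
#' first codon base *on the strand of its frame* (so minus-strand
#' coordinates count from the 3' end of the input). Products are ordered by
#' genome, then frame (`+1, +2, +3, -1, -2, -3`), then `start_nt`.
#'
#' @param genomes A data frame with columns `genome_id` and `seq`
#'   (nucleotide, IUPAC codes, case-insensitive).
#' @param min_len Minimum product length in amino acids (inclusive,
#'   default 40).
#' @return A tibble with columns `genome_id`, `frame`, `start_nt`, `aa_seq`.
#'   Genomes too short to yield any product contribute no rows.
#' @examples
#' translate_six_frames(
#'   tibble::tibble(genome_id = "g1", seq = strrep("A", 120))
#' )
#' @export
translate_six_frames <- function(genomes, min_len = 40) {
  stopifnot(is.data.frame(genomes), all(c("genome_id", "seq") %in% names(genomes)))
  if (min_len < 1) {
    abort("`min_len` must be >= 1")
  }
  n <- nrow(genomes)
  if (n == 0) {
    return(empty_products())
  }
  ids <- as.character(genomes$genome_id)
  seqs <- toupper(genomes$seq)
  for (i in seq_len(n)) {
    if (is.na(ids[i]) || !nzchar(ids[i])) {
      abort("genome ids must be non-empty")
    }
    check_nucleotides(seqs[i], ids[i])
  }
  rc <- revcomp(seqs)
  # one row per genome x frame; all frames are translated in a single
  # batched call, which is what keeps whole-collection translation fast
  tab <- tidyr::expand_grid(i = seq_len(n), frame = SIX_FRAMES)
  tab$off <- abs(tab$frame) - 1L
  strand_seq <- ifelse(tab$frame > 0, seqs[tab$i], rc[tab$i])
  n_codons <- pmax(0L, nchar(strand_seq) - tab$off) %/% 3L
  keep <- n_codons >= min_len
  if (!any(keep)) {
    return(empty_products())
  }
  tab <- tab[keep, , drop = FALSE]
  codons <- substr(strand_seq[keep], tab$off + 1L, tab$off + 3L * n_codons[keep])
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons), if.fuzzy.codon = "X"
  ))
  runs <- gregexpr("[^*]+", aa)
  out <- purrr::map(seq_along(aa), function(j) {
    r <- runs[[j]]
    if (r[1] == -1L) {
      return(NULL)
    }
    len <- attr(r, "match.length")
    k <- len >= min_len
    if (!any(k)) {
      return(NULL)
    }
    pos <- as.integer(r)[k]
    tibble(
      genome_id = ids[tab$i[j]],
      frame = tab$frame[j],
      start_nt = tab$off[j] + 3L * (pos - 1L),
      aa_seq = substring(aa[j], pos, pos + len[k] - 1L)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_products() else res
}

product_header <- function(genome_id, frame, start_nt) {
  if (any(grepl("|", genome_id, fixed = TRUE))) {
    abort("genome ids must not contain '|' (reserved for product headers)")
  }
  sprintf("%s|%+d|%d", genome_id, frame, start_nt)
}

parse_product_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    abort(sprintf("malformed product header: '%s'", header[bad][1]))
  }
  tibble(
    genome_id = map_chr(parts, ~ paste(.x[seq_len(length(.x) - 2L)], collapse = "|")),
    frame = as.integer(map_chr(parts, ~ .x[[length(.x) - 1L]])),
    start_nt = as.integer(map_chr(parts, ~ .x[[length(.x)]]))
  )
}

#' Write and read translation products as FASTA
#'
#' The FASTA header encodes provenance as `genome_id|frame|start_nt`
#' (frame signed, `start_nt` 0-based), so products round-trip losslessly
#' through external search tools. Genome ids must therefore not contain
#' `'|'`.
#'
#' @param products A product tibble from [translate_six_frames()].
#' @param path Output (or input) FASTA path.
#' @return `write_products_fasta()` returns `path` invisibly;
#'   `read_products_fasta()` returns a product tibble.
#' @export
write_products_fasta <- function(products, path) {
  if (nrow(products) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  aa <- Biostrings::AAStringSet(products$aa_seq)
  names(aa) <- product_header(products$genome_id, products$frame, products$start_nt)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_products_fasta
#' @export
read_products_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("product FASTA not found: '%s'", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    return(tibble(
      genome_id = character(), frame = integer(),
      start_nt = integer(), aa_seq = character()
    ))
  }
  dplyr::bind_cols(
    parse_product_header(names(aa)),
    tibble(aa_seq = unname(as.character(aa)))
  )
}
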