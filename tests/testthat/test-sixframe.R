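test_that("a 120-nt poly-A genome yields exactly the two 40-aa edge products", {
  p <- translate_six_frames(genome_tbl(g1 = strrep("A", 120)))
  # manual codon oracle: AAA = K on the plus strand, TTT = F on the minus
  # strand; frames +2/+3/-2/-3 only reach 39 codons and fall below 40 aa
  expect_equal(nrow(p), 2)
  expect_equal(p$frame, c(1L, -1L))
  expect_equal(p$start_nt, c(0L, 0L))
  expect_equal(p$aa_seq, c(strrep("K", 40), strrep("F", 40)))
})

test_that("degenerate inputs give empty product tables, not errors", {
  empty <- translate_six_frames(genome_tbl(g1 = ""))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("genome_id", "frame", "start_nt", "aa_seq"))
  # any sequence shorter than 3 * min_len nt cannot host a 40-aa product
  expect_equal(nrow(translate_six_frames(genome_tbl(g1 = random_dna(119, seed = 1)))), 0)
  # all-ambiguous sequence translates to X runs but they are never products
  # longer than the sequence allows
  expect_equal(
    nrow(translate_six_frames(genome_tbl(g1 = strrep("N", 60)))), 0
  )
})

test_that("min_len is inclusive and ambiguous codons become X, never stops", {
  p <- translate_six_frames(genome_tbl(g1 = strrep("A", 120)), min_len = 40)
  expect_equal(nrow(p), 2)
  expect_equal(nrow(translate_six_frames(genome_tbl(g1 = strrep("A", 120)), min_len = 41)), 0)
  # an N mid-sequence becomes an X inside one unbroken product
  seq <- paste0(strrep("A", 60), "ANA", strrep("A", 60))
  p <- translate_six_frames(genome_tbl(g1 = seq), min_len = 41)
  plus1 <- p[p$frame == 1, ]
  expect_equal(nrow(plus1), 1)
  expect_equal(nchar(plus1$aa_seq), 41)
  expect_true(grepl("X", plus1$aa_seq))
  expect_false(grepl("\\*", plus1$aa_seq))
})

test_that("non-IUPAC characters are rejected with character and position", {
  expect_error(
    translate_six_frames(genome_tbl(g1 = paste0(strrep("A", 10), "J", strrep("A", 10)))),
    "'J'.*position 11"
  )
})

test_that("lowercase input yields identical products to uppercase", {
  seq <- random_dna(400, seed = 7)
  expect_equal(
    translate_six_frames(genome_tbl(g1 = tolower(seq)), min_len = 10),
    translate_six_frames(genome_tbl(g1 = seq), min_len = 10)
  )
})

test_that("six-frame products are strand-symmetric as a multiset", {
  withr::with_seed(42, {
    for (i in 1:50) {
      seq <- random_dna(sample(150:500, 1))
      fwd <- translate_six_frames(genome_tbl(g = seq), min_len = 10)
      rev <- translate_six_frames(genome_tbl(g = revcomp(seq)), min_len = 10)
      expect_equal(sort(fwd$aa_seq), sort(rev$aa_seq))
      # frame signs swap: plus-strand products of one are minus of the other
      expect_equal(sort(fwd$aa_seq[fwd$frame > 0]), sort(rev$aa_seq[rev$frame < 0]))
    }
  })
})

test_that("each product re-translates exactly from its reported coordinates", {
  seq <- random_dna(600, seed = 11)
  p <- translate_six_frames(genome_tbl(g = seq), min_len = 10)
  expect_gt(nrow(p), 0)
  for (i in seq_len(nrow(p))) {
    strand_seq <- if (p$frame[i] > 0) seq else revcomp(seq)
    codons <- substr(strand_seq, p$start_nt[i] + 1, p$start_nt[i] + 3 * nchar(p$aa_seq[i]))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(codons), if.fuzzy.codon = "X"
    ))
    expect_identical(aa, p$aa_seq[i])
  }
})

test_that("an in-frame stop codon splits one product into at most two", {
  seq <- strrep("A", 240)
  before <- translate_six_frames(genome_tbl(g = seq), min_len = 1)
  plus1_before <- before[before$frame == 1, ]
  expect_equal(nchar(plus1_before$aa_seq), 80)
  # overwrite codon 41 (0-based nt 120..122) with TAA
  split_seq <- paste0(substr(seq, 1, 120), "TAA", substr(seq, 124, 240))
  after <- translate_six_frames(genome_tbl(g = split_seq), min_len = 1)
  plus1_after <- after[after$frame == 1, ]
  expect_equal(nrow(plus1_after), 2)
  expect_equal(sort(nchar(plus1_after$aa_seq)), c(39, 40))
  expect_equal(plus1_after$start_nt, c(0L, 123L))
  # and with the default threshold only the 40-aa half survives
  expect_equal(
    sum(translate_six_frames(genome_tbl(g = split_seq))$frame == 1), 1
  )
})

test_that("product FASTA round-trips provenance and X residues verbatim", {
  prods <- tibble::tibble(
    genome_id = c("phage_a", "phage_a", "phage_b"),
    frame = c(1L, -3L, 2L),
    start_nt = c(0L, 12L, 301L),
    aa_seq = c(strrep("K", 40), paste0(strrep("M", 20), "XXX", strrep("W", 20)), strrep("F", 41))
  )
  path <- withr::local_tempfile(fileext = ".faa")
  write_products_fasta(prods, path)
  expect_equal(read_products_fasta(path), prods)
})

test_that("an empty product list writes an empty FASTA that reads back empty", {
  path <- withr::local_tempfile(fileext = ".faa")
  empty <- translate_six_frames(genome_tbl(g = ""))
  write_products_fasta(empty, path)
  expect_true(file.exists(path))
  expect_equal(nrow(read_products_fasta(path)), 0)
})

test_that("genome ids containing the header separator are refused at write", {
  prods <- tibble::tibble(
    genome_id = "bad|id", frame = 1L, start_nt = 0L, aa_seq = strrep("K", 40)
  )
  expect_error(write_products_fasta(prods, tempfile()), "\\|")
})
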