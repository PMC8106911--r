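toy_domain_set <- function(n = 10) {
  tibble::tibble(
    accession = sprintf("d%d", seq_len(n)),
    description = sprintf("toy domain %d", seq_len(n))
  )
}

toy_products <- function(aa, ids = sprintf("p%d", seq_along(aa))) {
  tibble::tibble(
    genome_id = ids, frame = 1L,
    start_nt = 3L * (seq_along(aa) - 1L), aa_seq = aa
  )
}

test_that("the motif backend reports exactly the embedded markers", {
  motifs <- tibble::tibble(
    accession = c("d3", "d7"),
    motif = c(strrep("WMK", 15), strrep("HQV", 15))
  )
  prods <- toy_products(c(
    paste0(strrep("A", 10), motifs$motif[1], strrep("A", 10)),
    strrep("G", 60)
  ), ids = c("gA", "gB"))
  hits <- search_products(prods, toy_domain_set(), motif_backend(motifs))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$domain_accession, "d3")
  expect_equal(hits$genome_id, "gA")
})

test_that("zero products give an empty hit list", {
  hits <- search_products(
    toy_products(character(0), ids = character(0)),
    toy_domain_set(), motif_backend(tibble::tibble(accession = "d1", motif = "WWWW"))
  )
  expect_equal(nrow(hits), 0)
})

test_that("the same domain hit on two products keeps both hit rows", {
  motifs <- tibble::tibble(accession = "d2", motif = strrep("CWY", 14))
  prods <- toy_products(
    rep(paste0("AAAA", motifs$motif, "AAAA"), 2), ids = c("g1", "g1")
  )
  hits <- search_products(prods, toy_domain_set(), motif_backend(motifs))
  expect_equal(nrow(hits), 2)
  expect_equal(unique(hits$domain_accession), "d2")
})

test_that("hits for accessions outside the domain set are dropped with a warning", {
  motifs <- tibble::tibble(accession = "rogue", motif = strrep("WMK", 15))
  prods <- toy_products(paste0("AA", motifs$motif, "AA"))
  expect_warning(
    hits <- search_products(prods, toy_domain_set(), motif_backend(motifs)),
    "rogue"
  )
  expect_equal(nrow(hits), 0)
})

test_that("tblout parsing skips comments and extracts names, E-values and scores", {
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "# comment line",
    "#------------------- ----------",
    "gA|+1|0              -          d3  - 1e-10 134.4 0.2 1.2e-10 134.3 0.2 1.0 1 0 0 1 1 1 1 -",
    "gB|-2|12             -          d5  - 0.5   8.1   0.0 0.6     8.0   0.0 1.0 1 0 0 1 1 1 1 -"
  ), path)
  hits <- parse_hmmer_tblout(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$domain_accession, c("d3", "d5"))
  expect_equal(hits$genome_id, c("gA", "gB"))
  expect_equal(hits$frame, c(1L, -2L))
  expect_equal(hits$start_nt, c(0L, 12L))
  expect_equal(hits$evalue, c(1e-10, 0.5))
  expect_equal(hits$score, c(134.4, 8.1))
})

test_that("a tblout file of only comment lines parses to an empty hit list", {
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("# only", "# comments", "#"), path)
  expect_equal(nrow(parse_hmmer_tblout(path)), 0)
  # and an empty file likewise
  empty <- withr::local_tempfile(fileext = ".tblout")
  writeLines(character(), empty)
  expect_equal(nrow(parse_hmmer_tblout(empty)), 0)
})

test_that("malformed tblout lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "# header",
    "gA|+1|0 - d3 - 1e-10 134.4 0.2 1 1 1 1 1 1 1 1 1 -",
    "gB|+1|0 - d5 - not_a_number 8.1 0.0 1 1 1 1 1 1 1 1 1 -"
  ), path)
  expect_error(parse_hmmer_tblout(path), "line 3.*not_a_number")
})

test_that("presence vectors mark exactly the hit domains, once each", {
  ds <- toy_domain_set(10)
  hits <- tibble::tibble(
    domain_accession = c("d3", "d7", "d3"),
    genome_id = "gA", frame = 1L, start_nt = c(0L, 3L, 60L),
    evalue = 1e-12, score = 50
  )
  v <- build_presence_vector("gA", hits, ds)
  expect_equal(names(v), c("genome_id", ds$accession))
  expect_equal(unlist(v[ds$accession]), c(
    d1 = 0L, d2 = 0L, d3 = 1L, d4 = 0L, d5 = 0L,
    d6 = 0L, d7 = 1L, d8 = 0L, d9 = 0L, d10 = 0L
  ))
})

test_that("presence is invariant to hit order and multiplicity", {
  ds <- toy_domain_set(6)
  hits <- tibble::tibble(
    domain_accession = c("d2", "d5", "d2", "d5", "d5"),
    genome_id = "g", frame = 1L, start_nt = 0:4, evalue = 1e-9, score = 10
  )
  base <- build_presence_vector("g", hits, ds)
  withr::with_seed(5, {
    for (i in 1:5) {
      shuffled <- hits[sample(nrow(hits)), ]
      expect_equal(build_presence_vector("g", shuffled, ds), base)
    }
  })
  expect_equal(build_presence_vector("g", hits[c(1, 2), ], ds), base)
})

test_that("no hits give a zero vector of full domain-set width", {
  ds <- tibble::tibble(
    accession = sprintf("D%03d", 1:206), description = ""
  )
  v <- build_presence_vector("g", parse_hmmer_tblout(withr::local_tempfile(
    lines = "# none", fileext = ".tblout"
  )), ds)
  expect_equal(ncol(v), 207)
  expect_equal(sum(unlist(v[-1])), 0)
  # and one hit everywhere gives the all-ones vector
  all_hits <- tibble::tibble(
    domain_accession = ds$accession, genome_id = "g",
    frame = 1L, start_nt = 0L, evalue = 1e-9, score = 1
  )
  expect_equal(sum(unlist(build_presence_vector("g", all_hits, ds)[-1])), 206)
})

test_that("multi-record FASTA can be read per record or as one genome", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 contig one", "ACGTACGT", ">c2", "GGGGCCCC"), path)
  per <- read_genomes(path)
  expect_equal(per$genome_id, c("c1", "c2"))
  whole <- read_genomes(path, mode = "whole_file")
  expect_equal(whole$genome_id, "c1")
  expect_equal(whole$seq, "ACGTACGTGGGGCCCC")
})
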