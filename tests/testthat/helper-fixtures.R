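# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

genome_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(genome_id = names(seqs), seq = unname(seqs))
}

# A perfectly separable labeled dataset: feature `d_key` is 1 iff temperate;
# `n_noise` additional all-zero columns can be appended.
separable_dataset <- function(n_per_class = 10, n_noise = 0) {
  n <- 2 * n_per_class
  feats <- tibble::tibble(d_key = rep(c(1L, 0L), each = n_per_class))
  if (n_noise > 0) {
    for (i in seq_len(n_noise)) {
      feats[[paste0("d_zero", i)]] <- 0L
    }
  }
  dplyr::bind_cols(
    tibble::tibble(
      genome_id = sprintf("g%02d", seq_len(n)),
      lifestyle = rep(c("temperate", "virulent"), each = n_per_class)
    ),
    feats
  )
}

# Brute-force metric oracle: recomputes every score directly from the two
# label vectors, independently of the confusion-matrix path.
oracle_metrics <- function(truth, estimate) {
  acc <- mean(truth == estimate)
  sens <- if (sum(truth == "temperate") > 0) {
    mean(estimate[truth == "temperate"] == "temperate")
  } else 0
  spec <- if (sum(truth == "virulent") > 0) {
    mean(estimate[truth == "virulent"] == "virulent")
  } else 0
  tp <- sum(truth == "temperate" & estimate == "temperate")
  tn <- sum(truth == "virulent" & estimate == "virulent")
  fp <- sum(truth == "virulent" & estimate == "temperate")
  fn <- sum(truth == "temperate" & estimate == "virulent")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    accuracy = acc,
    balanced_accuracy = ((sens + spec) / 2 - 0.5) / 0.5,
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom,
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  )
}

random_labels <- function(n) {
  sample(c("virulent", "temperate"), n, replace = TRUE)
}

# Hand-enumerated 20-genome training fixture for the prevalence filter:
# 12 temperate + 8 virulent genomes, 7 domains with known fates.
prevalence_fixture <- function() {
  present_in <- list(
    dA = c(1, 2),          # 2 genomes (both temperate): dropped, too rare
    dB = c(1, 2, 3),       # 3 temperate, 0 virulent: retained
    dC = c(1, 2, 13, 14, 15), # 2/12 temp vs 3/8 vir: dropped, virulent-leaning
    dD = c(1, 2, 3, 13, 14),  # 3/12 vs 2/8 = 0.25 both: tie retained
    dE = integer(0),       # absent everywhere: dropped
    dF = c(1:6, 13, 14),   # 6/12 vs 2/8: retained
    dG = c(1, 13, 14)      # 3 genomes but 1/12 vs 2/8: dropped
  )
  feats <- purrr::map(present_in, function(rows) {
    v <- integer(20)
    v[rows] <- 1L
    v
  })
  dplyr::bind_cols(
    tibble::tibble(
      genome_id = sprintf("g%02d", 1:20),
      lifestyle = rep(c("temperate", "virulent"), c(12, 8))
    ),
    tibble::as_tibble(feats)
  )
}
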