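test_that("a single perfectly informative feature is learned decisively", {
  ds <- separable_dataset(10)
  model <- fit_lifestyle_model(ds, seed = 3)
  probe <- tibble::tibble(genome_id = c("present", "absent"), d_key = c(1L, 0L))
  pred <- predict(model, probe)
  expect_gt(pred$p_temperate[1], 0.9)
  expect_lt(pred$p_temperate[2], 0.1)
  expect_equal(pred$call, c("temperate", "virulent"))
  expect_equal(pred$p_virulent + pred$p_temperate, c(1, 1))
})

test_that("fitting is deterministic under a fixed seed and predict is pure", {
  ds <- separable_dataset(8, n_noise = 3)
  probe <- ds[c("genome_id", setdiff(names(ds), c("genome_id", "lifestyle")))]
  m1 <- fit_lifestyle_model(ds, seed = 11)
  m2 <- fit_lifestyle_model(ds, seed = 11)
  expect_equal(predict(m1, probe), predict(m2, probe))
  expect_equal(predict(m1, probe), predict(m1, probe))
  expect_equal(m1$training_fingerprint, m2$training_fingerprint)
})

test_that("the published hyperparameter configuration is accepted and recorded", {
  hp <- lifestyle_hyperparameters(
    bootstrap = FALSE, class_weight = "balanced_subsample",
    min_samples_leaf = 1, n_estimators = 80, max_depth = 40
  )
  model <- fit_lifestyle_model(separable_dataset(5), hp, seed = 1)
  g <- glance(model)
  expect_equal(g$n_estimators, 80L)
  expect_equal(g$max_depth, 40L)
  expect_false(g$bootstrap)
  expect_equal(g$class_weight, "balanced_subsample")
  expect_equal(g$min_samples_leaf, 1L)
})

test_that("single-class and non-binary training data are rejected", {
  ds <- separable_dataset(6)
  expect_error(fit_lifestyle_model(ds[1:6, ]), "each lifestyle")
  bad <- ds
  bad$d_key[1] <- 2L
  expect_error(fit_lifestyle_model(bad), "0 or 1")
})

test_that("the call rule is temperate only above 0.5, ties to virulent", {
  # the stated prior: an input genome is assumed virulent until domain
  # evidence overrides it
  expect_equal(phagelife:::lifestyle_call(c(0.5, 0.49, 0.51, 0, 1)),
               c("virulent", "virulent", "temperate", "virulent", "temperate"))
})

test_that("the confidence flag is inclusive at the threshold", {
  out <- phagelife:::annotate_predictions(
    c("a", "b", "c", "d"), c(0.951, 0.95, 0.949, 0.04), 0.95
  )
  expect_equal(out$confident, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$call, c("temperate", "temperate", "temperate", "virulent"))
})

test_that("prediction refuses vectors with the wrong feature contract", {
  ds <- separable_dataset(6, n_noise = 2)
  model <- fit_lifestyle_model(ds)
  short <- tibble::tibble(genome_id = "g", d_key = 1L, d_zero1 = 0L)
  expect_error(predict(model, short), "expects 3 domain columns")
  renamed <- tibble::tibble(genome_id = "g", d_key = 1L, d_zero1 = 0L, wrong = 0L)
  expect_error(predict(model, renamed), "feature mismatch")
  nonbinary <- tibble::tibble(genome_id = "g", d_key = 0.5, d_zero1 = 0L, d_zero2 = 0L)
  expect_error(predict(model, nonbinary), "0 or 1")
})

test_that("models round-trip through disk with identical predictions", {
  ds <- separable_dataset(8)
  model <- fit_lifestyle_model(ds, seed = 2)
  probe <- ds[c("genome_id", "d_key")]
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  restored <- load_model(path)
  expect_equal(predict(restored, probe), predict(model, probe))
  expect_equal(restored$domain_set, model$domain_set)
  # a restored model still enforces the feature contract
  expect_error(predict(restored, tibble::tibble(genome_id = "g")), "expects 1 domain")
})

test_that("corrupt or foreign model files fail loudly", {
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit_lifestyle_model(separable_dataset(5)), path)
  truncated <- withr::local_tempfile(fileext = ".rds")
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[1:20], truncated)
  expect_error(load_model(truncated), "cannot read model file")
  foreign <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), foreign)
  expect_error(load_model(foreign), "not a lifestyle model")
  expect_error(load_model("no/such/file.rds"), "not found")
})

test_that("feature importances normalize, order and accumulate correctly", {
  ds <- separable_dataset(10, n_noise = 4)
  model <- fit_lifestyle_model(ds, seed = 5)
  imp <- tidy(model)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(diff(imp$importance) <= 1e-12))
  expect_equal(imp$cumulative_share[nrow(imp)], 1, tolerance = 1e-12)
  expect_equal(imp$accession[1], "d_key")
  expect_equal(feature_importances(model), imp)
})

test_that("an extra all-zero feature column does not change calls", {
  ds <- separable_dataset(10)
  with_zero <- separable_dataset(10, n_noise = 1)
  m1 <- fit_lifestyle_model(ds, seed = 9)
  m2 <- fit_lifestyle_model(with_zero, seed = 9)
  probe1 <- tibble::tibble(genome_id = c("p", "a"), d_key = c(1L, 0L))
  probe2 <- dplyr::mutate(probe1, d_zero1 = 0L)
  expect_equal(predict(m1, probe1)$call, predict(m2, probe2)$call)
})
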