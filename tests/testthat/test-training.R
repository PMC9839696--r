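test_that("acquisition splitting partitions whole acquisitions", {
  ds <- generate_dataset(16, 8, 8, seed = 3, n_acquisitions = 8)
  ds <- split_by_acquisition(ds, 4, 2, 2, seed = 9)
  expect_setequal(unname(ds$split), c(rep("train", 4), rep("validation", 2),
                                      rep("test", 2)))
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  te <- dataset_split(ds, "test")
  # no acquisition (and hence no sequence) appears in two splits
  expect_length(intersect(tr$manifest$acquisition_id, va$manifest$acquisition_id), 0)
  expect_length(intersect(tr$manifest$acquisition_id, te$manifest$acquisition_id), 0)
  expect_equal(length(tr) + length(va) + length(te), length(ds))
  # determinism and the too-few-acquisitions guard
  ds2 <- split_by_acquisition(ds, 4, 2, 2, seed = 9)
  expect_identical(ds$split, ds2$split)
  expect_error(split_by_acquisition(ds, 6, 2, 2), "not enough")
})

test_that("a (1,1,1) split of three acquisitions is a partition", {
  ds <- generate_dataset(6, 3, 0, seed = 5, n_acquisitions = 3)
  ds <- split_by_acquisition(ds, 1, 1, 1, seed = 1)
  expect_setequal(names(ds$split), paste0("acq", 1:3))
  expect_setequal(unname(ds$split), c("train", "validation", "test"))
})

test_that("combined balancing reaches the stated targets through the real code path", {
  # scaled run of the stage-1 setting: (700 unreliable, 38 reliable) -> (50, 50)
  ds <- generate_dataset(30, 8, 700, seed = 21, n_acquisitions = 4,
                         length_sampler = function(n) rep(6, n))
  bal <- balance_classes(ds, "combined", stage = 1, down_to = 50, up_to = 50,
                         seed = 2)
  counts <- table(collapse_labels(bal$manifest$label, 1))
  expect_equal(as.integer(counts[c("unreliable", "reliable")]), c(50, 50))
  # the exact arithmetic of the full-scale setting, no sequence materialization
  expect_equal(balanced_counts(70000, 3800, down_to = 5000, up_to = 5000),
               c(5000, 5000))
})

test_that("balancing is a no-op on already balanced classes and copies only", {
  ds <- generate_dataset(10, 10, 0, seed = 31, n_acquisitions = 2,
                         length_sampler = function(n) rep(6, n))
  for (strat in c("downsample_majority", "upsample_minority")) {
    bal <- balance_classes(ds, strat, stage = 2, seed = 3)
    expect_equal(sort(as.integer(table(bal$manifest$label))), c(10, 10))
  }
  # upsampling adds copies only: the distinct-sequence set is the original
  ds2 <- generate_dataset(12, 3, 0, seed = 32, n_acquisitions = 2,
                          length_sampler = function(n) rep(6, n))
  up <- balance_classes(ds2, "upsample_minority", stage = 2, seed = 3)
  expect_equal(sum(up$manifest$label == "flipping"), 12)
  orig <- ds2$manifest$sequence_id[ds2$manifest$label == "flipping"]
  expect_setequal(up$manifest$sequence_id[up$manifest$label == "flipping"], orig)
  expect_error(balance_classes(ds2, "combined", stage = 1), "both classes")
})

test_that("cross-entropy matches its closed forms", {
  perfect <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(cross_entropy_loss(perfect, "a"), 0, tolerance = 1e-10)
  uniform <- matrix(0.5, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(cross_entropy_loss(uniform, c("a", "b", "a")), log(2))
  toy <- matrix(c(0.9, 0.8, 0.6, 0.1, 0.2, 0.4), 3, 2,
                dimnames = list(NULL, c("a", "b")))
  expect_equal(cross_entropy_loss(toy, c("a", "a", "a")),
               mean(-log(c(0.9, 0.8, 0.6))))
  # clamping keeps a zero probability finite
  zero <- matrix(c(0, 1), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(is.finite(cross_entropy_loss(zero, "a")))
  expect_error(cross_entropy_loss(toy, c("a", "a")), "batch sizes")
})

make_toy_stage2 <- function(n_per_class, seed, len = 6) {
  generate_dataset(n_per_class, n_per_class, 0, seed = seed,
                   n_acquisitions = 4,
                   length_sampler = function(n) rep(len, n))
}

test_that("single-epoch training selects epoch 1 and training is deterministic", {
  ds <- make_toy_stage2(12, seed = 41)
  ds <- split_by_acquisition(ds, 3, 1, 0, seed = 1)
  cfgp <- preprocess_config(K = 6, sampling = "uniform", pad_to_K = TRUE)
  tr <- preprocess_batch(dataset_split(ds, "train"), cfgp)
  va <- preprocess_batch(dataset_split(ds, "validation"), cfgp)
  spec <- model_spec("A", K = 6, stage = 2, seed = 2)
  one <- train_model(spec, train_config(stage = 2, epochs = 1, batch_size = 8,
                                        seed = 5), tr, va)
  expect_equal(one$best_epoch, 1)

  cfg <- train_config(stage = 2, epochs = 2, batch_size = 8, seed = 5)
  r1 <- train_model(spec, cfg, tr, va)
  r2 <- train_model(spec, cfg, tr, va)
  expect_identical(r1$train_loss, r2$train_loss)
  expect_identical(r1$val_loss, r2$val_loss)
  # the returned checkpoint is the argmin-validation epoch
  expect_equal(r1$best_epoch, which.min(r1$val_loss))
  expect_lte(r1$val_loss[r1$best_epoch], r1$val_loss[length(r1$val_loss)])
})

test_that("an untrained symmetric model sits near the ln 2 baseline on balanced data", {
  ds <- make_toy_stage2(8, seed = 51)
  cfgp <- preprocess_config(K = 6, sampling = "uniform", pad_to_K = TRUE)
  dsp <- preprocess_batch(ds, cfgp)
  m <- build_model_a(model_spec("A", K = 6, stage = 2, seed = 3))
  y <- match(collapse_labels(dsp$manifest$label, 2), m$spec$classes)
  expect_equal(rbcmotion:::dataset_loss(m, dsp, y), log(2), tolerance = 0.2)
})

test_that("balancing inside training never touches the validation set", {
  ds <- generate_dataset(24, 6, 0, seed = 61, n_acquisitions = 4,
                         length_sampler = function(n) rep(6, n))
  ds <- split_by_acquisition(ds, 3, 1, 0, seed = 2)
  cfgp <- preprocess_config(K = 6, sampling = "uniform", pad_to_K = TRUE)
  tr <- preprocess_batch(dataset_split(ds, "train"), cfgp)
  va <- preprocess_batch(dataset_split(ds, "validation"), cfgp)
  va_before <- va$manifest
  res <- train_model(model_spec("A", K = 6, stage = 2, seed = 2),
                     train_config(stage = 2, balancing = "downsample_majority",
                                  epochs = 1, batch_size = 8, seed = 5),
                     tr, va)
  expect_identical(va$manifest, va_before)
  expect_s3_class(res, "rbc_train_result")
})
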