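# MEET: sizing rule, class partition, expert/gate training, Hadamard fusion.

test_that("the sizing rule counts experts plus one gate", {
  expect_identical(required_experts(6, 2), 4L)
  expect_identical(required_experts(2, 2), 2L)
  expect_identical(required_experts(15, 2), 9L)
  for (N in 2:20) for (a in 1:5)
    expect_identical(required_experts(N, a), as.integer(ceiling(N / a)) + 1L)
  expect_error(required_experts(1, 2), "n_classes")
  expect_error(required_experts(6, 0), "`a`")
})

test_that("classes are partitioned into consecutive ascending chunks", {
  expect_equal(partition_classes(1:6, 2), list(1:2, 3:4, 5:6),
               ignore_attr = TRUE)
  expect_equal(partition_classes(1:5, 2), list(1:2, 3:4, 5L),
               ignore_attr = TRUE)
  expect_equal(partition_classes(1:2, 2), list(1:2), ignore_attr = TRUE)
  expect_equal(partition_classes(c(4, 2, 6), 2), list(c(2L, 4L), 6L),
               ignore_attr = TRUE)
  expect_error(partition_classes(c(1, 1, 2), 2), "duplicate")
  expect_length(partition_classes(1:6, 2), required_experts(6, 2) - 1L)
})

# Shared fixture: one small 6-class feature matrix.
fm6 <- featurize(segment_windows(notch_filter(bandpass_filter(
  generate_recording(quick_config(6, 8, seed = 42), 1)))))

test_that("fitting builds one expert per subset plus a gate", {
  m <- meet_fit(fm6, a = 2, seed = 7)
  expect_s3_class(m, "meet_model")
  expect_length(m$experts, 3)
  expect_equal(m$partition, list(1:2, 3:4, 5:6), ignore_attr = TRUE)
  expect_equal(m$class_order, 1:6)
  # each expert's class list equals its subset; the gate sees all classes
  for (e in 1:3)
    expect_identical(m$experts[[e]]$forest$levels, as.character(m$partition[[e]]))
  expect_identical(m$gate$forest$levels, as.character(1:6))
})

test_that("training is deterministic under a fixed seed", {
  split <- stratified_split(fm6$labels, 0.7, seed = 1)
  train <- meetsemg:::subset_features(fm6, split$train)
  test <- meetsemg:::subset_features(fm6, split$test)
  m1 <- meet_fit(train, seed = 13)
  m2 <- meet_fit(train, seed = 13)
  expect_identical(predict(m1, test), predict(m2, test))
  m3 <- meet_fit(train, seed = 14)
  expect_false(identical(m1$experts[[1]]$forest$split.values,
                         m3$experts[[1]]$forest$split.values))
})

test_that("two-class data degenerates to one expert plus gate", {
  rows <- fm6$labels %in% 1:2
  fm2 <- meetsemg:::subset_features(fm6, which(rows))
  m <- meet_fit(fm2, a = 2, seed = 3)
  expect_length(m$experts, 1)
  preds <- predict(m, fm2)
  expect_true(all(preds %in% 1:2))
})

test_that("degenerate training inputs raise informative errors", {
  one_row <- meetsemg:::subset_features(
    fm6, c(which(fm6$labels == 1)[1], which(fm6$labels == 2)))
  expect_error(meet_fit(one_row), "class 1")
  only1 <- meetsemg:::subset_features(fm6, which(fm6$labels == 1))
  expect_error(meet_fit(only1), "at least 2 classes")
})

test_that("fusion vectors stack expert blocks aligned to class order", {
  m <- meet_fit(fm6, a = 2, seed = 7)
  row <- fm6$values[10, ]
  fv <- fusion_vectors(m, row)
  expect_length(fv$Z, 6)
  expect_length(fv$M, 6)
  expect_equal(sum(fv$M), 1, tolerance = 1e-9)
  for (e in 1:3)   # each expert's block of Z is itself a distribution
    expect_equal(sum(fv$Z[(2 * e - 1):(2 * e)]), 1, tolerance = 1e-9)
  expect_true(all(fv$Z >= 0 & fv$Z <= 1))
  expect_error(fusion_vectors(m, row[1:5]), "schema")
})

test_that("fuse_predict matches hand-computed and brute-force fusion", {
  Z <- c(0.9, 0.1, 0.6, 0.4, 0.5, 0.5)
  # uniform gate reduces fusion to the argmax of Z
  expect_equal(fuse_predict(Z, rep(1 / 6, 6), 1:6), 1)
  # products: 0.045, 0.005, 0.36, 0.04, 0.05, 0.05 -> class 3
  expect_equal(fuse_predict(Z, c(0.05, 0.05, 0.60, 0.10, 0.10, 0.10), 1:6), 3)
  # all-equal products tie-break toward the lowest class code
  expect_equal(fuse_predict(rep(0.5, 4), rep(0.25, 4), 4:1), 1)
  expect_error(fuse_predict(Z, rep(1 / 4, 4), 1:6), "equal length")
  expect_error(fuse_predict(c(Z[-6], 1.2), rep(1 / 6, 6), 1:6), "\\[0, 1\\]")

  set.seed(55)
  for (i in 1:1000) {
    N <- sample(2:8, 1)
    Zr <- runif(N); Mr <- runif(N)
    if (i %% 7 == 0) { Zr <- round(Zr, 1); Mr <- round(Mr, 1) }  # force ties
    co <- sort(sample(1:50, N))
    expect_identical(fuse_predict(Zr, Mr, co), brute_force_fuse(Zr, Mr, co))
  }
})

test_that("fusion is invariant to positive rescaling of the gate", {
  set.seed(9)
  for (i in 1:50) {
    Z <- runif(6); M <- runif(6)
    expect_identical(fuse_predict(Z, M, 1:6),
                     fuse_predict(Z, 0.31 * M, 1:6))
  }
})

test_that("experts are local: other-class rows do not affect an expert", {
  m_full <- meet_fit(fm6, a = 2, seed = 77)
  fm12 <- meetsemg:::subset_features(fm6, which(fm6$labels %in% 1:2))
  m_sub <- meet_fit(fm12, a = 2, seed = 77)
  # expert 1 in both models was trained on identical rows with the same
  # derived seed, so its probability block must be identical
  X <- fm6$values[1:25, , drop = FALSE]
  z_full <- meetsemg:::meet_probability_stack(m_full, X)$Z[, 1:2]
  z_sub <- meetsemg:::meet_probability_stack(m_sub, X)$Z[, 1:2]
  expect_equal(z_full, z_sub, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("MEET recovers the generator's classes and beats the bias floor", {
  cmp <- compare_models(fm6, split = 0.7, seed = 5)
  expect_gte(cmp$reports$meet$accuracy, 0.95)
  # at worst one percentage point behind the gate-family baseline
  expect_gte(cmp$reports$meet$accuracy, cmp$reports$et$accuracy - 0.01)
  expect_gt(cmp$reports$meet$accuracy, 1 / 6)
  # empty input predicts an empty vector
  m <- meet_fit(fm6, seed = 1)
  expect_identical(predict(m, fm6$values[0, , drop = FALSE]), integer(0))
})

test_that("the per-expert gate-weighting variant is available and sane", {
  m <- meet_fit(fm6, a = 2, seed = 7, fusion = "per_expert")
  preds <- predict(m, fm6)
  expect_true(all(preds %in% 1:6))
  expect_gte(mean(preds == fm6$labels), 0.9)  # training-set recovery
})

test_that("models survive a save/load round trip with a JSON sidecar", {
  m <- meet_fit(fm6, seed = 21)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, fm6), predict(m, fm6))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$a, 2)
  expect_equal(side$train_seed, 21)
  expect_length(side$partition, 3)
})
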