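test_that("a separable 1-D problem yields a depth-1 tree with a valid cut", {
  x <- matrix(c(1, 2, 3, 4, 7, 8, 9, 10), ncol = 1,
              dimnames = list(NULL, "amp_avg"))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  tree <- train_tree(x, y)
  expect_identical(tree$root$type, "split")
  expect_gt(tree$root$threshold, 4)
  expect_lte(tree$root$threshold, 7)
  expect_identical(tree$root$left$type, "leaf")
  expect_equal(predict(tree, x), y)
})

test_that("training is deterministic: identical data gives identical files", {
  set.seed(41)
  X <- matrix(runif(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- as.integer(X[, 1] + X[, 2] > 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_tree(train_tree(X, y), f1)
  write_tree(train_tree(X, y), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("XOR needs depth 2: depth 1 is capped at 75%, depth 2 is exact", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(0L, 1L, 1L, 0L)
  t1 <- train_tree(X, y, max_depth = 1L, min_leaf = 1L)
  t2 <- train_tree(X, y, max_depth = 2L, min_leaf = 1L)
  expect_lte(mean(predict(t1, X) == y), 0.75)
  expect_equal(predict(t2, X), y)
})

test_that("degenerate and memorizing trees behave per contract", {
  X <- matrix(1:6, ncol = 1, dimnames = list(NULL, "f"))
  t0 <- train_tree(X, rep(3L, 6))
  expect_identical(t0$root$type, "leaf")
  expect_equal(predict(t0, X), rep(3L, 6))
  # unique feature values, unrestricted depth: perfect memorization
  set.seed(42)
  Xu <- matrix(sample(seq(0, 1, length.out = 40)), ncol = 2,
               dimnames = list(NULL, c("f1", "f2")))
  yu <- sample(0:4, 20, replace = TRUE)
  tm <- train_tree(Xu, yu, max_depth = 30L, min_leaf = 1L)
  expect_equal(predict(tm, Xu), yu)
})

test_that("prediction traverses manual trees and validates its schema", {
  model <- structure(list(
    root = list(type = "split", feature = 1L, threshold = 0.5,
                left = list(type = "leaf", class_index = 1L, counts = c(3L, 0L)),
                right = list(type = "leaf", class_index = 2L, counts = c(0L, 3L))),
    features = "amp_avg", classes = c(0L, 4L),
    config = list(max_depth = 1L, min_leaf = 1L, criterion = "gini")),
    class = "tap_tree")
  expect_identical(predict(model, c(amp_avg = 0.2)), 0L)
  expect_identical(predict(model, c(amp_avg = 0.9)), 4L)
  expect_error(predict(model, c(freq = 1)), "missing: amp_avg")
})

test_that("serialized models reload and predict identically", {
  set.seed(43)
  ds <- generate_dataset(severity_profile(), n_per_class = 8, seed = 5)
  feats <- suppressWarnings(dataset_features(ds))
  model <- train_tree(feats[, tap_feature_names()], feats$label)
  path <- tempfile(fileext = ".json")
  write_tree(model, path)
  back <- read_tree(path)
  expect_identical(predict(back, feats[, tap_feature_names()]),
                   predict(model, feats[, tap_feature_names()]))
  # internal nodes only use canonical feature names (white-box contract)
  txt <- paste(readLines(path), collapse = "")
  used <- regmatches(txt, gregexpr('"feature":\\s*"[a-z_0-9]+"', txt))[[1]]
  used <- gsub('.*"([a-z_0-9]+)"$', "\\1", used)
  expect_true(all(used %in% tap_feature_names()))
  unlink(path)
})

test_that("stratified split preserves class balance and reproducibility", {
  labels <- rep(0:4, each = 20)
  s1 <- stratified_split(labels, 0.2, seed = 9)
  s2 <- stratified_split(labels, 0.2, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1$test, 20)
  expect_equal(as.numeric(table(labels[s1$test])), rep(4, 5))
  expect_length(intersect(s1$train, s1$test), 0)
})

test_that("the rule classifier maps interruption counts per the rating bands", {
  f <- function(hh = 0, bp = 8, a2 = 0, vel = 7, amp = 1.2, n = 10) {
    fv <- stats::setNames(numeric(15), tap_feature_names())
    fv[c("age", "sex")] <- c(70, 1)
    fv["hh"] <- hh; fv["amp_bp"] <- bp; fv["amp_alpha2"] <- a2
    fv["vel_avg"] <- vel; fv["amp_avg"] <- amp; fv["n_peaks"] <- n
    fv["freq"] <- 2
    fv
  }
  expect_identical(baseline_sp(f()), 0L)
  expect_identical(baseline_sp(f(hh = 1)), 1L)
  expect_identical(baseline_sp(f(hh = 4)), 2L)
  expect_identical(baseline_sp(f(hh = 6)), 3L)
  # monotone in the interruption count
  scores <- vapply(0:8, function(h) baseline_sp(f(hh = h)), integer(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("the rule classifier grades decrement onset, slowing and severity", {
  f <- function(hh = 0, bp = 8, a2 = 0, vel = 7, amp = 1.2, n = 10) {
    fv <- stats::setNames(numeric(15), tap_feature_names())
    fv[c("age", "sex")] <- c(70, 1)
    fv["hh"] <- hh; fv["amp_bp"] <- bp; fv["amp_alpha2"] <- a2
    fv["vel_avg"] <- vel; fv["amp_avg"] <- amp; fv["n_peaks"] <- n
    fv["freq"] <- 2
    fv
  }
  # decrement position: late / midway / right after the first tap
  expect_identical(baseline_sp(f(a2 = -0.1, bp = 8)), 1L)
  expect_identical(baseline_sp(f(a2 = -0.1, bp = 5)), 2L)
  expect_identical(baseline_sp(f(a2 = -0.1, bp = 2)), 3L)
  # no decrement flag when the slope is shallow
  expect_identical(baseline_sp(f(a2 = -0.001, bp = 2)), 0L)
  # slowing bands
  expect_identical(baseline_sp(f(vel = 5)), 1L)
  expect_identical(baseline_sp(f(vel = 3.5)), 2L)
  expect_identical(baseline_sp(f(vel = 1.5)), 3L)
  # barely performable dominates everything
  expect_identical(baseline_sp(f(n = 3)), 4L)
  expect_identical(baseline_sp(f(amp = 0.2)), 4L)
  # worst criterion wins
  expect_identical(baseline_sp(f(hh = 1, a2 = -0.1, bp = 5)), 2L)
})

test_that("calibrated cutoffs derive from the severity profile ordering", {
  cuts <- calibrate_baseline_cutoffs(severity_profile())
  expect_gt(cuts$vel_slight, cuts$vel_mild)
  expect_gt(cuts$vel_mild, cuts$vel_moderate)
  expect_lt(cuts$decrement_slope, 0)
  # and they match the packaged defaults
  expect_equal(unclass(cuts), unclass(baseline_cutoffs()), tolerance = 1e-9)
})
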