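test_that("small-size splits share one test set and split 80/20", {
  d <- split_fixture()
  splits <- make_small_splits(d, sizes = c(10L, 20L),
                              replicates = c(101L, 23L), seed = 5)
  expect_length(splits, 124L)
  sizes <- vapply(splits, function(sp) sp$metadata$size, 0L)
  expect_equal(sum(sizes == 10L), 101L)
  expect_equal(sum(sizes == 20L), 23L)
  test0 <- splits[[1]]$test
  expect_length(test0, round(0.1 * nrow(d)))
  for (sp in splits) {
    expect_identical(sp$test, test0)
    expect_length(sp$train, round(0.8 * sp$metadata$size))
    expect_length(sp$val, sp$metadata$size - round(0.8 * sp$metadata$size))
    expect_length(intersect(c(sp$train, sp$val), sp$test), 0L)
    expect_length(intersect(sp$train, sp$val), 0L)
  }
  # replicates differ
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))
  # a size larger than the pool is refused
  expect_error(make_small_splits(d, sizes = 10000L, replicates = 1L),
               "exceeds")
})

test_that("position extrapolation separates positions between train and test", {
  d <- split_fixture()
  splits <- make_extrapolation_split(d, "position", n_replicates = 3L,
                                     seed = 7)
  keys <- biophyslm:::variant_keys(d$variant)
  for (sp in splits) {
    train_pos <- sp$metadata$train_units
    for (i in c(sp$train, sp$val))
      expect_true(all(keys[[i]]$pos %in% train_pos))
    for (i in sp$test)
      expect_false(any(keys[[i]]$pos %in% train_pos))
    expect_length(intersect(sp$train, sp$val), 0L)
    expect_length(intersect(c(sp$train, sp$val), sp$test), 0L)
  }
  expect_false(identical(splits[[1]]$metadata$train_units,
                         splits[[2]]$metadata$train_units))
})

test_that("mutation extrapolation discards train/test straddlers", {
  d <- split_fixture()
  sp <- make_extrapolation_split(d, "mutation", n_replicates = 1L,
                                 seed = 9)[[1]]
  keys <- biophyslm:::variant_keys(d$variant)
  train_m <- sp$metadata$train_units
  used <- c(sp$train, sp$val, sp$test)
  for (i in seq_len(nrow(d))) {
    mu <- keys[[i]]$mut
    mixed <- any(mu %in% train_m) && !all(mu %in% train_m)
    if (mixed) expect_false(i %in% used)
  }
  for (i in c(sp$train, sp$val)) expect_true(all(keys[[i]]$mut %in% train_m))
  for (i in sp$test) expect_false(any(keys[[i]]$mut %in% train_m))
})

test_that("regime and score extrapolation build the stated pools", {
  d <- split_fixture()
  n_subs <- vapply(biophyslm:::variant_keys(d$variant),
                   function(k) length(k$pos), 0L)
  sp <- make_extrapolation_split(d, "regime", n_replicates = 1L,
                                 seed = 3)[[1]]
  expect_true(all(n_subs[c(sp$train, sp$val)] == 1L))
  expect_true(all(n_subs[sp$test] == 2L))
  # 10% sample of the double pool, 80/20 train/val of singles
  expect_length(sp$test, max(1L, round(0.1 * sum(n_subs == 2L))))
  expect_length(sp$train, round(0.8 * sum(n_subs == 1L)))

  sc <- make_extrapolation_split(d, "score", n_replicates = 1L,
                                 seed = 4)[[1]]
  expect_true(all(d$score[c(sc$train, sc$val)] < 0))
  expect_true(all(d$score[sc$test] > 0))
  expect_length(sc$test, sum(d$score > 0))
})

test_that("the resampling cap bounds the split universe", {
  d <- split_fixture()
  sp <- make_extrapolation_split(d, "position", n_replicates = 1L,
                                 seed = 2, cap = 300L)[[1]]
  expect_lte(length(c(sp$train, sp$val, sp$test)), 300L)
})

test_that("rank metrics behave on hand-checkable cases", {
  y <- c(5, 4, 3, 2, 1, 0)
  expect_equal(evaluate_predictions(y, y, k = 2L),
               list(spearman = 1, recall_top_k = 1))
  expect_equal(evaluate_predictions(y, -y, k = 2L)$spearman, -1)
  # one swap across the top-2 boundary: recall@2 = 1/2
  pred <- c(5, 3, 4, 2, 1, 0)
  expect_equal(evaluate_predictions(y, pred, k = 2L)$recall_top_k, 0.5)
  # recall is invariant to strictly monotone transforms of predictions
  withr::with_seed(8, {
    yt <- rnorm(50); yp <- rnorm(50)
  })
  r1 <- evaluate_predictions(yt, yp, k = 10L)
  r2 <- evaluate_predictions(yt, exp(3 * yp) + 2, k = 10L)
  expect_equal(r2$recall_top_k, r1$recall_top_k)
  expect_equal(r2$spearman, r1$spearman)
  expect_warning(r3 <- evaluate_predictions(rep(1, 5), rnorm(5), k = 2L),
                 "constant")
  expect_true(is.na(r3$spearman))
  expect_error(evaluate_predictions(1:5, 1:5, k = 10L), "k exceeds")
})

test_that("epistasis arithmetic matches the worked example", {
  # base GV; score table: wt 0, G0A -> 1, V1L -> 2, double -> 5
  lookup <- c(GV = 0, AV = 1, GL = 2, AL = 5)
  score_fn <- function(seqs) unname(lookup[seqs])
  res <- epistasis_scores(score_fn, "GV", c("G0A", "V1L", "G0A,V1L"))
  sc <- res$scores
  expect_equal(sc$w[sc$variant == "G0A,V1L"], 5)
  expect_equal(sc$E[sc$variant == "G0A,V1L"], 2)
  expect_equal(sc$E[sc$variant == "G0A"], 0)
  expect_equal(res$positional[1, 2], 2)
  expect_identical(res$positional, t(res$positional))
})

test_that("split indices always serialize to valid JSON", {
  d <- split_fixture()
  sp <- make_extrapolation_split(d, "score", n_replicates = 2L, seed = 1)
  path <- tempfile(fileext = ".json")
  write_splits(sp, path)
  back <- jsonlite::read_json(path)
  expect_length(back, 2L)
  expect_setequal(unlist(back[[1]]$train), sp[[1]]$train)
  expect_identical(back[[1]]$split_type, "score")
})
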