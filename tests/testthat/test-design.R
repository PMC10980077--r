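test_that("the temperature schedule is log-spaced between its endpoints", {
  temps <- annealing_temperature(0:99, 100L)
  expect_equal(temps[1], 10)
  expect_equal(temps[100], 0.01)
  expect_true(all(diff(temps) < 0))
  # log-spacing: constant ratio between consecutive temperatures
  expect_equal(diff(log10(temps)), rep(diff(log10(temps))[1], 99),
               tolerance = 1e-12)
})

test_that("annealing finds the exhaustive optimum on an additive toy", {
  fx <- design_fixture()
  cfg <- design_config(2L, "observed", fx$allowed, n_runs = 10L,
                       n_steps = 2000L, seed = 1)
  legal <- biophyslm:::legal_mutations(fx$s$sequence, cfg)
  pairs <- combn(legal, 2L)
  ok <- biophyslm:::token_pos(pairs[1, ]) != biophyslm:::token_pos(pairs[2, ])
  cand <- apply(pairs[, ok], 2L, biophyslm:::tokens_to_variant)
  scores <- fx$score_fn(variant_sequences(fx$s$sequence, cand))
  opt <- cand[which.max(scores)]
  hits <- 0L
  for (r in 1:10) {
    res <- run_simulated_annealing(fx$score_fn, fx$s$sequence, cfg,
                                   run_seed = r)
    expect_equal(n_substitutions(res$best), 2L)
    expect_equal(n_substitutions(res$final), 2L)
    if (res$best == opt) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("every visited and proposed state satisfies the constraint", {
  fx <- design_fixture()
  for (mode in c("observed", "unobserved")) {
    cfg <- design_config(2L, mode, fx$allowed, n_steps = 300L, seed = 2)
    for (r in 1:4) {
      res <- run_simulated_annealing(fx$score_fn, fx$s$sequence, cfg,
                                     run_seed = 10 + r,
                                     log_trajectory = TRUE)
      toks <- unique(unlist(strsplit(res$trajectory$proposal, ",")))
      if (mode == "observed") {
        expect_true(all(toks %in% cfg$allowed_mutations))
      } else {
        expect_false(any(toks %in% cfg$allowed_mutations))
      }
      nm <- vapply(res$trajectory$proposal, n_substitutions, 0L)
      expect_true(all(nm == 2L))
    }
    base <- random_baseline_variants(fx$s$sequence, cfg, 200L, seed = 3)
    btoks <- strsplit(base, ",")
    expect_true(all(vapply(base, n_substitutions, 0L) == 2L))
    # distinct positions within every baseline
    expect_true(all(vapply(btoks, function(tk)
      anyDuplicated(biophyslm:::token_pos(tk)) == 0L, TRUE)))
    if (mode == "observed") {
      expect_true(all(unlist(btoks) %in% cfg$allowed_mutations))
    } else {
      expect_false(any(unlist(btoks) %in% cfg$allowed_mutations))
    }
  }
})

test_that("acceptance decays as the chain cools; constant scores always accept", {
  fx <- design_fixture()
  cfg <- design_config(2L, "observed", fx$allowed, n_steps = 2000L,
                       seed = 4)
  res <- run_simulated_annealing(fx$score_fn, fx$s$sequence, cfg,
                                 run_seed = 6, log_trajectory = TRUE)
  quart <- cut(seq_len(2000), 4, labels = FALSE)
  acc <- tapply(res$trajectory$accepted, quart, mean)
  # rank test across schedule quartiles: acceptance non-increasing
  expect_lte(cor(seq_len(4), as.numeric(acc), method = "spearman"), 0)
  expect_gt(acc[1], acc[4])

  # constant objective: a constraint-preserving random walk, all accepted
  flat <- run_simulated_annealing(function(seqs) rep(1, length(seqs)),
                                  fx$s$sequence,
                                  design_config(2L, "observed", fx$allowed,
                                                n_steps = 200L, seed = 1),
                                  run_seed = 2, log_trajectory = TRUE)
  expect_true(all(flat$trajectory$accepted))
})

test_that("BLOSUM62 dissimilarity is a proper zero-diagonal symmetric form", {
  seqs <- c("GAVL", "GAVL", "GAWL", "CCCC")
  D <- blosum_distance_matrix(seqs)
  expect_equal(D[1, 2], 0)
  expect_identical(D, t(D))
  expect_true(all(D >= 0))
  expect_true(all(diag(D) == 0))
  expect_gt(D[1, 4], D[1, 3])
  # raw-similarity variant is offered but differs
  Draw <- blosum_distance_matrix(seqs, raw_similarity = TRUE)
  expect_false(identical(D, Draw))
})

test_that("clustering selects diverse representatives greedily", {
  # three well-separated blobs built on disjoint position blocks
  s <- make_toy_structure(30, seed = 9)
  blocks <- list(0:4, 10:14, 20:24)
  blob <- function(block, n, seed) {
    chars <- strsplit(s$sequence, "")[[1]]
    withr::with_seed(seed, vapply(seq_len(n), function(i) {
      ps <- sample(block, 3)
      toks <- vapply(ps, function(p)
        paste0(chars[p + 1], p,
               sample(setdiff(c("W", "F", "Y"), chars[p + 1]), 1)), "")
      biophyslm:::tokens_to_variant(toks)
    }, ""))
  }
  designs <- c(blob(blocks[[1]], 160, 1), blob(blocks[[2]], 150, 2),
               blob(blocks[[3]], 150, 3))
  rep_ <- cluster_and_select(designs, s$sequence, n_clusters = 3L,
                             min_cluster_size = 100L, n_select = 2L)
  expect_length(rep_$selected, 2L)
  # first selected cluster is the largest blob
  first_members <- which(rep_$assignments ==
                           rep_$selected_clusters[1])
  expect_length(first_members, 160L)
  # the second is the exhaustively-checked farthest representative
  reps <- rep_$representatives
  Drep <- blosum_distance_matrix(
    variant_sequences(s$sequence, unname(reps)))
  first <- which(names(reps) == rep_$selected_clusters[1])
  expected_second <- as.integer(names(reps)[-first][
    which.max(Drep[first, -first])])
  expect_equal(rep_$selected_clusters[2], expected_second)

  # an undersized blob is never represented
  designs4 <- c(designs, blob(list(25:29)[[1]], 50, 4))
  expect_warning(
    rep4 <- cluster_and_select(designs4, s$sequence, n_clusters = 4L,
                               min_cluster_size = 100L, n_select = 4L),
    "survive")
  small_members <- tail(seq_along(designs4), 50)
  small_cluster <- unique(rep4$assignments[small_members])
  expect_false(any(small_cluster %in% rep4$selected_clusters))
})
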