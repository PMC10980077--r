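# tiny configuration used for exact-arithmetic checks
tiny_cfg <- function(mode = "3d") {
  model_config(embed_dim = 8L, n_layers = 1L, n_heads = 1L, ff_dim = 8L,
               n_tasks = 1L, head_hidden = 4L, rpe_mode = mode, dropout = 0)
}

test_that("parameter counts match a hand enumeration of tensor shapes", {
  s <- make_toy_structure(5, seed = 1)
  m <- build_model(tiny_cfg(), structure = s)
  d <- 8; ff <- 8; C <- 4; dh <- 8
  by_hand <- 21 * d +                         # embedding (20 aa + pad)
    (2 * d +                                  # ln1
       4 * (d * d + d) +                      # q, k, v, out projections
       2 * C * dh +                           # RPE key/value tables
       2 * d +                                # ln2
       d * ff + ff + ff * d + d) +            # feed-forward
    2 * d +                                   # final layer norm
    d * 4 + 4 +                               # pooled hidden layer
    4 * 1 + 1                                 # task output
  expect_identical(count_parameters(m), as.integer(by_hand))
  # every parameter tensor is counted exactly once
  expect_identical(count_parameters(m),
                   sum(vapply(m$params, length, 0L)))
})

test_that("prediction is shaped, deterministic, and length-checked", {
  fx <- fx_pretrain_table(TRUE)
  m <- build_model(fx_mini_config(), structure = fx$structure, seed = 2)
  seqs <- variant_sequences(fx$structure$sequence,
                            sample_subvariants(fx$structure$sequence, 3,
                                               max_subs = 2, seed = 1))
  p1 <- predict(m, seqs)
  expect_equal(dim(p1), c(3L, 55L))
  expect_identical(p1, predict(m, seqs))
  expect_error(predict(m, substr(seqs[1], 1, 10)), "length")
  # batch order permutes outputs identically (no cross-sequence leakage)
  p2 <- predict(m, seqs[c(3, 1, 2)])
  expect_equal(p2, p1[c(3, 1, 2), ])
})

test_that("relative position embeddings are the only positional signal", {
  s <- make_toy_structure(12, seed = 3)
  m3 <- build_model(tiny_cfg("3d"), structure = s, seed = 7)
  m1 <- build_model(tiny_cfg("1d"), structure = s, seed = 7)
  # zero the RPE tables and share every other weight
  m3$params$l0_rk[] <- 0
  m3$params$l0_rv[] <- 0
  m1$params <- m3$params
  m1$params$l0_rk <- matrix(0, 17, 8)
  m1$params$l0_rv <- matrix(0, 17, 8)
  seqs <- variant_sequences(s$sequence,
                            enumerate_variants(s$sequence, 1)[c(1, 50, 100)])
  expect_equal(predict(m3, seqs), predict(m1, seqs), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  s <- make_toy_structure(6, seed = 2)
  cfg <- model_config(embed_dim = 8L, n_layers = 2L, n_heads = 2L,
                      ff_dim = 12L, n_tasks = 3L, head_hidden = 7L,
                      rpe_mode = "3d", dropout = 0)
  m <- build_model(cfg, structure = s, seed = 5)
  seqs <- variant_sequences(s$sequence,
                            c("", enumerate_variants(s$sequence, 1)[1:3]))
  tokens <- biophyslm:::encode_tokens(seqs)
  targets <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  run_loss <- function(mm) biophyslm:::nn_run(mm, tokens,
                                              targets = targets)$loss
  r <- biophyslm:::nn_run(m, tokens, targets = targets, want_grads = TRUE)
  withr::with_seed(3, {
    for (nm in names(r$grads)) {
      for (i in sample(length(m$params[[nm]]),
                       min(3L, length(m$params[[nm]])))) {
        eps <- 1e-6
        mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
        mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
        num <- (run_loss(mp) - run_loss(mm)) / (2 * eps)
        expect_equal(r$grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("attention is row-normalized and introspection is shaped", {
  s <- make_toy_structure(10, seed = 4)
  m <- build_model(tiny_cfg(), structure = s, seed = 1)
  ins <- introspect(m)
  L <- 10
  expect_equal(dim(ins$attention), c(L, L))
  # each head's rows sum to 1; so does their mean
  expect_equal(unname(rowSums(ins$attention)), rep(1, L), tolerance = 1e-9)
  expect_equal(dim(ins$representations), c(L, 8L))
})

test_that("checkpoints reload to an equivalent model", {
  s <- make_toy_structure(8, seed = 5)
  m <- build_model(tiny_cfg(), structure = s, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  seqs <- variant_sequences(s$sequence,
                            enumerate_variants(s$sequence, 1)[1:4])
  expect_identical(predict(m2, seqs), predict(m, seqs))
})
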