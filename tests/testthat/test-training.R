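test_that("train_config presets supply defaults that explicit arguments override", {
  ft <- train_config(preset = "finetune")
  expect_equal(ft$epochs, 250L)
  expect_identical(ft$schedule, "cosine")
  expect_equal(ft$warmup_frac, 0.01)
  expect_equal(ft$weight_decay, 0.1)
  short <- train_config(preset = "finetune", epochs = 40L)
  expect_equal(short$epochs, 40L)
  expect_identical(short$schedule, "cosine")
  pre <- train_config(preset = "pretrain", schedule = "cosine")
  expect_equal(pre$epochs, 30L)
  expect_identical(pre$schedule, "cosine")
  expect_equal(pre$weight_decay, 0.01)
  # YAML round trip honors the same precedence
  path <- tempfile(fileext = ".yaml")
  writeLines(c("preset: finetune", "epochs: 40", "seed: 3"), path)
  yc <- train_config_from_yaml(path)
  expect_equal(yc$epochs, 40L)
  expect_identical(yc$schedule, "cosine")
  expect_equal(yc$seed, 3L)
  writeLines("bogus_field: 1", path)
  expect_error(train_config_from_yaml(path), "unknown")
})

test_that("the learning-rate schedule matches its closed form", {
  total <- 1000L
  base <- 1e-3
  warm <- round(0.02 * total)
  lr <- lr_schedule(0:(total - 1), total, base, 0.02, "constant")
  expect_equal(lr[1], 0)                       # warmup starts at 0
  expect_equal(lr[warm + 1], base)             # peak at warmup end
  expect_equal(lr[2], base / warm)
  expect_true(all(lr[(warm + 1):total] == base))
  lrc <- lr_schedule(0:(total - 1), total, base, 0.01, "cosine")
  w2 <- round(0.01 * total)
  prog <- ((w2:(total - 1)) - w2) / (total - w2)
  expect_equal(lrc[(w2 + 1):total], base * 0.5 * (1 + cos(pi * prog)))
  expect_lt(lrc[total], 1e-7)                  # decays to ~0
})

test_that("gradient clipping bounds the global norm", {
  g <- list(a = matrix(3, 2, 2), b = matrix(-4, 1, 5))
  cl <- biophyslm:::clip_grads(g, 0.5)
  nrm <- sqrt(sum(vapply(cl$grads, function(x) sum(x^2), 0)))
  expect_equal(nrm, 0.5, tolerance = 1e-12)
  # already-small gradients pass through untouched
  g2 <- lapply(g, function(x) x * 1e-3)
  expect_identical(biophyslm:::clip_grads(g2, 0.5)$grads, g2)
})

test_that("batches are single-structure and cover all rows", {
  base_pdb <- rep(c("p1", "p2"), c(130, 70))
  withr::with_seed(1, {
    batches <- pdb_batches(base_pdb, 32L)
    for (b in batches) expect_length(unique(base_pdb[b]), 1L)
    expect_setequal(unlist(batches), seq_along(base_pdb))
    expect_length(unlist(batches), 200L)
  })
})

test_that("gradient accumulation reproduces the full-batch computation", {
  fx <- fx_pretrain_table(TRUE)
  cfg <- fx_mini_config()
  cfg$dropout <- 0
  m <- build_model(cfg, structure = fx$structure, seed = 3)
  rows <- 1:48
  tokens <- biophyslm:::encode_tokens(
    variant_sequences(fx$structure$sequence, fx$table$variant[rows]))
  targets <- as.matrix(fx$table[rows, biophyslm:::attr_term_cols(fx$table)])
  full <- biophyslm:::accum_run(m, tokens, targets, training = FALSE,
                                dropout_seed = 1, chunk = NULL)
  chunked <- biophyslm:::accum_run(m, tokens, targets, training = FALSE,
                                   dropout_seed = 1, chunk = 13L)
  expect_equal(chunked$loss, full$loss, tolerance = 1e-10)
  for (nm in names(full$grads))
    expect_equal(chunked$grads[[nm]], full$grads[[nm]], tolerance = 1e-8)
})

test_that("pretraining learns the simulated energetics", {
  fit <- fx_pretrained("3d", additive = TRUE)
  h <- fit$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  val <- fit$splits$val
  seqs <- variant_sequences(fit$structure$sequence,
                            fit$table$variant[val])
  pred <- predict(fit$model, seqs)
  rho <- cor(pred[, "total_score"], fit$table$total_score[val],
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("pretraining rejects non-standardized tables", {
  fx <- fx_pretrain_table(TRUE)
  m <- build_model(fx_mini_config(), structure = fx$structure, seed = 1)
  raw <- fx$table
  raw$total_score <- raw$total_score * 40 + 100
  for (tm in biophyslm:::attr_term_cols(raw))
    raw[[tm]] <- raw[[tm]] * 3 + 2
  expect_error(pretrain(m, raw, fx$structure, fx$splits),
               "standardized")
})

test_that("phase-1 finetuning freezes the backbone; selection honors the threshold", {
  fx <- fx_pretrain_table(TRUE)
  s <- fx$structure
  d <- make_experimental_dataset(s, fx$params, 80, max_subs = 2, seed = 12)
  src <- build_model(fx_mini_config(), structure = s, seed = 6)
  tm <- make_target_model(src, attach = "fc")
  cfg <- train_config(preset = "finetune", epochs = 3L, batch_size = 64L,
                      seed = 2)
  # head-only phase: backbone weights bit-identical before and after
  res <- biophyslm:::run_training(
    tm, within(d, base_pdb <- s$id), setNames(list(s), s$id),
    list(train = 1:40, val = 41:56), cfg,
    targets = matrix(d$score, ncol = 1),
    phases = list(list(epochs = 3L, base_lr = cfg$base_lr,
                       trainable = c("head_w", "head_b"))))
  backbone <- setdiff(names(tm$params), c("head_w", "head_b"))
  for (nm in backbone)
    expect_identical(res$model$params[[nm]], tm$params[[nm]])
  expect_false(identical(res$model$params$head_w, tm$params$head_w))

  # validation below the threshold: last-epoch model; at threshold: best
  small <- finetune_dual_phase(src, d, s, list(train = 1:40, val = 41:56),
                               cfg, selection_threshold = 32L)
  expect_identical(attr(small$history, "selection_rule"), "last_epoch")
  big <- finetune_dual_phase(src, d, s, list(train = 1:40, val = 41:72),
                             cfg, selection_threshold = 32L)
  expect_identical(attr(big$history, "selection_rule"), "best_validation")
  expect_equal(nrow(big$history), 6L)  # selection spans both phases
})

test_that("the ridge head equals the normal-equations oracle", {
  withr::with_seed(4, {
    X <- matrix(rnorm(60 * 7), 60, 7)
    y <- rnorm(60)
  })
  fit <- biophyslm:::ridge_solve(X, y, alpha = 1)
  # oracle: centered normal equations solved directly
  Xc <- sweep(X, 2, colMeans(X))
  w <- solve(crossprod(Xc) + diag(1, 7), crossprod(Xc, y - mean(y)))
  expect_equal(fit$coef, drop(w), tolerance = 1e-8)
  expect_equal(fit$intercept, mean(y) - sum(colMeans(X) * w),
               tolerance = 1e-8)
  # huge alpha shrinks to the intercept-only model
  big <- biophyslm:::ridge_solve(X, y, alpha = 1e12)
  expect_lt(max(abs(big$coef)), 1e-9)
  expect_equal(big$intercept, mean(y), tolerance = 1e-6)
  # duplicated rows: solution still equals the oracle on the duplicated
  # design matrix
  X2 <- rbind(X, X[1:20, ]); y2 <- c(y, y[1:20])
  fit2 <- biophyslm:::ridge_solve(X2, y2, alpha = 1)
  X2c <- sweep(X2, 2, colMeans(X2))
  w2 <- solve(crossprod(X2c) + diag(1, 7), crossprod(X2c, y2 - mean(y2)))
  expect_equal(fit2$coef, drop(w2), tolerance = 1e-8)

  # end-to-end: predictions on the training rows match the oracle
  fx <- fx_pretrain_table(TRUE)
  s <- fx$structure
  d <- make_experimental_dataset(s, fx$params, 40, max_subs = 2, seed = 3)
  m <- build_model(fx_mini_config(), structure = s, seed = 2)
  rh <- fit_ridge_head(m, d, s, list(train = 1:30), alpha = 1)
  feats <- model_features(m, variant_sequences(s$sequence, d$variant[1:30]))
  fc <- sweep(feats, 2, colMeans(feats))
  wo <- solve(crossprod(fc) + diag(1, ncol(fc)),
              crossprod(fc, d$score[1:30] - mean(d$score[1:30])))
  pred <- predict(rh, variant_sequences(s$sequence, d$variant[1:30]))
  oracle_pred <- drop(feats %*% wo) + mean(d$score[1:30]) -
    sum(colMeans(feats) * wo)
  expect_equal(pred, oracle_pred, tolerance = 1e-6)
})

test_that("pretraining splits partition the rows 5/80/10/10", {
  sp <- make_pretrain_splits(1000, seed = 3)
  expect_length(sp$withheld, 50L)
  expect_length(sp$train, 760L)
  expect_length(sp$val, 95L)
  expect_setequal(c(sp$train, sp$val, sp$test, sp$withheld), 1:1000)
})
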