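#' Training configuration
#'
#' Optimizer and schedule hyperparameters. Two presets mirror the published
#' recipes: `"pretrain"` (30 epochs, AdamW lr 1e-3, linear warmup over 2% of
#' steps, weight decay 0.01, gradient-norm clip 0.5) and `"finetune"`
#' (dual-phase 250 + 250 epochs, lr 1e-3 then 1e-4, 1% warmup plus cosine
#' decay per phase, batch 128, weight decay 0.1, clip 0.5).
#'
#' @param epochs Number of epochs (per phase for finetuning).
#' @param base_lr Peak learning rate.
#' @param warmup_frac Fraction of total steps used for linear warmup.
#' @param schedule `"constant"` (after warmup) or `"cosine"` decay.
#' @param batch_size Batch size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param betas,eps AdamW moment coefficients and epsilon.
#' @param grad_clip_norm Global gradient-norm clip.
#' @param accum_chunk Maximum rows per forward/backward chunk; larger
#'   batches are reproduced by gradient accumulation.
#' @param seed Seed governing batch order and dropout.
#' @param preset `"pretrain"` or `"finetune"` (overrides the rest).
#' @return A `"train_config"` list.
#' @export
train_config <- function(epochs = 30L, base_lr = 1e-3, warmup_frac = 0.02,
                         schedule = c("constant", "cosine"),
                         batch_size = 128L, weight_decay = 0.01,
                         betas = c(0.9, 0.999), eps = 1e-8,
                         grad_clip_norm = 0.5, accum_chunk = NULL,
                         seed = 1L, preset = NULL) {
  user_gave <- c(epochs = !missing(epochs), base_lr = !missing(base_lr),
                 warmup_frac = !missing(warmup_frac),
                 schedule = !missing(schedule),
                 weight_decay = !missing(weight_decay),
                 batch_size = !missing(batch_size))
  schedule <- match.arg(schedule)
  if (!is.null(preset)) {
    # preset supplies defaults; explicitly passed arguments still win
    preset <- match.arg(preset, c("pretrain", "finetune"))
    defaults <- if (preset == "pretrain") {
      list(epochs = 30L, base_lr = 1e-3, warmup_frac = 0.02,
           schedule = "constant", weight_decay = 0.01)
    } else {
      list(epochs = 250L, base_lr = 1e-3, warmup_frac = 0.01,
           schedule = "cosine", batch_size = 128L, weight_decay = 0.1)
    }
    if (!user_gave[["epochs"]]) epochs <- defaults$epochs
    if (!user_gave[["base_lr"]]) base_lr <- defaults$base_lr
    if (!user_gave[["warmup_frac"]]) warmup_frac <- defaults$warmup_frac
    if (!user_gave[["schedule"]]) schedule <- defaults$schedule
    if (!user_gave[["weight_decay"]]) weight_decay <- defaults$weight_decay
    if (!user_gave[["batch_size"]] && !is.null(defaults$batch_size))
      batch_size <- defaults$batch_size
  }
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 warmup_frac = warmup_frac, schedule = schedule,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, betas = betas, eps = eps,
                 grad_clip_norm = grad_clip_norm,
                 accum_chunk = accum_chunk, seed = as.integer(seed)),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' The file holds any subset of the [train_config()] fields (and optionally
#' `preset`); unspecified fields fall back to the preset or function
#' defaults.
#'
#' @param path YAML file path.
#' @return A `"train_config"`.
#' @export
train_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown train_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(train_config, vals)
}

#' Learning-rate schedule
#'
#' Linear warmup from 0 (the rate at step 0 is exactly 0) to `base_lr` at
#' the end of warmup, then either constant or cosine decay to 0 at
#' `total_steps`.
#'
#' @param step 0-based step index (vectorized).
#' @param total_steps Total optimizer steps.
#' @param base_lr Peak rate.
#' @param warmup_frac Warmup fraction of `total_steps`.
#' @param schedule `"constant"` or `"cosine"`.
#' @return Numeric vector of learning rates.
#' @export
lr_schedule <- function(step, total_steps, base_lr, warmup_frac = 0.02,
                        schedule = c("constant", "cosine")) {
  schedule <- match.arg(schedule)
  warm <- max(1, round(warmup_frac * total_steps))
  vapply(step, function(s) {
    if (s < warm) return(base_lr * s / warm)
    if (schedule == "constant") return(base_lr)
    prog <- (s - warm) / max(1, total_steps - warm)
    base_lr * 0.5 * (1 + cos(pi * prog))
  }, 0)
}

# internal: AdamW optimizer state over a named list of parameter matrices
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# internal: clip the global gradient norm in place; returns list(grads, norm)
clip_grads <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(max_norm) && nrm > max_norm && nrm > 0)
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  list(grads = grads, norm = nrm)
}

# internal: one AdamW step over the named grads; only named params update
adamw_step <- function(params, grads, opt, lr, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$betas[1L]; b2 <- cfg$betas[2L]
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + cfg$eps) + cfg$weight_decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

#' Single-structure-per-batch sampler
#'
#' Shuffles rows within each `base_pdb` group and chunks them so that every
#' batch contains variants of a single base structure; batch order is then
#' shuffled across groups. Together the batches cover every row exactly
#' once.
#'
#' @param base_pdb Character vector of group ids, one per row.
#' @param batch_size Batch size.
#' @return List of integer row-index vectors.
#' @export
pdb_batches <- function(base_pdb, batch_size) {
  groups <- split(seq_along(base_pdb), base_pdb)
  batches <- list()
  for (g in groups) {
    g <- sample(g)
    starts <- seq(1L, length(g), by = batch_size)
    for (s in starts)
      batches[[length(batches) + 1L]] <- g[s:min(s + batch_size - 1L,
                                                 length(g))]
  }
  batches[sample.int(length(batches))]
}

# internal: forward/backward over a batch with gradient accumulation.
# Returns list(loss, grads) where loss/grads reproduce the full-batch values
# regardless of chunking.
accum_run <- function(m, tokens, targets, training, dropout_seed, chunk) {
  B <- ncol(tokens)
  if (is.null(chunk) || chunk >= B) {
    r <- nn_run(m, tokens, targets = targets, training = training,
                dropout_seed = dropout_seed, want_grads = TRUE)
    return(list(loss = r$loss, grads = r$grads))
  }
  starts <- seq(1L, B, by = chunk)
  loss <- 0
  grads <- NULL
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + chunk - 1L, B)
    r <- nn_run(m, tokens[, idx, drop = FALSE],
                targets = targets[idx, , drop = FALSE], training = training,
                dropout_seed = dropout_seed + k, want_grads = TRUE)
    w <- length(idx) / B
    loss <- loss + r$loss * w
    if (is.null(grads)) grads <- lapply(r$grads, function(g) g * w)
    else for (nm in names(grads))
      grads[[nm]] <- grads[[nm]] + r$grads[[nm]] * w
  }
  list(loss = loss, grads = grads)
}

# internal: targets matrix (rows x tasks) from an attribute table
attr_targets <- function(t) {
  as.matrix(t[, attr_term_cols(t), drop = FALSE])
}

#' Pretrain a source model on a standardized attribute table
#'
#' Optimizes the sum over score terms of the per-term batch mean squared
#' error with AdamW, linear warmup, and gradient-norm clipping; every batch
#' holds variants of a single base structure. The table must already be
#' standardized (train mean ~0, sd ~1 per group and term); grossly
#' non-standardized input is rejected.
#'
#' @param m A `"source_model"`.
#' @param t Standardized `"attribute_table"` whose score columns are the
#'   training tasks (their number must match the model's `n_tasks`).
#' @param structures Named list of `"protein_structure"` objects keyed by
#'   `base_pdb` (a single structure is accepted for single-protein tables).
#' @param splits List with integer row indices `train` and `val`.
#' @param cfg A `"train_config"`.
#' @return List with `model` (trained) and `history`, a data frame of
#'   per-epoch train/validation losses.
#' @export
pretrain <- function(m, t, structures, splits, cfg = train_config(preset = "pretrain")) {
  stopifnot(inherits(m, "source_model"), inherits(cfg, "train_config"))
  terms <- attr_term_cols(t)
  if (length(terms) != m$cfg$n_tasks)
    stop("table has ", length(terms), " score terms but the model expects ",
         m$cfg$n_tasks, " tasks", call. = FALSE)
  if (inherits(structures, "protein_structure"))
    structures <- setNames(list(structures), structures$id)
  tr <- splits$train
  mu <- mean(colMeans(t[tr, terms, drop = FALSE]))
  sg <- mean(apply(t[tr, terms, drop = FALSE], 2L, sd))
  if (abs(mu) > 0.1 || abs(sg - 1) > 0.1)
    stop("attribute table does not look standardized (train mean ",
         signif(mu, 3), ", sd ", signif(sg, 3), ")", call. = FALSE)
  run_training(m, t, structures, splits, cfg,
               targets = attr_targets(t), task_names = terms)
}

# internal shared loop for pretraining and single-phase finetuning.
# `targets`: full-table numeric matrix. Model must carry rclass for each
# structure; multi-structure tables switch the map per batch.
run_training <- function(m, t, structures, splits, cfg, targets,
                         task_names = NULL, phases = NULL,
                         selection_threshold = Inf) {
  base_pdb <- if ("base_pdb" %in% names(t)) t$base_pdb
              else rep(names(structures)[1L], nrow(t))
  seqs <- character(nrow(t))
  rclass_by_pdb <- list()
  for (pid in unique(base_pdb)) {
    s <- structures[[pid]]
    if (is.null(s)) stop("no structure for base_pdb '", pid, "'",
                         call. = FALSE)
    rows <- base_pdb == pid
    seqs[rows] <- variant_sequences(s$sequence, t$variant[rows])
    map <- relative_distances(if (m$cfg$rpe_mode == "3d") s
                              else nchar(s$sequence),
                              mode = m$cfg$rpe_mode, clip = m$cfg$rpe_clip)
    rclass_by_pdb[[pid]] <- rpe_class_index(map)
  }
  if (is.null(phases))
    phases <- list(list(epochs = cfg$epochs, base_lr = cfg$base_lr,
                        trainable = NULL))
  tr <- splits$train
  val <- splits$val
  val_targets <- targets[val, , drop = FALSE]
  opt <- adamw_init(m$params)
  history <- data.frame()
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  epoch_global <- 0L
  withr::with_seed(cfg$seed, {
    for (ph in seq_along(phases)) {
      phase <- phases[[ph]]
      steps_per_epoch <- length(pdb_batches(base_pdb[tr], cfg$batch_size))
      total_steps <- phase$epochs * steps_per_epoch
      step <- 0L
      for (ep in seq_len(phase$epochs)) {
        epoch_global <- epoch_global + 1L
        tr_loss <- 0
        n_batches <- 0L
        for (bidx in pdb_batches(base_pdb[tr], cfg$batch_size)) {
          rows <- tr[bidx]
          pid <- unique(base_pdb[rows])
          stopifnot(length(pid) == 1L)
          m$rclass <- rclass_by_pdb[[pid]]
          tokens <- encode_tokens(seqs[rows])
          lr <- lr_schedule(step, total_steps, phase$base_lr,
                            cfg$warmup_frac, cfg$schedule)
          ds <- cfg$seed + 7919L * epoch_global + step
          r <- accum_run(m, tokens, targets[rows, , drop = FALSE],
                         training = TRUE, dropout_seed = ds,
                         chunk = cfg$accum_chunk)
          grads <- r$grads
          if (!is.null(phase$trainable))
            grads <- grads[names(grads) %in% phase$trainable]
          cl <- clip_grads(grads, cfg$grad_clip_norm)
          upd <- adamw_step(m$params, cl$grads, opt, lr, cfg)
          m$params <- upd$params
          opt <- upd$opt
          tr_loss <- tr_loss + r$loss
          n_batches <- n_batches + 1L
          step <- step + 1L
        }
        val_loss <- NA_real_
        if (length(val) > 0L) {
          val_loss <- eval_loss(m, seqs[val], val_targets,
                                base_pdb[val], rclass_by_pdb)
          if (is.finite(val_loss) && val_loss < best$loss) {
            best$loss <- val_loss
            best$params <- m$params
            best$epoch <- epoch_global
          }
        }
        history <- rbind(history,
                         data.frame(phase = ph, epoch = epoch_global,
                                    train_loss = tr_loss / n_batches,
                                    val_loss = val_loss))
      }
    }
  })
  select_best <- length(val) >= selection_threshold &&
    !is.null(best$params)
  if (select_best) {
    m$params <- best$params
    selected <- best$epoch
    rule <- "best_validation"
  } else {
    selected <- epoch_global
    rule <- "last_epoch"
  }
  if (!is.null(task_names)) m$task_names <- task_names
  if (length(structures) == 1L) {
    m$rclass <- rclass_by_pdb[[1L]]
    m$base_seq <- structures[[1L]]$sequence
    m$structure_id <- names(structures)[1L]
  }
  attr(history, "selected_epoch") <- selected
  attr(history, "selection_rule") <- rule
  list(model = m, history = history)
}

# internal: evaluation loss over possibly multiple base structures
eval_loss <- function(m, seqs, targets, base_pdb, rclass_by_pdb) {
  total <- 0
  for (pid in unique(base_pdb)) {
    rows <- which(base_pdb == pid)
    m$rclass <- rclass_by_pdb[[pid]]
    r <- nn_run(m, encode_tokens(seqs[rows]),
                targets = targets[rows, , drop = FALSE])
    total <- total + r$loss * length(rows)
  }
  total / length(base_pdb)
}

#' Dual-phase finetuning on an experimental dataset
#'
#' Phase 1 freezes the backbone and trains only the head; phase 2 trains
#' all weights at one tenth of the base rate. Each phase uses linear warmup
#' and cosine decay. After both phases the model from the epoch with the
#' lowest validation loss is returned when the validation set has at least
#' `selection_threshold` examples (32 is the local-model convention, 128
#' the global one); otherwise the last epoch's model is returned, and the
#' selection is made over all epochs of both phases.
#'
#' @param m A `"source_model"` (pretrained, or freshly initialized for the
#'   random baseline) or a ready-made `"target_model"`.
#' @param d An `"experimental_dataset"`.
#' @param structure The base `"protein_structure"`.
#' @param split A list or `"split_spec"` with `train` and `val` indices.
#' @param cfg A `"train_config"` (the `"finetune"` preset by default).
#' @param selection_threshold Minimum validation size enabling
#'   best-validation model selection (default 32).
#' @param attach Head attachment when converting a source model.
#' @return List with `model` (a `"target_model"`) and `history`.
#' @export
finetune_dual_phase <- function(m, d, structure, split,
                                cfg = train_config(preset = "finetune"),
                                selection_threshold = 32L,
                                attach = c("fc", "pooled")) {
  attach <- match.arg(attach)
  if (inherits(m, "source_model"))
    m <- make_target_model(m, attach = attach, seed = cfg$seed)
  stopifnot(inherits(m, "target_model"))
  if (length(split$train) == 0L) stop("empty train set", call. = FALSE)
  targets <- matrix(d$score, ncol = 1L)
  head_names <- c("head_w", "head_b")
  phases <- list(
    list(epochs = cfg$epochs, base_lr = cfg$base_lr, trainable = head_names),
    list(epochs = cfg$epochs, base_lr = cfg$base_lr / 10, trainable = NULL))
  structures <- setNames(list(structure), structure$id)
  dd <- d
  dd$base_pdb <- structure$id
  run_training(m, dd, structures, split, cfg, targets = targets,
               phases = phases, selection_threshold = selection_threshold)
}

#' Closed-form ridge-regression head (feature extraction)
#'
#' Freezes the backbone, extracts its features (final fully-connected
#' activation for local-style models, pooled encoding for global-style),
#' and fits the head by ridge regression with an unpenalized intercept via
#' the Cholesky-factorized normal equations
#' \eqn{(X^\top X + \alpha I) w = X^\top y}.
#'
#' @param m A `"source_model"` or `"target_model"`.
#' @param d An `"experimental_dataset"`.
#' @param structure The base `"protein_structure"`.
#' @param split List with `train` indices (only these rows are fitted).
#' @param alpha Ridge penalty (default 1.0).
#' @param attach Feature choice: `"fc"` (default) or `"pooled"`.
#' @return An object of class `"ridge_head_model"` with a `predict` method.
#' @export
fit_ridge_head <- function(m, d, structure, split, alpha = 1.0,
                           attach = c("fc", "pooled")) {
  attach <- match.arg(attach)
  tr <- split$train
  if (length(tr) < 1L) stop("fewer train rows than 1", call. = FALSE)
  seqs <- variant_sequences(structure$sequence, d$variant)
  if (is.null(m$rclass)) {
    map <- relative_distances(if (m$cfg$rpe_mode == "3d") structure
                              else nchar(structure$sequence),
                              mode = m$cfg$rpe_mode, clip = m$cfg$rpe_clip)
    m$rclass <- rpe_class_index(map)
  }
  X <- model_features(m, seqs[tr], attach = attach)
  y <- d$score[tr]
  fit <- ridge_solve(X, y, alpha)
  structure(list(backbone = m, attach = attach, alpha = alpha,
                 coef = fit$coef, intercept = fit$intercept),
            class = "ridge_head_model")
}

# internal: ridge with unpenalized intercept via Cholesky
ridge_solve <- function(X, y, alpha) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  R <- chol(A)
  w <- backsolve(R, forwardsolve(t(R), crossprod(Xc, yc)))
  list(coef = drop(w), intercept = ybar - sum(xbar * w))
}

#' @export
predict.ridge_head_model <- function(object, seqs, ...) {
  X <- model_features(object$backbone, seqs, attach = object$attach)
  drop(X %*% object$coef) + object$intercept
}

#' @export
print.ridge_head_model <- function(x, ...) {
  cat("<ridge_head_model> alpha", x$alpha, "on", x$attach, "features\n")
  invisible(x)
}

#' Random train/validation/test split for pretraining tables
#'
#' Withholds 5% of rows for final evaluation, then splits the remainder
#' into 80% train, 10% validation, and 10% test.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return List with integer indices `train`, `val`, `test`, `withheld`.
#' @export
make_pretrain_splits <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    perm <- sample.int(n)
    n_wh <- round(0.05 * n)
    wh <- perm[seq_len(n_wh)]
    rest <- perm[-seq_len(n_wh)]
    n_tr <- round(0.8 * length(rest))
    n_va <- round(0.1 * length(rest))
    list(train = sort(rest[seq_len(n_tr)]),
         val = sort(rest[n_tr + seq_len(n_va)]),
         test = sort(rest[-seq_len(n_tr + n_va)]),
         withheld = sort(wh))
  })
}
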