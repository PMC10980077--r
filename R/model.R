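#' Transformer model configuration
#'
#' Architecture hyperparameters of the encoder. Three presets reproduce the
#' published model sizes: `"local"` (256 embedding, 3 layers, 4 heads, 1024
#' feed-forward, 0.1 dropout, 256-unit pooled hidden layer; ~2.5M
#' parameters), `"global"` (512, 6, 8, 2048, 0.1, 512; ~19M), and
#' `"global_xl"` (`"global"` with 16 encoder layers; ~50M).
#'
#' @param embed_dim Embedding dimension (divisible by `n_heads`).
#' @param n_layers Number of encoder layers.
#' @param n_heads Attention heads.
#' @param ff_dim Feed-forward hidden width.
#' @param dropout Dropout rate used during training.
#' @param rpe_mode `"1d"` (sequence offsets) or `"3d"` (contact-graph
#'   shortest paths).
#' @param rpe_clip Relative-distance clipping bound; defaults to 8 for
#'   `"1d"` and 3 for `"3d"`.
#' @param n_tasks Output width of the source head (55 score terms by
#'   default; 72 with binding terms).
#' @param head_hidden Width of the nonlinear pooled hidden layer.
#' @param preset One of `"local"`, `"global"`, `"global_xl"`; overrides the
#'   individual architecture arguments.
#' @return A `"model_config"` list.
#' @export
model_config <- function(embed_dim = 256L, n_layers = 3L, n_heads = 4L,
                         ff_dim = 1024L, dropout = 0.1,
                         rpe_mode = c("1d", "3d"), rpe_clip = NULL,
                         n_tasks = 55L, head_hidden = NULL, preset = NULL) {
  rpe_mode <- match.arg(rpe_mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("local", "global", "global_xl"))
    if (preset == "local") {
      embed_dim <- 256L; n_layers <- 3L; n_heads <- 4L; ff_dim <- 1024L
      dropout <- 0.1; head_hidden <- 256L
    } else {
      embed_dim <- 512L; n_layers <- if (preset == "global_xl") 16L else 6L
      n_heads <- 8L; ff_dim <- 2048L; dropout <- 0.1; head_hidden <- 512L
    }
  }
  if (is.null(head_hidden)) head_hidden <- embed_dim
  if (is.null(rpe_clip)) rpe_clip <- if (rpe_mode == "3d") 3L else 8L
  if (embed_dim %% n_heads != 0L)
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  structure(list(
    embed_dim = as.integer(embed_dim), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
    dropout = dropout, rpe_mode = rpe_mode, rpe_clip = as.integer(rpe_clip),
    n_tasks = as.integer(n_tasks), head_hidden = as.integer(head_hidden),
    n_classes = rpe_n_classes(rpe_mode, rpe_clip),
    vocab = 21L,                      # 20 amino acids + padding token
    head_type = "source", head_attach = "fc", head_dropout = 0,
    pooling = "mean"), class = "model_config")
}

# internal: Glorot-uniform weight matrix
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# internal: initialize the full parameter list for a config
init_params <- function(cfg, seed = 1L) {
  d <- cfg$embed_dim; ff <- cfg$ff_dim; C <- cfg$n_classes
  dh <- d %/% cfg$n_heads
  withr::with_seed(seed, {
    p <- list(embed = matrix(rnorm(cfg$vocab * d, sd = 0.02), cfg$vocab, d))
    for (l in seq_len(cfg$n_layers) - 1L) {
      nm <- function(x) paste0("l", l, "_", x)
      p[[nm("ln1_g")]] <- matrix(1, d, 1)
      p[[nm("ln1_b")]] <- matrix(0, d, 1)
      p[[nm("wq")]] <- glorot(d, d); p[[nm("bq")]] <- matrix(0, d, 1)
      p[[nm("wk")]] <- glorot(d, d); p[[nm("bk")]] <- matrix(0, d, 1)
      p[[nm("wv")]] <- glorot(d, d); p[[nm("bv")]] <- matrix(0, d, 1)
      p[[nm("wo")]] <- glorot(d, d); p[[nm("bo")]] <- matrix(0, d, 1)
      p[[nm("rk")]] <- matrix(rnorm(C * dh, sd = 0.02), C, dh)
      p[[nm("rv")]] <- matrix(rnorm(C * dh, sd = 0.02), C, dh)
      p[[nm("ln2_g")]] <- matrix(1, d, 1)
      p[[nm("ln2_b")]] <- matrix(0, d, 1)
      p[[nm("w1")]] <- glorot(d, ff); p[[nm("b1")]] <- matrix(0, ff, 1)
      p[[nm("w2")]] <- glorot(ff, d); p[[nm("b2")]] <- matrix(0, d, 1)
    }
    p$final_ln_g <- matrix(1, d, 1)
    p$final_ln_b <- matrix(0, d, 1)
    p$fc_w <- glorot(d, cfg$head_hidden)
    p$fc_b <- matrix(0, cfg$head_hidden, 1)
    p$out_w <- glorot(cfg$head_hidden, cfg$n_tasks)
    p$out_b <- matrix(0, cfg$n_tasks, 1)
    p
  })
}

#' Build a source model
#'
#' Instantiates the multi-task encoder. `"3d"` relative position embeddings
#' require a structure (the contact graph defines the relative distances);
#' `"1d"` models only need the sequence length, taken from the structure
#' when one is given.
#'
#' @param cfg A `"model_config"`.
#' @param structure A `"protein_structure"`; required for `rpe_mode
#'   = "3d"`.
#' @param seq_len Sequence length for structure-free `"1d"` models.
#' @param seed Integer initialization seed (deterministic weights).
#' @return An object of class `"source_model"`: config, parameter list, the
#'   relative-distance class index map, and the base sequence (if known).
#' @export
build_model <- function(cfg, structure = NULL, seq_len = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$rpe_mode == "3d" && is.null(structure))
    stop("3d relative position embeddings require a structure",
         call. = FALSE)
  rclass <- NULL
  base_seq <- NULL
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "protein_structure"))
    map <- relative_distances(structure, mode = cfg$rpe_mode,
                              clip = cfg$rpe_clip)
    rclass <- rpe_class_index(map)
    base_seq <- structure$sequence
  } else if (!is.null(seq_len)) {
    map <- relative_distances(as.integer(seq_len), mode = "1d",
                              clip = cfg$rpe_clip)
    rclass <- rpe_class_index(map)
  }
  structure(list(cfg = cfg, params = init_params(cfg, seed = seed),
                 rclass = rclass, base_seq = base_seq,
                 structure_id = if (!is.null(structure)) structure$id),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat("<source_model>", x$cfg$n_tasks, "tasks,", x$cfg$rpe_mode,
      sprintf("RPE, %.2fM parameters\n", count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param m A `"source_model"` or `"target_model"`.
#' @return Exact integer count of trainable parameter scalars.
#' @export
count_parameters <- function(m) {
  sum(vapply(m$params, length, 0L))
}

#' Convert a source model to a target model
#'
#' Replaces the multi-task output layer with a randomly initialized linear
#' single-output head, with a dropout layer (rate 0.5) between backbone and
#' head. For local-style models the head attaches after the final
#' fully-connected layer; for global-style models immediately after the
#' pooling layer (pass `attach = "pooled"`).
#'
#' @param m A `"source_model"` (pretrained or not).
#' @param attach `"fc"` (default, local convention) or `"pooled"` (global
#'   convention).
#' @param head_dropout Dropout rate between backbone and head.
#' @param seed Head initialization seed.
#' @return An object of class `"target_model"`.
#' @export
make_target_model <- function(m, attach = c("fc", "pooled"),
                              head_dropout = 0.5, seed = 1L) {
  stopifnot(inherits(m, "source_model"))
  attach <- match.arg(attach)
  p <- m$params
  p$out_w <- NULL
  p$out_b <- NULL
  if (attach == "pooled") {
    p$fc_w <- NULL
    p$fc_b <- NULL
  }
  nf <- if (attach == "fc") m$cfg$head_hidden else m$cfg$embed_dim
  p$head_w <- withr::with_seed(seed, glorot(nf, 1L))
  p$head_b <- matrix(0, 1, 1)
  cfg <- m$cfg
  cfg$head_type <- "target"
  cfg$head_attach <- attach
  cfg$head_dropout <- head_dropout
  out <- m
  out$cfg <- cfg
  out$params <- p
  class(out) <- "target_model"
  out
}

#' @export
print.target_model <- function(x, ...) {
  cat("<target_model> head on", x$cfg$head_attach,
      sprintf("layer, %.2fM parameters\n", count_parameters(x) / 1e6))
  invisible(x)
}

# internal: L x B integer token matrix from sequences (1..20, pad = 21)
encode_tokens <- function(seqs, expected_len = NULL) {
  lens <- nchar(seqs)
  if (!is.null(expected_len) && any(lens != expected_len))
    stop("sequence length mismatch: expected ", expected_len, call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("sequences in one batch must share a length", call. = FALSE)
  codes <- vapply(seqs, aa_encode, integer(lens[1L]), USE.NAMES = FALSE)
  codes <- matrix(codes, lens[1L])
  if (anyNA(codes)) stop("non-canonical amino acid in input", call. = FALSE)
  storage.mode(codes) <- "integer"
  codes
}

# internal: the model's stored rclass map (error if absent)
model_rclass <- function(m) {
  if (is.null(m$rclass))
    stop("model has no relative-distance map; build it with a structure ",
         "or seq_len", call. = FALSE)
  m$rclass
}

# internal: single entry point into the C++ core
nn_run <- function(m, tokens, targets = NULL, training = FALSE,
                   dropout_seed = 0L, want_grads = FALSE, want_attn = FALSE,
                   want_features = FALSE, want_encodings = FALSE) {
  call_core <- function() {
    nn_run_cpp(tokens, model_rclass(m), m$params, m$cfg, targets, training,
               as.integer(dropout_seed), want_grads, want_attn,
               want_features, want_encodings)
  }
  if (training) withr::with_seed(as.integer(dropout_seed), call_core())
  else call_core()
}

#' Predict with a model
#'
#' Evaluation-mode (dropout off) forward pass; bitwise deterministic for
#' fixed weights and inputs.
#'
#' @param object A `"source_model"` or `"target_model"`.
#' @param seqs Character vector of amino-acid sequences, all of the model's
#'   sequence length.
#' @param ... Unused.
#' @return Source models: numeric matrix (sequences x tasks, columns named
#'   when the model carries task names). Target models: numeric vector.
#' @export
predict.source_model <- function(object, seqs, ...) {
  tokens <- encode_tokens(seqs, expected_len = nrow(model_rclass(object)))
  out <- nn_run(object, tokens)$pred
  if (!is.null(object$task_names) &&
      length(object$task_names) == ncol(out))
    colnames(out) <- object$task_names
  out
}

#' @rdname predict.source_model
#' @export
predict.target_model <- function(object, seqs, ...) {
  tokens <- encode_tokens(seqs, expected_len = nrow(model_rclass(object)))
  drop(nn_run(object, tokens)$pred)
}

#' Extract backbone features
#'
#' The representation the target head consumes: the pooled encoder output
#' (`"pooled"`) or the final fully-connected activation (`"fc"`). Dropout is
#' off.
#'
#' @param m A model.
#' @param seqs Sequences.
#' @param attach Which representation: defaults to the model's own head
#'   attachment (target models) or `"fc"` (source models).
#' @return Numeric matrix, sequences by feature dimension.
#' @export
model_features <- function(m, seqs, attach = NULL) {
  if (is.null(attach))
    attach <- if (inherits(m, "target_model")) m$cfg$head_attach else "fc"
  tokens <- encode_tokens(seqs, expected_len = nrow(model_rclass(m)))
  out <- nn_run(m, tokens, want_features = TRUE)
  if (attach == "fc") {
    if (is.null(out$feat_fc))
      stop("model has no fc layer on its active path", call. = FALSE)
    out$feat_fc
  } else out$feat_pooled
}

#' Attention and representation introspection
#'
#' Computes (a) the attention map of a sequence, averaged over all layers
#' and heads of the row-normalized attention, and (b) per-position
#' representations: the encoder output at position i averaged over the 20
#' single-mutant sequences placing each amino acid at i.
#'
#' @param m A model.
#' @param seq Sequence to introspect (defaults to the model's base
#'   sequence).
#' @return List with `attention` (n x n) and `representations`
#'   (n x embed_dim).
#' @export
introspect <- function(m, seq = NULL) {
  if (is.null(seq)) seq <- m$base_seq
  if (is.null(seq)) stop("no sequence to introspect", call. = FALSE)
  L <- nchar(seq)
  tokens <- encode_tokens(seq, expected_len = nrow(model_rclass(m)))
  attn <- nn_run(m, tokens, want_attn = TRUE)$attn
  chars <- strsplit(seq, "")[[1]]
  reps <- matrix(0, L, m$cfg$embed_dim)
  for (i in seq_len(L)) {
    muts <- vapply(amino_acids(), function(a) {
      ch <- chars; ch[i] <- a; paste(ch, collapse = "")
    }, "")
    tk <- encode_tokens(muts, expected_len = L)
    enc <- nn_run(m, tk, want_encodings = TRUE)$encodings  # L x d x 20
    reps[i, ] <- rowMeans(enc[i, , ])
  }
  list(attention = attn, representations = reps)
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the config, weights, relative-distance map and base
#' sequence. Reload-equivalence is guaranteed on one platform; bit-exact
#' portability across platforms is not.
#'
#' @param m Model to save.
#' @param path Checkpoint file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(m, path) {
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
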