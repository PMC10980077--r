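# internal constructor for split specifications
new_split_spec <- function(split_type, replicate, seed, train, val, test,
                           metadata = list()) {
  stopifnot(length(intersect(train, val)) == 0L,
            length(intersect(train, test)) == 0L,
            length(intersect(val, test)) == 0L)
  structure(list(split_type = split_type, replicate = as.integer(replicate),
                 seed = as.integer(seed), train = as.integer(train),
                 val = as.integer(val), test = as.integer(test),
                 metadata = metadata),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec>", x$split_type, "replicate", x$replicate, "-",
      length(x$train), "train /", length(x$val), "val /", length(x$test),
      "test\n")
  invisible(x)
}

#' Serialize split specifications as JSON
#' @param splits A `"split_spec"` or list of them.
#' @param path Output file.
#' @export
write_splits <- function(splits, path) {
  if (inherits(splits, "split_spec")) splits <- list(splits)
  jsonlite::write_json(lapply(splits, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Replicated small-training-size splits
#'
#' Samples one global 10% test set shared by every size and replicate, then
#' for each requested size draws the stated number of replicate datasets
#' from the non-test pool and splits each 80% train / 20% validation. The
#' default size and replicate schedules are (10, 20, 40, ..., 20480) with
#' (101, 23, 11, 11, 11, 11, 7, 7, 5, 5, 3, 3) replicates.
#'
#' @param d An `"experimental_dataset"` (or any data frame; only the row
#'   count matters).
#' @param sizes Integer vector of dataset sizes.
#' @param replicates Integer vector, same length as `sizes`.
#' @param seed Integer seed.
#' @return List of `"split_spec"` objects (metadata carries the size).
#' @export
make_small_splits <- function(d,
                              sizes = c(10L, 20L, 40L, 80L, 160L, 320L,
                                        640L, 1280L, 2560L, 5120L, 10240L,
                                        20480L),
                              replicates = c(101L, 23L, 11L, 11L, 11L, 11L,
                                             7L, 7L, 5L, 5L, 3L, 3L),
                              seed = 1L) {
  if (length(sizes) != length(replicates))
    stop("sizes and replicates must have equal length", call. = FALSE)
  n <- nrow(d)
  withr::with_seed(seed, {
    test <- sort(sample.int(n, round(0.1 * n)))
    pool <- setdiff(seq_len(n), test)
    out <- list()
    for (k in seq_along(sizes)) {
      size <- sizes[k]
      if (size > length(pool))
        stop("requested size ", size, " exceeds the non-test pool (",
             length(pool), ")", call. = FALSE)
      for (r in seq_len(replicates[k])) {
        rep_seed <- sample.int(.Machine$integer.max, 1L)
        idx <- withr::with_seed(rep_seed, sample(pool, size))
        n_tr <- round(0.8 * size)
        out[[length(out) + 1L]] <- new_split_spec(
          "small_n", r, rep_seed,
          train = idx[seq_len(n_tr)], val = idx[-seq_len(n_tr)],
          test = test, metadata = list(size = size))
      }
    }
    out
  })
}

# internal: 0-based positions and "pos:mut" mutation keys per variant
variant_keys <- function(variants) {
  lapply(strsplit(variants, ",", fixed = TRUE), function(toks) {
    if (length(toks) == 0L || identical(toks, ""))
      return(list(pos = integer(0), mut = character(0)))
    n <- nchar(toks)
    list(pos = as.integer(substr(toks, 2L, n - 1L)),
         mut = paste0(substr(toks, 2L, n - 1L), ":", substr(toks, n, n)))
  })
}

#' Extrapolation benchmark splits
#'
#' Four constructions testing generalization beyond the training
#' distribution, each replicated (9 replicates by default):
#' \describe{
#'   \item{position}{80% of observed sequence positions designated train,
#'     20% test; variants mixing train and test positions are discarded;
#'     train pool split 90/10 train/validation, full test pool as test.}
#'   \item{mutation}{as position, over the distinct (position, amino acid)
#'     mutations present in the dataset.}
#'   \item{regime}{singles as train pool (split 80/20), doubles as test
#'     pool, of which a 10% sample forms the test set. With
#'     `deep_regime = TRUE`, singles and doubles train and 3+ variants
#'     test.}
#'   \item{score}{variants scoring below wild type (negative) train,
#'     above wild type test; exact zeros belong to neither pool; train
#'     pool split 90/10, full test pool as test.}
#' }
#' Datasets larger than `cap` rows are first resampled down to `cap`.
#'
#' @param d An `"experimental_dataset"` with `variant` and `score`.
#' @param kind One of `"position"`, `"mutation"`, `"regime"`, `"score"`.
#' @param n_replicates Number of replicate splits.
#' @param seed Integer seed.
#' @param cap Resampling cap (default 50000).
#' @param deep_regime Use the single+double to triple-plus regime variant.
#' @return List of `"split_spec"` objects; indices refer to rows of `d`.
#' @export
make_extrapolation_split <- function(d, kind = c("position", "mutation",
                                                 "regime", "score"),
                                     n_replicates = 9L, seed = 1L,
                                     cap = 50000L, deep_regime = FALSE) {
  kind <- match.arg(kind)
  n <- nrow(d)
  keys <- variant_keys(d$variant)
  n_subs <- vapply(keys, function(k) length(k$pos), 0L)
  withr::with_seed(seed, {
    rows <- seq_len(n)
    if (kind %in% c("position", "mutation", "score") && n > cap)
      rows <- sort(sample.int(n, cap))
    lapply(seq_len(n_replicates), function(r) {
      rep_seed <- sample.int(.Machine$integer.max, 1L)
      withr::with_seed(rep_seed, {
        if (kind %in% c("position", "mutation")) {
          units <- if (kind == "position")
            sort(unique(unlist(lapply(keys[rows], `[[`, "pos"))))
          else sort(unique(unlist(lapply(keys[rows], `[[`, "mut"))))
          n_train_units <- round(0.8 * length(units))
          train_units <- sample(units, n_train_units)
          member <- vapply(rows, function(i) {
            u <- if (kind == "position") keys[[i]]$pos else keys[[i]]$mut
            if (length(u) == 0L) return("drop")       # wild-type row
            in_tr <- u %in% train_units
            if (all(in_tr)) "train" else if (!any(in_tr)) "test" else "drop"
          }, "")
          train_pool <- rows[member == "train"]
          test_pool <- rows[member == "test"]
          if (length(test_pool) == 0L)
            stop("empty test pool for ", kind, " extrapolation",
                 call. = FALSE)
          perm <- sample(train_pool)
          n_tr <- round(0.9 * length(perm))
          new_split_spec(kind, r, rep_seed,
                         train = perm[seq_len(n_tr)],
                         val = perm[-seq_len(n_tr)], test = test_pool,
                         metadata = list(train_units = train_units))
        } else if (kind == "regime") {
          if (deep_regime) {
            train_pool <- rows[n_subs[rows] %in% c(1L, 2L)]
            test_pool <- rows[n_subs[rows] >= 3L]
          } else {
            train_pool <- rows[n_subs[rows] == 1L]
            test_pool <- rows[n_subs[rows] == 2L]
          }
          if (length(test_pool) == 0L)
            stop("empty test pool for regime extrapolation", call. = FALSE)
          perm <- sample(train_pool)
          n_tr <- round(0.8 * length(perm))
          test <- sort(sample(test_pool,
                              max(1L, round(0.1 * length(test_pool)))))
          new_split_spec("regime", r, rep_seed,
                         train = perm[seq_len(n_tr)],
                         val = perm[-seq_len(n_tr)], test = test,
                         metadata = list(deep = deep_regime))
        } else {
          train_pool <- rows[d$score[rows] < 0]
          test_pool <- rows[d$score[rows] > 0]
          if (length(test_pool) == 0L)
            stop("empty test pool for score extrapolation", call. = FALSE)
          perm <- sample(train_pool)
          n_tr <- round(0.9 * length(perm))
          new_split_spec("score", r, rep_seed,
                         train = perm[seq_len(n_tr)],
                         val = perm[-seq_len(n_tr)], test = test_pool,
                         metadata = list())
        }
      })
    })
  })
}

#' Rank-based evaluation metrics
#'
#' Spearman rank correlation and top-k recall: the fraction of the k
#' highest-scoring true variants recovered among the k highest predictions
#' (ties broken by stable index order).
#'
#' @param y_true,y_pred Numeric vectors of equal length (at least 2, at
#'   least k).
#' @param k Top-set size (default 100).
#' @return List with `spearman` and `recall_top_k`.
#' @export
evaluate_predictions <- function(y_true, y_pred, k = 100L) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  if (k > length(y_true))
    stop("k exceeds the number of observations", call. = FALSE)
  if (length(unique(y_true)) == 1L) {
    warning("constant y_true: Spearman correlation undefined",
            call. = FALSE)
    rho <- NA_real_
  } else {
    rho <- suppressWarnings(cor(y_true, y_pred, method = "spearman"))
  }
  top_true <- order(y_true, decreasing = TRUE)[seq_len(k)]
  top_pred <- order(y_pred, decreasing = TRUE)[seq_len(k)]
  list(spearman = rho,
       recall_top_k = length(intersect(top_true, top_pred)) / k)
}

#' Epistasis scores of multi-mutant variants
#'
#' For each variant S, the effect relative to wild type is
#' `w(S) = score(S) - score(wt)`, and its epistasis is
#' `E(S) = w(S) - sum over constituent single mutations m of w(m)`
#' (identically 0 for singles). Positional epistasis between positions i
#' and j is the mean absolute epistasis over variants with mutations
#' exactly at \{i, j\}.
#'
#' @param score_fn Function mapping a sequence string (or vector of them)
#'   to numeric scores.
#' @param base_seq Wild-type sequence.
#' @param variants Character vector of canonical 0-based variant strings
#'   (doubles and the singles they are built from; higher orders allowed
#'   when all their singles are present or scoreable).
#' @return An `"epistasis_result"`: data frame `scores` with columns
#'   `variant`, `w`, `E`, and `positional`, the symmetric mean |E| matrix
#'   (NA where no variant covers a pair).
#' @export
epistasis_scores <- function(score_fn, base_seq, variants) {
  check_aa_seq(base_seq, "base_seq")
  variants <- setdiff(unique(variants), "")
  keys <- variant_keys(variants)
  singles_needed <- sort(unique(unlist(lapply(strsplit(variants, ",",
                                                       fixed = TRUE),
                                              identity))))
  all_vars <- union(variants, singles_needed)
  seqs <- variant_sequences(base_seq, c("", all_vars))
  sc <- score_fn(seqs)
  if (length(sc) != length(seqs))
    stop("score_fn must return one score per sequence", call. = FALSE)
  wt_score <- sc[1L]
  w_all <- setNames(sc[-1L] - wt_score, all_vars)
  w_single <- w_all[singles_needed]
  if (anyNA(w_single)) stop("missing constituent single", call. = FALSE)
  E <- vapply(seq_along(variants), function(i) {
    toks <- strsplit(variants[i], ",", fixed = TRUE)[[1]]
    if (length(toks) == 1L) return(0)
    w_all[[variants[i]]] - sum(w_single[toks])
  }, 0)
  L <- nchar(base_seq)
  pos_sum <- matrix(0, L, L)
  pos_n <- matrix(0L, L, L)
  for (i in seq_along(variants)) {
    p <- keys[[i]]$pos
    if (length(p) == 2L) {
      a <- p[1L] + 1L; b <- p[2L] + 1L
      pos_sum[a, b] <- pos_sum[a, b] + abs(E[i])
      pos_n[a, b] <- pos_n[a, b] + 1L
    }
  }
  positional <- ifelse(pos_n + t(pos_n) > 0,
                       (pos_sum + t(pos_sum)) / pmax(pos_n + t(pos_n), 1L),
                       NA_real_)
  structure(list(scores = data.frame(variant = variants,
                                     w = unname(w_all[variants]), E = E,
                                     stringsAsFactors = FALSE),
                 wt_score = wt_score, positional = positional),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat("<epistasis_result>", nrow(x$scores), "variants; mean |E| =",
      signif(mean(abs(x$scores$E)), 4), "\n")
  invisible(x)
}
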