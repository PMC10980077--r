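#' Clean a raw attribute table
#'
#' Applies the pretraining-data cleaning pipeline in fixed order:
#' (1) drop any row with a NaN/NA in a score column; (2) deduplicate on
#' (`base_pdb`, `variant`), keeping one seeded-random row per duplicate set;
#' (3) within each `base_pdb` group, compute the modified z-score of
#' `total_score`,
#' \deqn{s_i = |x_i - \tilde x| / MAD,}
#' with \eqn{\tilde x} the group median and MAD the median absolute
#' deviation from it, and drop rows with \eqn{s_i >} `z_threshold`. Groups
#' with MAD = 0 are skipped (the score is undefined there) with a warning.
#' The deviation is taken in absolute value so that both tails are filtered;
#' no 0.6745 consistency constant is applied.
#'
#' @param t An `"attribute_table"` (must contain `total_score`).
#' @param seed Integer seed for the duplicate lottery.
#' @param z_threshold Modified z-score removal threshold (default 6.5).
#' @return List with `table` (the cleaned table) and `report`, an
#'   `"outlier_report"`: per-group median, MAD and per-row scores, plus
#'   per-cause removal counts and removed row ids (row indices of the
#'   input table).
#' @export
clean_attribute_table <- function(t, seed = 1L, z_threshold = 6.5) {
  stopifnot(is.data.frame(t))
  if (nrow(t) == 0L) stop("empty attribute table", call. = FALSE)
  if (!"total_score" %in% names(t))
    stop("attribute table must contain a total_score column", call. = FALSE)
  terms <- attr_term_cols(t)
  rid <- seq_len(nrow(t))

  # 1. NaN drop
  has_na <- !stats::complete.cases(t[, terms, drop = FALSE])
  removed_nan <- rid[has_na]
  t1 <- t[!has_na, , drop = FALSE]
  rid1 <- rid[!has_na]

  # 2. seeded-random dedup per (base_pdb, variant)
  key <- paste(t1$base_pdb, t1$variant, sep = "\r")
  keep <- withr::with_seed(seed, {
    perm <- sample.int(nrow(t1))
    !duplicated(key[perm])[order(perm)]
  })
  removed_dup <- rid1[!keep]
  t2 <- t1[keep, , drop = FALSE]
  rid2 <- rid1[keep]

  # 3. per-group modified z-score filter on total_score
  groups <- split(seq_len(nrow(t2)), t2$base_pdb)
  group_stats <- list()
  drop_out <- logical(nrow(t2))
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    x <- t2$total_score[idx]
    med <- median(x)
    mad_ <- median(abs(x - med))
    if (mad_ == 0) {
      warning("group '", gname, "' has MAD = 0; outlier filter skipped",
              call. = FALSE)
      s <- rep(NA_real_, length(x))
    } else {
      s <- abs(x - med) / mad_
      drop_out[idx[s > z_threshold]] <- TRUE
    }
    group_stats[[gname]] <- list(median = med, mad = mad_,
                                 z = setNames(s, rid2[idx]))
  }
  removed_out <- rid2[drop_out]
  out <- t2[!drop_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("attribute_table", "data.frame")
  report <- structure(list(
    groups = group_stats,
    z_threshold = z_threshold,
    removed = list(nan = removed_nan, duplicate = removed_dup,
                   outlier = removed_out),
    n_in = nrow(t), n_out = nrow(out)), class = "outlier_report")
  list(table = out, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report>", x$n_in, "rows in,", x$n_out, "out; removed:",
      length(x$removed$nan), "NaN,", length(x$removed$duplicate),
      "duplicate,", length(x$removed$outlier), "outlier (s >",
      x$z_threshold, ")\n")
  invisible(x)
}

#' Serialize an outlier report as JSON
#' @param report An `"outlier_report"`.
#' @param path Output path.
#' @export
write_outlier_report <- function(report, path) {
  jsonlite::write_json(
    list(z_threshold = report$z_threshold, n_in = report$n_in,
         n_out = report$n_out,
         removed = lapply(report$removed, as.integer),
         groups = lapply(report$groups, function(g)
           list(median = g$median, mad = g$mad))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Drop the excluded score terms
#'
#' Removes the five near-constant catalog terms (see [excluded_terms()]).
#' On the full 60-term catalog this leaves the 55 pretraining score terms;
#' binding-term columns are never touched. Absent columns are ignored with
#' a warning.
#'
#' @param t An `"attribute_table"`.
#' @return The table without the excluded columns.
#' @export
drop_excluded_terms <- function(t) {
  stopifnot(is.data.frame(t))
  excl <- excluded_terms()
  missing <- setdiff(excl, names(t))
  if (length(missing) > 0L)
    warning("excluded term(s) not present: ",
            paste(missing, collapse = ", "), call. = FALSE)
  out <- t[, !names(t) %in% excl, drop = FALSE]
  class(out) <- c("attribute_table", "data.frame")
  out
}

#' Standardize score terms with train-set statistics
#'
#' Per (`base_pdb`, term), subtracts the mean and divides by the standard
#' deviation computed on the training rows only, so every group/term has
#' train mean 0 and train sd 1. Held-out rows are transformed with the same
#' train statistics. Constant terms within a group (sd = 0) are centered
#' only, with the scale left at 1.
#'
#' @param t An `"attribute_table"`.
#' @param train_ids Integer row indices of the training rows.
#' @return List with `table` (standardized) and `stats`, a `"group_stats"`
#'   object: per group, matrices of per-term means and sds.
#' @export
standardize_attributes <- function(t, train_ids) {
  stopifnot(is.data.frame(t))
  terms <- attr_term_cols(t)
  train_ids <- as.integer(train_ids)
  if (length(train_ids) == 0L) stop("train_ids is empty", call. = FALSE)
  is_train <- seq_len(nrow(t)) %in% train_ids
  groups <- split(seq_len(nrow(t)), t$base_pdb)
  stats_out <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    tr <- intersect(idx, train_ids)
    if (length(tr) == 0L)
      stop("group '", gname, "' has no training rows", call. = FALSE)
    mu <- vapply(terms, function(tm) mean(t[tr, tm]), 0)
    sdv <- vapply(terms, function(tm) sd(t[tr, tm]), 0)
    sdv[is.na(sdv) | sdv == 0] <- 1
    for (k in seq_along(terms))
      t[idx, terms[k]] <- (t[idx, terms[k]] - mu[k]) / sdv[k]
    stats_out[[gname]] <- list(mean = mu, sd = sdv)
  }
  class(t) <- c("attribute_table", "data.frame")
  list(table = t,
       stats = structure(stats_out, class = "group_stats"))
}

#' Normalize a raw experimental variant-score table
#'
#' Removes variants with stop-codon substitutions, converts variant
#' indexing to 0-based, log-transforms scores unless they already are
#' log-scale, subtracts the wild-type score so the wild type is exactly 0,
#' and rounds to 7 decimal places.
#'
#' @param raw Data frame with columns `variant` and `score`.
#' @param wt_score Wild-type raw score. If missing, inferred from a
#'   wild-type row (empty variant string); an error otherwise.
#' @param log_already Scores are already log-scale (default TRUE). When
#'   FALSE, scores must be positive and are log-transformed first.
#' @param offset Indexing offset of the incoming variant strings (1 for
#'   1-based published tables, 0 if already 0-based).
#' @param base_seq Optional base sequence for validation of the variants.
#' @return An `"experimental_dataset"` with 0-based variants.
#' @export
normalize_experimental_dataset <- function(raw, wt_score = NULL,
                                           log_already = TRUE, offset = 0L,
                                           base_seq = NULL) {
  stopifnot(is.data.frame(raw), all(c("variant", "score") %in% names(raw)))
  if (!is.numeric(raw$score)) stop("scores must be numeric", call. = FALSE)
  v <- as.character(raw$variant)
  v[is.na(v)] <- ""
  has_stop <- grepl("\\*", v)
  raw <- raw[!has_stop, , drop = FALSE]
  v <- v[!has_stop]
  v0 <- vapply(v, function(x)
    format(parse_variant(x, base_seq = base_seq, offset = offset)), "",
    USE.NAMES = FALSE)
  score <- raw$score
  if (!log_already) {
    if (any(score <= 0))
      stop("non-positive scores cannot be log-transformed", call. = FALSE)
    score <- log(score)
    if (!is.null(wt_score)) wt_score <- log(wt_score)
  }
  if (is.null(wt_score)) {
    wt_rows <- which(v0 == "")
    if (length(wt_rows) == 0L)
      stop("wt_score missing and no wild-type row to infer it from",
           call. = FALSE)
    wt_score <- mean(score[wt_rows])
  }
  out <- data.frame(variant = v0, score = round(score - wt_score, 7L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("experimental_dataset", "data.frame")
  out
}
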