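#' Parse a substitution-string variant
#'
#' A variant is written as a comma-separated list of `<wt><pos><mut>` tokens,
#' e.g. `"G41L,V54G"`. Positions are 0-based by default; published tables are
#' often 1-based, in which case `offset = 1` converts on input. The empty
#' string denotes the wild type.
#'
#' @param text Variant string (comma-separated substitution tokens, or `""`).
#' @param base_seq Optional base amino-acid sequence. When supplied, the
#'   wild-type letter of every token is checked against it and positions are
#'   range-checked.
#' @param offset Indexing offset of the input string: 0 (default) or 1.
#' @return An object of class `"variant"`: a list with element `subs`, a
#'   data frame with columns `pos` (0-based integer), `wt`, `mut`.
#' @examples
#' v <- parse_variant("A1G", base_seq = "GAVL")
#' format(v)
#' @export
parse_variant <- function(text, base_seq = NULL, offset = 0L) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("variant text must be a single string", call. = FALSE)
  if (!offset %in% c(0L, 1L)) stop("offset must be 0 or 1", call. = FALSE)
  if (!is.null(base_seq)) check_aa_seq(base_seq, "base_seq")
  text <- gsub("[[:space:]]", "", text)
  if (identical(text, "")) {
    return(new_variant(data.frame(pos = integer(0), wt = character(0),
                                  mut = character(0))))
  }
  tokens <- unique(strsplit(text, ",", fixed = TRUE)[[1]])
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z*])$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed substitution token(s): ",
         paste(tokens[bad], collapse = ", "), call. = FALSE)
  wt <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L)) - as.integer(offset)
  mut <- vapply(m, `[`, "", 4L)
  aa <- amino_acids()
  if (any(!wt %in% aa) || any(!mut %in% aa))
    stop("substitution letters must be canonical amino acids (no stop codons): ",
         paste(tokens[!(wt %in% aa) | !(mut %in% aa)], collapse = ", "),
         call. = FALSE)
  if (any(wt == mut))
    stop("wild-type and mutant letter identical in: ",
         paste(tokens[wt == mut], collapse = ", "), call. = FALSE)
  if (any(pos < 0L))
    stop("position below 0 after applying offset", call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicate position(s): ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "), call. = FALSE)
  if (!is.null(base_seq)) {
    L <- nchar(base_seq)
    if (any(pos >= L))
      stop("position out of range for base sequence of length ", L,
           call. = FALSE)
    base <- strsplit(base_seq, "")[[1]]
    mism <- base[pos + 1L] != wt
    if (any(mism))
      stop("wild-type letter mismatch at 0-based position(s) ",
           paste(pos[mism], collapse = ", "), ": sequence has ",
           paste(base[pos + 1L][mism], collapse = ", "), call. = FALSE)
  }
  ord <- order(pos)
  new_variant(data.frame(pos = pos[ord], wt = wt[ord], mut = mut[ord],
                         stringsAsFactors = FALSE))
}

new_variant <- function(subs) {
  structure(list(subs = subs), class = "variant")
}

#' @export
format.variant <- function(x, one_based = FALSE, ...) {
  if (nrow(x$subs) == 0L) return("")
  paste0(x$subs$wt, x$subs$pos + as.integer(one_based), x$subs$mut,
         collapse = ",")
}

#' @export
print.variant <- function(x, ...) {
  if (nrow(x$subs) == 0L) cat("<variant> wild type\n")
  else cat("<variant>", format(x), "\n")
  invisible(x)
}

#' Number of substitutions in a variant
#' @param v A `"variant"` object or variant string.
#' @return Integer count (0 for wild type).
#' @export
n_substitutions <- function(v) {
  if (is.character(v)) v <- parse_variant(v)
  nrow(v$subs)
}

#' Apply a variant to a base sequence
#'
#' @param base_seq Base amino-acid sequence.
#' @param v A `"variant"` object or a variant string (0-based).
#' @return The mutated sequence string; differs from `base_seq` at exactly
#'   the substituted positions.
#' @examples
#' apply_variant("GAVL", "A1G")
#' @export
apply_variant <- function(base_seq, v) {
  check_aa_seq(base_seq, "base_seq")
  if (is.character(v)) v <- parse_variant(v, base_seq = base_seq)
  chars <- strsplit(base_seq, "")[[1]]
  if (nrow(v$subs) == 0L) return(base_seq)
  if (any(v$subs$pos >= length(chars)))
    stop("variant position out of range", call. = FALSE)
  if (any(chars[v$subs$pos + 1L] != v$subs$wt))
    stop("wild-type letter mismatch between variant and base sequence",
         call. = FALSE)
  chars[v$subs$pos + 1L] <- v$subs$mut
  paste(chars, collapse = "")
}

# internal: fast application for canonical variant strings, no re-validation
apply_variant_fast <- function(base_chars, text) {
  if (text == "") return(paste(base_chars, collapse = ""))
  toks <- strsplit(text, ",", fixed = TRUE)[[1]]
  n <- nchar(toks)
  pos <- as.integer(substr(toks, 2L, n - 1L))
  base_chars[pos + 1L] <- substr(toks, n, n)
  paste(base_chars, collapse = "")
}

#' Sequences for a set of variant strings
#'
#' Vectorized convenience wrapper around [apply_variant()] for canonical
#' 0-based variant strings.
#'
#' @param base_seq Base sequence.
#' @param variants Character vector of canonical variant strings.
#' @return Character vector of mutated sequences.
#' @export
variant_sequences <- function(base_seq, variants) {
  check_aa_seq(base_seq, "base_seq")
  base_chars <- strsplit(base_seq, "")[[1]]
  vapply(variants, function(v) apply_variant_fast(base_chars, v), "",
         USE.NAMES = FALSE)
}

#' Exhaustively enumerate low-order variants
#'
#' Generates all 1-substitution variants (`order = 1`; `L * 19` of them) or
#' all 1- and 2-substitution variants (`order = 2`; additionally
#' `choose(L, 2) * 19^2` doubles).
#'
#' @param base_seq Base sequence of length `L`.
#' @param order 1 or 2.
#' @return Character vector of canonical 0-based variant strings, duplicate
#'   free, singles first.
#' @export
enumerate_variants <- function(base_seq, order = 1L) {
  check_aa_seq(base_seq, "base_seq")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  chars <- strsplit(base_seq, "")[[1]]
  L <- length(chars)
  aa <- amino_acids()
  single_tokens <- lapply(seq_len(L) - 1L, function(p) {
    muts <- setdiff(aa, chars[p + 1L])
    paste0(chars[p + 1L], p, muts)
  })
  singles <- unlist(single_tokens)
  if (order == 1L) return(singles)
  doubles <- character(0)
  if (L >= 2L) {
    pairs <- combn(seq_len(L) - 1L, 2L)
    doubles <- unlist(lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      as.vector(outer(single_tokens[[i + 1L]], single_tokens[[j + 1L]],
                      paste, sep = ","))
    }))
  }
  c(singles, doubles)
}

# internal: size of the full variant space with 1..max_subs substitutions
variant_space_size <- function(L, max_subs) {
  sum(choose(L, seq_len(max_subs)) * 19^seq_len(max_subs))
}

# internal: full enumeration of all variants with 1..max_subs substitutions.
# Only called when the space is small (guarded by variant_space_size).
enumerate_full_space <- function(base_seq, max_subs) {
  chars <- strsplit(base_seq, "")[[1]]
  L <- length(chars)
  aa <- amino_acids()
  out <- character(0)
  for (k in seq_len(min(max_subs, L))) {
    possets <- combn(seq_len(L) - 1L, k)
    for (col in seq_len(ncol(possets))) {
      ps <- possets[, col]
      tok_lists <- lapply(ps, function(p)
        paste0(chars[p + 1L], p, setdiff(aa, chars[p + 1L])))
      grid <- do.call(expand.grid,
                      c(tok_lists, list(stringsAsFactors = FALSE)))
      out <- c(out, do.call(paste, c(as.list(grid), sep = ",")))
    }
  }
  out
}

#' Sample a variant space by the sub-variants algorithm
#'
#' Iteratively draws a random variant with `max_subs` substitutions (uniform
#' over position sets and non-wild-type amino acids), generates every
#' sub-variant carrying a non-empty subset of its substitutions, discards
#' duplicates, and stops once `n_target` unique variants are collected. When
#' the final iteration overshoots, the freshly generated batch is truncated
#' in seeded random order. If the full space of variants with up to
#' `max_subs` substitutions is smaller than `n_target`, the full space is
#' returned.
#'
#' @param base_seq Base sequence.
#' @param n_target Number of variants to return.
#' @param max_subs Maximum substitutions per variant (the seed variants have
#'   exactly this many).
#' @param seed Integer seed; equal seeds give identical output.
#' @return Character vector of canonical 0-based variant strings; duplicate
#'   free; every variant has between 1 and `max_subs` substitutions.
#' @export
sample_subvariants <- function(base_seq, n_target, max_subs = 5L, seed) {
  check_aa_seq(base_seq, "base_seq")
  if (n_target < 1L) stop("n_target must be >= 1", call. = FALSE)
  if (max_subs < 1L) stop("max_subs must be >= 1", call. = FALSE)
  chars <- strsplit(base_seq, "")[[1]]
  L <- length(chars)
  if (L < max_subs) stop("base sequence shorter than max_subs", call. = FALSE)
  space <- variant_space_size(L, max_subs)
  if (space <= n_target) {
    out <- withr::with_seed(seed, enumerate_full_space(base_seq, max_subs))
    return(out)
  }
  aa <- amino_acids()
  # all non-empty subsets of 1..max_subs, precomputed once
  subsets <- unlist(lapply(seq_len(max_subs), function(k)
    combn(seq_len(max_subs), k, simplify = FALSE)), recursive = FALSE)
  withr::with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- character(n_target)
    n_have <- 0L
    while (n_have < n_target) {
      ps <- sort(sample.int(L, max_subs) - 1L)
      toks <- vapply(ps, function(p)
        paste0(chars[p + 1L], p, sample(setdiff(aa, chars[p + 1L]), 1L)), "")
      batch <- vapply(subsets, function(ss)
        paste(toks[ss], collapse = ","), "")
      fresh <- batch[!vapply(batch, exists, TRUE, envir = seen)]
      if (length(fresh) == 0L) next
      room <- n_target - n_have
      if (length(fresh) > room)
        fresh <- sample(fresh, room)
      for (v in fresh) assign(v, TRUE, envir = seen)
      out[n_have + seq_along(fresh)] <- fresh
      n_have <- n_have + length(fresh)
    }
    out
  })
}

#' Read / write variant lists
#'
#' Variant lists are exchanged as single-column CSV files with header
#' `variant`; the wild type is encoded as the empty string.
#'
#' @param path File path.
#' @param variants Character vector of canonical variant strings.
#' @return `read_variants` returns a character vector.
#' @export
read_variants <- function(path) {
  df <- read.csv(path, colClasses = "character", blank.lines.skip = FALSE)
  if (!"variant" %in% names(df))
    stop("variant CSV must have a 'variant' column", call. = FALSE)
  v <- df$variant
  v[is.na(v)] <- ""
  v
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path) {
  write.csv(data.frame(variant = variants), path, row.names = FALSE,
            quote = TRUE)
  invisible(path)
}
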