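#' Sequence-design configuration
#'
#' Settings for simulated-annealing design of variants with an exact
#' substitution count under an Observed/Unobserved constraint. The
#' constraint is defined over (position, mutant amino acid) pairs:
#' `"observed"` designs draw only from `allowed_mutations`, `"unobserved"`
#' designs exclude them entirely.
#'
#' @param n_mutations Exact number of substitutions per design (e.g. 5 or
#'   10).
#' @param constraint `"observed"` or `"unobserved"`.
#' @param allowed_mutations Character vector of substitution tokens
#'   (`<wt><pos><mut>`, 0-based) defining the observed set, typically the
#'   unique mutations of a training set (see [observed_mutations()]).
#' @param n_runs Number of independent annealing runs (default 10000).
#' @param n_steps Monte Carlo steps per run (default 10000).
#' @param t_start,t_end Temperature schedule endpoints (default 10 and
#'   0.01), traversed on a logarithmic gradient.
#' @param proposal_lambda Poisson rate for the number of mutations changed
#'   per step (min-clipped to 1, max-clipped to `n_mutations`).
#' @param seed Integer seed.
#' @return A `"design_config"` list.
#' @export
design_config <- function(n_mutations, constraint = c("observed",
                                                      "unobserved"),
                          allowed_mutations, n_runs = 10000L,
                          n_steps = 10000L, t_start = 10, t_end = 0.01,
                          proposal_lambda = 1, seed = 1L) {
  constraint <- match.arg(constraint)
  if (!(t_start > t_end && t_end > 0))
    stop("need t_start > t_end > 0", call. = FALSE)
  structure(list(n_mutations = as.integer(n_mutations),
                 constraint = constraint,
                 allowed_mutations = unique(allowed_mutations),
                 n_runs = as.integer(n_runs), n_steps = as.integer(n_steps),
                 t_start = t_start, t_end = t_end,
                 proposal_lambda = proposal_lambda,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Unique substitutions observed in a dataset
#'
#' @param variants Character vector of canonical variant strings.
#' @return Character vector of unique substitution tokens.
#' @export
observed_mutations <- function(variants) {
  unique(unlist(strsplit(variants[variants != ""], ",", fixed = TRUE)))
}

# internal: the legal single-substitution tokens for a config
legal_mutations <- function(base_seq, cfg) {
  all_tokens <- enumerate_variants(base_seq, order = 1L)
  if (cfg$constraint == "observed") {
    legal <- intersect(all_tokens, cfg$allowed_mutations)
  } else {
    legal <- setdiff(all_tokens, cfg$allowed_mutations)
  }
  if (length(unique(token_pos(legal))) < cfg$n_mutations)
    stop("constraint set cannot form ", cfg$n_mutations,
         " substitutions at distinct positions", call. = FALSE)
  legal
}

# internal: 0-based positions of substitution tokens
token_pos <- function(tokens) {
  n <- nchar(tokens)
  as.integer(substr(tokens, 2L, n - 1L))
}

# internal: canonical variant string from a token set
tokens_to_variant <- function(tokens) {
  paste(tokens[order(token_pos(tokens))], collapse = ",")
}

# internal: sample a constraint-legal set of n tokens at distinct positions
sample_legal_set <- function(legal, n) {
  picked <- character(0)
  used_pos <- integer(0)
  for (tok in sample(legal)) {
    p <- token_pos(tok)
    if (!p %in% used_pos) {
      picked <- c(picked, tok)
      used_pos <- c(used_pos, p)
      if (length(picked) == n) break
    }
  }
  if (length(picked) < n)
    stop("constraint set too small for ", n, " distinct positions",
         call. = FALSE)
  picked
}

#' Log-spaced annealing temperature schedule
#'
#' @param step 0-based step index (vectorized).
#' @param n_steps Total steps; step 0 maps to `t_start` and step
#'   `n_steps - 1` to `t_end`.
#' @param t_start,t_end Schedule endpoints.
#' @return Numeric temperatures.
#' @export
annealing_temperature <- function(step, n_steps, t_start = 10,
                                  t_end = 0.01) {
  if (n_steps == 1L) return(rep(t_start, length(step)))
  10^(log10(t_start) + (log10(t_end) - log10(t_start)) *
        step / (n_steps - 1))
}

#' One simulated-annealing design run
#'
#' Metropolis optimization over variants with exactly `cfg$n_mutations`
#' substitutions. Each step draws the number of mutations to change from a
#' Poisson distribution (clipped to 1..n_mutations), keeps a random subset
#' of the current mutations, and refills with constraint-legal single
#' mutations sampled without replacement at unused positions. Improvements
#' are always accepted; a score drop of `delta` is accepted with
#' probability `exp(delta / T)` (`delta = 0` is accepted).
#'
#' @param score_fn Function from sequence string(s) to numeric score(s);
#'   higher is better.
#' @param base_seq Wild-type sequence.
#' @param cfg A `"design_config"`.
#' @param run_seed Integer seed for this run.
#' @param log_trajectory Record per-step scores, temperatures and
#'   acceptance flags.
#' @return List with `final` and `best` variant strings, `final_score`,
#'   `best_score`, and optionally `trajectory`.
#' @export
run_simulated_annealing <- function(score_fn, base_seq, cfg, run_seed = 1L,
                                    log_trajectory = FALSE) {
  stopifnot(inherits(cfg, "design_config"))
  check_aa_seq(base_seq, "base_seq")
  legal <- legal_mutations(base_seq, cfg)
  legal_pos <- token_pos(legal)
  temps <- annealing_temperature(seq_len(cfg$n_steps) - 1L, cfg$n_steps,
                                 cfg$t_start, cfg$t_end)
  withr::with_seed(run_seed, {
    cur <- sample_legal_set(legal, cfg$n_mutations)
    cur_score <- score_fn(apply_variant(base_seq, tokens_to_variant(cur)))
    best <- cur
    best_score <- cur_score
    traj <- if (log_trajectory)
      data.frame(step = seq_len(cfg$n_steps), temperature = temps,
                 score = NA_real_, accepted = NA,
                 proposal = NA_character_) else NULL
    for (st in seq_len(cfg$n_steps)) {
      n_change <- min(max(rpois(1L, cfg$proposal_lambda), 1L),
                      cfg$n_mutations)
      keep <- if (n_change == cfg$n_mutations) character(0)
              else sample(cur, cfg$n_mutations - n_change)
      used_pos <- token_pos(keep)
      cand_pool <- legal[!legal_pos %in% used_pos]
      prop <- keep
      while (length(prop) < cfg$n_mutations) {
        tok <- cand_pool[sample.int(length(cand_pool), 1L)]
        prop <- c(prop, tok)
        cand_pool <- cand_pool[token_pos(cand_pool) != token_pos(tok)]
      }
      prop_score <- score_fn(apply_variant(base_seq,
                                           tokens_to_variant(prop)))
      delta <- prop_score - cur_score
      accept <- delta >= 0 || runif(1L) < exp(delta / temps[st])
      if (accept) {
        cur <- prop
        cur_score <- prop_score
        if (cur_score > best_score) {
          best <- cur
          best_score <- cur_score
        }
      }
      if (log_trajectory) {
        traj$score[st] <- cur_score
        traj$accepted[st] <- accept
        traj$proposal[st] <- tokens_to_variant(prop)
      }
    }
    out <- list(final = tokens_to_variant(cur), final_score = cur_score,
                best = tokens_to_variant(best), best_score = best_score)
    if (log_trajectory) out$trajectory <- traj
    out
  })
}

#' Run a batch of annealing designs
#'
#' Executes `cfg$n_runs` independent runs with distinct seeds derived from
#' `cfg$seed` and collects final (and best-seen) variants.
#'
#' @inheritParams run_simulated_annealing
#' @return Data frame with columns `run`, `final`, `final_score`, `best`,
#'   `best_score`.
#' @export
run_design_batch <- function(score_fn, base_seq, cfg) {
  res <- lapply(seq_len(cfg$n_runs), function(r)
    run_simulated_annealing(score_fn, base_seq, cfg,
                            run_seed = cfg$seed + r))
  data.frame(run = seq_len(cfg$n_runs),
             final = vapply(res, `[[`, "", "final"),
             final_score = vapply(res, `[[`, 0, "final_score"),
             best = vapply(res, `[[`, "", "best"),
             best_score = vapply(res, `[[`, 0, "best_score"),
             stringsAsFactors = FALSE)
}

#' BLOSUM62 dissimilarity between aligned sequences
#'
#' `d(x, y) = sum over positions of (B(a,a) + B(b,b) - 2 B(a,b)) / 2` with
#' B the BLOSUM62 substitution matrix: nonnegative, symmetric, and zero
#' exactly for identical sequences. With `raw_similarity = TRUE` the
#' negated raw similarity `-sum B(a,b)` is returned instead (not a
#' dissimilarity in the metric sense).
#'
#' @param seqs Character vector of equal-length sequences.
#' @param raw_similarity Use the negated raw BLOSUM62 similarity.
#' @return A symmetric numeric matrix.
#' @export
blosum_distance_matrix <- function(seqs, raw_similarity = FALSE) {
  B62 <- get_blosum62()
  aa <- amino_acids()
  Bs <- B62[aa, aa]
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must be aligned (equal length)",
                            call. = FALSE)
  codes <- matrix(vapply(seqs, aa_encode, integer(L), USE.NAMES = FALSE), L)
  cost <- if (raw_similarity) -Bs
          else (outer(diag(Bs), diag(Bs), "+") - 2 * Bs) / 2
  D <- matrix(0, n, n)
  for (p in seq_len(L)) {
    cp <- codes[p, ]
    D <- D + cost[cp, cp]
  }
  D
}

# internal: BLOSUM62 from Biostrings, cached
get_blosum62 <- local({
  B <- NULL
  function() {
    if (is.null(B)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      B <<- e$BLOSUM62
    }
    B
  }
})

#' Cluster designs and select diverse representatives
#'
#' Clusters designed sequences by complete-linkage agglomerative clustering
#' on the BLOSUM62 dissimilarity, drops clusters smaller than
#' `min_cluster_size`, picks as each cluster's representative the member
#' with the lowest mean distance to its co-members, and greedily selects
#' `n_select` clusters: the largest first, then repeatedly the cluster
#' whose representative has the largest mean distance to the
#' already-selected representatives.
#'
#' @param designs Character vector of variant strings (one per design run).
#' @param base_seq Wild-type sequence.
#' @param n_clusters Number of clusters to cut (default 20).
#' @param min_cluster_size Minimum surviving cluster size (default 100).
#'   Alternatively `min_cluster_frac` expresses the threshold as a
#'   fraction of the number of designs.
#' @param n_select Number of representatives to select (default 5).
#' @param min_cluster_frac Optional fractional size threshold overriding
#'   `min_cluster_size`.
#' @return A `"design_report"`: cluster assignments, per-cluster
#'   representatives, and the selected representative variants in
#'   selection order.
#' @export
cluster_and_select <- function(designs, base_seq, n_clusters = 20L,
                               min_cluster_size = 100L, n_select = 5L,
                               min_cluster_frac = NULL) {
  if (length(designs) < n_clusters)
    stop("fewer designs than clusters", call. = FALSE)
  if (!is.null(min_cluster_frac))
    min_cluster_size <- ceiling(min_cluster_frac * length(designs))
  seqs <- variant_sequences(base_seq, designs)
  D <- blosum_distance_matrix(seqs)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  assign <- stats::cutree(hc, k = n_clusters)
  sizes <- table(assign)
  surviving <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(surviving) == 0L)
    stop("no cluster reaches min_cluster_size", call. = FALSE)
  reps <- vapply(surviving, function(cl) {
    idx <- which(assign == cl)
    if (length(idx) == 1L) return(idx)
    md <- rowMeans(D[idx, idx, drop = FALSE]) * length(idx) /
      (length(idx) - 1L)
    idx[which.min(md)]
  }, 0L)
  names(reps) <- surviving
  if (length(surviving) < n_select) {
    warning("only ", length(surviving), " clusters survive the size ",
            "filter; reporting all of them", call. = FALSE)
    n_select <- length(surviving)
  }
  sel <- surviving[which.max(sizes[as.character(surviving)])]
  while (length(sel) < n_select) {
    remaining <- setdiff(surviving, sel)
    mean_dist <- vapply(remaining, function(cl)
      mean(D[reps[as.character(cl)], reps[as.character(sel)]]), 0)
    sel <- c(sel, remaining[which.max(mean_dist)])
  }
  structure(list(assignments = assign, cluster_sizes = sizes,
                 surviving_clusters = surviving,
                 representatives = setNames(designs[reps],
                                            names(reps)),
                 selected_clusters = sel,
                 selected = unname(designs[reps[as.character(sel)]])),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>", length(x$assignments), "designs,",
      length(x$surviving_clusters), "surviving clusters,",
      length(x$selected), "selected\n")
  invisible(x)
}

#' Serialize a design report as JSON
#' @param report A `"design_report"`.
#' @param path Output path.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(
    list(cluster_sizes = as.list(report$cluster_sizes),
         surviving_clusters = report$surviving_clusters,
         representatives = as.list(report$representatives),
         selected_clusters = report$selected_clusters,
         selected = report$selected),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Random baseline designs
#'
#' Samples `n` variants with exactly `cfg$n_mutations` substitutions at
#' distinct positions, drawn without replacement from the constraint-legal
#' mutation set (the observed set, or its complement for unobserved
#' designs).
#'
#' @param base_seq Wild-type sequence.
#' @param cfg A `"design_config"`.
#' @param n Number of baseline variants.
#' @param seed Integer seed.
#' @return Character vector of variant strings.
#' @export
random_baseline_variants <- function(base_seq, cfg, n, seed = 1L) {
  legal <- legal_mutations(base_seq, cfg)
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i)
      tokens_to_variant(sample_legal_set(legal, cfg$n_mutations)), "")
  })
}
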