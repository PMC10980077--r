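#' Parameters of the synthetic biophysics simulator
#'
#' The simulator assigns every sequence an energy
#' \deqn{E(a) = \sum_i [h(a_i) + b(a_i)\,deg_i] + \sum_{(i,j)\in edges} J(a_i, a_j),}
#' where `deg_i` is the residue's contact-graph degree (a burial proxy) and
#' the sum over edges runs over the contact graph. The three energy
#' components (field sum, burial sum, pair sum) are mixed into each named
#' score term through a row-normalized mixing matrix `A`, plus optional
#' Gaussian observation noise; `total_score` is the plain sum of the three
#' components. Binding terms use interface analogues `g` and `J_b` evaluated
#' on contacts touching a designated interface residue set.
#'
#' Unless supplied, all parameter tables are drawn once from seeded standard
#' normals, making the ground truth reproducible without magic constants.
#' `J` carries the epistatic signal: with `J = 0` the energy is exactly
#' additive over substitutions.
#'
#' @param seed Integer seed for drawing the parameter tables.
#' @param n_terms Number of non-binding score terms (default the full
#'   60-name catalog).
#' @param h,b Length-20 per-amino-acid field and burial vectors.
#' @param J Symmetric 20x20 contact-pair energy matrix.
#' @param A Mixing matrix, one row per score term, 3 columns; rows are
#'   L2-normalized so terms share the energy scale.
#' @param sigma Per-term observation noise standard deviations (default
#'   0.05).
#' @param interface Integer vector of 0-based interface residue positions
#'   (used only by binding terms).
#' @param g,J_b Interface analogues of `h` and `J`.
#' @param J_scale Scale multiplier applied to a freshly drawn `J` (set 0 for
#'   a purely additive landscape).
#' @param coupled_pairs Optional 2-column matrix of 0-based position pairs:
#'   when given, only contact-graph edges between these pairs carry the `J`
#'   interaction (all edges by default). Lets a coupling be planted on a
#'   single known contact.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(seed = 1L, n_terms = length(score_terms()),
                       h = NULL, b = NULL, J = NULL, A = NULL, sigma = NULL,
                       interface = integer(0), g = NULL, J_b = NULL,
                       J_scale = 1, coupled_pairs = NULL) {
  withr::with_seed(seed, {
    if (is.null(h)) h <- rnorm(20)
    if (is.null(b)) b <- rnorm(20) * 0.25
    if (is.null(J)) {
      Jr <- matrix(rnorm(400), 20, 20)
      J <- (Jr + t(Jr)) / 2 * 0.5 * J_scale
    }
    if (is.null(A)) A <- matrix(rnorm(n_terms * 3), n_terms, 3)
    if (is.null(g)) g <- rnorm(20)
    if (is.null(J_b)) {
      Jr <- matrix(rnorm(400), 20, 20)
      J_b <- (Jr + t(Jr)) / 2 * 0.5
    }
  })
  if (is.null(sigma)) sigma <- rep(0.05, n_terms)
  sigma <- rep_len(sigma, n_terms)
  stopifnot(length(h) == 20, length(b) == 20, all(dim(J) == c(20, 20)),
            nrow(A) == n_terms, ncol(A) == 3, all(sigma >= 0),
            length(g) == 20, all(dim(J_b) == c(20, 20)))
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric", call. = FALSE)
  if (max(abs(J_b - t(J_b))) > 1e-12) stop("J_b must be symmetric", call. = FALSE)
  A <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  names(h) <- names(b) <- names(g) <- amino_acids()
  dimnames(J) <- dimnames(J_b) <- list(amino_acids(), amino_acids())
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- matrix(as.integer(coupled_pairs), ncol = 2L)
  }
  structure(list(h = h, b = b, J = J, A = A, sigma = sigma,
                 interface = as.integer(interface), g = g, J_b = J_b,
                 coupled_pairs = coupled_pairs, seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a toy protein structure
#'
#' `"chain"` style places residues on a straight line at 3.8 A spacing
#' (a path-graph contact structure). `"globule"` style grows a compact
#' self-avoiding-ish random walk confined to a sphere of protein-like
#' density, yielding both sequence-local and long-range contacts with mean
#' contact degree in roughly 2-10 for lengths 20-100.
#'
#' @param length Number of residues.
#' @param seed Integer seed; same seed gives identical coordinates.
#' @param style `"globule"` (default) or `"chain"`.
#' @param id Structure identifier.
#' @return A `"protein_structure"` with a random sequence.
#' @export
make_toy_structure <- function(length, seed = 1L,
                               style = c("globule", "chain"),
                               id = NULL) {
  style <- match.arg(style)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (is.null(id)) id <- paste0("toy_", style, "_L", length, "_s", seed)
  withr::with_seed(seed, {
    seqn <- paste(sample(amino_acids(), length, replace = TRUE),
                  collapse = "")
    if (style == "chain") {
      coords <- cbind(3.8 * (seq_len(length) - 1L), 0, 0)
    } else {
      # uniform packing in a sphere whose radius fixes the density so a
      # residue sees ~6 others within 8 A, with a 3.8 A exclusion radius
      r <- 8 * (length / 6)^(1 / 3)
      coords <- matrix(NA_real_, length, 3L)
      for (i in seq_len(length)) {
        repeat {
          cand <- runif(3, -r, r)
          if (sum(cand^2) > r^2) next
          if (i == 1L) break
          d2 <- colSums((t(coords[seq_len(i - 1L), , drop = FALSE]) -
                           cand)^2)
          if (min(d2) >= 3.8^2) break
        }
        coords[i, ] <- cand
      }
    }
  })
  protein_structure(seqn, coords, id = id)
}

# internal: contact edges carrying the pair interaction for these params
sim_edges <- function(g, p) {
  if (is.null(p$coupled_pairs)) return(g$edges)
  want <- paste(pmin(p$coupled_pairs[, 1L], p$coupled_pairs[, 2L]) + 1L,
                pmax(p$coupled_pairs[, 1L], p$coupled_pairs[, 2L]) + 1L)
  have <- paste(g$edges[, 1L], g$edges[, 2L])
  g$edges[have %in% want, , drop = FALSE]
}

# internal: energy components of integer-coded sequences.
# codes: L x B integer matrix (1..20); deg: length-L degrees; edges: 2-col
# matrix. Returns 3 x B matrix (field, burial, pair).
energy_components <- function(codes, deg, edges, h, b, J) {
  field <- colSums(matrix(h[codes], nrow(codes)))
  burial <- colSums(matrix(b[codes], nrow(codes)) * deg)
  if (nrow(edges) > 0L) {
    ai <- codes[edges[, 1L], , drop = FALSE]
    aj <- codes[edges[, 2L], , drop = FALSE]
    pair <- colSums(matrix(J[cbind(as.vector(ai), as.vector(aj))],
                           nrow(edges)))
  } else pair <- numeric(ncol(codes))
  rbind(field = field, burial = burial, pair = pair)
}

#' Total simulator energy of sequences
#'
#' The noiseless ground-truth energy `E` described in [sim_params()];
#' deterministic in the sequence. Lower energies correspond to fitter
#' sequences in the synthetic landscape (latent fitness is `-E`).
#'
#' @param s A `"protein_structure"` (defines the contact graph).
#' @param p A `"sim_params"`.
#' @param seqs Character vector of sequences (same length as the structure).
#' @return Numeric vector of energies.
#' @export
sim_energy <- function(s, p, seqs) {
  stopifnot(inherits(s, "protein_structure"), inherits(p, "sim_params"))
  g <- build_contact_graph(s)
  deg <- tabulate(g$edges, nbins = g$n)
  codes <- vapply(seqs, aa_encode, integer(nchar(s$sequence)),
                  USE.NAMES = FALSE)
  codes <- matrix(codes, nchar(s$sequence))
  comp <- energy_components(codes, deg, sim_edges(g, p), p$h, p$b, p$J)
  colSums(comp)
}

#' Score variants with the synthetic simulator
#'
#' Emits the named attribute vector for every variant: the 60-term catalog
#' (or 77 columns when `with_binding`), each term a mixed projection of the
#' sequence's energy components plus optional Gaussian noise. `total_score`
#' is the plain component sum; `res_count_all` is the constant sequence
#' length; `filter_total_score` mirrors `total_score`, and the chain-break
#' and disulfide terms are near-zero columns — together exercising the
#' preprocessing exclusions.
#'
#' @param s A `"protein_structure"`.
#' @param p A `"sim_params"`.
#' @param variants Character vector of canonical 0-based variant strings.
#' @param with_binding Also emit the 17 interface binding terms.
#' @param noise Add per-term Gaussian observation noise (`p$sigma`).
#' @param seed Integer seed for the noise draws.
#' @return A data frame (`"attribute_table"`) with columns `base_pdb`,
#'   `variant`, then one column per score term.
#' @export
score_variants <- function(s, p, variants, with_binding = FALSE,
                           noise = TRUE, seed = 1L) {
  stopifnot(inherits(s, "protein_structure"), inherits(p, "sim_params"))
  g <- build_contact_graph(s)
  deg <- tabulate(g$edges, nbins = g$n)
  L <- nchar(s$sequence)
  seqs <- variant_sequences(s$sequence, variants)
  codes <- matrix(vapply(seqs, aa_encode, integer(L), USE.NAMES = FALSE), L)
  comp <- energy_components(codes, deg, sim_edges(g, p), p$h, p$b, p$J)
  B <- ncol(comp)
  terms <- score_terms()
  stopifnot(nrow(p$A) == length(terms))
  vals <- t(p$A %*% comp)                      # B x n_terms
  colnames(vals) <- terms
  vals[, "total_score"] <- colSums(comp)
  # columns engineered to trigger the preprocessing exclusions
  vals[, "res_count_all"] <- L
  vals[, "filter_total_score"] <- vals[, "total_score"]
  vals[, "dslf_fa13"] <- 0
  vals[, "linear_chainbreak"] <- 0
  vals[, "overlap_chainbreak"] <- 0
  if (with_binding) {
    if (length(p$interface) == 0L)
      stop("with_binding requires a non-empty interface set in sim_params",
           call. = FALSE)
    iface <- p$interface + 1L
    degb <- deg
    edges_b <- g$edges[g$edges[, 1L] %in% iface | g$edges[, 2L] %in% iface,
                       , drop = FALSE]
    codes_if <- codes[iface, , drop = FALSE]
    fieldb <- colSums(matrix(p$g[codes_if], nrow(codes_if)))
    if (nrow(edges_b) > 0L) {
      ai <- codes[edges_b[, 1L], , drop = FALSE]
      aj <- codes[edges_b[, 2L], , drop = FALSE]
      pairb <- colSums(matrix(p$J_b[cbind(as.vector(ai), as.vector(aj))],
                              nrow(edges_b)))
    } else pairb <- numeric(B)
    compb <- rbind(fieldb, pairb)
    bt <- binding_terms()
    Ab <- withr::with_seed(p$seed + 1L,
                           matrix(rnorm(length(bt) * 2), length(bt), 2))
    Ab <- Ab / pmax(sqrt(rowSums(Ab^2)), 1e-12)
    valsb <- t(Ab %*% compb)
    colnames(valsb) <- bt
    vals <- cbind(vals, valsb)
  }
  if (noise) {
    sig <- c(p$sigma, if (with_binding) rep(0.05, length(binding_terms())))
    eps <- withr::with_seed(seed,
      matrix(rnorm(B * ncol(vals)), B) %*% diag(sig, ncol(vals)))
    vals <- vals + eps
    vals[, "res_count_all"] <- L  # stays exactly constant
  }
  out <- data.frame(base_pdb = s$id, variant = variants,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals))
  class(out) <- c("attribute_table", "data.frame")
  out
}

# internal: names of the score-term columns of an attribute table
attr_term_cols <- function(t) setdiff(names(t), c("base_pdb", "variant"))

#' Inject faults into an attribute table
#'
#' Emulates real pipeline pathologies for testing the preprocessing stage:
#' each original row independently receives a NaN in one random score column
#' with probability `r_nan`; is duplicated (row appended) with probability
#' `r_dup`; and has its `total_score` shifted by `out_magnitude` times the
#' group's interquartile range (sign random) with probability `r_out`.
#'
#' @param t An `"attribute_table"`.
#' @param r_nan,r_dup,r_out Per-row fault rates.
#' @param out_magnitude Outlier shift in IQR units (default 50).
#' @param seed Integer seed.
#' @return List with elements `table` (the faulted table) and `counts`
#'   (named integer vector of injected nan/dup/outlier events).
#' @export
inject_faults <- function(t, r_nan = 0, r_dup = 0, r_out = 0,
                          out_magnitude = 50, seed = 1L) {
  stopifnot(is.data.frame(t))
  terms <- attr_term_cols(t)
  n <- nrow(t)
  withr::with_seed(seed, {
    nan_rows <- which(runif(n) < r_nan)
    dup_rows <- which(runif(n) < r_dup)
    out_rows <- which(runif(n) < r_out)
    for (i in nan_rows)
      t[i, sample(terms, 1L)] <- NaN
    scale <- stats::IQR(t$total_score[is.finite(t$total_score)])
    if (!is.finite(scale) || scale == 0) scale <- 1
    t$total_score[out_rows] <- t$total_score[out_rows] +
      sample(c(-1, 1), length(out_rows), replace = TRUE) *
        out_magnitude * scale
    if (length(dup_rows) > 0L)
      t <- rbind(t, t[dup_rows, , drop = FALSE])
  })
  rownames(t) <- NULL
  class(t) <- c("attribute_table", "data.frame")
  list(table = t,
       counts = c(nan = length(nan_rows), dup = length(dup_rows),
                  outlier = length(out_rows)),
       outlier_rows = out_rows, nan_rows = nan_rows)
}

#' Fabricate an experimental sequence-function dataset
#'
#' Samples variants with the sub-variants algorithm, assigns each the latent
#' fitness `-E(seq)` (optionally passed through a monotone sigmoid link),
#' adds Gaussian assay noise, normalizes so the wild type scores exactly 0,
#' and rounds to 7 decimal places.
#'
#' @param s A `"protein_structure"`.
#' @param p A `"sim_params"`.
#' @param n Number of variants.
#' @param max_subs Maximum substitutions per variant.
#' @param assay_noise Assay noise standard deviation (default 0).
#' @param link `"identity"` (default) or `"sigmoid"`.
#' @param seed Integer seed.
#' @param include_wt Prepend a wild-type row (empty variant string).
#' @return A data frame (`"experimental_dataset"`) with columns `variant`
#'   and `score`.
#' @export
make_experimental_dataset <- function(s, p, n, max_subs = 2L,
                                      assay_noise = 0,
                                      link = c("identity", "sigmoid"),
                                      seed = 1L, include_wt = FALSE) {
  link <- match.arg(link)
  stopifnot(n >= 1L)
  variants <- sample_subvariants(s$sequence, n, max_subs = max_subs,
                                 seed = seed)
  if (include_wt) variants <- c("", variants)
  fit <- -sim_energy(s, p, variant_sequences(s$sequence, variants))
  wt_fit <- -sim_energy(s, p, s$sequence)
  if (link == "sigmoid") {
    scl <- max(stats::sd(fit), 1e-12)
    fit <- 1 / (1 + exp(-(fit - wt_fit) / scl))
    wt_fit <- 0.5
  }
  if (assay_noise > 0)
    fit <- fit + withr::with_seed(seed + 1L,
                                  rnorm(length(fit), sd = assay_noise))
  score <- round(fit - wt_fit, 7L)
  out <- data.frame(variant = variants, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("experimental_dataset", "data.frame")
  out
}

#' Read / write attribute tables and experimental datasets
#'
#' Attribute tables are CSV files with columns `base_pdb`, `variant`, then
#' one column per score term; experimental datasets have columns `variant`
#' and `score`.
#'
#' @param t Table to write.
#' @param path File path.
#' @return The read data frame (with the appropriate class) or,
#'   invisibly, `path`.
#' @export
write_attribute_table <- function(t, path) {
  write.csv(t, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_attribute_table
#' @export
read_attribute_table <- function(path) {
  t <- read.csv(path, colClasses = c(base_pdb = "character",
                                     variant = "character"))
  t$variant[is.na(t$variant)] <- ""
  class(t) <- c("attribute_table", "data.frame")
  t
}
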