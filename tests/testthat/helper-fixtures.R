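# Shared fixtures, memoized so that expensive objects (pretrained toy
# models) are built once per test run and only when a test asks for them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the standard length-20 globular toy protein
fx_struct20 <- function() {
  fixture("struct20", function() make_toy_structure(20, seed = 11))
}

# mini architecture used for all trained-model tests
fx_mini_config <- function(rpe_mode = "3d") {
  model_config(embed_dim = 32L, n_layers = 2L, n_heads = 2L, ff_dim = 64L,
               n_tasks = 55L, head_hidden = 32L, rpe_mode = rpe_mode,
               dropout = 0.1)
}

# cleaned + standardized pretraining table on the toy protein.
# additive = TRUE gives the purely additive landscape (J = 0).
fx_pretrain_table <- function(additive) {
  nm <- paste0("pretab_", additive)
  fixture(nm, function() {
    s <- fx_struct20()
    p <- sim_params(seed = 7, J_scale = if (additive) 0 else 1)
    vars <- sample_subvariants(s$sequence, 2000, max_subs = 5, seed = 3)
    tab <- score_variants(s, p, vars, noise = FALSE)
    tab <- drop_excluded_terms(clean_attribute_table(tab, seed = 1)$table)
    splits <- make_pretrain_splits(nrow(tab), seed = 2)
    std <- standardize_attributes(tab, splits$train)
    list(structure = s, params = p, table = std$table, splits = splits)
  })
}

# a pretrained mini source model on the toy protein
fx_pretrained <- function(rpe_mode = "3d", additive = TRUE) {
  nm <- paste0("pre_", rpe_mode, "_", additive)
  fixture(nm, function() {
    fx <- fx_pretrain_table(additive)
    m <- build_model(fx_mini_config(rpe_mode), structure = fx$structure,
                     seed = 4)
    fit <- pretrain(m, fx$table, fx$structure, fx$splits,
                    train_config(preset = "pretrain", batch_size = 128L,
                                 seed = 9))
    c(fit, fx)
  })
}

# synthetic dataset with singles and doubles for split construction
split_fixture <- function() {
  fixture("split_dataset", function() {
    s <- make_toy_structure(18, seed = 21)
    p <- sim_params(seed = 22)
    make_experimental_dataset(s, p, 900, max_subs = 2, seed = 23)
  })
}

# a small additive design problem shared across tests
design_fixture <- function() {
  fixture("design_problem", function() {
    s <- make_toy_structure(8, seed = 5)
    p <- sim_params(seed = 13, J_scale = 0)
    singles <- enumerate_variants(s$sequence, 1)
    allowed <- withr::with_seed(17, sample(singles, 12))
    list(s = s, p = p,
         score_fn = function(seqs) -sim_energy(s, p, seqs),
         allowed = allowed)
  })
}

# dense Floyd-Warshall all-pairs shortest paths: the independent oracle for
# the contact-graph relative distances
floyd_warshall <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges[k, 1L], edges[k, 2L]] <- 1
    D[edges[k, 2L], edges[k, 1L]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# minimal three-residue PDB text (ALA with CB, GLY without, VAL with CB)
toy_pdb_text <- function() {
  mk <- function(serial, elety, resid, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, elety, resid, resno, x, y, z)
  }
  paste(c(
    mk(1, "N", "ALA", 1, 0, 0, 0),
    mk(2, "CA", "ALA", 1, 1, 0, 0),
    mk(3, "CB", "ALA", 1, 2, 0, 0),
    mk(4, "CA", "GLY", 2, 5, 0, 0),
    mk(5, "CA", "VAL", 3, 19, 0, 0),
    mk(6, "CB", "VAL", 3, 20, 0, 0),
    "END"), collapse = "\n")
}

write_toy_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text(), path)
  path
}
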