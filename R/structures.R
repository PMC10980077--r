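#' Construct a protein structure object
#'
#' A minimal per-residue representation: one 3D point per residue (the
#' beta-carbon, or the alpha-carbon for residues lacking one), in Angstroms.
#'
#' @param sequence Amino-acid sequence string.
#' @param coords Numeric matrix, `nchar(sequence)` rows by 3 columns.
#' @param id Identifier string.
#' @return An object of class `"protein_structure"`.
#' @export
protein_structure <- function(sequence, coords, id = "protein") {
  check_aa_seq(sequence, "sequence")
  coords <- as.matrix(coords)
  if (nrow(coords) != nchar(sequence) || ncol(coords) != 3L)
    stop("coords must have one 3D row per residue", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, sequence = sequence, coords = coords),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure>", x$id, "-", nchar(x$sequence), "residues\n")
  invisible(x)
}

#' Load a protein structure from a PDB file
#'
#' Extracts one coordinate per residue: the beta-carbon (CB) atom, falling
#' back to the alpha-carbon (CA) for glycine or any residue lacking a CB.
#' Only standard amino-acid residues are accepted; missing residues are an
#' error (no remodeling is attempted).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier. Required when the file holds several
#'   chains; defaults to the single chain present.
#' @param expected_seq Optional sequence the parsed structure must match
#'   exactly.
#' @return A `"protein_structure"` object.
#' @export
load_structure <- function(path, chain = NULL, expected_seq = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("PDB file has chains ", paste(chains, collapse = ", "),
           "; supply `chain`", call. = FALSE)
    chain <- chains
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not present in PDB file", call. = FALSE)
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, call. = FALSE)
  resids <- unique(at$resno)
  take <- function(resno, name) {
    row <- at[at$resno == resno & at$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    c(row$x[1L], row$y[1L], row$z[1L])
  }
  seq3 <- character(length(resids))
  coords <- matrix(NA_real_, length(resids), 3L)
  for (k in seq_along(resids)) {
    rows <- at[at$resno == resids[k], , drop = FALSE]
    seq3[k] <- rows$resid[1L]
    xyz <- take(resids[k], "CB")
    if (is.null(xyz)) xyz <- take(resids[k], "CA")
    if (is.null(xyz))
      stop("residue ", resids[k], " has neither CB nor CA atom", call. = FALSE)
    coords[k, ] <- xyz
  }
  seq1 <- bio3d::aa321(seq3)
  if (any(seq1 == "X"))
    stop("non-standard residue(s): ",
         paste(unique(seq3[seq1 == "X"]), collapse = ", "), call. = FALSE)
  s <- protein_structure(paste(seq1, collapse = ""), coords,
                         id = basename(path))
  if (!is.null(expected_seq) && !identical(s$sequence, expected_seq))
    stop("parsed sequence does not match expected_seq", call. = FALSE)
  s
}

#' Build the residue contact graph
#'
#' Residues i and j (i != j) are in contact when their representative atoms
#' lie within `threshold` Angstroms of each other (inclusive boundary).
#'
#' @param s A `"protein_structure"`.
#' @param threshold Contact distance cutoff in Angstroms (default 8).
#' @return An object of class `"contact_graph"`: list with `n` and `edges`,
#'   a 2-column matrix of 1-based residue index pairs with `i < j`.
#' @export
build_contact_graph <- function(s, threshold = 8) {
  stopifnot(inherits(s, "protein_structure"))
  d <- as.matrix(stats::dist(s$coords))
  adj <- d <= threshold
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  structure(list(n = nrow(s$coords), edges = idx, threshold = threshold),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph>", x$n, "residues,", nrow(x$edges), "contacts (<=",
      x$threshold, "A)\n")
  invisible(x)
}

# internal: mean node degree of a contact graph
graph_mean_degree <- function(g) 2 * nrow(g$edges) / g$n

#' Relative-distance map for position embeddings
#'
#' In `"1d"` mode the relative distance between sequence positions i and j is
#' the signed offset `j - i`, clipped to `[-clip, clip]` (default clip 8). In
#' `"3d"` mode it is the shortest-path length between residues i and j in the
#' contact graph, clipped at `clip` (default 3); 0 is self, 1 a direct
#' contact, 2 a second-degree neighbour, and `clip` any other pair, including
#' pairs in disconnected components.
#'
#' @param s A `"protein_structure"` (required for `"3d"`), or an integer
#'   sequence length for `"1d"`.
#' @param mode `"1d"` or `"3d"`.
#' @param clip Clipping bound; defaults to 8 for `"1d"` and 3 for `"3d"`.
#' @param threshold Contact cutoff in Angstroms passed to
#'   [build_contact_graph()] in `"3d"` mode.
#' @return An object of class `"relative_distance_map"`: list with `mode`,
#'   `clip` and `values`, an n-by-n integer matrix.
#' @export
relative_distances <- function(s, mode = c("1d", "3d"), clip = NULL,
                               threshold = 8) {
  mode <- match.arg(mode)
  if (mode == "1d") {
    n <- if (inherits(s, "protein_structure")) nchar(s$sequence)
         else as.integer(s)
    if (is.null(clip)) clip <- 8L
    idx <- seq_len(n)
    vals <- outer(idx, idx, function(i, j) pmin(pmax(j - i, -clip), clip))
  } else {
    if (!inherits(s, "protein_structure"))
      stop("3d mode requires a protein_structure", call. = FALSE)
    if (is.null(clip)) clip <- 3L
    g <- build_contact_graph(s, threshold = threshold)
    n <- g$n
    ig <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(g$edges) > 0L)
      ig <- igraph::add_edges(ig, t(g$edges))
    sp <- igraph::distances(ig)
    sp[!is.finite(sp)] <- clip
    vals <- pmin(sp, clip)
  }
  structure(list(mode = mode, clip = as.integer(clip),
                 values = matrix(as.integer(vals), nrow(vals))),
            class = "relative_distance_map")
}

#' @export
print.relative_distance_map <- function(x, ...) {
  cat("<relative_distance_map>", x$mode, "mode,", nrow(x$values),
      "positions, clip", x$clip, "\n")
  invisible(x)
}

# internal: 1-based embedding-class index matrix for a distance map.
# 3d: classes 1..clip+1 (distance 0..clip); 1d: classes 1..2*clip+1
# (distance -clip..clip).
rpe_class_index <- function(map) {
  stopifnot(inherits(map, "relative_distance_map"))
  if (map$mode == "3d") map$values + 1L
  else map$values + map$clip + 1L
}

# internal: number of embedding classes for a mode/clip
rpe_n_classes <- function(mode, clip) {
  if (mode == "3d") clip + 1L else 2L * clip + 1L
}

#' Export a relative-distance map as CSV
#' @param map A `"relative_distance_map"`.
#' @param path Output file path.
#' @export
write_distance_map <- function(map, path) {
  write.csv(map$values, path, row.names = FALSE)
  invisible(path)
}
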