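# ---- atom featurization and batching ----------------------------------------

# One-hot feature schema. Every block has a catch-all bin, so any atom maps to
# exactly one active bin per block; the two binary properties (aromatic,
# in-ring) are single bits. Total width 23+6+6+1+1+8+4+8+9+5 = 71.
feature_schema <- function() {
  list(
    identity = c("C", "O", "S", "N", "Cl", "Na", "P", "F", "Mg", "I", "Br",
                 "Zn", "Fe", "As", "Ca", "B", "Si", "K", "Co", "Cr", "H",
                 "Al", "others"),
    n_heavy = c("0", "1", "2", "3", "4", "other"),
    n_h = c("0", "1", "2", "3", "4", "other"),
    aromatic = "aromatic",
    in_ring = "in_ring",
    hybridization = c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2",
                      "unspecified", "other"),
    chirality = c("CW", "CCW", "unspecified", "other"),
    formal_charge = c("0", "-1", "1", "-2", "2", "3", "4", "other"),
    explicit_valence = c("0", "1", "2", "3", "4", "5", "6", "7", "other"),
    implicit_valence = c("0", "1", "2", "3", "other")
  )
}

#' Atom feature dimension
#' @return Width of the one-hot atom feature vector (71).
#' @export
feature_dim <- function() sum(lengths(feature_schema()))

feature_names <- function() {
  sch <- feature_schema()
  unlist(lapply(names(sch), function(b) paste(b, sch[[b]], sep = ".")),
         use.names = FALSE)
}

# Stable hash of the feature schema, stored in checkpoints so a model is never
# applied to inputs featurized under a different schema.
feature_schema_hash <- function() {
  s <- paste(feature_names(), collapse = "|")
  # polynomial rolling hash over the schema string (exact in doubles)
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

one_hot <- function(values, levels, catch_all) {
  idx <- match(as.character(values), levels)
  idx[is.na(idx)] <- match(catch_all, levels)
  m <- matrix(0, length(values), length(levels))
  m[cbind(seq_along(values), idx)] <- 1
  m
}

# Vectorized Table-of-atomic-features encoding for a backend atoms frame.
feature_matrix <- function(atoms) {
  sch <- feature_schema()
  cbind(
    one_hot(atoms$symbol, sch$identity, "others"),
    one_hot(atoms$n_heavy, sch$n_heavy, "other"),
    one_hot(atoms$n_h, sch$n_h, "other"),
    as.numeric(atoms$aromatic == 1),
    as.numeric(atoms$in_ring == 1),
    one_hot(atoms$hybridization, sch$hybridization, "other"),
    one_hot(atoms$chirality, sch$chirality, "other"),
    one_hot(atoms$formal_charge, sch$formal_charge, "other"),
    one_hot(atoms$explicit_valence, sch$explicit_valence, "other"),
    one_hot(atoms$implicit_valence, sch$implicit_valence, "other")
  )
}

#' Atom feature vector
#'
#' Encodes one atom's perceived properties as the concatenation of one-hot
#' blocks: atomic identity (23 bins, 'others' catch-all), heavy-neighbor count
#' (6), hydrogen-neighbor count (6), aromaticity (1 bit), ring membership
#' (1 bit), hybridization (8), tetrahedral chirality (4), formal charge (8),
#' explicit valence (9), implicit valence (5); exactly one bin is active per
#' block.
#'
#' @param symbol Element symbol.
#' @param n_heavy,n_h Heavy- and hydrogen-neighbor counts.
#' @param aromatic,in_ring Logical/0-1 flags.
#' @param hybridization One of `"S","SP","SP2","SP3","SP3D","SP3D2",
#'   "unspecified"` (anything else falls in `"other"`).
#' @param chirality One of `"CW","CCW","unspecified"` or other.
#' @param formal_charge Integer formal charge.
#' @param explicit_valence,implicit_valence Integer valences.
#' @return Named numeric vector of length [feature_dim()].
#' @export
atom_features <- function(symbol, n_heavy, n_h, aromatic, in_ring,
                          hybridization, chirality, formal_charge,
                          explicit_valence, implicit_valence) {
  v <- feature_matrix(data.frame(
    symbol = symbol, n_heavy = n_heavy, n_h = n_h,
    aromatic = as.integer(aromatic), in_ring = as.integer(in_ring),
    hybridization = hybridization, chirality = chirality,
    formal_charge = formal_charge, explicit_valence = explicit_valence,
    implicit_valence = implicit_valence, stringsAsFactors = FALSE))[1, ]
  names(v) <- feature_names()
  v
}

# Assemble a mol_graph from backend describe output for one molecule.
build_mol_graph <- function(id, smiles, atoms, bonds) {
  atoms <- atoms[order(atoms$atom), , drop = FALSE]
  n <- nrow(atoms)
  adj <- matrix(0, n, n)
  if (!is.null(bonds) && nrow(bonds)) {
    i <- bonds$a1 + 1L
    j <- bonds$a2 + 1L
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dist <- as.matrix(stats::dist(xyz))
  dimnames(dist) <- NULL
  structure(list(id = id, smiles = smiles, n_atoms = n,
                 features = feature_matrix(atoms),
                 adjacency = adj, distance = dist,
                 atoms = atoms[, c("symbol", "aromatic", "in_ring")]),
            class = "mol_graph")
}

#' Build a molecular graph from a single SMILES
#'
#' Convenience wrapper around [compute_geometry()] for one molecule.
#' @param smiles A SMILES string.
#' @param embed_seed Conformer embedding seed.
#' @return A `mol_graph` object with fields `features` (n x 71), `adjacency`
#'   and `distance` (n x n), or an error if parsing/embedding fails.
#' @export
mol_graph <- function(smiles, embed_seed = 42L) {
  geo <- compute_geometry(smiles, embed_seed = embed_seed)
  g <- geo$graphs[[1]]
  if (is.null(g)) stop("could not build geometry for: ", smiles,
                       " (", geo$records$status[1], ")")
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph", x$id, ":", x$smiles, "-", x$n_atoms, "atoms\n")
  invisible(x)
}

#' Pad molecular graphs into a batch
#'
#' Stacks graphs into zero-padded arrays. Features are stored as a stacked
#' (B*N_max) x d_f matrix in molecule-major row order; adjacency and exp(-D)
#' masks as N_max x N_max x B arrays. Padded rows/columns are zero and are
#' excluded from every softmax downstream, so model outputs for the real atoms
#' are invariant to the padding width.
#'
#' @param graphs List of `mol_graph` objects (all with the same feature
#'   dimension).
#' @param labels Optional numeric matrix (one row per graph).
#' @return A `molattn_batch`: `features`, `adjacency`, `gdist` (elementwise
#'   exp(-distance)), `distance`, `atom_mask` (B x N_max), `n_atoms`, `ids`,
#'   `labels`, `N`, `B`.
#' @export
build_batch <- function(graphs, labels = NULL) {
  if (!length(graphs)) stop("empty graph list")
  B <- length(graphs)
  n_atoms <- vapply(graphs, `[[`, 0L, "n_atoms")
  N <- max(n_atoms)
  d_f <- ncol(graphs[[1]]$features)
  feats <- matrix(0, B * N, d_f)
  adj <- array(0, c(N, N, B))
  dst <- array(0, c(N, N, B))
  gD <- array(0, c(N, N, B))
  mask <- matrix(0L, B, N)
  for (b in seq_len(B)) {
    g <- graphs[[b]]
    n <- g$n_atoms
    feats[(b - 1L) * N + seq_len(n), ] <- g$features
    adj[seq_len(n), seq_len(n), b] <- g$adjacency
    dst[seq_len(n), seq_len(n), b] <- g$distance
    gD[seq_len(n), seq_len(n), b] <- exp(-g$distance)
    mask[b, seq_len(n)] <- 1L
  }
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (nrow(labels) != B) stop("labels must have one row per graph")
  }
  structure(list(features = feats, adjacency = adj, distance = dst,
                 gdist = gD, atom_mask = mask,
                 n_atoms = as.integer(n_atoms),
                 ids = vapply(graphs, `[[`, "", "id"),
                 labels = labels, N = N, B = B),
            class = "molattn_batch")
}

#' Recover per-molecule arrays from a batch
#'
#' Inverse of [build_batch()] up to the stored fields: strips padding and
#' returns each molecule's feature, adjacency and distance matrices.
#' @param batch A `molattn_batch`.
#' @return List of lists with `features`, `adjacency`, `distance`, `id`.
#' @export
unbuild_batch <- function(batch) {
  lapply(seq_len(batch$B), function(b) {
    n <- batch$n_atoms[b]
    rows <- (b - 1L) * batch$N + seq_len(n)
    list(id = batch$ids[b],
         features = batch$features[rows, , drop = FALSE],
         adjacency = batch$adjacency[seq_len(n), seq_len(n), b],
         distance = batch$distance[seq_len(n), seq_len(n), b])
  })
}

#' Save / load featurized molecular graphs
#'
#' Serializes a list of `mol_graph` objects (keyed by molecule id) to a single
#' compressed archive, so featurization need not be repeated across runs.
#' @param graphs Named list of `mol_graph` objects.
#' @param path Archive path (`.rds`).
#' @export
write_molgraphs <- function(graphs, path) {
  names(graphs) <- vapply(graphs, `[[`, "", "id")
  saveRDS(list(schema = feature_schema_hash(), graphs = graphs), path,
          compress = "gzip")
  invisible(path)
}

#' @rdname write_molgraphs
#' @export
read_molgraphs <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, feature_schema_hash()))
    stop("feature schema mismatch: archive was written under a different schema")
  obj$graphs
}
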