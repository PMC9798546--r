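# ---- molecule tables, geometry, filtering, SMARTS labeling ------------------

#' Define a prediction target
#'
#' A target is either a substructure, given as one or more SMARTS patterns
#' that must *all* match for the label to be 1 (a conjunction, used for
#' combination targets), or a named 0/1 column already present in the
#' molecule table.
#'
#' @param name Target name (used as the label column name).
#' @param patterns Character vector of SMARTS patterns (for `kind = "smarts"`).
#'   Lowercase atoms are aromatic; matching uses RDKit's standard aromaticity
#'   perception.
#' @param kind `"smarts"` or `"label_column"`.
#' @param min_positives Minimum number of positive samples required for the
#'   target to be trainable (checked by [compute_class_weights()]).
#' @return An object of class `target_spec`.
#' @examples
#' target_spec("ester", "C(=O)O")
#' target_spec("isopropyl_on_arene", c("CC(C)C", "cCc"))
#' @export
target_spec <- function(name, patterns = NULL,
                        kind = if (is.null(patterns)) "label_column" else "smarts",
                        min_positives = 1L) {
  kind <- match.arg(kind, c("smarts", "label_column"))
  if (kind == "smarts" && (is.null(patterns) || !length(patterns)))
    stop("a 'smarts' target needs at least one SMARTS pattern")
  structure(list(name = name, kind = kind,
                 patterns = as.character(patterns %||% character(0)),
                 min_positives = as.integer(min_positives)),
            class = "target_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_target_list <- function(targets) {
  if (inherits(targets, "target_spec")) targets <- list(targets)
  if (!is.list(targets) || !all(vapply(targets, inherits, TRUE, "target_spec")))
    stop("'targets' must be a target_spec or a list of them")
  nm <- vapply(targets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate target names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(targets) <- nm
  targets
}

#' Default substructure target set
#'
#' Twenty-four substructure-presence targets: twelve single SMARTS patterns
#' and twelve conjunctions of two or three patterns. The list covers common
#' small-molecule motifs (carboxyl/ester, peroxide, isopropyl, benzylic
#' aromatic carbon, alkenes, carbonyls, nitriles, benzene, amines, thioethers,
#' tert-butyl) and is meant as an editable starting point, not a canonical
#' benchmark.
#'
#' @return A named list of [target_spec()] objects.
#' @export
default_substructure_targets <- function() {
  singles <- list(
    target_spec("carboxyl",  "C(=O)O"),
    target_spec("peroxide",  "OO"),
    target_spec("isopropyl", "CC(C)C"),
    target_spec("benzylic",  "cCc"),
    target_spec("alkene",    "C=C"),
    target_spec("carbonyl",  "C=O"),
    target_spec("nitrile",   "C#N"),
    target_spec("benzene",   "c1ccccc1"),
    target_spec("sulfide",   "S"),
    target_spec("amine",     "N"),
    target_spec("ether",     "COC"),
    target_spec("tert_butyl", "CC(C)(C)C")
  )
  combos <- list(
    target_spec("carboxyl_and_benzene",  c("C(=O)O", "c1ccccc1")),
    target_spec("carboxyl_and_isopropyl", c("C(=O)O", "CC(C)C")),
    target_spec("isopropyl_and_benzylic", c("CC(C)C", "cCc")),
    target_spec("peroxide_and_alkene",   c("OO", "C=C")),
    target_spec("carbonyl_and_amine",    c("C=O", "N")),
    target_spec("sulfide_and_benzene",   c("S", "c1ccccc1")),
    target_spec("ether_and_alkene",      c("COC", "C=C")),
    target_spec("carboxyl_and_peroxide", c("C(=O)O", "OO")),
    target_spec("alkene_and_carbonyl",   c("C=C", "C=O")),
    target_spec("benzene_and_amine",     c("c1ccccc1", "N")),
    target_spec("tert_butyl_and_benzene", c("CC(C)(C)C", "c1ccccc1")),
    target_spec("carboxyl_benzene_isopropyl", c("C(=O)O", "c1ccccc1", "CC(C)C"))
  )
  as_target_list(c(singles, combos))
}

#' Read a molecule table (CSV/TSV)
#'
#' Reads a delimited table with a SMILES column and optional 0/1 label
#' columns, parses each SMILES, and returns one record per row (row order
#' preserved). Rows whose SMILES cannot be parsed get status
#' `removed_parse_error`; everything else starts as `ok`.
#'
#' @param path Path to a CSV (comma) or TSV (tab) file with a header row.
#'   The delimiter is taken from the file extension (`.tsv`/`.tab` means tab)
#'   or can be forced with `sep`.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param label_columns Character vector of 0/1 label column names to carry
#'   along; a non-binary cell is an error naming the offending row.
#' @param id_col Optional id column; defaults to `mol_<row>` ids.
#' @param sep Field separator override.
#' @return A `molattn_records` data frame with columns `id`, `smiles`,
#'   `status`, `n_atoms`, then any label columns.
#' @export
read_molecule_table <- function(path, smiles_col = "smiles",
                                label_columns = NULL, id_col = NULL,
                                sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!smiles_col %in% names(df))
    stop("SMILES column '", smiles_col, "' not found in ", path)
  for (lc in label_columns) {
    if (!lc %in% names(df)) stop("label column '", lc, "' not found in ", path)
    bad <- which(!(df[[lc]] %in% c(0, 1)))
    if (length(bad))
      stop("label column '", lc, "' has a non-binary value in row ", bad[1])
    df[[lc]] <- as.integer(df[[lc]])
  }
  ids <- if (!is.null(id_col)) as.character(df[[id_col]])
         else sprintf("mol_%d", seq_len(nrow(df)))
  molattn_records(ids, as.character(df[[smiles_col]]),
                  labels = df[label_columns %||% character(0)])
}

#' Read molecules from an SDF file
#'
#' Molecule titles become record ids; structures are canonicalized to SMILES.
#' @param path Path to an SDF file.
#' @return A `molattn_records` data frame, as for [read_molecule_table()].
#' @export
read_molecule_sdf <- function(path) {
  tab <- backend_sdf2smi(path)
  molattn_records(as.character(tab$id), as.character(tab$smiles))
}

# Build the records frame: one parse pass (no geometry yet).
molattn_records <- function(ids, smiles, labels = NULL) {
  smiles[is.na(smiles)] <- ""
  desc <- backend_describe(smiles, coords = "none")
  status <- ifelse(desc$mols$status == "parse_error", "removed_parse_error", "ok")
  rec <- data.frame(id = ids, smiles = smiles, status = status,
                    n_atoms = desc$mols$n_atoms, stringsAsFactors = FALSE)
  if (!is.null(labels) && length(labels)) rec <- cbind(rec, labels)
  class(rec) <- c("molattn_records", "data.frame")
  rec
}

#' Compute molecular geometry and graphs
#'
#' Parses each record's SMILES, embeds one 3D conformer with the backend's
#' default embedding parameters and a fixed seed, and builds the model inputs:
#' the one-hot atom-feature matrix, the binary covalent adjacency matrix
#' (zero diagonal, symmetric), and the pairwise Euclidean distance matrix in
#' angstroms. Modeled atoms are heavy atoms; hydrogens enter only through the
#' hydrogen-neighbor-count feature. Embedding failure is recorded as status
#' `removed_no_geometry`, not raised as an error.
#'
#' @param records A `molattn_records` frame or a character vector of SMILES.
#' @param embed_seed Integer seed for the conformer embedding.
#' @return A list with `records` (statuses updated) and `graphs`, a list
#'   parallel to the rows holding [mol_graph] objects (`NULL` where geometry
#'   failed or parsing failed).
#' @export
compute_geometry <- function(records, embed_seed = 42L) {
  if (is.character(records)) {
    records <- molattn_records(sprintf("mol_%d", seq_along(records)), records)
  }
  graphs <- vector("list", nrow(records))
  ok <- which(records$status == "ok")
  if (length(ok)) {
    desc <- backend_describe(records$smiles[ok], seed = embed_seed,
                             coords = "3d")
    failed <- desc$mols$idx[desc$mols$status == "embed_error"]
    records$status[ok[failed]] <- "removed_no_geometry"
    atoms_by <- split(desc$atoms, desc$atoms$idx)
    bonds_by <- split(desc$bonds, desc$bonds$idx)
    for (i in desc$mols$idx[desc$mols$status == "ok"]) {
      row <- ok[i]
      graphs[[row]] <- build_mol_graph(
        id = records$id[row], smiles = records$smiles[row],
        atoms = atoms_by[[as.character(i)]],
        bonds = bonds_by[[as.character(i)]]
      )
    }
  }
  names(graphs) <- records$id
  list(records = records, graphs = graphs)
}

#' Partition records into kept and removed sets
#'
#' Keeps records whose geometry succeeded and whose heavy-atom count does not
#' exceed `max_atoms` (boundary inclusive: a 60-atom molecule is kept at the
#' default). Every input record lands in exactly one of the two sets.
#'
#' @param records A `molattn_records` frame with geometry already attempted.
#' @param max_atoms Maximum heavy-atom count (default 60).
#' @return `list(kept=, removed=)`, two `molattn_records` frames; `removed`
#'   carries the reason in its `status` column.
#' @export
filter_molecules <- function(records, max_atoms = 60L) {
  too_big <- records$status == "ok" & records$n_atoms > max_atoms
  records$status[too_big] <- "removed_too_large"
  keep <- records$status == "ok"
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Label molecules by SMARTS substructure matching
#'
#' For each target, the label is 1 iff *every* SMARTS pattern in the target's
#' conjunction has at least one match in the molecule.
#'
#' @param records A `molattn_records` frame or character vector of SMILES.
#' @param targets A list of [target_spec()] objects, all of kind `"smarts"`.
#' @return Integer matrix, one row per molecule, one named column per target
#'   (`NA` rows for unparseable SMILES).
#' @export
label_substructures <- function(records, targets) {
  targets <- as_target_list(targets)
  if (any(vapply(targets, `[[`, "", "kind") != "smarts"))
    stop("label_substructures only applies to 'smarts' targets")
  smiles <- if (is.character(records)) records else records$smiles
  pats <- unique(unlist(lapply(targets, `[[`, "patterns")))
  m <- backend_match(smiles, pats)
  lab <- matrix(NA_integer_, nrow = length(smiles), ncol = length(targets),
                dimnames = list(NULL, names(targets)))
  for (t in seq_along(targets)) {
    cols <- match(targets[[t]]$patterns, pats)
    hit <- m$counts[, cols, drop = FALSE] > 0
    lab[, t] <- as.integer(rowSums(hit) == length(cols))
    lab[apply(is.na(m$counts[, cols, drop = FALSE]), 1, any), t] <- NA_integer_
  }
  lab
}

#' Atoms matched by each substructure target
#'
#' Returns, per molecule and target, the union of atom indices (1-based,
#' heavy atoms in SMILES parse order) over all matches of all patterns in the
#' target's conjunction. Used to define the target atom set of the
#' attention-localization statistics.
#'
#' @inheritParams label_substructures
#' @return A list (one element per molecule) of named lists of integer
#'   vectors, one per target.
#' @export
substructure_atoms <- function(records, targets) {
  targets <- as_target_list(targets)
  smiles <- if (is.character(records)) records else records$smiles
  pats <- unique(unlist(lapply(targets, `[[`, "patterns")))
  m <- backend_match(smiles, pats)
  lapply(seq_along(smiles), function(i) {
    out <- lapply(targets, function(tg) {
      cols <- match(tg$patterns, pats)
      sort(unique(unlist(m$atoms[[i]][cols])))
    })
    names(out) <- names(targets)
    out
  })
}

#' Merge child labels into a parent label
#'
#' Sets the parent label to 1 for every record where the parent or any child
#' label is 1 (e.g. folding 'berry', 'apple', ... into 'fruity'). Child labels
#' are unchanged; the operation is idempotent and never flips a 1 to 0.
#'
#' @param labels A matrix or data frame of 0/1 labels with named columns.
#' @param groups Named list: parent label name -> character vector of child
#'   label names. Unknown child names are an error.
#' @return The updated label table.
#' @export
merge_label_groups <- function(labels, groups) {
  for (parent in names(groups)) {
    children <- groups[[parent]]
    missing <- setdiff(c(parent, children), colnames(labels))
    if (length(missing))
      stop("unknown label column(s): ", paste(missing, collapse = ", "))
    any_child <- as.integer(
      rowSums(as.matrix(labels[, children, drop = FALSE]) == 1, na.rm = TRUE) > 0
    )
    labels[, parent] <- pmax(labels[, parent], any_child)
  }
  labels
}

#' Prepare a modeling dataset from molecules and targets
#'
#' Runs the full input pipeline: geometry embedding, size/geometry filtering,
#' and labeling (SMARTS matching for substructure targets, column pass-through
#' for `label_column` targets).
#'
#' @param x A `molattn_records` frame (from [read_molecule_table()]), a
#'   character vector of SMILES, or a path to a CSV/TSV file.
#' @param targets A list of [target_spec()] objects.
#' @param max_atoms Heavy-atom cutoff (default 60).
#' @param embed_seed Conformer embedding seed.
#' @param label_groups Optional label-merge groups, see [merge_label_groups()].
#' @return A `molattn_data` object: `records` (all, with statuses), `graphs`
#'   (kept molecules), `labels` (kept x targets integer matrix), `targets`.
#' @export
prepare_molecules <- function(x, targets, max_atoms = 60L, embed_seed = 42L,
                              label_groups = NULL) {
  targets <- as_target_list(targets)
  records <- if (is.character(x) && length(x) == 1 && file.exists(x)) {
    read_molecule_table(x)
  } else if (is.character(x)) {
    molattn_records(sprintf("mol_%d", seq_along(x)), x)
  } else x

  geo <- compute_geometry(records, embed_seed = embed_seed)
  parts <- filter_molecules(geo$records, max_atoms = max_atoms)
  kept <- parts$kept
  graphs <- geo$graphs[match(kept$id, names(geo$graphs))]

  kinds <- vapply(targets, `[[`, "", "kind")
  labels <- matrix(0L, nrow(kept), length(targets),
                   dimnames = list(kept$id, names(targets)))
  if (any(kinds == "smarts")) {
    sm <- label_substructures(kept, targets[kinds == "smarts"])
    labels[, kinds == "smarts"] <- sm
  }
  for (nm in names(targets)[kinds == "label_column"]) {
    if (!nm %in% names(kept))
      stop("label column '", nm, "' not present in records")
    labels[, nm] <- as.integer(kept[[nm]])
  }
  if (!is.null(label_groups)) labels <- merge_label_groups(labels, label_groups)

  structure(list(records = geo$records, graphs = graphs, labels = labels,
                 targets = targets, max_atoms = max_atoms,
                 embed_seed = embed_seed),
            class = "molattn_data")
}

#' @export
print.molattn_data <- function(x, ...) {
  st <- table(x$records$status)
  cat("molattn_data:", length(x$graphs), "molecules kept of",
      nrow(x$records), "\n")
  if (length(st) > 1) {
    rm <- st[names(st) != "ok"]
    cat("  removed:", paste(sprintf("%s=%d", names(rm), rm), collapse = ", "),
        "\n")
  }
  cat("  targets:", paste(colnames(x$labels), collapse = ", "), "\n")
  if (nrow(x$labels)) {
    pos <- colSums(x$labels, na.rm = TRUE)
    cat("  positives:", paste(sprintf("%s=%d", names(pos), pos),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a filtered molecule table
#'
#' @param records A `molattn_records` frame.
#' @param path Output CSV path; includes the `status` column.
#' @export
write_molecule_table <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
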