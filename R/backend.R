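#' @useDynLib molattn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom predict quantile var
#' @importFrom utils read.delim read.csv write.csv head
NULL

# ---- Python / RDKit backend -------------------------------------------------

# The chemistry layer (SMILES parsing, conformer embedding, SMARTS matching,
# 2D depiction) is delegated to inst/python/chem_backend.py, executed through
# a Python interpreter with rdkit. One process call per dataset; all exchange
# is via temporary TSV files.

find_python <- function() {
  cand <- getOption("molattn.python", "")
  if (!nzchar(cand)) cand <- Sys.getenv("MOLATTN_PYTHON", "")
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) {
    stop("No Python interpreter found; set options(molattn.python=) or ",
         "the MOLATTN_PYTHON environment variable.", call. = FALSE)
  }
  unname(cand)
}

backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "molattn")
  if (!nzchar(p)) stop("chem_backend.py not found in the installed package")
  p
}

run_backend <- function(args) {
  out <- suppressWarnings(
    system2(find_python(), c(shQuote(backend_script()), args),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed: ", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  invisible(out)
}

write_smiles_tsv <- function(smiles, path) {
  writeLines(paste(seq_along(smiles), smiles, sep = "\t"), path)
}

read_backend_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE, na.strings = "NA",
             comment.char = "")
}

# Parse + per-atom properties (and, optionally, one embedded 3D conformer).
# Returns list(mols=, atoms=, bonds=) data frames; `idx` indexes into `smiles`.
backend_describe <- function(smiles, seed = 42L, coords = c("3d", "none")) {
  coords <- match.arg(coords)
  td <- tempfile("molattn_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  sf <- file.path(td, "smiles.tsv")
  write_smiles_tsv(smiles, sf)
  run_backend(c("describe", "--smiles", shQuote(sf), "--outdir", shQuote(td),
                "--seed", as.integer(seed), "--coords", coords))
  list(mols  = read_backend_tsv(file.path(td, "mols.tsv")),
       atoms = read_backend_tsv(file.path(td, "atoms.tsv")),
       bonds = read_backend_tsv(file.path(td, "bonds.tsv")))
}

# SMARTS matching. Returns list(counts = molecules x patterns integer matrix
# (NA for unparseable molecules), atoms = list [molecule][pattern] of 1-based
# matched-atom index vectors (union over all matches)).
backend_match <- function(smiles, smarts) {
  td <- tempfile("molattn_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  sf <- file.path(td, "smiles.tsv")
  pf <- file.path(td, "smarts.tsv")
  write_smiles_tsv(smiles, sf)
  writeLines(paste(seq_along(smarts), smarts, sep = "\t"), pf)
  run_backend(c("match", "--smiles", shQuote(sf), "--smarts", shQuote(pf),
                "--outdir", shQuote(td)))
  m <- read_backend_tsv(file.path(td, "matches.tsv"))
  counts <- matrix(NA_integer_, nrow = length(smiles), ncol = length(smarts))
  counts[cbind(m$idx, m$pattern)] <- m$n_matches
  a <- read_backend_tsv(file.path(td, "match_atoms.tsv"))
  atoms <- replicate(length(smiles),
                     replicate(length(smarts), integer(0), simplify = FALSE),
                     simplify = FALSE)
  if (nrow(a)) {
    key <- split(a$atom + 1L, list(a$idx, a$pattern), drop = TRUE)
    for (nm in names(key)) {
      ij <- as.integer(strsplit(nm, ".", fixed = TRUE)[[1]])
      atoms[[ij[1]]][[ij[2]]] <- sort(key[[nm]])
    }
  }
  list(counts = counts, atoms = atoms)
}

# 2D depiction coordinates for rendering.
backend_depict <- function(smiles) {
  td <- tempfile("molattn_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  sf <- file.path(td, "smiles.tsv")
  write_smiles_tsv(smiles, sf)
  run_backend(c("depict", "--smiles", shQuote(sf), "--outdir", shQuote(td)))
  list(atoms = read_backend_tsv(file.path(td, "coords2d.tsv")),
       bonds = read_backend_tsv(file.path(td, "bonds2d.tsv")))
}

backend_sdf2smi <- function(sdf_path) {
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  run_backend(c("sdf2smi", "--sdf", shQuote(sdf_path), "--out", shQuote(out)))
  read_backend_tsv(out)
}
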