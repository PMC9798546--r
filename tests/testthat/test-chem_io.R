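# molecule tables, geometry, filtering, SMARTS labeling

fullerene <- paste0(
  "C12=C3C4=C5C6=C1C7=C8C9=C1C%10=C%11C(=C29)C3=C2C3=C4C4=C5C5=C9C6=C7C6=C7",
  "C8=C1C1=C8C%10=C%10C%11=C2C2=C3C3=C4C4=C5C5=C%11C%12=C(C6=C95)C7=C1C1=C%12",
  "C5=C%11C4=C3C3=C5C(=C81)C%10=C23")

test_that("reading a molecule table preserves rows, labels and parse status", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,fruity", "CCO,1", "C(C,0", "c1ccccc1,0"), path)
  rec <- read_molecule_table(path, label_columns = "fruity")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$status,
               c("ok", "removed_parse_error", "ok"))
  expect_equal(rec$fruity, c(1L, 0L, 0L))
  expect_equal(rec$n_atoms[c(1, 3)], c(3L, 6L))

  # tab-separated variant
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("smiles\tfruity", "CCO\t1"), tsv)
  expect_equal(read_molecule_table(tsv, label_columns = "fruity")$fruity, 1L)

  expect_error(read_molecule_table(path, smiles_col = "smi"), "not found")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,fruity", "CCO,2"), bad)
  expect_error(read_molecule_table(bad, label_columns = "fruity"),
               "non-binary.*row 1")
})

test_that("geometry: CO2 connectivity, bond lengths, symmetry, embed failure", {
  geo <- compute_geometry(c("O=C=O", "CCO", fullerene))
  co2 <- geo$graphs[[1]]
  expect_equal(sum(co2$adjacency) / 2, 2)       # exactly two bonds
  expect_equal(diag(co2$adjacency), rep(0, 3))
  expect_equal(co2$distance, t(co2$distance))
  expect_equal(diag(co2$distance), rep(0, 3))
  # bonded pairs sit at covalent bond lengths
  for (g in geo$graphs[1:2]) {
    bonded <- g$distance[g$adjacency == 1]
    expect_true(all(bonded > 0.9 & bonded < 2.0))
  }
  # default-settings embedding failure is recorded as data, not an error
  expect_equal(geo$records$status[3], "removed_no_geometry")
  expect_null(geo$graphs[[3]])
})

test_that("filtering is an exhaustive partition with the 60-atom boundary kept", {
  rec <- data.frame(
    id = paste0("m", 1:5),
    smiles = "",
    status = c("ok", "ok", "ok", "removed_no_geometry", "removed_parse_error"),
    n_atoms = c(61L, 60L, 5L, 10L, 0L), stringsAsFactors = FALSE)
  parts <- filter_molecules(rec, max_atoms = 60)
  expect_equal(parts$kept$id, c("m2", "m3"))          # 60 atoms inclusive
  expect_equal(parts$removed$status,
               c("removed_too_large", "removed_no_geometry",
                 "removed_parse_error"))
  expect_equal(nrow(parts$kept) + nrow(parts$removed), nrow(rec))
  expect_length(intersect(parts$kept$id, parts$removed$id), 0)
})

test_that("substructure labels implement conjunction semantics", {
  tg <- list(target_spec("ester", "C(=O)O"),
             target_spec("combo", c("CC(C)C", "cCc")))
  lab <- label_substructures(c("CCOC(C)=O", "CC(C)CC", "CC(C)Cc1ccc(Cc2ccccc2)cc1"),
                             tg)
  expect_equal(lab[, "ester"], c(1L, 0L, 0L))
  # first pattern matches but second absent -> 0; both present -> 1
  expect_equal(lab[, "combo"], c(0L, 0L, 1L))
  expect_error(target_spec("empty", character(0)), "at least one")
})

test_that("SMARTS labeling agrees with a brute-force subgraph oracle", {
  pats <- c("C(=O)O", "OO", "CC(C)C", "C=C", "C=O", "c1ccccc1", "N",
            "S", "COC", "CC(C)(C)C")
  smi <- withr::with_seed(42, {
    cfg <- generator_config(200, atom_range = c(4L, 12L), seed = 99,
                            target_prevalence = c("C(=O)O" = 0.25, "OO" = 0.2,
                                                  "c1ccccc1" = 0.3,
                                                  "CC(C)(C)C" = 0.2))
    as.character(generate_molecules(cfg))
  })
  targets <- lapply(seq_along(pats), function(i)
    target_spec(paste0("t", i), pats[i]))
  fast <- label_substructures(smi, targets)
  desc <- fixture_described(smi)
  atoms_by <- split(desc$atoms, desc$atoms$idx)
  bonds_by <- split(desc$bonds, desc$bonds$idx)
  patterns <- lapply(pats, parse_pattern)
  slow <- matrix(0L, length(smi), length(pats))
  for (i in seq_along(smi)) {
    mol <- mol_for_oracle(atoms_by[[as.character(i)]],
                          bonds_by[[as.character(i)]])
    for (j in seq_along(pats))
      slow[i, j] <- as.integer(oracle_smarts_match(mol, patterns[[j]]))
  }
  expect_equal(unname(fast), slow)
})

test_that("label-group merging is monotone and idempotent", {
  lab <- cbind(fruity = c(0L, 0L, 1L), berry = c(1L, 0L, 0L),
               apple = c(0L, 0L, 1L))
  grp <- list(fruity = c("berry", "apple"))
  m1 <- merge_label_groups(lab, grp)
  expect_equal(m1[, "fruity"], c(1L, 0L, 1L))   # child triggers parent
  expect_equal(m1[, "berry"], lab[, "berry"])   # children untouched
  expect_equal(merge_label_groups(m1, grp), m1) # idempotent
  expect_true(all(m1[, "fruity"] >= lab[, "fruity"]))  # never flips 1 -> 0
  expect_error(merge_label_groups(lab, list(fruity = "citrus")), "unknown")
})

test_that("substructure_atoms returns matched atom sets in parse order", {
  ta <- substructure_atoms("CCOC(C)=O", list(target_spec("ester", "C(=O)O")))
  # ester core of ethyl acetate: O3 (ester O), C4 (carbonyl C), O6 (=O)
  expect_equal(ta[[1]]$ester, c(3L, 4L, 6L))
})
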