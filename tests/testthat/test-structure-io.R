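test_that("single- and multi-model PDB files parse into consistent atom tables", {
  one_chain <- function(chain, serial0) {
    unlist(lapply(1:5, function(i) {
      pdb_line(serial0 + i, "CA", "GLY", chain, i,
               x = i * 5, y = if (chain == "A") 0 else 20, z = 0)
    }))
  }
  p1 <- write_pdb_fixture(c(one_chain("A", 0), one_chain("B", 10)))
  atoms <- suppressMessages(read_structures(p1))
  expect_equal(dplyr::n_distinct(atoms$model_id), 1)
  expect_equal(nrow(residue_keys(atoms)), 10)
  expect_setequal(unique(atoms$chain), c("A", "B"))

  body <- c(one_chain("A", 0), one_chain("B", 10))
  p3 <- write_pdb_fixture(c(
    "MODEL        1", body, "ENDMDL",
    "MODEL        2", body, "ENDMDL",
    "MODEL        3", body, "ENDMDL"))
  atoms3 <- suppressMessages(read_structures(p3))
  expect_equal(dplyr::n_distinct(atoms3$model_id), 3)
  keys_by_model <- split(
    res_id(atoms3$chain, atoms3$resseq, atoms3$icode), atoms3$model_id)
  expect_length(unique(lapply(keys_by_model, sort)), 1)

  ## parsing is order-stable on repeated reads
  expect_identical(atoms3, suppressMessages(read_structures(p3)))
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties to 'A'", {
  p <- write_pdb_fixture(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.4, altloc = "B"),
    pdb_line(3, "CB", "SER", "A", 1, 1, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line(4, "CB", "SER", "A", 1, 8, 8, 8, occ = 0.5, altloc = "A")))
  atoms <- suppressMessages(read_structures(p))
  ca <- atoms[atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0)            # occupancy 0.6 wins
  cb <- atoms[atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 8)            # occupancy tie: altloc 'A' wins
})

test_that("hydrogens are retained but flagged non-heavy; het groups flagged", {
  p <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "HA", "GLY", "A", 1, 0.5, 0, 0, element = "H"),
    pdb_line(3, "FE", "HEM", "A", 90, 5, 5, 5, element = "FE",
             record = "HETATM")))
  atoms <- suppressMessages(read_structures(p))
  expect_equal(nrow(atoms), 3)
  expect_false(atoms$is_heavy[atoms$atom == "HA"])
  expect_true(atoms$is_het[atoms$resname == "HEM"])
  expect_equal(nrow(residue_keys(atoms)), 1)  # het excluded by default
  expect_equal(nrow(residue_keys(atoms, include_het = TRUE)), 2)
})

test_that("blank element columns are inferred from atom names", {
  lines <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "  "),
    pdb_line(2, "HB2", "GLY", "A", 1, 1, 0, 0, element = "  "))
  p <- write_pdb_fixture(lines)
  expect_message(atoms <- read_structures(p), "inferred")
  expect_equal(atoms$element[atoms$atom == "CA"], "C")
  expect_equal(atoms$element[atoms$atom == "HB2"], "H")
  expect_false(atoms$is_heavy[atoms$atom == "HB2"])
})

test_that("residue-key mismatch across models is a hard error naming keys", {
  p <- write_pdb_fixture(c(
    "MODEL        1",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 4, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 3, 4, 0, 0),
    "ENDMDL"))
  expect_error(suppressMessages(read_structures(p)), "A:3")
})

test_that("empty or unparseable files are hard errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_structures(empty))
  expect_error(read_structures(tempfile(fileext = ".pdb")), "No files")
})

test_that("bead PDB writing round-trips coordinates and encodes delta as B-factor", {
  beads <- tibble::tibble(
    res1 = c("A:1", "A:2"), res2 = c("B:1", "B:2"),
    x = c(1.0, -2.25), y = c(0, 3.125), z = c(0, -7.5),
    delta = c(1, -0.45))
  beads <- dplyr::bind_cols(beads[, 1:5], delta = beads$delta,
                            delta_color(beads$delta))
  path <- tempfile(fileext = ".pdb")
  write_bead_pdb(beads, path)
  back <- suppressMessages(read_structures(path))
  expect_equal(nrow(back), 2)
  expect_true(all(back$resname == "BED"))
  expect_equal(back$bfactor, round(beads$delta, 2))
  expect_equal(back$x, beads$x, tolerance = 1e-3)
  expect_equal(back$y, beads$y, tolerance = 1e-3)
  expect_equal(back$z, beads$z, tolerance = 1e-3)
  ## companion colors TSV
  tsv <- readr::read_tsv(sub("\\.pdb$", "_colors.tsv", path),
                         show_col_types = FALSE)
  expect_equal(tsv$r, c(1, 0.55))
  ## magnitudes out of range rejected
  expect_error(write_bead_pdb(dplyr::mutate(beads, delta = 2), path),
               "\\[-1, 1\\]")
})

test_that("an empty bead list still writes a valid file pair", {
  beads <- tibble::tibble(res1 = character(), res2 = character(),
                          x = double(), y = double(), z = double(),
                          delta = double(), r = double(), g = double(),
                          b = double())
  path <- tempfile(fileext = ".pdb")
  write_bead_pdb(beads, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.pdb$", "_colors.tsv", path)))
  expect_true(any(grepl("^END", readLines(path))))
})

test_that("write_structures/read_structures round-trips keys, names and coordinates", {
  spec <- ensemble_spec(n_models = 2, chains = c(A = 4, B = 3),
                        conserved_contacts = list(c("A:2", "B:2")),
                        seed = 7)
  ens <- make_perturbed_ensembles(spec)
  dir <- file.path(tempdir(), "rt-models")
  write_structures(ens$wt, dir)
  back <- suppressMessages(read_structures(file.path(dir, "*.pdb")))
  expect_equal(dplyr::n_distinct(back$model_id), 2)
  expect_equal(residue_keys(back)[, c("chain", "resseq", "icode")],
               residue_keys(ens$wt)[, c("chain", "resseq", "icode")])
  orig <- dplyr::arrange(ens$wt, model_id, chain, resseq, atom)
  got <- dplyr::arrange(back, model_id, chain, resseq, atom)
  expect_equal(got$x, orig$x, tolerance = 1e-3)
  expect_equal(got$atom, orig$atom)
})
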