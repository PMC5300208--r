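pdb_atom_line <- function(serial, name, res, resid, x, y, z, chain = "A",
                          element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, res, chain, resid, x, y, z, element)
}

three_model_pdb <- function(n_atoms = 10, drop_from_model = NULL) {
  lines <- character(0)
  for (m in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    keep <- seq_len(if (!is.null(drop_from_model) && m == drop_from_model)
      n_atoms - 1 else n_atoms)
    for (i in keep) {
      lines <- c(lines, pdb_atom_line(i, paste0("C", i), "LIG", 1,
                                      i + m / 10, 0, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  write_pdb_text(c(lines, "END"))
}

test_that("multi-model PDB files map one MODEL block to one frame", {
  ens <- read_multimodel_pdb(three_model_pdb())
  expect_s3_class(ens, "gag_ensemble")
  expect_equal(n_frames(ens), 3)
  expect_equal(n_atoms(ens), 10)
  expect_equal(ens$times, c(0, 1, 2))

  # a single-structure file (no MODEL records) is one frame
  single <- write_pdb_text(c(
    pdb_atom_line(1, "N", "GLY", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", 1, 1.5, 0, 0),
    pdb_atom_line(3, "C", "GLY", 1, 2.2, 1.2, 0), "END"))
  expect_equal(n_frames(read_multimodel_pdb(single)), 1)
})

test_that("models with inconsistent atom counts are rejected by name", {
  expect_error(read_multimodel_pdb(three_model_pdb(drop_from_model = 2)),
               class = "gagmimic_malformed_ensemble")
  expect_error(read_multimodel_pdb(three_model_pdb(drop_from_model = 2)),
               regexp = "model")
})

test_that("unreadable coordinates raise a parse error naming the line", {
  bad <- write_pdb_text(c(
    pdb_atom_line(1, "C1", "LIG", 1, 0, 0, 0),
    sub("   0.000", "   x.000", pdb_atom_line(2, "C2", "LIG", 1, 1, 0, 0),
        fixed = TRUE), "END"))
  expect_error(read_multimodel_pdb(bad), class = "gagmimic_parse")
  expect_error(read_multimodel_pdb(bad), regexp = "line 2")
})

test_that("PDB write -> read round trip preserves identity and coordinates", {
  gen <- generate_chain_ensemble(6, 4, 5, 0.5, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(gen$ensemble, path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 4)
  expect_equal(back$topology$atoms$atom_name, gen$ensemble$topology$atoms$atom_name)
  expect_equal(back$topology$atoms$residue_id, gen$ensemble$topology$atoms$residue_id)
  # PDB fixed-width precision: 3 decimals
  expect_equal(back$coords, gen$ensemble$coords, tolerance = 1e-3)
  expect_true(max(abs(back$coords - gen$ensemble$coords)) <= 5.01e-4)
  # CONECT records survive
  expect_equal(back$topology$bonds, gen$ensemble$topology$bonds)
})

test_that("coordinate tables are dense, round-trip exactly, and reject gaps", {
  top <- simple_topology(3)
  coords <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
  ens <- conformer_ensemble(top, coords)
  path <- tempfile(fileext = ".csv")
  write_coord_table(ens, path)
  back <- read_coord_table(path, top)
  expect_equal(back$coords, ens$coords)   # full stored precision
  expect_equal(n_frames(back), 2)

  # drop one (frame, atom) row -> incomplete-table error
  df <- readr::read_csv(path, show_col_types = FALSE)
  broken <- tempfile(fileext = ".csv")
  readr::write_csv(df[-(which(df$frame == 1 & df$atom_index == 2)), ], broken)
  expect_error(read_coord_table(broken, top), class = "gagmimic_incomplete_table")

  # duplicate a row -> duplicate error
  dup <- tempfile(fileext = ".csv")
  readr::write_csv(rbind(df, df[1, ]), dup)
  expect_error(read_coord_table(dup, top), class = "gagmimic_duplicate")
})

test_that("bond inference follows covalent radii with hydrogen uniqueness", {
  at <- tibble::tibble(atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
                       residue_name = "X", residue_id = 1)
  top <- topology(at)
  # N-H at 1.0 A bonded; O far away not
  t1 <- infer_bonds(top, rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0)))
  expect_equal(unname(t1$bonds), rbind(c(1L, 2L)))
  # C and O at 3.0 A are not bonded
  t2 <- infer_bonds(simple_topology(2), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(t2$bonds), 0)
  # water: exactly two O-H bonds
  wat <- topology(tibble::tibble(atom_name = c("O", "H1", "H2"),
                                 element = c("O", "H", "H"),
                                 residue_name = "HOH", residue_id = 1))
  t3 <- infer_bonds(wat, rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  expect_equal(nrow(t3$bonds), 2)
  expect_true(all(t3$bonds[, 1] == 1))
  # a hydrogen between two heavy atoms binds only the nearest
  trio <- topology(tibble::tibble(atom_name = c("O1", "H", "O2"),
                                  element = c("O", "H", "O"),
                                  residue_name = "X", residue_id = 1))
  t4 <- infer_bonds(trio, rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.1, 0, 0)))
  expect_equal(unname(t4$bonds), rbind(c(1L, 2L)))
  # unknown element symbol is an explicit error
  bad <- topology(tibble::tibble(atom_name = c("Q1", "Q2", "Q3", "Q4"),
                                 element = "Qq", residue_name = "X",
                                 residue_id = 1))
  expect_error(infer_bonds(bad, matrix(rnorm(12), 4)),
               class = "gagmimic_unknown_element")
})

test_that("frame windows are half-open with an anchored stride grid", {
  top <- simple_topology(2)
  ens <- conformer_ensemble(top, array(rnorm(200 * 2 * 3), dim = c(200, 2, 3)),
                            times = 1:200)
  sub <- select_frames(ens, frame_window(100, 200, 10))
  expect_equal(n_frames(sub), 10)
  expect_equal(sub$times, seq(110, 200, 10))
  # half-open: a frame exactly at start_time is excluded, at end_time included
  expect_false(100 %in% sub$times)
  expect_true(200 %in% sub$times)
  # full-range window at the native stride is the identity
  full <- select_frames(ens, frame_window(0, 200, 1))
  expect_equal(full$coords, ens$coords)
  # disjoint window and incompatible stride are explicit errors
  expect_error(select_frames(ens, frame_window(300, 400, 10)),
               class = "gagmimic_empty_window")
  expect_error(select_frames(ens, frame_window(0, 200, 2.5)),
               class = "gagmimic_stride")
})

test_that("nested frame windows compose like their intersection", {
  ens <- conformer_ensemble(simple_topology(2),
                            array(rnorm(120 * 2 * 3), dim = c(120, 2, 3)),
                            times = 1:120)
  a <- select_frames(select_frames(ens, frame_window(20, 120, 1)),
                     frame_window(20, 80, 5))
  b <- select_frames(ens, frame_window(20, 80, 5))
  expect_equal(a$coords, b$coords)
  expect_equal(a$times, b$times)
})

test_that("atom selection preserves order, commutes with frame selection, and
          refuses to return nothing", {
  at <- tibble::tibble(
    atom_name = c("C1", "H1", "C2", "H2", "O1", "H3", "S1", "O2", "H4", "N1"),
    element = c("C", "H", "C", "H", "O", "H", "S", "O", "H", "N"),
    residue_name = "LIG", residue_id = 1,
    chain_id = c(rep("A", 6), rep("B", 4)))
  ens <- conformer_ensemble(topology(at),
                            array(rnorm(6 * 10 * 3), dim = c(6, 10, 3)),
                            times = 1:6)
  heavy <- select_atoms(ens, element != "H")
  expect_equal(n_atoms(heavy), 6)
  expect_false("H" %in% heavy$topology$atoms$element)
  chainA <- select_atoms(ens, chain_id == "A")
  expect_equal(unique(chainA$topology$atoms$chain_id), "A")
  expect_error(select_atoms(ens, element == "Xe"),
               class = "gagmimic_empty_selection")
  # commutation with frame selection
  w <- frame_window(2, 6, 2)
  ab <- select_frames(select_atoms(ens, element != "H"), w)
  ba <- select_atoms(select_frames(ens, w), element != "H")
  expect_equal(ab$coords, ba$coords)
  expect_equal(ab$topology$atoms, ba$topology$atoms)
})

test_that("written PDB files are readable by an independent structure
          library", {
  gen <- generate_chain_ensemble(6, 3, 5, 0.5, seed = 23)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(gen$ensemble, path)
  ref <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
  expect_equal(dim(ref$xyz)[1], 3)                 # three models
  xyz1 <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(xyz1, frame_coords(gen$ensemble, 1),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ref$atom$resid[1], "CHN")
})

test_that("the command-line interface round-trips fixtures through its
          subcommands", {
  cli <- system.file("cli", "gagmimic.R", package = "gagmimic")
  expect_true(nzchar(cli))
  dir <- tempfile(); dir.create(dir)
  run <- function(...) system2("Rscript", c(cli, ...), stdout = TRUE,
                               stderr = TRUE)
  run("simulate", "mixture", "--seed", "4", "--out", dir)
  expect_true(file.exists(file.path(dir, "mixture.pdb")))
  out_csv <- file.path(dir, "clusters.csv")
  run("cluster", "--ensemble", file.path(dir, "mixture.pdb"),
      "--radius", "2.0", "--seed", "7", "--out", out_csv)
  cl <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_equal(nrow(cl), 120)
  expect_equal(sort(unique(cl$label)), 1:3)
  series_csv <- file.path(dir, "series.csv")
  run("free-analyze", "--ensemble", file.path(dir, "mixture.pdb"),
      "--metrics", "eed,mvee", "--out", series_csv)
  s <- readr::read_csv(series_csv, show_col_types = FALSE)
  expect_setequal(unique(s$metric),
                  c("EED", "MVEE_volume", "axis_longest", "axis_mid",
                    "axis_shortest"))
})
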