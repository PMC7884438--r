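test_that("fixtures round-trip through PDB and mmCIF with identity and precision preserved", {
  fx <- make_grid(4, 12, seed = 11)
  for (fmt in c("pdb", "mmcif")) {
    dir <- withr::local_tempdir()
    path <- write_fixture(fx, dir, fmt)
    m <- suppressWarnings(load_structure(path))
    expect_equal(nrow(m$atoms), fx$ledger$n_atoms)
    # residue identity tuples exact, author numbering untouched
    r0 <- pigmentnet:::model_residues(fx$model)
    r1 <- pigmentnet:::model_residues(m)
    expect_equal(r1[c("chain", "comp_id", "seq_num", "icode")],
                 r0[c("chain", "comp_id", "seq_num", "icode")])
    # coordinates at format precision (1e-3 A fields)
    expect_lt(max(abs(m$atoms$x - fx$model$atoms$x)), 1e-3)
    expect_lt(max(abs(m$atoms$y - fx$model$atoms$y)), 1e-3)
    expect_lt(max(abs(m$atoms$z - fx$model$atoms$z)), 1e-3)
  }
})

test_that("a file holding only water records is an empty-model error", {
  fx <- make_pair(8, seed = 3)
  waters <- fx$model
  waters$atoms <- waters$atoms[waters$atoms$atom_name == "MG", ]
  waters$atoms$comp_id <- c("HOH", "WAT")
  waters$atoms$atom_name <- "O"
  waters$atoms$element <- "O"
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(waters, path, "pdb")
  expect_error(load_structure(path), "no atoms")
})

test_that("waters are excluded and nothing else is", {
  fx <- make_pair(8, seed = 3)
  withwat <- fx$model
  wat <- withwat$atoms[withwat$atoms$atom_name == "MG", ][1, ]
  wat$comp_id <- "HOH"
  wat$atom_name <- "O"
  wat$element <- "O"
  wat$seq_num <- 901L
  wat[c("x", "y", "z")] <- c(50, 50, 50)
  withwat$atoms <- rbind(withwat$atoms, wat)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(withwat, path, "pdb")
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), fx$ledger$n_atoms)
  expect_false(any(m$atoms$comp_id == "HOH"))
})

test_that("unparseable input names the file in the error", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_X", "loop_", "_atom_site.id", "not a valid row at all",
               "x y z"), path)
  expect_error(load_structure(path), "could not parse|no atoms")
})

test_that("altloc resolution keeps the highest occupancy, ties by tag", {
  fx <- make_pair(8, seed = 3)
  alt <- fx$model
  base <- alt$atoms[alt$atoms$atom_name %in% c("MG", "C1A") &
                      alt$atoms$seq_num == 601, ]
  a <- base; a$altloc <- "A"
  b <- base; b$altloc <- "B"; b$x <- b$x + 5
  a$occupancy <- c(0.30, 0.50)  # MG, C1A
  b$occupancy <- c(0.70, 0.50)
  alt$atoms <- rbind(a, b)
  alt$atoms$seq_num <- 601L
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(alt, path, "pdb")
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), 2L)
  mg <- m$atoms[m$atoms$atom_name == "MG", ]
  expect_equal(mg$altloc, "B")               # occupancy 0.70 wins
  expect_equal(mg$x, b$x[1], tolerance = 1e-3)
  c1a <- m$atoms[m$atoms$atom_name == "C1A", ]
  expect_equal(c1a$altloc, "A")              # tie: first altloc tag
  expect_equal(c1a$x, a$x[2], tolerance = 1e-3)
})

test_that("subunit maps resolve lookups, warn on mismatches, and reject duplicates", {
  fx <- make_ligand_fixture("HIS", 2.2, 4.0, seed = 2)
  model <- fx$model
  model$subunit_of[] <- "unknown"

  cfg <- data.frame(entry = "*", chain = c("A", "B"),
                    subunit = c("Lhca1", "PsaF"), stringsAsFactors = FALSE)
  m <- apply_subunit_map(model, cfg)
  expect_equal(pigmentnet:::subunit_chain(m, "PsaF"), "B")
  expect_equal(pigmentnet:::chain_subunit(m, "A"), "Lhca1")

  cfg_bad_chain <- rbind(cfg, data.frame(entry = "*", chain = "Z",
                                         subunit = "PsaA"))
  expect_warning(apply_subunit_map(model, cfg_bad_chain),
                 "not in model")

  cfg_dup <- data.frame(entry = "*", chain = c("A", "B"),
                        subunit = c("PsaF", "PsaF"))
  expect_error(apply_subunit_map(model, cfg_dup), "duplicate")

  # empty config: every chain unknown, with a warning
  empty <- data.frame(entry = character(), chain = character(),
                      subunit = character())
  expect_warning(m2 <- apply_subunit_map(model, empty), "unknown")
  expect_true(all(m2$subunit_of == "unknown"))
})

test_that("subunit map files parse, validate vocabulary, and ship for the deposited entries", {
  path <- withr::local_tempfile(fileext = ".map")
  writeLines(c("# test map", "SYN1 A Lhca1", "SYN1 B PsaF"), path)
  m <- read_subunit_map(path)
  expect_equal(m$subunit, c("Lhca1", "PsaF"))

  writeLines("SYN1 A NotASubunit", path)
  expect_error(read_subunit_map(path), "vocabulary")

  for (entry in c("6L35", "4XK8", "6IJO")) {
    dm <- default_subunit_map(entry)
    expect_s3_class(dm, "subunit_map")
    expect_true(all(dm$subunit %in% subunit_vocabulary()))
  }
})

test_that("writing rejects atom names wider than the PDB field", {
  fx <- make_pair(8, seed = 4)
  fx$model$atoms$atom_name[1] <- "TOOLONG"
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(fx$model, path, "pdb"), "4-character")
})
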