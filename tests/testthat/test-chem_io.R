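test_that("SMILES parsing produces indexed, standardized structures", {
  b <- parse_structure("c1ccccc1")
  expect_equal(n_atoms(b), 6)
  expect_equal(n_bonds(b), 6)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$bonds$aromatic))
  expect_identical(b$atoms$atom_id, 0:5)

  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  expect_equal(n_atoms(nn), 13)
  expect_equal(sum(nn$atoms$aromatic), 10)
  expect_equal(nn$atoms$charge[2], 1L)   # nitro N

  # stereo stripping: chiral and achiral forms canonicalise identically
  expect_identical(canonical_smiles(parse_structure("[C@H](N)(C)O")),
                   canonical_smiles(parse_structure("C(N)(C)O")))

  # kekulized input is aromatized
  expect_identical(canonical_smiles(parse_structure("C1=CC=CC=C1")),
                   canonical_smiles(parse_structure("c1ccccc1")))

  expect_error(parse_structure("c1ccccc"), "parse")
  expect_error(parse_structure("Q"), "parse")
})

test_that("MOL block parsing agrees with SMILES parsing", {
  mol <- paste(
    "benzene", "", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "  1  2  4  0", "  2  3  4  0", "  3  4  4  0",
    "  4  5  4  0", "  5  6  4  0", "  6  1  4  0",
    "M  END", sep = "\n")
  s <- parse_structure(mol)
  expect_equal(n_atoms(s), 6)
  expect_identical(canonical_smiles(s), canonical_smiles(parse_structure("c1ccccc1")))
  expect_identical(s$name, "benzene")
})

test_that("standardization is idempotent and strips salts deterministically", {
  # largest-organic-component rule
  s <- standardize(parse_structure("CC(=O)O.[Na+]"), strip_salts = TRUE)
  expect_identical(canonical_smiles(s), canonical_smiles(parse_structure("CC(=O)O")))
  expect_error(standardize(parse_structure("[Na+].[Cl-]"), strip_salts = TRUE),
               "organic")

  # idempotence over a set of randomized toy structures
  lib <- make_toy_library(50, seed = 11)
  for (st in lib$structures) {
    once <- standardize(st, strip_salts = TRUE)
    twice <- standardize(once, strip_salts = TRUE)
    expect_identical(canonical_smiles(once), canonical_smiles(twice))
  }
})

test_that("canonical SMILES is invariant to atom order and round-trips", {
  pairs <- list(
    c("N(c1ccccc1)C(=O)C", "CC(=O)Nc1ccccc1"),
    c("O=[N+]([O-])c1ccccc1", "c1ccc(cc1)[N+](=O)[O-]"),
    c("OC(=O)c1ccccc1N", "Nc1ccccc1C(=O)O")
  )
  for (p in pairs) {
    expect_identical(canonical_smiles(parse_structure(p[1])),
                     canonical_smiles(parse_structure(p[2])))
  }
  # parse -> write -> parse fixpoint
  for (smi in c("c1ccc2ccccc2c1", "C1CO1", "O=C1C=CC(=O)C=C1",
                "c1cc[nH]c1", "CC(C)(C)c1ccc(O)cc1")) {
    c1 <- canonical_smiles(parse_structure(smi))
    expect_identical(canonical_smiles(parse_structure(c1)), c1)
  }
})

test_that("read_structures reads SMILES and SDF, skipping bad records", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", "CCC propane"), tmp)
  ss <- read_structures(tmp, "smiles")
  expect_length(ss, 3)
  expect_identical(ss[[1]]$name, "benzene")

  bad <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1", "notasmiles((", "CC"), bad)
  expect_warning(ss2 <- read_structures(bad, "smiles"), "skipped")
  expect_length(ss2, 2)

  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines("((bad", empty)
  expect_error(suppressWarnings(read_structures(empty, "smiles")), "no valid")

  # write -> read round trip preserves heavy-atom counts
  out <- withr::local_tempfile(fileext = ".smi")
  write_structures(ss, out)
  back <- read_structures(out, "smiles")
  expect_identical(vapply(back, n_atoms, 0L), vapply(ss, n_atoms, 0L))
})

test_that("parser agrees with an independent toolkit on basic facts", {
  # RDKit (via the system python) as an independent oracle for heavy-atom
  # counts, aromatic-atom counts and ring counts on a fixed panel
  py <- Sys.which("python")
  skip_if(py == "", "no python available")
  smis <- c("c1ccccc1", "O=[N+]([O-])c1cccc2ccccc12", "Nc1ccccc1C(=O)O",
            "C1CO1", "c1ccc2c(c1)ccc1ccccc21", "CC(=O)Nc1ccccc1")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for smi in sys.argv[1:]:",
    "    m = Chem.MolFromSmiles(smi)",
    "    n_arom = sum(1 for a in m.GetAtoms() if a.GetIsAromatic())",
    "    print(m.GetNumAtoms(), n_arom, len(Chem.GetSSSR(m)))",
    sep = "\n")
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  res <- tryCatch(system2(py, c(f, shQuote(smis)), stdout = TRUE, stderr = FALSE),
                  warning = function(w) NULL, error = function(e) NULL)
  skip_if(is.null(res) || length(res) != length(smis), "rdkit oracle unavailable")
  expected <- do.call(rbind, lapply(strsplit(res, " "), as.integer))
  for (i in seq_along(smis)) {
    s <- parse_structure(smis[i])
    expect_equal(n_atoms(s), expected[i, 1], info = smis[i])
    expect_equal(sum(s$atoms$aromatic), expected[i, 2], info = smis[i])
    expect_equal(length(sssr(s)), expected[i, 3], info = smis[i])
  }
})
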