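three_key_lib <- function() {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("key_id\tsmarts\tdescription\tunit",
               "0\t[N+](=O)[O-]\tnitro\t1",
               "1\t[N+0]c1ccccc1\taromatic amine\t0",
               "2\tC1CO1\tepoxide\t0"), tmp)
  on.exit(unlink(tmp), add = TRUE)
  load_key_library(tmp)
}

test_that("structural keys set bits with match witnesses", {
  lib <- three_key_lib()
  nb <- parse_structure("O=[N+]([O-])c1ccccc1")
  fv <- structural_key_fp(nb, lib)
  expect_identical(fv$bits, c(1L, 0L, 0L))
  wit <- fv$provenance[[1]]
  expect_length(wit, 1)
  expect_setequal(wit[[1]]$atoms, c(0, 1, 2))   # O, N+, O-
  expect_length(wit[[1]]$bonds, 2)

  expect_identical(structural_key_fp(parse_structure("c1ccccc1"), lib)$bits,
                   c(0L, 0L, 0L))

  # two nitro groups -> one bit, two witnesses (brute-force match count)
  dnb <- parse_structure("O=[N+]([O-])c1cccc([N+](=O)[O-])c1")
  fv2 <- structural_key_fp(dnb, lib)
  expect_identical(fv2$bits[1], 1L)
  expect_length(fv2$provenance[[1]], 2)
  expect_length(match_pattern("[N+](=O)[O-]", dnb), 2)
})

test_that("key library loading validates input", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("key_id\tsmarts\tdescription", "0\t((bad\tbroken"), tmp)
  expect_error(load_key_library(tmp), "bad SMARTS")
  writeLines(c("key_id\tsmarts\tdescription", "0\tC\tcarbon", "0\tN\tdup"), tmp)
  expect_error(load_key_library(tmp), "unique")
  # 3-column files load with unit defaulting to 0
  writeLines(c("key_id\tsmarts\tdescription", "0\tC\tcarbon"), tmp)
  lib <- load_key_library(tmp)
  expect_identical(lib$unit, 0L)
  unlink(tmp)
})

test_that("hashed path fingerprints are deterministic and discriminate", {
  b <- parse_structure("c1ccccc1")
  n <- parse_structure("c1ccc2ccccc2c1")
  f1 <- hashed_path_fp(b, 6, 1024)
  expect_identical(f1$bits, hashed_path_fp(parse_structure("C1=CC=CC=C1"), 6, 1024)$bits)
  expect_false(identical(f1$bits, hashed_path_fp(n, 6, 1024)$bits))
  expect_error(hashed_path_fp(b, 6, 1000), "power of two")
  expect_null(f1$provenance)
})

test_that("fragment fingerprints are subsets of the parent's", {
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  rg <- build_reduced_graph(nn)
  frags <- enumerate_fragments(rg)

  # whole-structure fragment reproduces the parent fingerprint
  root <- frags[[length(frags)]]
  expect_identical(fp_for_fragment(nn, root)$bits, structural_key_fp(nn)$bits)

  parent_keys <- structural_key_fp(nn)$bits
  parent_hash <- hashed_path_fp(nn)$bits
  for (f in frags) {
    fk <- fp_for_fragment(nn, f, "structural_keys")
    expect_true(all(fk$bits <= parent_keys))
    fh <- fp_for_fragment(nn, f, "hashed_path")
    expect_true(all(fh$bits <= parent_hash))
  }

  # nitro key bit of the nitro fragment maps to the nitro atoms of the query
  lib <- default_key_library()
  nitro_frag <- frags[[1]]
  expect_setequal(nitro_frag$atom_ids, c(0, 1, 2))
  fv <- fp_for_fragment(nn, nitro_frag, "structural_keys", lib)
  nitro_bit <- which(lib$smarts == "[N+](=O)[O-]")
  expect_identical(fv$bits[nitro_bit], 1L)
  expect_setequal(fv$provenance[[nitro_bit]][[1]]$atoms, c(0, 1, 2))
})

test_that("subset property holds across a randomized structure panel", {
  lib20 <- make_toy_library(20, seed = 3)
  checked <- 0L
  for (s in lib20$structures) {
    pk <- structural_key_fp(s)$bits
    ph <- hashed_path_fp(s)$bits
    frags <- enumerate_fragments(build_reduced_graph(s))
    for (f in frags) {
      expect_true(all(fp_for_fragment(s, f, "structural_keys")$bits <= pk))
      expect_true(all(fp_for_fragment(s, f, "hashed_path")$bits <= ph))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 100)   # the panel exercises a meaningful fragment count
})
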