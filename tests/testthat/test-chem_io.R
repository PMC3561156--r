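# Library reading, standardization, filtering, deduplication, subsampling.

write_smi <- function(lines) {
  tf <- tempfile(fileext = ".smi")
  writeLines(lines, tf)
  tf
}

test_that("read_library parses a SMILES file with ids", {
  tf <- write_smi(c("c1ccccc1 benzene", "CCO ethanol", "CC(=O)O acetic"))
  lib <- read_library(tf, "smiles", name = "demo")
  expect_s3_class(lib, "scaff_library")
  expect_equal(nrow(lib), 3L)
  expect_equal(lib$id, c("benzene", "ethanol", "acetic"))
  expect_equal(lib$n_rings, c(1L, 0L, 0L))
})

test_that("malformed records are skipped or fatal depending on strict", {
  tf <- write_smi(c("c1ccccc1 a", "CCO b", "notasmiles))( c", "CC(=O)O d", "CCN e"))
  expect_message(lib <- read_library(tf, "smiles"), "skipped 1")
  expect_equal(nrow(lib), 4L)
  expect_error(read_library(tf, "smiles", strict = TRUE), "3")
})

test_that("missing and empty files are fatal", {
  expect_error(read_library(tempfile(), "smiles"), "not found")
  tf <- write_smi(character(0))
  expect_error(read_library(tf, "smiles"), "empty")
})

test_that("SDF input round-trips against the SMILES reader", {
  smis <- c(x1 = "c1ccccc1", x2 = "CC(=O)Oc1ccccc1C(=O)O", x3 = "C1CC2CCC1C2")
  sdf <- ChemmineR::smiles2sdf(smis)
  tf <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, tf)
  lib <- read_library(tf, "sdf")
  expect_equal(nrow(lib), 3L)
  expect_setequal(lib$smiles, canonical_smiles(smis))
})

test_that("standardization keeps the largest organic fragment", {
  lib <- library_from_smiles(c("CC(=O)[O-].[Na+]", "O", "c1ccccc1", "[13CH4]"),
                             name = "salts")
  std <- suppressMessages(standardize_library(lib))
  # water has no carbon and is dropped; the sodium counter-ion is stripped
  expect_equal(nrow(std), 3L)
  expect_true(canonical_smiles("CC(=O)[O-]") %in% std$smiles)
  expect_false(any(grepl("Na", std$smiles)))
  # isotope labels cleared
  expect_identical(std$smiles[std$id == "M4"], "C")
  # clean organics are untouched
  expect_identical(std$smiles[std$id == "M3"], "c1ccccc1")
})

test_that("MW filter uses a strict cutoff and preserves order", {
  lib <- library_from_smiles(c("c1ccccc1", "CCO", "CC(=O)O"), name = "mw")
  mw_benzene <- lib$mw[1]
  kept <- filter_by_mw(lib, max_mw = mw_benzene)
  # the record weighing exactly the cutoff is excluded
  expect_false("M1" %in% kept$id)
  expect_identical(kept$id, c("M2", "M3"))
  expect_identical(nrow(filter_by_mw(lib, 1000)), 3L)
  expect_identical(nrow(filter_by_mw(lib, 1)), 0L)
})

test_that("deduplication is stereo-aware and keeps first occurrences", {
  lib <- library_from_smiles(
    c("c1ccccc1", "C1=CC=CC=C1", "Cc1ccccc1", "C/C=C/C", "C/C=C\\C"),
    name = "dup")
  dd <- deduplicate(lib)
  # benzene written twice collapses; cis/trans butene stays distinct
  expect_equal(nrow(dd), 4L)
  expect_identical(dd$id[1], "M1")
  expect_identical(deduplicate(dd)$id, dd$id)
})

test_that("random subsampling is seed-reproducible", {
  lib <- library_from_smiles(sprintf("C%s", strrep("C", 1:60)), name = "alkanes")
  s1 <- subsample_random(lib, 20, seed = 9)
  s2 <- subsample_random(lib, 20, seed = 9)
  s3 <- subsample_random(lib, 20, seed = 10)
  expect_identical(s1$id, s2$id)
  expect_false(identical(sort(s1$id), sort(s3$id)))
  expect_equal(nrow(subsample_random(lib, 0, seed = 1)), 0L)
  expect_setequal(subsample_random(lib, nrow(lib), seed = 1)$id, lib$id)
  expect_error(subsample_random(lib, nrow(lib) + 1, seed = 1), "sample")
})

test_that("MW-distribution matching hits the target within KS 0.05", {
  # synthetic MW spread: interleaved homologous series give a near-continuous
  # grid of molecular weights from ~100 to ~500 Da
  src_smi <- c(sprintf("C(=O)%s", strrep("C", 6:34)),
               sprintf("OC%s", strrep("C", 6:34)),
               sprintf("NCC%s", strrep("C", 6:34)))
  src_smi <- src_smi[order(vapply(parse_smiles(src_smi),
                                  scaffscape:::mol_mw, numeric(1)))]
  base <- library_from_smiles(rep(src_smi, each = 25), name = "src")
  # triangular target: weight rises then falls across the MW-sorted series
  w <- pmin(seq_along(src_smi), rev(seq_along(src_smi)))
  tgt <- library_from_smiles(rep(src_smi, times = ceiling(w / 6)), name = "tgt")
  out <- match_mw_distribution(base, tgt, n = 1500, bin_width = 25, seed = 3)
  expect_equal(nrow(out), 1500L)
  # brute-force KS on the sampled set
  ks <- suppressWarnings(stats::ks.test(out$mw, tgt$mw)$statistic)
  expect_lt(unname(ks), 0.05)
  expect_equal(unname(ks), attr(out, "ks_distance"), tolerance = 1e-12)
  # determinism
  out2 <- match_mw_distribution(base, tgt, n = 1500, bin_width = 25, seed = 3)
  expect_identical(out$id, out2$id)
})

test_that("prepare composition is idempotent on its own output", {
  lib <- library_from_smiles(
    c("c1ccccc1", "c1ccccc1", "Cc1ccccc1", "CC(=O)[O-].[Na+]", "CCCCCCCC"),
    name = "prep")
  prep <- function(l) deduplicate(filter_by_mw(suppressMessages(standardize_library(l)), 600))
  once <- prep(lib)
  twice <- prep(once)
  expect_identical(once$id, twice$id)
  expect_identical(once$smiles, twice$smiles)
  expect_identical(once$mw, twice$mw)
})
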