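# Synthetic library generator: planted structure, determinism, census.

test_that("pools load and every entry is chemically valid", {
  pools <- load_pools()
  expect_named(pools, c("ring_units", "linkers", "side_chains"))
  expect_gte(nrow(pools$ring_units), 40L)
  expect_gte(nrow(pools$linkers), 10L)
  expect_gte(nrow(pools$side_chains), 15L)
  expect_true(all(pools$ring_units$n_rings >= 1L))
  expect_true(all(pools$ring_units$n_sites >= 1L))
  # bridged and fused systems are represented so those code paths run
  expect_true(any(pools$ring_units$class == "bridged"))
  expect_true(any(pools$ring_units$class == "fused"))
  expect_true(all(pools$side_chains$n_rings == 0L))
})

test_that("a single-scaffold config plants that framework everywhere", {
  pools <- load_pools()
  pools$ring_units <- pools$ring_units[pools$ring_units$name == "benzene", ]
  cfg <- generator_config(n_molecules = 40, n_scaffolds = 1,
                          rings_law = c(`1` = 1), pools = pools, seed = 3)
  g <- generate_library(cfg)
  expect_identical(unique(g$manifest$scaffold), canonical_smiles("c1ccccc1"))
  mur <- vapply(g$library$mol, function(m) mol_to_smiles(murcko_framework(m)),
                character(1))
  expect_identical(unique(mur), canonical_smiles("c1ccccc1"))
})

test_that("zipf frequencies land within multinomial sampling error", {
  cfg <- generator_config(n_molecules = 3000, n_scaffolds = 3, zipf_s = 1,
                          seed = 17)
  g <- generate_library(cfg, chains = FALSE)
  counts <- table(factor(g$manifest$scaffold_id, levels = 1:3))
  p <- (1:3)^-1; p <- p / sum(p)  # planted proportions 1 : 1/2 : 1/3
  expected <- 3000 * p
  # within 4 standard deviations of the multinomial expectation
  sd <- sqrt(3000 * p * (1 - p))
  expect_true(all(abs(as.integer(counts) - expected) < 4 * sd))
})

test_that("generation is deterministic per seed", {
  cfg <- generator_config(n_molecules = 60, n_scaffolds = 10, seed = 23)
  g1 <- generate_library(cfg)
  g2 <- generate_library(cfg)
  expect_identical(g1$manifest$smiles, g2$manifest$smiles)
  expect_identical(g1$manifest$chain, g2$manifest$chain)
  g3 <- generate_library(generator_config(n_molecules = 60, n_scaffolds = 10,
                                          seed = 24))
  expect_false(identical(g1$manifest$smiles, g3$manifest$smiles))
})

test_that("every generated molecule parses, standardizes and round-trips", {
  g <- generate_library(generator_config(n_molecules = 80, n_scaffolds = 12,
                                         seed = 29))
  expect_identical(nrow(g$library), 80L)
  expect_false(anyNA(g$library$smiles))
  std <- standardize_library(g$library)
  expect_identical(nrow(std), 80L)
  expect_identical(std$smiles, g$library$smiles)
})

test_that("manifest census aggregates a hand-checked mini manifest", {
  mani <- tibble::tibble(
    id = sprintf("m%d", 1:10),
    smiles = NA_character_,
    scaffold_id = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    scaffold = rep(c("BIP", "ANT", "BNZ"), c(4, 3, 3)),
    n_levels = rep(c(2L, 3L, 1L), c(4, 3, 3)),
    chain = rep(list(c("bz", "BIP"), c("bz", "np", "ANT"), "BNZ"), c(4, 3, 3)))
  mur <- manifest_census(mani, "murcko")
  expect_identical(mur$scaffold, c("BIP", "ANT", "BNZ"))
  expect_identical(mur$count, c(4L, 3L, 3L))
  l0 <- manifest_census(mani, 0)
  expect_identical(l0$scaffold[1], "bz")    # 7 molecules share Level 0 benzene
  expect_identical(l0$count, c(7L, 3L))
  l1 <- manifest_census(mani, 1)
  expect_identical(sum(l1$count), 7L)       # three-molecule BNZ group has no Level 1
  l9 <- manifest_census(mani, 9)
  expect_identical(nrow(l9), 0L)
})

test_that("pipeline recovery of planted frequencies is exact at small n", {
  g <- generate_library(generator_config(n_molecules = 120, n_scaffolds = 10,
                                         seed = 37))
  ch <- scaffold_chains(g$library)
  n <- nrow(g$library)
  p1 <- count_frequencies(ch[ch$level == 1L, ], n)
  m1 <- manifest_census(g$manifest, 1)
  expect_identical(p1$scaffold, m1$scaffold)
  expect_identical(p1$count, m1$count)
  topch <- ch |> dplyr::group_by(molecule_id) |>
    dplyr::filter(level == max(level)) |> dplyr::ungroup()
  pm <- count_frequencies(topch, n)
  mm <- manifest_census(g$manifest, "murcko")
  expect_identical(pm$scaffold, mm$scaffold)
  expect_identical(pm$count, mm$count)
})

test_that("generator configs read back from YAML", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("n_molecules: 25", "n_scaffolds: 4", "frequency_law: uniform",
               "sidechain_lambda: 0.5", "seed: 12"), tf)
  cfg <- read_generator_config(tf)
  expect_identical(cfg$n_molecules, 25L)
  expect_identical(cfg$frequency_law, "uniform")
  g <- generate_library(cfg, chains = FALSE)
  expect_identical(nrow(g$library), 25L)
})
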