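# Murcko decomposition against hand expectations and the brute-force oracle.

can <- function(s) canonical_smiles(s)

test_that("murcko framework matches hand-derived cases", {
  cases <- list(
    toluene = "c1ccccc1",            # methyl pruned
    diphenylmethane = "c1ccc(Cc2ccccc2)cc1",  # linker retained
    ethylbiphenyl = "c1ccc(-c2ccccc2)cc1",    # ethyl pruned, ring-ring bond kept
    acetophenone = "c1ccccc1",       # whole acetyl side chain pruned
    cyclohexanone = "O=C1CCCCC1",    # ring-attached carbonyl O retained
    methylenecyclohexane = "C=C1CCCCC1",  # exocyclic =CH2 retained
    benzene = "c1ccccc1")
  for (nm in names(cases)) {
    expect_identical(mol_to_smiles(murcko_framework(FIXTURE_MOLS[[nm]])),
                     can(cases[[nm]]), info = nm)
  }
  for (nm in c("butane", "ethanol", "acetone", "trimethylamine")) {
    expect_null(murcko_framework(FIXTURE_MOLS[[nm]]), info = nm)
  }
})

test_that("murcko framework is idempotent", {
  for (nm in c("toluene", "diphenylmethane", "coumarin", "npa", "adamantane",
               "benzylpyridine", "methylcyclohexane")) {
    m1 <- murcko_framework(FIXTURE_MOLS[[nm]])
    s1 <- mol_to_smiles(m1)
    m2 <- murcko_framework(parse_smiles(s1)[[1]])
    expect_identical(mol_to_smiles(m2), s1, info = nm)
  }
})

test_that("murcko atom set equals the brute-force keep-set on every fixture", {
  for (nm in names(ring_bearing_fixture())) {
    mol <- FIXTURE_MOLS[[nm]]
    mine <- murcko_framework(mol)
    expect_identical(sort(attr(mine, "parent_atoms")), o_murcko_atoms(mol),
                     info = nm)
  }
})

test_that("graph framework forces carbon skeleton with single bonds", {
  expect_identical(mol_to_smiles(graph_framework(FIXTURE_MOLS[["pyridine"]])),
                   can("C1CCCCC1"))
  expect_identical(mol_to_smiles(graph_framework(FIXTURE_MOLS[["benzene"]])),
                   can("C1CCCCC1"))
  expect_identical(mol_to_smiles(graph_framework(FIXTURE_MOLS[["biphenyl"]])),
                   can("C1CCC(CC1)C1CCCCC1"))
})

test_that("graph framework is invariant under heteroatom substitution", {
  groups <- list(
    c("benzene", "pyridine", "pyrimidine"),
    c("cyclopentane", "thf", "pyrrolidine"),
    c("naphthalene", "quinoline"))
  for (g in groups) {
    gf <- vapply(g, function(nm)
      mol_to_smiles(graph_framework(murcko_framework(FIXTURE_MOLS[[nm]]))),
      character(1))
    expect_length(unique(gf), 1L)
  }
})

test_that("ring extraction counts circuit rank rings", {
  expect_length(extract_rings(FIXTURE_MOLS[["naphthalene"]]), 2L)
  expect_length(extract_rings(FIXTURE_MOLS[["biphenyl"]]), 2L)
  expect_length(extract_rings(FIXTURE_MOLS[["cubane"]]), 5L)
  expect_length(extract_rings(FIXTURE_MOLS[["butane"]]), 0L)
  rings <- extract_rings(FIXTURE_MOLS[["biphenyl"]])
  expect_identical(unique(mol_to_smiles(rings)), can("c1ccccc1"))
})

test_that("ring assemblies split at non-ring bonds only", {
  expect_length(extract_ring_assemblies(FIXTURE_MOLS[["biphenyl"]]), 2L)
  expect_length(extract_ring_assemblies(FIXTURE_MOLS[["naphthalene"]]), 1L)
  expect_length(extract_ring_assemblies(FIXTURE_MOLS[["diphenylmethane"]]), 2L)
  asm <- extract_ring_assemblies(FIXTURE_MOLS[["diphenylmethane"]])
  expect_identical(unique(mol_to_smiles(asm)), can("c1ccccc1"))
  # assembly atom sets match the oracle's ring systems (plus exocyclic atoms)
  for (nm in names(ring_bearing_fixture())) {
    mol <- FIXTURE_MOLS[[nm]]
    mine <- lapply(extract_ring_assemblies(mol), function(a)
      sort(attr(a, "parent_atoms")))
    oracle <- o_ring_systems(mol)
    expect_equal(length(mine), length(oracle), info = nm)
  }
})

test_that("bridge assemblies require a ring pair sharing two bonds", {
  expect_length(extract_bridge_assemblies(FIXTURE_MOLS[["norbornane"]]), 1L)
  expect_length(extract_bridge_assemblies(FIXTURE_MOLS[["adamantane"]]), 1L)
  expect_length(extract_bridge_assemblies(FIXTURE_MOLS[["naphthalene"]]), 0L)
  expect_length(extract_bridge_assemblies(FIXTURE_MOLS[["biphenyl"]]), 0L)
  expect_length(extract_bridge_assemblies(FIXTURE_MOLS[["spiro44nonane"]]), 0L)
  # agreement with exhaustive shared-bond enumeration over the oracle basis
  for (nm in names(ring_bearing_fixture())) {
    mol <- FIXTURE_MOLS[[nm]]
    expect_identical(length(extract_bridge_assemblies(mol)) > 0L,
                     o_has_bridge(mol), info = nm)
  }
})

test_that("linkers and side chains follow the path definitions", {
  p <- extract_acyclic_parts(FIXTURE_MOLS[["diphenylmethane"]])
  expect_identical(mol_to_smiles(p$linkers), "C")
  expect_length(p$side_chains, 0L)
  # a direct ring-ring bond contributes no linker atoms
  p <- extract_acyclic_parts(FIXTURE_MOLS[["ethylbiphenyl"]])
  expect_length(p$linkers, 0L)
  expect_identical(mol_to_smiles(p$side_chains), "*CC")
  p <- extract_acyclic_parts(FIXTURE_MOLS[["toluene"]])
  expect_length(p$linkers, 0L)
  expect_identical(mol_to_smiles(p$side_chains), "*C")
  # acyclic molecules are outside the partition
  p <- extract_acyclic_parts(FIXTURE_MOLS[["butane"]])
  expect_length(p$linkers, 0L)
  expect_length(p$side_chains, 0L)
  # bibenzyl: one two-carbon linker
  p <- extract_acyclic_parts(FIXTURE_MOLS[["bibenzyl"]])
  expect_identical(mol_to_smiles(p$linkers), can("CC"))
})

test_that("atom partition covers every heavy atom exactly once", {
  for (nm in names(ring_bearing_fixture())) {
    mol <- FIXTURE_MOLS[[nm]]
    asm <- extract_ring_assemblies(mol)
    parts <- extract_acyclic_parts(mol)
    asm_atoms <- unlist(lapply(asm, function(a) attr(a, "parent_atoms")))
    link_atoms <- unlist(lapply(parts$linkers, function(a) attr(a, "parent_atoms")))
    side_atoms <- unlist(lapply(parts$side_chains, function(a) attr(a, "parent_atoms")))
    all_atoms <- c(asm_atoms, link_atoms, side_atoms)
    expect_identical(sort(all_atoms), seq_len(length(mol$elem)), info = nm)
  }
})

test_that("decompose_library emits tidy rows and a census", {
  lib <- library_from_smiles(
    c("Cc1ccccc1", "Cc1ccccc1", "c1ccc(Cc2ccccc2)cc1", "CCCC"),
    name = "tiny")
  d <- decompose_library(lib)
  expect_named(d, c("molecule_id", "representation", "smiles"))
  # acyclic butane contributes nothing
  expect_false("M4" %in% d$molecule_id)
  cen <- decomposition_census(d)
  mur <- cen[cen$representation == "murcko", ]
  expect_identical(mur$n_total, 3L)
  expect_identical(mur$n_unique, 2L)
  sc <- cen[cen$representation == "side_chain", ]
  expect_identical(sc$n_total, 2L)  # two toluene methyls, counted per occurrence
  expect_identical(sc$n_unique, 1L)
})
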