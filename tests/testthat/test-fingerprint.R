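# Circular fingerprints and Tanimoto similarity.

# naive reference: features as canonical neighborhood descriptions built by
# breadth-first expansion with explicit string environments, no hashing
naive_env_features <- function(mol, radius = 3) {
  n <- length(mol$elem)
  adj <- o_adj(mol)
  b <- mol$bonds
  bond_order <- function(i, j) {
    k <- which((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
    b[k[1], 3]
  }
  ring_atoms <- o_ring_atoms(mol)
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
           F = 1, Cl = 1, Br = 1, I = 1)
  nh <- function(a) {
    v <- val[mol$elem[a]]
    if (is.na(v)) v <- 0
    if (mol$elem[a] %in% c("N", "O")) v <- v + mol$charge[a]
    ords <- sum(b[b[, 1] == a | b[, 2] == a, 3])
    max(0, round(v - ords))
  }
  base <- function(a) paste0(mol$elem[a], "/", length(adj[[a]]), "/",
                             mol$charge[a], "/", nh(a), "/",
                             as.integer(a %in% ring_atoms))
  desc <- vapply(seq_len(n), base, character(1))
  feats <- paste0("0|", desc)
  cur <- desc
  for (r in seq_len(radius)) {
    nxt <- character(n)
    for (a in seq_len(n)) {
      nb <- sort(vapply(adj[[a]], function(w)
        paste0(bond_order(a, w), ":", cur[w]), character(1)))
      nxt[a] <- paste0(cur[a], "(", paste(nb, collapse = ","), ")")
    }
    cur <- nxt
    feats <- c(feats, paste0(r, "|", cur))
  }
  unique(feats)
}

naive_tanimoto <- function(m1, m2) {
  f1 <- naive_env_features(m1); f2 <- naive_env_features(m2)
  length(intersect(f1, f2)) / length(union(f1, f2))
}

test_that("fingerprints are invariant to input atom ordering", {
  pairs <- list(
    c("Cc1ccccc1", "c1ccccc1C"),
    c("O=C(Nc1ccccc1)c1ccccc1", "c1ccccc1NC(=O)c1ccccc1"),
    c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"))
  for (p in pairs) {
    f1 <- circular_fingerprint(p[1])
    f2 <- circular_fingerprint(p[2])
    expect_identical(unclass(f1), unclass(f2), info = p[1])
  }
})

test_that("single-atom molecules yield only radius features of that atom", {
  f <- circular_fingerprint("C")
  expect_true(length(f) >= 1L)
  expect_true(all(grepl("^[0-3]:", f)))
  # all radii collapse to the same environment for a lone atom: one feature
  # per radius at most, and radius-0 present
  expect_true(any(grepl("^0:", f)))
})

test_that("tanimoto follows set arithmetic", {
  f1 <- structure(c("a:x", "a:y", "a:z"), class = "scaff_fp")
  f2 <- structure(c("a:y", "a:z", "a:w"), class = "scaff_fp")
  expect_equal(tanimoto(f1, f2), 0.5)  # 2 shared / 4 total
  expect_equal(tanimoto(f1, f1), 1)
  f3 <- structure(c("b:q"), class = "scaff_fp")
  expect_equal(tanimoto(f1, f3), 0)
})

test_that("hashed similarity structure agrees with a naive reimplementation", {
  smis <- c("c1ccccc1", "C1CCCCC1", "Cc1ccccc1", "c1ccncc1", "CC1CCCCC1",
            "c1ccc2ccccc2c1", "C1CC2CCC1C2")
  mols <- parse_smiles(smis)
  fps <- lapply(mols, circular_fingerprint)
  for (i in seq_along(smis)) for (j in seq_along(smis)) {
    mine <- tanimoto(fps[[i]], fps[[j]])
    ref <- naive_tanimoto(mols[[i]], mols[[j]])
    # identity and disjointness must agree exactly between implementations
    expect_identical(mine == 1, ref == 1, info = paste(smis[i], smis[j]))
    expect_identical(mine == 0, ref == 0, info = paste(smis[i], smis[j]))
  }
  # benzene vs cyclohexane: aromatic and aliphatic rings share nothing
  expect_equal(tanimoto(fps[[1]], fps[[2]]), 0)
  expect_lt(tanimoto(fps[[1]], fps[[2]]), 1)
})

test_that("1 - tanimoto respects the triangle inequality on fixture scaffolds", {
  smis <- unique(vapply(names(ring_bearing_fixture())[1:20], function(nm)
    mol_to_smiles(murcko_framework(FIXTURE_MOLS[[nm]])), character(1)))
  fps <- lapply(smis, circular_fingerprint)
  n <- length(fps)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- 1 - tanimoto(fps[[i]], fps[[j]])
  expect_true(all(abs(D - t(D)) < 1e-12))
  expect_true(all(diag(D) == 0))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    expect_true(D[i, j] <= D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("the batched similarity matrix matches pairwise calls", {
  smis <- c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "C1CCCCC1")
  fps <- lapply(smis, circular_fingerprint)
  M <- scaffscape:::tanimoto_matrix(fps, fps)
  for (i in seq_along(fps)) for (j in seq_along(fps)) {
    expect_equal(M[i, j], tanimoto(fps[[i]], fps[[j]]))
  }
})
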