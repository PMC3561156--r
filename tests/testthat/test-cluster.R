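# Maxmin clustering: center count, determinism, oracle agreement.

scaffold_pool <- function(n, seed = 5) {
  # distinct scaffolds drawn from assembled pool structures
  cfg <- generator_config(n_molecules = n * 8L, n_scaffolds = n, seed = seed,
                          frequency_law = "uniform", sidechain_lambda = 0)
  g <- generate_library(cfg, chains = FALSE)
  scaf <- unique(g$manifest$scaffold)
  stopifnot(length(scaf) >= n)
  tibble::tibble(scaffold = scaf[seq_len(n)], count = seq_len(n) + 2L)
}

test_that("center count is ceil(N / target size)", {
  sc <- scaffold_pool(24, seed = 31)
  for (target in c(50, 10, 7)) {
    model <- cluster_scaffolds(sc, target_avg_size = target, seed = 1)
    expect_identical(length(attr(model, "centers")),
                     as.integer(ceiling(nrow(sc) / target)))
    expect_identical(sort(unique(model$cluster)),
                     seq_len(ceiling(nrow(sc) / target)))
  }
  expect_error(cluster_scaffolds(sc, target_avg_size = 0, seed = 1), "positive")
})

test_that("a single scaffold forms cluster 1 with zero distance", {
  model <- cluster_scaffolds(tibble::tibble(scaffold = "c1ccccc1", count = 3L),
                             target_avg_size = 50, seed = 1)
  expect_identical(model$cluster, 1L)
  expect_true(model$is_center)
  expect_identical(model$distance_to_closest, 0)
  expect_identical(model$cluster_size, 1L)
})

test_that("model invariants hold: sizes sum to N, centers at distance 0", {
  sc <- scaffold_pool(30, seed = 8)
  model <- cluster_scaffolds(sc, target_avg_size = 10, seed = 4)
  sizes <- model |> dplyr::distinct(cluster, cluster_size)
  expect_identical(sum(sizes$cluster_size), nrow(sc))
  expect_true(all(model$distance_to_closest[model$is_center] == 0))
  expect_true(all(model$distance_to_closest >= 0 & model$distance_to_closest <= 1))
})

test_that("clustering agrees with a brute-force maxmin oracle at N = 30", {
  sc <- scaffold_pool(30, seed = 13)
  model <- cluster_scaffolds(sc, target_avg_size = 10, seed = 2)
  # oracle: direct O(N^2) distances, greedy maxmin, nearest-center assignment
  fps <- lapply(sc$scaffold, circular_fingerprint)
  N <- length(fps)
  D <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) D[i, j] <- 1 - tanimoto(fps[[i]], fps[[j]])
  k <- ceiling(N / 10)
  centers <- withr::with_seed(2, sample.int(N, 1))
  while (length(centers) < k) {
    mind <- apply(D[, centers, drop = FALSE], 1, min)
    best <- max(mind)
    tied <- which(mind >= best - 1e-12)
    centers <- c(centers, tied[order(sc$scaffold[tied])][1])
  }
  assign <- apply(D[, centers, drop = FALSE], 1, which.min)
  assign[centers] <- seq_len(k)
  expect_identical(attr(model, "centers"), sc$scaffold[centers])
  expect_identical(model$cluster, as.integer(assign))
})

test_that("same seed reproduces the model bit-exactly, center count is stable", {
  sc <- scaffold_pool(25, seed = 21)
  m1 <- cluster_scaffolds(sc, target_avg_size = 10, seed = 7)
  m2 <- cluster_scaffolds(sc, target_avg_size = 10, seed = 7)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- cluster_scaffolds(sc, target_avg_size = 10, seed = 8)
  expect_identical(length(attr(m3, "centers")), length(attr(m1, "centers")))
})

test_that("more scaffold islands yield more populated clusters", {
  # two libraries with the same target size but different vocabulary breadth
  red <- generate_library(generator_config(300, n_scaffolds = 8, seed = 51),
                          chains = FALSE)
  div <- generate_library(generator_config(300, n_scaffolds = 80,
                                           frequency_law = "uniform", seed = 52),
                          chains = FALSE)
  tab_r <- manifest_census(red$manifest, "murcko")
  tab_d <- manifest_census(div$manifest, "murcko")
  m_r <- cluster_scaffolds(tab_r, target_avg_size = 10, seed = 3)
  m_d <- cluster_scaffolds(tab_d, target_avg_size = 10, seed = 3)
  expect_gt(length(attr(m_d, "centers")), length(attr(m_r, "centers")))
})
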