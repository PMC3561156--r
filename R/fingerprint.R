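# ---------------------------------------------------------------------------
# Circular (ECFP-style) fingerprints and Tanimoto overlap tables.
#
# Features are sparse (radius, hash) pairs: each atom starts from an invariant
# tuple (element, degree, charge, implicit H count, ring membership) and is
# iteratively re-hashed together with its sorted (bond order, neighbor hash)
# pairs out to radius diameter/2. The feature set of a molecule is the union
# over radii 0..diameter/2 — binary presence semantics, no folding, so exact
# feature-set identity is meaningful for the "= 1" row of overlap tables.
# ---------------------------------------------------------------------------

.elem_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                  S = 16, Cl = 17, Br = 35, I = 53, "*" = 0,
                  Na = 11, K = 19, Li = 3, Ca = 20, Mg = 12, Fe = 26, Zn = 30,
                  Se = 34, As = 33)

# deterministic integer mixing in double arithmetic (exact below 2^53)
hash_ints <- function(x) {
  h <- 0
  for (v in x) h <- (h * 1000003 + (v + 7)) %% 2147483647
  h
}

#' Circular fingerprint of a scaffold
#'
#' @param mol a molecule object or SMILES string.
#' @param diameter even bond diameter of the largest environment (default 6,
#'   i.e. radius 3).
#' @return character vector of feature identifiers (`"radius:hash"`), sorted;
#'   class `scaff_fp`.
#' @export
circular_fingerprint <- function(mol, diameter = 6L) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  if (is.null(mol) || n_atoms(mol) == 0L) stop("cannot fingerprint an empty structure")
  stopifnot(diameter %% 2 == 0)
  radius <- diameter %/% 2L
  n <- n_atoms(mol)
  deg <- atom_degree(mol)
  nh <- implicit_h(mol)
  rb <- ring_bond_ids(mol)
  inring <- integer(n); inring[ring_atom_ids(mol, rb)] <- 1L
  an <- .elem_number[mol$elem]; an[is.na(an)] <- 0
  inv <- vapply(seq_len(n), function(a)
    hash_ints(c(an[a], deg[a], mol$charge[a], nh[a], inring[a])), numeric(1))
  feats <- paste0(0L, ":", inv)
  adj <- adjacency(mol)
  for (r in seq_len(radius)) {
    newinv <- numeric(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      if (length(nb$nbr) > 0L) {
        ord <- order(nb$order, inv[nb$nbr])
        pairs <- as.numeric(rbind(nb$order[ord], inv[nb$nbr][ord]))
      } else pairs <- numeric(0)
      newinv[a] <- hash_ints(c(r, inv[a], pairs))
    }
    inv <- newinv
    feats <- c(feats, paste0(r, ":", inv))
  }
  structure(sort(unique(feats)), class = "scaff_fp")
}

#' Tanimoto similarity of two fingerprints
#'
#' @param a,b fingerprints from [circular_fingerprint()].
#' @return |intersection| / |union|, in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  i <- sum(a %in% b)
  i / (length(a) + length(b) - i)
}

# fingerprints for a character vector of SMILES, parsed in one batch
fingerprint_set <- function(smiles, diameter = 6L) {
  mols <- parse_smiles(smiles)
  lapply(seq_along(mols), function(i) {
    if (is.null(mols[[i]])) stop("unparsable scaffold: ", smiles[i])
    circular_fingerprint(mols[[i]], diameter)
  })
}

# sparse feature matrix (features x molecules) for fast pairwise Tanimoto
fp_matrix <- function(fps) {
  feats <- sort(unique(unlist(fps, use.names = FALSE)))
  ii <- unlist(lapply(fps, function(f) match(f, feats)), use.names = FALSE)
  jj <- rep(seq_along(fps), lengths(fps))
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(feats), length(fps)))
}

# full pairwise Tanimoto similarity between two fingerprint lists
tanimoto_matrix <- function(fpsA, fpsB = fpsA) {
  MA <- fp_matrix(c(fpsA, fpsB))
  A <- MA[, seq_along(fpsA), drop = FALSE]
  B <- MA[, length(fpsA) + seq_along(fpsB), drop = FALSE]
  inter <- as.matrix(Matrix::crossprod(A, B))
  sa <- lengths(fpsA); sb <- lengths(fpsB)
  un <- outer(sa, sb, "+") - inter
  inter / un
}

#' Cross-library scaffold overlap table
#'
#' For every scaffold of library A, the maximum Tanimoto similarity to any
#' scaffold of library B is computed on circular fingerprints; the table
#' counts A-scaffolds meeting each similarity cutoff. The cutoff-1 row uses
#' identity semantics (similarity exactly 1, i.e. identical feature sets);
#' every other row uses ">= cutoff"; the cutoff-0 row equals |A| by
#' definition (every scaffold is trivially similar at cutoff 0, even against
#' an empty B).
#'
#' @param setA,setB character vectors of unique scaffold SMILES.
#' @param cutoffs descending similarity grid (default 1.0, 0.9, ..., 0.0).
#' @param diameter fingerprint diameter (default 6).
#' @param names length-2 character vector naming the two libraries (used in
#'   the table's `direction` attribute).
#' @return an object of class `scaff_overlap`: tibble with `cutoff` and
#'   `count`, with attributes `direction` (`"A in B"` names) and `max_sim`
#'   (per-A-scaffold maximum similarity).
#' @export
cross_library_overlap <- function(setA, setB, cutoffs = seq(1, 0, by = -0.1),
                                  diameter = 6L, names = c("A", "B")) {
  stopifnot(!is.unsorted(rev(cutoffs)))
  if (anyDuplicated(setA)) stop("setA must be deduplicated")
  if (anyDuplicated(setB)) stop("setB must be deduplicated")
  fpsA <- fingerprint_set(setA, diameter)
  if (length(setB) == 0L) {
    maxsim <- rep(0, length(setA))
  } else {
    fpsB <- fingerprint_set(setB, diameter)
    sim <- tanimoto_matrix(fpsA, fpsB)
    maxsim <- apply(sim, 1L, max)
  }
  eps <- 1e-12
  count <- vapply(cutoffs, function(ct) {
    if (ct >= 1) sum(maxsim >= 1 - eps)
    else if (ct <= 0) length(setA)
    else sum(maxsim >= ct - eps)
  }, numeric(1))
  structure(tibble::tibble(cutoff = cutoffs, count = as.integer(count)),
            direction = paste(names[1], "in", names[2]), max_sim = maxsim,
            class = c("scaff_overlap", class(tibble::tibble())))
}

#' Overlap tables for every ordered pair of libraries
#'
#' @param scaffold_sets named list of character vectors (unique scaffolds per
#'   library).
#' @param cutoffs descending similarity grid.
#' @param diameter fingerprint diameter.
#' @return tibble in the layout of a published overlap table: one row per
#'   cutoff, one count column per ordered pair (`"A in B"`).
#' @export
overlap_table <- function(scaffold_sets, cutoffs = seq(1, 0, by = -0.1),
                          diameter = 6L) {
  nms <- names(scaffold_sets)
  stopifnot(length(nms) >= 2L)
  out <- tibble::tibble(cutoff = cutoffs)
  for (a in nms) for (b in nms) {
    if (a == b) next
    ov <- cross_library_overlap(scaffold_sets[[a]], scaffold_sets[[b]],
                                cutoffs, diameter, names = c(a, b))
    out[[paste(a, "in", b)]] <- ov$count
  }
  out
}
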